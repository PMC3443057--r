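#' Construct an ExpressionStudy
#'
#' Container for a gene x sample expression matrix with a binary phenotype.
#' Rows are genes (unique symbols after probe collapsing), columns samples.
#' Labels assign every sample to one of two pathological conditions.
#'
#' @param values numeric matrix, genes x samples, with dimnames set.
#' @param labels character/factor of length `ncol(values)`; exactly two
#'   distinct values, each with at least 2 samples.
#' @param name dataset identifier.
#' @return An object of class `ExpressionStudy` with elements `genes`,
#'   `samples`, `values`, `labels` (factor with two levels) and `name`.
#' @export
expression_study <- function(values, labels, name = "study") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse probes first")
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two sample classes required, got ", nlevels(labels))
  if (any(table(labels) < 2L))
    stop("each class needs >= 2 samples")
  structure(
    list(genes = rownames(values), samples = colnames(values),
         values = values, labels = labels, name = name),
    class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("ExpressionStudy '%s': %d genes x %d samples (%s: %d, %s: %d)\n",
              x$name, length(x$genes), length(x$samples),
              names(tab)[1], tab[1], names(tab)[2], tab[2]))
  cat(sprintf("  missing values: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column holds gene/probe identifiers, header row holds sample
#' identifiers. Blank cells and "NA" become missing values. CRLF line ends
#' and trailing whitespace are tolerated.
#'
#' @param path file path.
#' @param label_spec named character vector mapping sample id -> class label,
#'   covering every sample in the header.
#' @param name dataset identifier (defaults to file name).
#' @return An [expression_study()].
#' @export
read_expression_matrix <- function(path, label_spec,
                                   name = basename(path)) {
  lines <- read_clean_lines(path)
  if (length(lines) < 2L) stop("expression file needs header plus data rows")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- trimws(header[-1])
  missing_samp <- setdiff(names(label_spec), samples)
  if (length(missing_samp))
    stop("label_spec names samples absent from header: ",
         paste(missing_samp, collapse = ", "))
  unlabeled <- setdiff(samples, names(label_spec))
  if (length(unlabeled))
    stop("samples without a label: ", paste(unlabeled, collapse = ", "))

  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    length(row) <- length(samples) + 1L   # pad short rows (trailing blanks)
    ids[i] <- trimws(row[1])
    cells <- trimws(row[-1])
    cells[cells == "" | toupper(cells) == "NA"] <- NA
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d ('%s'), column '%s': '%s'",
                   i + 1L, ids[i], samples[bad[1]], cells[bad[1]]))
    vals[i, ] <- num
  }
  dimnames(vals) <- list(ids, samples)
  expression_study(vals, label_spec[samples], name = name)
}

#' Write an ExpressionStudy as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]; values are written with full
#' precision (up to 15 significant digits) so a round trip is lossless at
#' printed precision. Missing values are written as "NA".
#'
#' @param study an ExpressionStudy.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(study, path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", study$samples), collapse = "\t"), con)
  txt <- format(study$values, digits = 15, trim = TRUE, scientific = FALSE)
  txt[is.na(study$values)] <- "NA"
  writeLines(paste(study$genes, apply(txt, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Impute missing expression values from nearest-neighbour genes
#'
#' Each missing cell is replaced by the mean, over the `k` genes nearest in
#' Euclidean distance (computed on samples where both genes are observed and
#' rescaled to the full sample count), of those genes' values in the same
#' sample. Mirrors the behaviour of the standard k-nearest-neighbour
#' expression imputer.
#'
#' @param study an ExpressionStudy, possibly with missing values.
#' @param k number of neighbour genes (default 10).
#' @return A complete ExpressionStudy; non-missing entries are unchanged.
#' @export
impute_missing <- function(study, k = 10) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (k < 1) stop("k must be >= 1")
  x <- study$values
  if (!anyNA(x)) return(study)
  if (k >= nrow(x)) stop("k must be smaller than the number of genes")
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing))
    stop("gene(s) missing in all samples cannot be imputed: ",
         paste(study$genes[all_missing], collapse = ", "))
  frac <- rowMeans(is.na(x))
  if (any(frac >= 0.5))
    warning(sum(frac >= 0.5), " gene(s) have >= 50% missing values")

  need <- which(rowSums(is.na(x)) > 0L)
  out <- x
  for (g in need) {
    d <- gene_euclidean_dist(x, g)
    ord <- order(d, na.last = NA)
    miss_cols <- which(is.na(x[g, ]))
    for (s in miss_cols) {
      donors <- ord[!is.na(x[ord, s])]
      donors <- utils::head(donors, k)
      if (!length(donors))
        stop("no observed neighbour available for gene ", study$genes[g],
             " in sample ", study$samples[s])
      out[g, s] <- mean(x[donors, s])
    }
  }
  study$values <- out
  study
}

# Euclidean distance from gene g to every other gene over co-observed
# samples, rescaled by sqrt(n_samples / n_shared); NA when nothing co-observed.
gene_euclidean_dist <- function(x, g) {
  diff <- sweep(x, 2, x[g, ])
  sq <- diff^2
  nshared <- rowSums(!is.na(sq))
  d <- sqrt(rowSums(sq, na.rm = TRUE) * ncol(x) / pmax(nshared, 1L))
  d[nshared == 0L] <- NA
  d[g] <- NA
  d
}

#' Collapse probe-level rows to gene-level means
#'
#' @param values numeric matrix, probes x samples, probe ids as rownames.
#' @param probe_map named character vector mapping probe id -> gene symbol.
#'   Probes absent from the map (or mapped to "" / NA) are dropped.
#' @param labels,name passed to [expression_study()].
#' @param normalize_case if TRUE, gene symbols are upper-cased before
#'   collapsing (off by default: symbols differing by case stay distinct).
#' @return An ExpressionStudy with one row per gene, values averaged across
#'   that gene's probes per sample.
#' @export
collapse_probes <- function(values, probe_map, labels, name = "study",
                            normalize_case = FALSE) {
  if (is.null(rownames(values))) stop("probe matrix needs rownames")
  map <- probe_map[!is.na(probe_map) & probe_map != ""]
  keep <- intersect(rownames(values), names(map))
  if (!length(keep)) stop("no probe in the matrix maps to a gene symbol")
  sub <- values[keep, , drop = FALSE]
  genes <- unname(map[keep])
  if (normalize_case) genes <- toupper(genes)
  agg <- rowsum(sub, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  expression_study(as.matrix(agg), labels, name = name)
}

#' Read gene sets in GMT format
#'
#' Each tab-delimited line is: set name, description, member genes. Empty
#' member fields are dropped; duplicate members collapse.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `source`.
#' @export
read_gene_sets <- function(path) {
  lines <- read_clean_lines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    f <- f[f != "" | seq_along(f) <= 2]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    sets[[f[1]]] <- unique(f[-(1:2)][f[-(1:2)] != ""])
  }
  gene_set_collection(sets, source = path)
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors of gene symbols.
#' @param source free-text provenance.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (!length(sets) || is.null(names(sets)))
    stop("`sets` must be a non-empty named list")
  if (any(!lengths(sets)))
    stop("empty gene set(s): ",
         paste(names(sets)[!lengths(sets)], collapse = ", "))
  if (any(vapply(sets, function(s) any(is.na(s) | s == ""), TRUE)))
    stop("blank gene symbol in a gene set")
  structure(list(sets = lapply(sets, unique), source = source),
            class = "GeneSetCollection")
}

#' Write gene sets in GMT format
#' @param collection a GeneSetCollection.
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from a two-column edge list
#'
#' Self-loops are dropped and duplicate/reversed edges collapsed; the counts
#' are reported via `message()`.
#'
#' @param path tab-delimited file, two gene symbols per line.
#' @return An `InteractionNetwork`: list with `nodes` and `edges`
#'   (data.frame with columns `from`, `to`, canonically ordered).
#' @export
read_interactions <- function(path) {
  lines <- read_clean_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("edge line ", bad[1], " has fewer than 2 fields")
  from <- trimws(vapply(parts, `[`, "", 1L))
  to <- trimws(vapply(parts, `[`, "", 2L))
  interaction_network(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE))
}

#' @rdname read_interactions
#' @param edges data.frame with character columns `from` and `to`.
#' @param nodes optional extra isolated nodes to retain.
#' @export
interaction_network <- function(edges, nodes = character()) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  n0 <- nrow(edges)
  loops <- edges$from == edges$to
  if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
  edges <- edges[!loops, , drop = FALSE]
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message("collapsed ", sum(dup), " duplicate edge(s)")
  edges <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to, nodes))), edges = edges),
    class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write an interaction network as a two-column edge list
#' @param network an InteractionNetwork.
#' @param path output path.
#' @export
write_interactions <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-condition mutated-gene catalogs
#'
#' Expects a two-column tab-delimited table: condition name, gene symbol
#' (one mutated gene per line).
#'
#' @param path file path.
#' @return A `MutationCatalog`: named list of character vectors
#'   (condition -> set of mutated gene symbols).
#' @export
read_mutations <- function(path) {
  lines <- read_clean_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("mutation line ", bad[1], " has fewer than 2 fields")
  cond <- trimws(vapply(parts, `[`, "", 1L))
  gene <- trimws(vapply(parts, `[`, "", 2L))
  if (any(gene == "")) stop("blank gene symbol in mutation catalog")
  mutation_catalog(split(gene, cond))
}

#' @rdname read_mutations
#' @param conditions named list of character vectors of mutated genes.
#' @export
mutation_catalog <- function(conditions) {
  if (!length(conditions) || is.null(names(conditions)))
    stop("`conditions` must be a non-empty named list")
  conditions <- lapply(conditions, function(g) sort(unique(g)))
  if (any(vapply(conditions, function(g) any(is.na(g) | g == ""), TRUE)))
    stop("blank gene symbol in mutation catalog")
  structure(list(conditions = conditions), class = "MutationCatalog")
}

#' Write a mutation catalog as a condition/gene table
#' @param catalog a MutationCatalog.
#' @param path output path.
#' @export
write_mutations <- function(catalog, path) {
  df <- data.frame(
    condition = rep(names(catalog$conditions),
                    lengths(catalog$conditions)),
    gene = unlist(catalog$conditions, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Read a text file into trimmed-right lines, tolerating CRLF; blank lines
# are dropped.
read_clean_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[\r[:space:]]+$", "", lines)
  lines[nzchar(lines)]
}
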