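#' Network topology summary statistics
#'
#' Degree-sequence and clustering statistics for an undirected simple graph:
#' \itemize{
#'   \item per-node clustering coefficient C = 2 e / (k (k - 1)) where e is
#'     the number of edges among the node's k neighbours; the mean is taken
#'     over nodes with degree >= 2 (C is undefined below that);
#'   \item density = mean(k) / (N - 1), equivalently the number of present
#'     edges over the number of possible ones (0 for an edgeless graph, 1
#'     for a complete one);
#'   \item centralization = N/(N - 2) * (max(k)/(N - 1) - density), 1 for a
#'     star, 0 for any regular graph; undefined (NA) when N < 3;
#'   \item heterogeneity = variance(k) / mean(k) with population variance by
#'     default (`sample_variance = TRUE` switches to n - 1);
#'   \item per-node closeness, see [node_closeness()].
#' }
#'
#' @param network an InteractionNetwork, igraph object, or edge data.frame
#'   (columns `from`, `to`).
#' @param nodes optional isolated nodes to include when `network` is an edge
#'   data.frame.
#' @param sample_variance use the n - 1 variance in heterogeneity.
#' @return List with `n_nodes`, `n_edges`, `mean_clustering`, `density`,
#'   `centralization`, `heterogeneity`, `closeness` (named vector) and
#'   `degree` (named vector).
#' @export
topology_summary <- function(network, nodes = character(),
                             sample_variance = FALSE) {
  g <- as_igraph_undirected(network, nodes)
  n <- igraph::vcount(g)
  if (n < 1) stop("empty graph")
  k <- igraph::degree(g)
  dens <- if (n > 1) mean(k) / (n - 1) else 0
  centr <- if (n >= 3) n / (n - 2) * (max(k) / (n - 1) - dens) else NA_real_
  vk <- if (sample_variance) stats::var(k) else mean((k - mean(k))^2)
  het <- if (mean(k) > 0) vk / mean(k) else 0
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  names(cc) <- igraph::V(g)$name
  eligible <- k >= 2
  mean_cc <- if (any(eligible)) mean(cc[eligible]) else NA_real_
  list(n_nodes = n, n_edges = igraph::ecount(g),
       mean_clustering = mean_cc, clustering = cc,
       n_low_degree = sum(!eligible),
       density = dens, centralization = centr, heterogeneity = het,
       closeness = node_closeness(g), degree = k)
}

#' Closeness centrality within a node's connected component
#'
#' Closeness(v) = 1 / sum of shortest-path distances from v to the other
#' nodes of its connected component (unweighted hops). Nodes in other
#' components are excluded rather than treated as infinitely distant.
#' An isolated node gets closeness 0 by convention.
#'
#' @param network as in [topology_summary()].
#' @param node optional single node name; default returns all nodes.
#' @param nodes optional isolated nodes when `network` is an edge data.frame.
#' @return Named numeric vector of closeness values (or a single value).
#' @export
node_closeness <- function(network, node = NULL, nodes = character()) {
  g <- as_igraph_undirected(network, nodes)
  d <- igraph::distances(g, weights = NA)
  d[!is.finite(d)] <- NA                   # other components excluded
  tot <- rowSums(d, na.rm = TRUE)
  cl <- ifelse(tot > 0, 1 / tot, 0)
  names(cl) <- igraph::V(g)$name
  if (!is.null(node)) {
    if (!node %in% names(cl)) stop("node not in network: ", node)
    return(cl[[node]])
  }
  cl
}

# Coerce the accepted network representations to an undirected simple igraph.
as_igraph_undirected <- function(network, nodes = character()) {
  if (inherits(network, "igraph")) return(network)
  edges <- if (inherits(network, "InteractionNetwork")) {
    nodes <- union(nodes, network$nodes)
    network$edges
  } else network
  igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = sort(union(nodes, unique(c(edges$from, edges$to)))))
}

#' Build the mutated-gene network over core modules
#'
#' Nodes are the mutated genes appearing in any dataset's core modules;
#' edges are the known interactions among them. Each node is annotated with
#' the datasets whose core modules contain it.
#'
#' @param core_gene_sets named list: dataset -> genes in its core modules.
#' @param mutated_by_dataset named list: dataset -> mutated gene symbols.
#' @param interactions the reference InteractionNetwork.
#' @return List with `nodes` (data.frame `gene`, `datasets`
#'   (comma-joined), `n_datasets`), `edges`, and `membership` (named list
#'   gene -> datasets).
#' @export
mutated_gene_network <- function(core_gene_sets, mutated_by_dataset,
                                 interactions) {
  stopifnot(identical(sort(names(core_gene_sets)),
                      sort(names(mutated_by_dataset))))
  membership <- list()
  for (ds in names(core_gene_sets)) {
    hit <- intersect(core_gene_sets[[ds]], mutated_by_dataset[[ds]])
    for (gn in hit) membership[[gn]] <- c(membership[[gn]], ds)
  }
  genes <- sort(names(membership))
  e <- interactions$edges
  e <- e[e$from %in% genes & e$to %in% genes, , drop = FALSE]
  rownames(e) <- NULL
  nodes <- data.frame(
    gene = genes,
    datasets = vapply(membership[genes], paste, "", collapse = ","),
    n_datasets = lengths(membership[genes]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(nodes = nodes, edges = e, membership = membership[genes])
}

#' Number-of-cancer-types score with half credit
#'
#' For each cancer type (1 or 2 datasets): a gene present in all of the
#' type's datasets scores 1; present in exactly one of a two-dataset type
#' scores 1/2; otherwise 0. The gene's N is the sum over types.
#'
#' @param gene gene symbol.
#' @param membership named list gene -> character vector of datasets whose
#'   core modules contain the gene (as from [mutated_gene_network()]).
#' @param dataset_types named character vector dataset -> cancer type.
#' @return The N score (multiple of 1/2, >= 0).
#' @export
cancer_type_score <- function(gene, membership, dataset_types) {
  per_type <- split(names(dataset_types), dataset_types)
  if (any(lengths(per_type) > 2L))
    stop("types with more than 2 datasets are unsupported")
  present <- membership[[gene]]
  if (is.null(present)) return(0)
  sum(vapply(per_type, function(ds) {
    hit <- sum(ds %in% present)
    if (hit == length(ds)) 1 else if (hit >= 1) 0.5 else 0
  }, 0))
}

#' Regression of median closeness on the number of cancer types
#'
#' For each distinct N score, the median closeness of the genes at that
#' score is taken; an ordinary least-squares line is fitted through the
#' (N, median closeness) points.
#'
#' @param N numeric vector of per-gene type scores.
#' @param closeness numeric vector of per-gene closeness values.
#' @return List with `slope`, `intercept`, `r_squared`, and the fitted
#'   `points` data.frame.
#' @export
closeness_vs_types_regression <- function(N, closeness) {
  stopifnot(length(N) == length(closeness))
  med <- tapply(closeness, N, stats::median)
  x <- as.numeric(names(med))
  if (length(x) < 2) stop("need >= 2 distinct N levels")
  fit <- stats::lm(med ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((med - mean(med))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
       points = data.frame(N = x, median_closeness = as.numeric(med)))
}

#' Classify mutated genes as general, type-specific or unstable
#'
#' Each gene's observed N score is compared with its label-permutation null
#' distribution by a one-sample Wilcoxon signed-rank test (observed minus
#' permuted values, alternative "greater"); genes failing at `wilcoxon_alpha`
#' are unstable. Stable genes split at N > 1 (general candidates) versus
#' N <= 1 (type-specific candidates), and within each group the one-sided
#' Grubbs outlier procedure (see [grubbs_test()]) flags the reported genes.
#'
#' @param N named numeric vector of observed per-gene scores.
#' @param perm_N named list gene -> numeric vector of permutation scores.
#' @param wilcoxon_alpha stability cutoff (default 0.01).
#' @param grubbs_alpha one-tail outlier cutoff (default 0.05).
#' @return List with character vectors `general`, `type_specific`,
#'   `unstable`.
#' @export
classify_mutated_genes <- function(N, perm_N, wilcoxon_alpha = 0.01,
                                   grubbs_alpha = 0.05) {
  if (is.null(names(N)) || !length(perm_N))
    stop("named observed scores and permutation distributions required")
  missing <- setdiff(names(N), names(perm_N))
  if (length(missing))
    stop("no permutation distribution for: ",
         paste(missing, collapse = ", "))
  stable <- vapply(names(N), function(gn) {
    diffs <- N[[gn]] - perm_N[[gn]]
    if (all(diffs == 0)) return(FALSE)
    p <- suppressWarnings(
      stats::wilcox.test(diffs, alternative = "greater")$p.value)
    p < wilcoxon_alpha
  }, TRUE)
  unstable <- names(N)[!stable]
  hi <- N[stable & N > 1]
  lo <- N[stable & N <= 1]
  pick_outliers <- function(v) {
    if (length(v) < 3) return(character())
    names(v)[grubbs_test(v, one_tail_alpha = grubbs_alpha)]
  }
  list(general = pick_outliers(hi), type_specific = pick_outliers(lo),
       unstable = unstable)
}
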