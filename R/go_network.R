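#' Intersect gene sets with the measured genes to form GO clusters
#'
#' Genes absent from the expression data are dropped from each set; sets
#' whose intersection is smaller than `min_size` are discarded. A gene may
#' belong to several clusters (multi-functional genes are not forced into a
#' single module).
#'
#' @param collection a GeneSetCollection.
#' @param study an ExpressionStudy.
#' @param min_size minimum cluster size (default 3; 2-node clusters cannot
#'   be split into multi-gene modules).
#' @return Named list of character vectors (cluster name -> genes).
#' @export
assign_go_clusters <- function(collection, study, min_size = 3) {
  stopifnot(inherits(collection, "GeneSetCollection"),
            inherits(study, "ExpressionStudy"))
  if (min_size < 2) stop("min_size must be >= 2")
  clusters <- lapply(collection$sets, intersect, y = study$genes)
  clusters[lengths(clusters) >= min_size]
}

#' Absolute co-expression weight between two expression vectors
#'
#' S = |cor(x, y)|, Pearson by default or Spearman. A zero-variance vector
#' makes the correlation undefined; such edges receive the small floor
#' weight `eps` (keeping the interaction in the network) with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param kind "pearson" or "spearman".
#' @param eps floor weight for undefined correlations.
#' @return A weight in \[0, 1\].
#' @export
coexpression_weight <- function(x, y, kind = c("pearson", "spearman"),
                                eps = 1e-6) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance expression vector; weight floored at ", eps)
    return(eps)
  }
  abs(stats::cor(x, y, method = kind))
}

#' Build one GO cluster's weighted interaction subgraph
#'
#' Keeps exactly the global interactions whose two endpoints both lie in the
#' cluster (inter-cluster edges are cut) and weights each retained edge by
#' the absolute co-expression of its endpoints across all samples of the
#' study (both conditions pooled). Cluster genes without any retained edge
#' stay in the node set; the partitioner ignores them later.
#'
#' @param genes character vector: one GO cluster's genes.
#' @param interactions an InteractionNetwork (the global network).
#' @param study an ExpressionStudy covering the cluster genes.
#' @param kind correlation flavour, see [coexpression_weight()].
#' @param name cluster name.
#' @return A `GoNetwork`: list with `name`, `genes`, and `edges` (data.frame
#'   `from`, `to`, `weight`).
#' @export
build_go_network <- function(genes, interactions, study,
                             kind = c("pearson", "spearman"),
                             name = "cluster") {
  kind <- match.arg(kind)
  stopifnot(inherits(interactions, "InteractionNetwork"),
            inherits(study, "ExpressionStudy"))
  e <- interactions$edges
  keep <- e$from %in% genes & e$to %in% genes
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    x <- study$values[e$from, , drop = FALSE]
    y <- study$values[e$to, , drop = FALSE]
    if (kind == "spearman") {
      x <- t(apply(x, 1, rank))
      y <- t(apply(y, 1, rank))
    }
    w <- abs(row_cor(x, y))
    bad <- !is.finite(w)
    if (any(bad)) {
      warning(sum(bad), " edge weight(s) undefined (zero variance); ",
              "floored at 1e-6")
      w[bad] <- 1e-6
    }
    e$weight <- pmax(w, 1e-6)
  } else {
    e <- data.frame(from = character(), to = character(),
                    weight = numeric())
  }
  rownames(e) <- NULL
  structure(list(name = name, genes = sort(genes), edges = e,
                 correlation_kind = kind),
            class = "GoNetwork")
}

# Row-wise Pearson correlation between paired rows of x and y.
row_cor <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
}

#' @export
print.GoNetwork <- function(x, ...) {
  cat(sprintf("GoNetwork '%s': %d genes, %d weighted edges (%s)\n",
              x$name, length(x$genes), nrow(x$edges), x$correlation_kind))
  invisible(x)
}

#' Build all GO networks for a study
#'
#' Convenience wrapper: [assign_go_clusters()] then [build_go_network()]
#' per cluster.
#'
#' @inheritParams assign_go_clusters
#' @inheritParams build_go_network
#' @return Named list of GoNetwork objects.
#' @export
build_go_networks <- function(collection, study, interactions,
                              min_size = 3,
                              kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  clusters <- assign_go_clusters(collection, study, min_size = min_size)
  nets <- lapply(names(clusters), function(nm) {
    build_go_network(clusters[[nm]], interactions, study,
                     kind = kind, name = nm)
  })
  names(nets) <- names(clusters)
  nets
}

#' Export a GoNetwork as a weighted edge-list TSV
#' @param network a GoNetwork.
#' @param path output path.
#' @export
write_go_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
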