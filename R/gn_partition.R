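#' Weighted edge betweenness
#'
#' Edge betweenness for module discovery: the standard shortest-path edge
#' betweenness computed on the unweighted topology (each unordered node pair
#' contributes 1, split across equally short paths), divided by the edge's
#' co-expression weight. Low-weight edges between co-regulated blocks are
#' thereby removed first. `mode = "dijkstra"` instead treats 1/weight as the
#' path length and computes ordinary weighted betweenness (no division).
#'
#' @param network a GoNetwork, or a data.frame with columns `from`, `to`,
#'   `weight`.
#' @param mode "divide" (default) or "dijkstra".
#' @return data.frame `from`, `to`, `score`, one row per edge.
#' @export
weighted_edge_betweenness <- function(network, mode = c("divide", "dijkstra")) {
  mode <- match.arg(mode)
  edges <- if (is.data.frame(network)) network else network$edges
  if (!nrow(edges)) stop("network has no edges")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  eb <- if (mode == "divide") {
    igraph::edge_betweenness(g, directed = FALSE, weights = NA) /
      edges$weight
  } else {
    igraph::edge_betweenness(g, directed = FALSE, weights = 1 / edges$weight)
  }
  data.frame(from = edges$from, to = edges$to, score = as.numeric(eb),
             stringsAsFactors = FALSE)
}

#' Partition a weighted GO network into small functional modules
#'
#' Iterative divisive community detection: the edge with the highest
#' [weighted_edge_betweenness()] is removed and all scores recomputed, over
#' and over. Instead of the classical modularity-based cut point, a size cap
#' is used: whenever a connected component drops below `size_limit` genes it
#' is frozen as a module and takes no further part in edge removal.
#' Components of a single gene are discarded. Components already below the
#' cap at entry are emitted immediately with zero removals.
#'
#' Ties in the betweenness score are broken toward the lexicographically
#' smallest (from, to) pair, making the partition deterministic.
#'
#' @param network a GoNetwork (or any list with `genes` and an edge
#'   data.frame `edges` carrying `from`, `to`, `weight`).
#' @param size_limit modules must have fewer than this many genes
#'   (default 20).
#' @param mode betweenness flavour, see [weighted_edge_betweenness()].
#' @return List of modules, each a sorted character vector of gene symbols
#'   with 2 <= length < `size_limit`; modules are pairwise disjoint.
#' @export
partition_modules <- function(network, size_limit = 20,
                              mode = c("divide", "dijkstra")) {
  mode <- match.arg(mode)
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = network$genes)
  igraph::E(g)$weight <- if (nrow(edges)) edges$weight else numeric()
  modules <- list()

  repeat {
    comp <- igraph::components(g)
    small <- which(comp$csize < size_limit)
    if (length(small)) {
      frozen <- comp$membership %in% small
      for (ci in small) {
        gs <- names(comp$membership)[comp$membership == ci]
        if (length(gs) >= 2L) modules[[length(modules) + 1L]] <- sort(gs)
      }
      g <- igraph::delete_vertices(g, which(frozen))
    }
    if (igraph::vcount(g) == 0L) break
    w <- igraph::E(g)$weight
    eb <- if (mode == "divide")
      igraph::edge_betweenness(g, directed = FALSE, weights = NA) / w
    else
      igraph::edge_betweenness(g, directed = FALSE, weights = 1 / w)
    ends <- igraph::ends(g, igraph::E(g))
    top <- order(-eb, ends[, 1], ends[, 2])[1]
    g <- igraph::delete_edges(g, top)
  }
  modules[order(vapply(modules, `[`, "", 1L))]
}

#' Write a module table as TSV
#'
#' @param modules list of gene vectors (as from [partition_modules()]) or of
#'   module records carrying `genes`.
#' @param go_cluster per-module source cluster name(s).
#' @param path output path.
#' @export
write_module_table <- function(modules, go_cluster, path) {
  genes <- lapply(modules, function(m) if (is.list(m)) m$genes else m)
  df <- data.frame(
    module_id = seq_along(genes),
    go_cluster = rep_len(go_cluster, length(genes)),
    size = lengths(genes),
    genes = vapply(genes, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
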