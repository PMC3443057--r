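# Shared fixtures and independent oracles for the test suite.

# A tiny 4-gene x 6-sample study with an obvious DE gene (g1).
tiny_study <- function() {
  vals <- rbind(
    g1 = c(1, 1.2, 0.8, 5, 5.2, 4.8),
    g2 = c(2, 2.1, 1.9, 2.05, 1.95, 2.0),
    g3 = c(0, 1, 2, 0.5, 1.5, 2.5),
    g4 = c(3, 2, 1, 3.2, 2.1, 0.9))
  colnames(vals) <- paste0("s", 1:6)
  expression_study(vals, rep(c("A", "B"), each = 3), name = "tiny")
}

edge_df <- function(from, to, weight = NULL) {
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- weight
  df
}

# Minimal GoNetwork-like object for the partitioner.
fake_go_network <- function(edges, genes = NULL, name = "net") {
  if (is.null(genes)) genes <- sort(unique(c(edges$from, edges$to)))
  structure(list(name = name, genes = genes, edges = edges,
                 correlation_kind = "pearson"), class = "GoNetwork")
}

# Independent edge-betweenness oracle: exhaustive enumeration of all
# shortest paths between every unordered node pair; each pair contributes
# 1 split equally across its shortest paths.
oracle_edge_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    c(edges$to[edges$from == v], edges$from[edges$to == v]))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  score <- stats::setNames(numeric(nrow(edges)),
                           key(edges$from, edges$to))
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) for (w in adj[[v]])
        if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) next
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- c(s, rev(acc)); return() }
      for (u in adj[[v]]) if (dist[u] == dist[v] - 1) walk(u, c(acc, v))
    }
    walk(t, character())
    for (p in paths)
      for (k in seq_len(length(p) - 1))
        score[key(p[k], p[k + 1])] <-
          score[key(p[k], p[k + 1])] + 1 / length(paths)
  }
  score
}

# Random connected G(n, p) graph as an edge data.frame with weights.
random_connected_graph <- function(n, p, weights = TRUE) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  e <- igraph::as_edgelist(g)
  lab <- sprintf("n%02d", seq_len(n))
  df <- edge_df(lab[pmin(e[, 1], e[, 2])], lab[pmax(e[, 1], e[, 2])])
  df$weight <- if (weights) stats::runif(nrow(df), 1e-3, 1) else 1
  df[order(df$from, df$to), , drop = FALSE]
}

# Small synthetic world that keeps pipeline-level tests fast.
small_spec <- function(seed = 1, ...) {
  defaults <- list(n_genes = 600, n_per_class = 12, n_noise_sets = 30,
                   set_size_mean = 25, set_size_sd = 4, n_planted = 3,
                   seed = seed)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

small_config <- function(gen, K = 30, ...) {
  pipeline_config(gen$collection, gen$interactions, K = K, ...)
}
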