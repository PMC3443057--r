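star_edges <- function(n) {
  edge_df(rep("h", n - 1), sprintf("l%02d", seq_len(n - 1)))
}
complete_edges <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  p <- t(combn(v, 2))
  edge_df(p[, 1], p[, 2])
}

test_that("density, centralization and heterogeneity match the formulas", {
  full <- topology_summary(complete_edges(8))
  expect_equal(full$density, 1)
  expect_equal(full$mean_clustering, 1)

  empty <- topology_summary(edge_df(character(), character()),
                            nodes = letters[1:8])
  expect_equal(empty$density, 0)
  expect_equal(empty$heterogeneity, 0)

  star10 <- topology_summary(star_edges(10))
  expect_equal(star10$centralization, 1)

  # any regular graph: heterogeneity 0; a cycle: centralization 0
  cyc <- edge_df(letters[1:6], letters[c(2:6, 1)])
  ring <- topology_summary(cyc)
  expect_equal(ring$heterogeneity, 0)
  expect_equal(ring$centralization, 0)

  # 4-node star, population variance: degrees (3,1,1,1)
  star4 <- topology_summary(star_edges(4))
  expect_equal(star4$heterogeneity, 0.75 / 1.5)
  expect_equal(topology_summary(star_edges(4),
                                sample_variance = TRUE)$heterogeneity,
               1 / 1.5)
  # centralization undefined below 3 nodes
  expect_true(is.na(topology_summary(edge_df("a", "b"))$centralization))
})

test_that("the two density forms agree on random graphs", {
  set.seed(31)
  for (rep in 1:8) {
    df <- random_connected_graph(sample(5:25, 1), 0.3, weights = FALSE)
    ts <- topology_summary(df)
    n <- ts$n_nodes
    expect_equal(ts$density, 2 * nrow(df) / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("clustering coefficient counts neighbour connections", {
  # triangle plus pendant: a-b-c-a, c-d
  g <- edge_df(c("a", "a", "b", "c"), c("b", "c", "c", "d"))
  ts <- topology_summary(g)
  expect_equal(unname(ts$clustering[c("a", "b", "c")]), c(1, 1, 1 / 3))
  expect_identical(ts$n_low_degree, 1L)          # d has degree 1
  expect_equal(ts$mean_clustering, mean(c(1, 1, 1 / 3)))
})

test_that("closeness is the reciprocal summed within-component distance", {
  s4 <- star_edges(4)
  expect_equal(node_closeness(s4, "h"), 1 / 3)
  expect_equal(node_closeness(s4, "l01"), 1 / 5)    # distances 1, 2, 2
  path <- edge_df(c("A", "B"), c("B", "C"))
  expect_equal(node_closeness(path, "B"), 1 / 2)
  # isolated node: closeness 0; other component excluded, not infinite
  two <- edge_df(c("a", "p"), c("b", "q"))
  cl <- node_closeness(two, nodes = "z")
  expect_equal(unname(cl["z"]), 0)
  expect_equal(unname(cl["a"]), 1)
  # tree property: an internal node is at least as close as its worst leaf
  set.seed(12)
  for (rep in 1:5) {
    tr <- igraph::sample_tree(12)
    igraph::V(tr)$name <- sprintf("t%02d", 1:12)
    cl <- node_closeness(tr)
    deg <- igraph::degree(tr)
    expect_gte(min(cl[deg >= 2]), min(cl[deg == 1]))
  }
})

test_that("cancer-type N scores apply the half-credit rule", {
  dstype <- c(colon1 = "colon", colon2 = "colon",
              breast1 = "breast", breast2 = "breast", mel1 = "melanoma")
  member <- list(gA = c("colon1", "colon2"),
                 gB = "colon1",
                 gC = c("mel1", "breast2"),
                 gD = c("colon1", "colon2", "breast1", "breast2", "mel1"))
  expect_equal(cancer_type_score("gA", member, dstype), 1)
  expect_equal(cancer_type_score("gB", member, dstype), 0.5)
  expect_equal(cancer_type_score("gC", member, dstype), 1.5)
  expect_equal(cancer_type_score("gD", member, dstype), 3)
  expect_equal(cancer_type_score("absent", member, dstype), 0)
  expect_error(cancer_type_score("gA", member,
                                 c(a = "x", b = "x", c = "x")), "2 datasets")
})

test_that("median-closeness regression matches a least-squares oracle", {
  # exactly collinear medians
  fit <- closeness_vs_types_regression(
    N = c(1, 1, 2, 2, 3, 3), closeness = c(0.1, 0.3, 0.2, 0.4, 0.3, 0.5))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.1)
  # constant medians
  flat <- closeness_vs_types_regression(
    N = c(1, 2, 3), closeness = c(0.2, 0.2, 0.2))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  # three levels, hand-computed OLS on (1,.1), (2,.2), (3,.25)
  y <- c(0.1, 0.2, 0.25)
  fit3 <- closeness_vs_types_regression(N = 1:3, closeness = y)
  sxy <- sum((1:3 - 2) * (y - mean(y))); sxx <- sum((1:3 - 2)^2)
  expect_equal(fit3$slope, sxy / sxx)
  expect_equal(fit3$intercept, mean(y) - fit3$slope * 2)
  expect_error(closeness_vs_types_regression(c(1, 1), c(0.1, 0.2)),
               "2 distinct")
})

test_that("mutated genes classify into general / type-specific / unstable", {
  N <- c(big = 3, mid = 0.5, same = 1,
         h1 = 1.4, h2 = 1.3, h3 = 1.5, h4 = 1.45,
         l1 = 0.5, l2 = 0.45, l3 = 0.55, l4 = 0.5)
  perm <- lapply(N, function(x) rep(0, 30))
  perm$same <- rep(1, 30)                      # matches observed -> unstable
  cls <- classify_mutated_genes(N, perm)
  expect_identical(cls$unstable, "same")
  expect_identical(cls$general, "big")         # planted high outlier
  expect_identical(cls$type_specific, character(0))
  expect_error(classify_mutated_genes(N, perm[1:3]), "permutation")
})

test_that("the mutated-gene network annotates dataset membership", {
  core <- list(d1 = c("a", "b", "c"), d2 = c("b", "c", "d"))
  mut <- list(d1 = c("a", "b"), d2 = c("b", "d", "zz"))
  ref <- interaction_network(edge_df(c("a", "b", "b"), c("b", "d", "zz")))
  mg <- mutated_gene_network(core, mut, ref)
  expect_identical(mg$nodes$gene, c("a", "b", "d"))
  expect_identical(mg$membership$b, c("d1", "d2"))
  expect_identical(mg$nodes$n_datasets, c(1L, 2L, 1L))
  expect_identical(nrow(mg$edges), 2L)         # a-b, b-d; b-zz excluded
})
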