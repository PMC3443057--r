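test_that("relatedness at cutoff 0 is the Jaccard index of node sets", {
  ref <- interaction_network(edge_df(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(network_relatedness(c("a", "b"), c("a", "b"), ref), 1)
  expect_equal(network_relatedness(c("a", "b"), c("c", "d"), ref), 0)
  expect_equal(network_relatedness(c("a", "b"), c("b", "c"), ref), 1 / 3)
  expect_warning(r <- network_relatedness(character(), character(), ref),
                 "empty")
  expect_true(is.na(r))
  expect_error(network_relatedness("a", "b", ref, cutoff = 3), "cutoff")
})

test_that("positive cutoffs count close pairs (enumeration oracle)", {
  # path a-b-c-d-e
  ref <- interaction_network(edge_df(letters[1:4], letters[2:5]))
  gi <- c("a", "b"); gj <- c("d", "e")
  # cutoff 1: qualifying cross pairs among {a,b,d,e}: none within distance 1
  # across the two sets; union pairs within 1: a-b, d-e, plus 4 self pairs
  expect_equal(network_relatedness(gi, gj, ref, cutoff = 1), 0 / 6)
  # cutoff 2: cross pairs: b-d (distance 2); union: a-b, d-e, b-d, a-c?(c
  # not a member) -> pairs among members within 2: a-b(1), d-e(1), b-d(2),
  # plus 4 selves = 7
  expect_equal(network_relatedness(gi, gj, ref, cutoff = 2), 1 / 7)

  # brute-force oracle on random graphs
  set.seed(61)
  for (rep in 1:10) {
    df <- random_connected_graph(8, 0.35, weights = FALSE)
    ref <- interaction_network(df)
    gi <- sample(ref$nodes, 4)
    gj <- sample(ref$nodes, 4)
    for (cut in 1:2) {
      g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                         vertices = ref$nodes)
      d <- igraph::distances(g)
      u <- sort(union(gi, gj))
      n0 <- 0; n1 <- 0
      for (x in seq_along(u)) for (y in x:length(u)) {
        if (d[u[x], u[y]] <= cut) {
          n1 <- n1 + 1
          if ((u[x] %in% gi && u[y] %in% gj) ||
              (u[x] %in% gj && u[y] %in% gi)) n0 <- n0 + 1
        }
      }
      got <- network_relatedness(gi, gj, ref, cutoff = cut)
      expect_equal(got, n0 / n1)
    }
  }
})

test_that("relatedness matrices are symmetric, bounded, unit-diagonal", {
  set.seed(77)
  ref <- interaction_network(random_connected_graph(20, 0.2,
                                                    weights = FALSE))
  nets <- list(x = sample(ref$nodes, 6), y = sample(ref$nodes, 6),
               z = sample(ref$nodes, 6))
  for (cut in 0:2) {
    R <- relatedness_matrix(nets, ref, cutoff = cut)
    expect_equal(R, t(R))
    expect_true(all(R >= 0 & R <= 1))
    expect_equal(unname(diag(R)), rep(1, 3))
    D <- distance_from_relatedness(R)
    expect_equal(unname(diag(D)), rep(0, 3))
    expect_equal(D[upper.tri(D)], 1 - R[upper.tri(R)])
  }
})

test_that("neighbor joining matches the three-point closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj <- neighbor_joining(D)
  len <- nj$tree$edge.length
  tip <- nj$tree$tip.label[nj$tree$edge[, 2]]
  expect_equal(sort(len), c(0.5, 1.5, 2.5))
  expect_equal(len[tip == "A"], (2 + 3 - 4) / 2)
  expect_equal(len[tip == "B"], (2 + 4 - 3) / 2)
  expect_equal(len[tip == "C"], (3 + 4 - 2) / 2)
  expect_match(nj$newick, "^\\(.*\\);$")
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ exactly recovers additive trees (tree-construction oracle)", {
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:1):1);")
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj$tree)), 0)
  expect_equal(ape::cophenetic.phylo(nj$tree)[rownames(D), colnames(D)], D)
  expect_true(is_cherry(nj$tree, "A", "B"))
  expect_true(is_cherry(nj$tree, "C", "D"))
  expect_false(is_cherry(nj$tree, "A", "C"))

  # random additive trees with up to 6 taxa
  set.seed(9)
  for (n in 4:6) {
    rt <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(rt)
    nj <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(rt, nj$tree)), 0)
    expect_equal(ape::cophenetic.phylo(nj$tree)[rownames(D), colnames(D)],
                 D, tolerance = 1e-10)
  }
})

test_that("equidistant taxa give a star-like tree with equal tips", {
  D <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  nj <- neighbor_joining(D)
  tip_edges <- nj$tree$edge[, 2] <= 4
  expect_equal(unname(nj$tree$edge.length[tip_edges]), rep(0.5, 4))
  internal <- nj$tree$edge.length[!tip_edges]
  expect_true(all(internal >= 0 & internal < 1e-12))
})

test_that("PHYLIP distance export is readable", {
  D <- matrix(c(0, .25, .25, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  path <- withr::local_tempfile()
  write_phylip_distances(D, path)
  lines <- readLines(path)
  expect_match(lines[1], "^\\s*2$")
  expect_length(lines, 3)
})
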