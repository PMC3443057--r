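test_that("gene t scores match the Welch formula and t.test oracle", {
  vals <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
                g2 = c(2, 2.1, 1.9, 2.0, 2.05, 1.95))
  colnames(vals) <- paste0("s", 1:6)
  st <- expression_study(vals, rep(c("A", "B"), each = 3))
  t <- gene_t_scores(st)
  # direct Welch evaluation: (2 - 5) / sqrt(1/3 + 1/3)
  expect_equal(unname(t["g1"]), -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(t["g1"]), -3.674, tolerance = 1e-3)
  oracle <- t.test(vals[1, 1:3], vals[1, 4:6])
  expect_equal(unname(t["g1"]), unname(oracle$statistic))
  expect_equal(attr(t, "df")[1], unname(oracle$parameter))
  # swapping labels flips every sign
  st2 <- st
  st2$labels <- factor(as.character(st$labels), levels = c("B", "A"))
  expect_equal(as.numeric(gene_t_scores(st2)), -as.numeric(t))
  # identical classes give T = 0
  same <- expression_study(
    matrix(rep(c(1, 2, 1, 2), each = 2), 2, 4,
           dimnames = list(c("a", "b"), paste0("s", 1:4))),
    c("A", "A", "B", "B"))
  expect_equal(as.numeric(gene_t_scores(same)), c(0, 0))
  # pooled-variance flavour matches var.equal t.test
  tp <- gene_t_scores(st, var_equal = TRUE)
  expect_equal(unname(tp["g1"]),
               unname(t.test(vals[1, 1:3], vals[1, 4:6],
                             var.equal = TRUE)$statistic))
})

test_that("standardized scores are exact normal quantiles of the t null", {
  set.seed(15)
  vals <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  st <- expression_study(vals, rep(c("A", "B"), each = 5))
  t <- gene_t_scores(st)
  z <- gene_t_scores(st, standardize = TRUE)
  expect_equal(as.numeric(z), qnorm(pt(as.numeric(t), attr(t, "df"))),
               tolerance = 1e-10)
  expect_identical(sign(as.numeric(z)), sign(as.numeric(t)))
  expect_identical(order(as.numeric(z)), order(as.numeric(t)))
  expect_true(all(abs(z) <= abs(t)))   # finite-sample shrinkage toward N(0,1)
  # antisymmetry survives standardization
  st2 <- st
  st2$labels <- factor(as.character(st$labels), levels = c("B", "A"))
  expect_equal(as.numeric(gene_t_scores(st2, standardize = TRUE)),
               -as.numeric(z))
})

test_that("SDS is the sign-invariant quadratic sum", {
  t <- c(a = 1, b = 2, c = -2)
  expect_identical(module_sds(c("a", "b"), t), 5)
  expect_identical(module_sds(c("b", "c"), t), 8)
  expect_identical(module_sds(c("a", "b"), -t), 5)
  expect_identical(module_sds(character(0), t), 0)
  expect_error(module_sds(c("a", "zz"), t), "zz")
})

test_that("module p-values come from the chi-square upper tail", {
  expect_equal(module_pvalue(0, 5), 1)
  # closed form at df = 2: survival = exp(-x/2)
  expect_equal(module_pvalue(5, 2), exp(-2.5))
  expect_equal(module_pvalue(5, 2), 0.0821, tolerance = 1e-3)
  sds <- seq(0, 30, by = 0.5)
  expect_true(all(diff(module_pvalue(sds, 4)) < 0))
})

test_that("module ranking is ascending in p with deterministic ties", {
  t <- c(a = 3, b = 0.1, c = 0.1, d = 3, e = 0.2)
  mods <- list(hot = c("a", "d"), cold = c("b", "c"), mid = c("a", "e"))
  r <- rank_modules(mods, t, K = 1)
  expect_identical(r$module_id[1], "hot")
  expect_identical(r$is_TRM, c(TRUE, FALSE, FALSE))
  expect_identical(trm_genes(r), c("a", "d"))
  r_all <- rank_modules(mods, t, K = 10)   # K capped at module count
  expect_true(all(r_all$is_TRM))
  # exact ties: larger SDS first, then id
  t2 <- c(a = 2, b = 2, c = 2)
  tie <- rank_modules(list(z = c("a", "b"), y = c("b", "c"),
                           x = c("a", "b", "c")), t2, K = 2)
  expect_identical(tie$module_id, c("x", "y", "z"))  # x: df 3 but SDS 12
})

test_that("single-gene ranking finds the shifted gene, label-invariantly", {
  set.seed(3)
  vals <- matrix(rnorm(50 * 12), 50, 12,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
  vals["g07", 7:12] <- vals["g07", 7:12] + 4
  st <- expression_study(vals, rep(c("A", "B"), each = 6))
  expect_identical(rank_genes_ttest(st, 1), "g07")
  expect_identical(rank_genes_ttest(st, 0), character())
  expect_error(rank_genes_ttest(st, 51), "M exceeds")
  st2 <- st
  st2$labels <- factor(as.character(st$labels), levels = c("B", "A"))
  expect_identical(rank_genes_ttest(st, 10), rank_genes_ttest(st2, 10))
})
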