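test_that("generation is fully deterministic in the seed", {
  g1 <- generate_study(small_spec(seed = 5))
  g2 <- generate_study(small_spec(seed = 5))
  expect_identical(g1, g2)
  g3 <- generate_study(small_spec(seed = 6))
  expect_false(identical(g1$study$values, g3$study$values))
})

test_that("emitted files pass the readers unmodified", {
  gen <- generate_study(small_spec(seed = 2))
  dir <- withr::local_tempdir()
  write_study_files(gen, dir)
  st <- read_expression_matrix(
    file.path(dir, "expression.tsv"),
    stats::setNames(as.character(gen$study$labels), gen$study$samples),
    name = gen$study$name)
  expect_equal(st$values, gen$study$values, tolerance = 1e-12)
  gs <- read_gene_sets(file.path(dir, "gene_sets.gmt"))
  expect_identical(gs$sets, gen$collection$sets)
  net <- read_interactions(file.path(dir, "interactions.tsv"))
  expect_identical(net$edges, gen$interactions$edges)
  mut <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_identical(mut$conditions, gen$mutations$conditions)
})

test_that("planted structure matches the requested parameters", {
  spec <- small_spec(seed = 13, n_per_class = 200, rho = 0.6)
  gen <- generate_study(spec)
  planted <- gen$truth$planted[[1]]
  x <- gen$study$values[planted, gen$study$labels == "A"]
  cors <- cor(t(x))
  expect_equal(mean(cors[upper.tri(cors)]), spec$rho, tolerance = 0.05)
  # background genes uncorrelated with the module
  bg <- setdiff(gen$study$genes, unlist(gen$truth$planted))[1:20]
  cross <- cor(t(gen$study$values[planted, ]),
               t(gen$study$values[bg, ]))
  expect_equal(mean(abs(cross)), 0, tolerance = 0.06)
  # condition shift delta on planted genes
  shift <- rowMeans(gen$study$values[planted, gen$study$labels == "B"]) -
    rowMeans(gen$study$values[planted, gen$study$labels == "A"])
  expect_equal(mean(shift), spec$delta, tolerance = 0.2)
  # planted genes mutate more often than background
  mut <- gen$mutations$conditions$synth
  expect_gt(mean(unlist(gen$truth$planted) %in% mut),
            mean(bg %in% mut))
})

test_that("the null configuration plants nothing", {
  gen <- generate_study(small_spec(seed = 3, delta = 0,
                                   mutation_multiplier = 1))
  expect_identical(gen$truth$de_genes, character())
  shift <- rowMeans(gen$study$values[, gen$study$labels == "B"]) -
    rowMeans(gen$study$values[, gen$study$labels == "A"])
  expect_lt(abs(mean(shift)), 0.05)
})

test_that("multitype layouts share planted modules as designed", {
  types <- list(colon = c("colon1", "colon2"), breast = c("breast1",
                "breast2"), mel = "mel1", gli = "gli1")
  lay <- generate_multitype_layout(
    types, shared = list(c("colon", "breast")),
    spec = small_spec(seed = 19))
  expect_identical(sort(names(lay$datasets)),
                   sort(unlist(types, use.names = FALSE)))
  expect_identical(unname(lay$dataset_types[["colon2"]]), "colon")
  shared_mod <- setdiff(lay$truth$owner$colon,
                        setdiff(lay$truth$owner$colon, lay$truth$owner$breast))
  expect_length(shared_mod, 1)
  shared_genes <- lay$truth$planted[[shared_mod]]
  # the shared module is shifted in datasets of both owner types, not others
  for (ds in names(lay$datasets)) {
    st <- lay$datasets[[ds]]$study
    shift <- mean(rowMeans(st$values[shared_genes, st$labels == "B"]) -
                    rowMeans(st$values[shared_genes, st$labels == "A"]))
    if (lay$dataset_types[[ds]] %in% c("colon", "breast"))
      expect_gt(shift, 1)
    else expect_lt(abs(shift), 1)
  }
  expect_error(
    generate_multitype_layout(list(a = c("d1", "d2", "d3")),
                              spec = small_spec()), "at most 2")
  expect_error(
    generate_multitype_layout(types, shared = list(c("colon", "nope")),
                              spec = small_spec()), "pairs of type names")
  # a single-type layout cannot support a phylogeny
  one <- generate_multitype_layout(list(solo = "d1"),
                                   spec = small_spec(seed = 4))
  sets <- list(d1 = c("a", "b"))
  expect_error(neighbor_joining(matrix(0, 1, 1)), "3 taxa")
  expect_length(one$datasets, 1)
})
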