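#' Specification for a synthetic study with planted ground truth
#'
#' Describes the world the generator emits: a gene pool, GO-style gene sets,
#' an interaction network that is denser inside gene sets than between them,
#' a two-condition expression matrix, and a mutated-gene catalog. A handful
#' of "planted" modules carry the signal the pipeline is meant to find:
#' their genes are co-expressed (pairwise correlation `rho` via a shared
#' latent factor), shifted by `delta` in the second condition, densely
#' interconnected (`p_in`), and mutated at `mutation_rate * mutation_multiplier`
#' instead of the background `mutation_rate`.
#'
#' Defaults encode a realistic desk-scale microarray study: 4000 genes,
#' 25 samples per condition, 200 noise gene sets of ~30 genes, 5 planted
#' modules of 8 genes, delta = 2 (log-scale units), rho = 0.6, background
#' somatic-mutation catalog covering 10\% of genes with a 5x excess inside
#' planted modules.
#'
#' @param n_genes size of the gene pool.
#' @param n_per_class samples per condition.
#' @param n_noise_sets number of signal-free gene sets.
#' @param set_size_mean,set_size_sd gene-set size distribution (sizes are
#'   rounded and floored at 10, mirroring curated GO collections).
#' @param n_planted,planted_size planted modules and their size.
#' @param delta expression shift of planted genes in condition B.
#' @param rho within-planted-module pairwise correlation, in \[0, 1).
#' @param p_in edge probability inside a planted module.
#' @param within_set_edge_p edge probability between genes of the same set.
#' @param background_edge_p edge probability for arbitrary gene pairs.
#' @param mutation_rate background per-gene mutation probability.
#' @param mutation_multiplier excess mutation factor inside planted modules.
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 4000, n_per_class = 25,
                           n_noise_sets = 200, set_size_mean = 30,
                           set_size_sd = 5, n_planted = 5, planted_size = 8,
                           delta = 2, rho = 0.6, p_in = 0.8,
                           within_set_edge_p = 0.15,
                           background_edge_p = 0.001,
                           mutation_rate = 0.1, mutation_multiplier = 5,
                           seed = 1) {
  spec <- as.list(environment())
  probs <- c(rho_ok = rho >= 0 && rho < 1,
             p = all(c(p_in, within_set_edge_p, background_edge_p,
                       mutation_rate) >= 0 &
                       c(p_in, within_set_edge_p, background_edge_p,
                         mutation_rate) <= 1))
  if (!all(probs)) stop("probabilities must lie in [0,1] and rho in [0,1)")
  if (planted_size >= set_size_mean)
    stop("planted modules must fit inside their host gene sets")
  class(spec) <- "SyntheticSpec"
  spec
}

# Build the static world: gene pool, planted assignments, GO sets and the
# reference interaction network. Consumes RNG state.
generate_world <- function(spec, n_planted = spec$n_planted) {
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  planted <- split(genes[seq_len(n_planted * spec$planted_size)],
                   rep(seq_len(n_planted), each = spec$planted_size))
  names(planted) <- sprintf("planted_%02d", seq_len(n_planted))
  free <- setdiff(genes, unlist(planted))

  set_size <- function() max(10L, round(stats::rnorm(1, spec$set_size_mean,
                                                     spec$set_size_sd)))
  sets <- list()
  for (m in names(planted)) {
    host <- c(planted[[m]],
              sample(free, max(2L, set_size() - spec$planted_size)))
    sets[[paste0("GO_HOST_", m)]] <- host
  }
  for (i in seq_len(spec$n_noise_sets))
    sets[[sprintf("GO_NOISE_%03d", i)]] <- sample(free, set_size())

  edges <- list()
  for (nm in names(sets)) {
    s <- sort(sets[[nm]])
    pr <- utils::combn(s, 2)
    keep <- stats::runif(ncol(pr)) < spec$within_set_edge_p
    edges[[nm]] <- t(pr[, keep, drop = FALSE])
  }
  for (m in names(planted)) {
    pr <- utils::combn(sort(planted[[m]]), 2)
    keep <- stats::runif(ncol(pr)) < spec$p_in
    edges[[paste0("in_", m)]] <- t(pr[, keep, drop = FALSE])
  }
  npairs <- spec$n_genes * (spec$n_genes - 1) / 2
  nbg <- stats::rbinom(1, npairs, spec$background_edge_p)
  if (nbg > 0) {
    i <- sample(spec$n_genes, nbg, replace = TRUE)
    j <- sample(spec$n_genes, nbg, replace = TRUE)
    ok <- i != j
    edges[["background"]] <- cbind(pmin(genes[i[ok]], genes[j[ok]]),
                                   pmax(genes[i[ok]], genes[j[ok]]))
  }
  em <- do.call(rbind, edges)
  net <- suppressMessages(interaction_network(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE)))
  list(genes = genes, planted = planted,
       collection = gene_set_collection(sets, source = "synthetic"),
       interactions = net)
}

# Expression matrix for one dataset: background genes i.i.d. N(0,1);
# genes of each active planted module share a latent factor (pairwise
# correlation rho) and gain +delta in condition B. Consumes RNG state.
generate_expression <- function(world, active_planted, spec, name) {
  n <- 2 * spec$n_per_class
  labels <- rep(c("A", "B"), each = spec$n_per_class)
  x <- matrix(stats::rnorm(length(world$genes) * n),
              nrow = length(world$genes),
              dimnames = list(world$genes,
                              sprintf("%s_s%02d", name, seq_len(n))))
  for (m in active_planted) {
    gs <- world$planted[[m]]
    f <- stats::rnorm(n)
    x[gs, ] <- sqrt(spec$rho) * matrix(f, length(gs), n, byrow = TRUE) +
      sqrt(1 - spec$rho) * x[gs, ]
    x[gs, labels == "B"] <- x[gs, labels == "B"] + spec$delta
  }
  expression_study(x, labels, name = name)
}

# Mutated-gene set for one dataset. Consumes RNG state.
generate_mutations <- function(world, active_planted, spec) {
  rate <- rep(spec$mutation_rate, length(world$genes))
  names(rate) <- world$genes
  for (m in active_planted)
    rate[world$planted[[m]]] <-
      pmin(1, spec$mutation_rate * spec$mutation_multiplier)
  sort(world$genes[stats::runif(length(rate)) < rate])
}

#' Generate a complete synthetic study
#'
#' Emits every input the pipeline needs — expression study, gene-set
#' collection, interaction network, mutation catalog — plus the planted
#' ground truth. Fully deterministic in `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `study`, `collection`, `interactions`, `mutations`
#'   (a MutationCatalog with one condition) and `truth` (list: `planted`
#'   gene sets, `de_genes`, `mutated_genes`).
#' @export
generate_study <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  world <- generate_world(spec)
  active <- names(world$planted)
  study <- generate_expression(world, active, spec, name = "synth")
  mut <- generate_mutations(world, active, spec)
  truth <- list(planted = world$planted,
                de_genes = if (spec$delta != 0)
                  sort(unlist(world$planted, use.names = FALSE))
                else character(),
                mutated_genes = mut)
  list(study = study, collection = world$collection,
       interactions = world$interactions,
       mutations = mutation_catalog(list(synth = mut)), truth = truth)
}

#' Generate a multi-type, multi-dataset synthetic layout
#'
#' Emulates the cancer-type layout of a multi-cohort compendium: each cancer
#' type has 1 or 2 datasets, every type gets private planted modules, and
#' designated type pairs additionally share planted modules whose mutated
#' genes therefore surface in the core modules of both types. All datasets
#' share the gene pool, gene sets and reference interaction network.
#'
#' @param types named list: cancer type -> character vector of 1 or 2
#'   dataset names.
#' @param shared list of character pairs: types sharing one planted module
#'   each (default: none).
#' @param spec a [synthetic_spec()]; `n_planted` is ignored (derived from
#'   the layout: one private module per type plus one per shared pair).
#' @param modules_per_type private planted modules per type (default 1).
#' @return List with `datasets` (named list of per-dataset lists `study`,
#'   `mutated`), `collection`, `interactions`, `dataset_types` (named
#'   vector dataset -> type), `truth` (planted module assignment per type).
#' @export
generate_multitype_layout <- function(types, shared = list(),
                                      spec = synthetic_spec(),
                                      modules_per_type = 1) {
  if (any(lengths(types) > 2L))
    stop("at most 2 datasets per type are supported")
  if (any(vapply(shared, length, 0L) != 2L) ||
      !all(unlist(shared) %in% names(types)))
    stop("`shared` must be pairs of type names from `types`")
  set.seed(spec$seed)
  n_private <- modules_per_type * length(types)
  n_mod <- n_private + length(shared)
  world <- generate_world(spec, n_planted = n_mod)
  mods <- names(world$planted)
  owner <- split(mods[seq_len(n_private)],
                 rep(names(types), each = modules_per_type))
  for (i in seq_along(shared)) {
    m <- mods[n_private + i]
    for (ty in shared[[i]]) owner[[ty]] <- c(owner[[ty]], m)
  }
  dataset_types <- stats::setNames(
    rep(names(types), lengths(types)), unlist(types))
  datasets <- list()
  for (ds in names(dataset_types)) {
    active <- owner[[dataset_types[[ds]]]]
    datasets[[ds]] <- list(
      study = generate_expression(world, active, spec, name = ds),
      mutated = generate_mutations(world, active, spec))
  }
  list(datasets = datasets, collection = world$collection,
       interactions = world$interactions, dataset_types = dataset_types,
       truth = list(planted = world$planted, owner = owner))
}

#' Write all components of a generated study to a directory
#'
#' Files use the exact on-disk formats of the readers: `expression.tsv`,
#' `gene_sets.gmt`, `interactions.tsv`, `mutations.tsv`.
#'
#' @param generated output of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_files <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(generated$study, file.path(dir, "expression.tsv"))
  write_gene_sets(generated$collection, file.path(dir, "gene_sets.gmt"))
  write_interactions(generated$interactions,
                     file.path(dir, "interactions.tsv"))
  write_mutations(generated$mutations, file.path(dir, "mutations.tsv"))
  invisible(dir)
}
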