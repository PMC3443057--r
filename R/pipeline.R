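#' Pipeline configuration
#'
#' Bundles the shared inputs and tuning parameters of the core-module
#' pipeline. Defaults follow the published procedure where it states them:
#' module size limit 20, top-100 ranked modules, Fisher cutoff 0.05,
#' relatedness shortest-path cutoff 0.
#'
#' @param gene_sets a GeneSetCollection.
#' @param interactions an InteractionNetwork.
#' @param kind correlation flavour for edge weights ("pearson" or
#'   "spearman").
#' @param min_size minimum GO-cluster size (default 3).
#' @param size_limit module size cap for the partitioner (default 20).
#' @param K number of top-ranked modules (default 100).
#' @param fisher_alpha mutated-module cutoff (default 0.05).
#' @param relatedness_cutoff shortest-path allowance for network
#'   relatedness (default 0).
#' @param betweenness_mode see [weighted_edge_betweenness()].
#' @param seed base RNG seed for stochastic stages.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(gene_sets, interactions,
                            kind = c("pearson", "spearman"),
                            min_size = 3, size_limit = 20, K = 100,
                            fisher_alpha = 0.05, relatedness_cutoff = 0,
                            betweenness_mode = c("divide", "dijkstra"),
                            seed = 1) {
  structure(list(gene_sets = gene_sets, interactions = interactions,
                 kind = match.arg(kind), min_size = min_size,
                 size_limit = size_limit, K = K,
                 fisher_alpha = fisher_alpha,
                 relatedness_cutoff = relatedness_cutoff,
                 betweenness_mode = match.arg(betweenness_mode),
                 seed = seed),
            class = "PipelineConfig")
}

#' Run Steps 1-3 for one study: GO networks, partition, rank
#'
#' @param study an ExpressionStudy.
#' @param config a [pipeline_config()].
#' @return List with `modules` (named list of gene vectors), `ranked`
#'   (see [rank_modules()]), `universe` (genes in any GO network) and
#'   `n_clusters`.
#' @export
score_modules_for_study <- function(study, config) {
  nets <- build_go_networks(config$gene_sets, study, config$interactions,
                            min_size = config$min_size, kind = config$kind)
  modules <- list()
  cluster_of <- character()
  for (nm in names(nets)) {
    mods <- partition_modules(nets[[nm]], size_limit = config$size_limit,
                              mode = config$betweenness_mode)
    if (length(mods)) {
      ids <- sprintf("%s.m%d", nm, seq_along(mods))
      names(mods) <- ids
      modules <- c(modules, mods)
      cluster_of <- c(cluster_of, stats::setNames(rep(nm, length(mods)),
                                                  ids))
    }
  }
  if (!length(modules))
    stop("no module produced; check gene-set / network / expression overlap")
  t_scores <- gene_t_scores(study, standardize = TRUE)
  ranked <- rank_modules(modules, t_scores, K = config$K)
  list(modules = modules, cluster_of = cluster_of, ranked = ranked,
       universe = sort(unique(unlist(lapply(nets, `[[`, "genes"),
                                     use.names = FALSE))),
       n_clusters = length(nets))
}

#' Identify the core modules of one study
#'
#' Steps 1-4: score and rank modules, test each for mutation enrichment and
#' intersect the mutated modules with the top-ranked ones.
#'
#' @param study an ExpressionStudy.
#' @param mutated mutated gene symbols for the study's condition.
#' @param config a [pipeline_config()].
#' @return List with everything from [score_modules_for_study()] plus `mm`
#'   (enrichment table), `core` (core-module table), `mm_enrichment`
#'   (the MM enrichment score) and `core_gene_sets`.
#' @export
find_core_modules <- function(study, mutated, config) {
  scored <- score_modules_for_study(study, config)
  mm <- module_mutation_tests(scored$modules, mutated, scored$universe,
                              alpha = config$fisher_alpha)
  core <- core_modules(scored$ranked, mm)
  is_mm <- mm$is_MM[match(scored$ranked$module_id, mm$module_id)]
  scored$mm <- mm
  scored$core <- core
  scored$mm_enrichment <- mm_enrichment_score(scored$ranked$is_TRM, is_mm)
  scored$core_gene_sets <- attr(core, "genes")
  scored
}

#' Run the full multi-dataset core-module pipeline
#'
#' For every dataset: builds the weighted GO networks, partitions them,
#' ranks modules by differential expression, tests mutation enrichment and
#' extracts core modules. Across datasets it builds the mutated-gene
#' networks, their topology summaries, the relatedness and distance
#' matrices, and (with >= 3 datasets) the neighbor-joining tree. All tables
#' are written under `out_dir` together with a JSON run manifest.
#'
#' @param studies named list of ExpressionStudy objects.
#' @param catalog a MutationCatalog whose conditions cover the study names.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); NULL skips writing.
#' @return Named list of per-dataset [find_core_modules()] results, with
#'   attributes `relatedness`, `distance`, `newick`, `topology`.
#' @export
run_core_module_pipeline <- function(studies, catalog, config,
                                     out_dir = NULL) {
  missing <- setdiff(names(studies), names(catalog$conditions))
  if (length(missing))
    stop("stage mutation_core: no mutation catalog for dataset(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (ds in names(studies)) {
    res <- tryCatch(
      find_core_modules(studies[[ds]], catalog$conditions[[ds]], config),
      error = function(e) stop("stage core_modules [", ds, "]: ",
                               conditionMessage(e), call. = FALSE))
    message(sprintf(
      "[%s] %d GO clusters, %d modules, %d MMs, %d core modules",
      ds, res$n_clusters, length(res$modules), sum(res$mm$is_MM),
      nrow(res$core)))
    if (!is.null(out_dir)) {
      write_ranked_modules(res$ranked,
                           file.path(out_dir, paste0(ds, "_modules.tsv")))
      write_core_modules(res$core,
                         file.path(out_dir, paste0(ds, "_core.tsv")))
    }
    results[[ds]] <- res
  }

  mut_nets <- lapply(names(studies), function(ds)
    sort(unique(intersect(unlist(results[[ds]]$core_gene_sets,
                                 use.names = FALSE),
                          catalog$conditions[[ds]]))))
  names(mut_nets) <- names(studies)
  topo <- lapply(mut_nets, function(gs) {
    e <- config$interactions$edges
    e <- e[e$from %in% gs & e$to %in% gs, , drop = FALSE]
    if (length(gs) >= 1)
      topology_summary(e, nodes = gs)
    else NULL
  })
  attr(results, "mutated_gene_sets") <- mut_nets
  attr(results, "topology") <- topo

  nonempty <- names(mut_nets)[lengths(mut_nets) > 0]
  if (length(nonempty) >= 2) {
    R <- relatedness_matrix(mut_nets[nonempty], config$interactions,
                            cutoff = config$relatedness_cutoff)
    D <- distance_from_relatedness(R)
    attr(results, "relatedness") <- R
    attr(results, "distance") <- D
    if (length(nonempty) >= 3 && all(is.finite(D))) {
      nj <- neighbor_joining(D)
      attr(results, "newick") <- nj$newick
      if (!is.null(out_dir))
        writeLines(nj$newick, file.path(out_dir, "tree.nwk"))
    }
    if (!is.null(out_dir))
      write_phylip_distances(D, file.path(out_dir, "distance.phylip"))
  }
  if (!is.null(out_dir)) {
    manifest <- list(
      datasets = names(studies),
      parameters = config[setdiff(names(config),
                                  c("gene_sets", "interactions"))],
      n_gene_sets = length(config$gene_sets$sets),
      n_interactions = nrow(config$interactions$edges),
      versions = list(coremod = as.character(
        utils::packageVersion("coremod")), R = R.version.string))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}

#' Run the split-half reproducibility protocol
#'
#' @param study an ExpressionStudy.
#' @param config a [pipeline_config()].
#' @param trials number of trials (>= 1).
#' @param mode "split_half" or "permutation" (label-shuffled control).
#' @param include_trg also score the single-gene comparator.
#' @param out_path optional TSV path for the trial log.
#' @return List of [split_half_trial()] results.
#' @export
run_reproducibility <- function(study, config, trials = 10,
                                mode = c("split_half", "permutation"),
                                include_trg = FALSE, out_path = NULL) {
  mode <- match.arg(mode)
  if (trials < 1) stop("trials must be >= 1")
  seeds <- config$seed + seq_len(trials) - 1L
  res <- lapply(seeds, function(s)
    split_half_trial(study, config, seed = s,
                     permute_labels = mode == "permutation",
                     include_trg = include_trg))
  if (!is.null(out_path)) write_trial_log(res, out_path)
  res
}

# Read a sample -> class label table (two tab-separated columns).
read_label_spec <- function(path) {
  lines <- read_clean_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(trimws(vapply(parts, `[`, "", 2L)),
                  trimws(vapply(parts, `[`, "", 1L)))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic study to disk), `run-all`
#' (full pipeline on files), `reproduce` (split-half / permutation trials).
#' Run `coremod_cli("help")` for usage. Designed to be called from an
#' Rscript wrapper, e.g.
#' `Rscript -e 'coremod::coremod_cli()' simulate --out-dir sim`.
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
coremod_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: coremod <simulate|run-all|reproduce> [options]",
    "  simulate  --out-dir DIR [--seed N]",
    "  run-all   --expression F --labels F --gene-sets F --interactions F",
    "            --mutations F --out-dir DIR [--k N] [--size-limit N]",
    "            [--fisher-alpha X] [--min-size N] [--kind pearson|spearman]",
    "            [--cutoff 0|1|2] [--seed N]",
    "  reproduce (inputs as run-all) --trials N [--mode split_half|permutation]",
    sep = "\n")
  if (!length(args) || args[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- parse_cli_options(args[-1])
  get <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else default
  }
  if (cmd == "simulate") {
    spec <- synthetic_spec(seed = as.integer(get("seed", 1)))
    dir <- get("out-dir", stop("--out-dir required"))
    write_study_files(generate_study(spec), dir)
    message("synthetic study written to ", dir)
    return(invisible(dir))
  }
  if (!cmd %in% c("run-all", "reproduce")) stop("unknown subcommand: ", cmd)
  study <- read_expression_matrix(get("expression"),
                                  read_label_spec(get("labels")))
  config <- pipeline_config(
    gene_sets = read_gene_sets(get("gene-sets")),
    interactions = read_interactions(get("interactions")),
    kind = get("kind", "pearson"),
    min_size = as.integer(get("min-size", 3)),
    size_limit = as.integer(get("size-limit", 20)),
    K = as.integer(get("k", 100)),
    fisher_alpha = as.numeric(get("fisher-alpha", 0.05)),
    relatedness_cutoff = as.integer(get("cutoff", 0)),
    seed = as.integer(get("seed", 1)))
  if (cmd == "run-all") {
    catalog <- read_mutations(get("mutations"))
    if (length(catalog$conditions) == 1L)
      names(catalog$conditions) <- study$name
    res <- run_core_module_pipeline(
      stats::setNames(list(study), study$name), catalog, config,
      out_dir = get("out-dir", stop("--out-dir required")))
    return(invisible(res))
  }
  res <- run_reproducibility(
    study, config, trials = as.integer(get("trials", 10)),
    mode = get("mode", "split_half"),
    out_path = file.path(get("out-dir", "."), "trials.tsv"))
  invisible(res)
}

# Parse "--key value" pairs into a named list.
parse_cli_options <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}
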