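#' Overlap of two gene sets (intersection over union)
#'
#' The overlap percentage is the Jaccard fraction |A n B| / |A u B|. When a
#' gene universe is supplied, the significance of the overlap is assessed by
#' a one-sided Fisher exact test on the 2x2 membership table.
#'
#' @param set_a,set_b character vectors (at least one non-empty).
#' @param universe optional background gene set containing both.
#' @return List `overlap_fraction`, `n_intersection`, `n_union`, `fisher_p`
#'   (NA without a universe).
#' @export
overlap_percentage <- function(set_a, set_b, universe = NULL) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b))
    return(list(overlap_fraction = NA_real_, n_intersection = 0L,
                n_union = 0L, fisher_p = NA_real_))
  i <- length(intersect(set_a, set_b))
  u <- length(union(set_a, set_b))
  p <- NA_real_
  if (!is.null(universe)) {
    n <- length(unique(universe))
    if (u > n) stop("sets exceed the stated universe")
    tab <- matrix(c(i, length(set_a) - i, length(set_b) - i, n - u),
                  nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(overlap_fraction = i / u, n_intersection = i, n_union = u,
       fisher_p = p)
}

#' Stratified split of samples into two halves
#'
#' @param labels factor of sample class labels.
#' @param stratified keep class proportions in each half (default TRUE).
#' @return List of two integer index vectors.
#' @keywords internal
split_samples <- function(labels, stratified = TRUE) {
  n <- length(labels)
  if (stratified) {
    half1 <- integer()
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < 4)
        stop("class '", lv, "' needs >= 4 samples for a split-half trial")
      half1 <- c(half1, sample(idx, floor(length(idx) / 2)))
    }
  } else {
    half1 <- sample(n, floor(n / 2))
  }
  half1 <- sort(half1)
  list(half1, setdiff(seq_len(n), half1))
}

# Subset an ExpressionStudy to a set of sample indices.
subset_study <- function(study, idx, suffix = "") {
  expression_study(study$values[, idx, drop = FALSE],
                   as.character(study$labels)[idx],
                   name = paste0(study$name, suffix))
}

#' One split-half reproducibility trial
#'
#' Splits the samples into two halves (stratified by class), runs the whole
#' module pipeline through TRM selection independently on each half, and
#' measures the overlap of the two TRM gene sets. Optionally the same split
#' is also scored with equally many top single-gene t-test hits (TRGs),
#' matching each half's TRM gene count.
#'
#' @param study an ExpressionStudy (>= 4 samples per class).
#' @param config a [pipeline_config()] carrying `gene_sets`, `interactions`
#'   and the tuning parameters.
#' @param seed RNG seed for the split (and label permutation).
#' @param permute_labels shuffle the class labels before splitting
#'   (negative control).
#' @param include_trg also compute the single-gene comparator overlap.
#' @param stratified see [split_samples()].
#' @return List with `trm` (an [overlap_percentage()] result), `trg`
#'   (ditto or NULL), `seed`, `permuted`.
#' @export
split_half_trial <- function(study, config, seed = 1,
                             permute_labels = FALSE, include_trg = FALSE,
                             stratified = TRUE) {
  set.seed(seed)
  labels <- study$labels
  if (permute_labels) {
    labels <- sample(labels)
    study$labels <- labels
  }
  halves <- split_samples(labels, stratified = stratified)
  universe <- NULL
  trm_sets <- list(); trg_sets <- list()
  for (h in 1:2) {
    sub <- subset_study(study, halves[[h]], suffix = paste0(".h", h))
    res <- score_modules_for_study(sub, config)
    if (is.null(universe)) universe <- res$universe
    trm_sets[[h]] <- trm_genes(res$ranked)
    if (include_trg)
      trg_sets[[h]] <- rank_genes_ttest(sub, M = length(trm_sets[[h]]))
  }
  out <- list(trm = overlap_percentage(trm_sets[[1]], trm_sets[[2]],
                                       universe = study$genes),
              seed = seed, permuted = permute_labels)
  if (include_trg)
    out$trg <- overlap_percentage(trg_sets[[1]], trg_sets[[2]],
                                  universe = study$genes)
  out
}

#' Permutation control distribution for split-half overlaps
#'
#' Runs [split_half_trial()] with label shuffling for each seed, producing
#' the null (TRM_P / TRG_P) overlap distribution.
#'
#' @param study an ExpressionStudy.
#' @param config a [pipeline_config()].
#' @param seeds one seed per control trial (length >= 1).
#' @param include_trg also compute the single-gene comparator.
#' @return List of [split_half_trial()] results, one per seed.
#' @export
permutation_control <- function(study, config, seeds, include_trg = FALSE) {
  if (!length(seeds)) stop("need >= 1 permutation seed")
  lapply(seeds, function(s)
    split_half_trial(study, config, seed = s, permute_labels = TRUE,
                     include_trg = include_trg))
}

#' One-sided iterative Grubbs outlier test (upper tail)
#'
#' Repeatedly tests G = (max(x) - mean(x)) / sd(x) against the one-sided
#' critical value G_crit = ((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2)) with
#' t the upper alpha/n quantile of the t distribution on n - 2 degrees of
#' freedom, removing the detected maximum and repeating until no rejection.
#' Removal is capped at 20\% of the values.
#'
#' @param values numeric vector, length >= 3.
#' @param one_tail_alpha significance level (default 0.05).
#' @return Integer indices (into `values`) of the detected upper outliers.
#' @export
grubbs_test <- function(values, one_tail_alpha = 0.05) {
  if (length(values) < 3) stop("need >= 3 values")
  if (stats::sd(values) == 0) {
    warning("zero standard deviation; no outliers")
    return(integer())
  }
  active <- seq_along(values)
  outliers <- integer()
  max_remove <- ceiling(0.2 * length(values))
  while (length(outliers) < max_remove && length(active) >= 3) {
    x <- values[active]
    s <- stats::sd(x)
    if (s == 0) break
    g <- (max(x) - mean(x)) / s
    n <- length(x)
    tq <- stats::qt(one_tail_alpha / n, df = n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g <= gcrit) break
    hit <- active[which.max(x)]
    outliers <- c(outliers, hit)
    active <- setdiff(active, hit)
  }
  outliers
}

#' Write a reproducibility trial log as TSV
#' @param trials list of [split_half_trial()] results.
#' @param path output path.
#' @export
write_trial_log <- function(trials, path) {
  df <- data.frame(
    trial_id = seq_along(trials),
    seed = vapply(trials, `[[`, 0, "seed"),
    permuted = vapply(trials, `[[`, TRUE, "permuted"),
    overlap_fraction = vapply(trials, function(t) t$trm$overlap_fraction, 0),
    fisher_p = vapply(trials, function(t) t$trm$fisher_p, 0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
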