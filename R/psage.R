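#' Per-gene two-sample t scores
#'
#' Welch (unequal-variance) t statistic per gene, oriented first class minus
#' second class (factor level order). A pooled-variance Student flavour is
#' available via `var_equal = TRUE`. A gene whose two class means are equal
#' with zero variance in both classes gets T = 0 with a warning.
#'
#' With `standardize = TRUE` each t score is mapped to its exact standard
#' normal quantile, z = qnorm(pt(T, df)), preserving sign and order. The
#' module score's chi-square reference distribution assumes standard-normal
#' inputs; the raw t is only asymptotically normal, so squared raw scores
#' are slightly overdispersed at finite sample sizes (var t = df/(df-2)).
#' The module-scoring pipeline therefore standardizes by default; the raw
#' statistic remains the default of this function.
#'
#' @param study an ExpressionStudy (complete; impute first).
#' @param var_equal use the pooled-variance statistic instead of Welch.
#' @param standardize map each t to its exact null normal quantile.
#' @return Named numeric vector of t scores (sign retained), plus attributes
#'   `df` (per-gene degrees of freedom) used by [rank_genes_ttest()].
#' @export
gene_t_scores <- function(study, var_equal = FALSE, standardize = FALSE) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (anyNA(study$values)) stop("missing values present; impute first")
  a <- study$values[, study$labels == levels(study$labels)[1], drop = FALSE]
  b <- study$values[, study$labels == levels(study$labels)[2], drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep.int(na + nb - 2, nrow(study$values))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / sqrt(se2)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with zero variance in both classes; ",
            "T set to 0 where means are equal")
    t[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 0, Inf *
                              sign(ma - mb)[degenerate])
    df[degenerate] <- na + nb - 2
  }
  if (standardize) {
    z <- t
    neg <- !is.na(t) & t <= 0
    # log-scale tail transforms keep extreme scores finite and antisymmetric
    z[neg] <- stats::qnorm(stats::pt(t[neg], df[neg], log.p = TRUE),
                           log.p = TRUE)
    z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df[!neg], log.p = TRUE),
                             log.p = TRUE)
    t <- z
  }
  names(t) <- study$genes
  attr(t, "df") <- unname(df)
  t
}

#' Module differential-expression score (quadratic sum of t scores)
#'
#' SDS = sum of squared member-gene t scores; invariant to t-score signs.
#'
#' @param genes character vector of module member genes.
#' @param t_scores named vector from [gene_t_scores()].
#' @return The SDS (>= 0).
#' @export
module_sds <- function(genes, t_scores) {
  missing <- setdiff(genes, names(t_scores))
  if (length(missing))
    stop("module gene(s) without a t score: ",
         paste(missing, collapse = ", "))
  sum(t_scores[genes]^2)
}

#' Module p-value from the chi-square reference distribution
#'
#' Under no differential expression the quadratic sum of n (approximately
#' standard-normal) t scores is referred to a chi-square distribution with
#' n degrees of freedom; the p-value is its upper tail at the observed SDS.
#'
#' @param sds the module score, >= 0.
#' @param n module size (degrees of freedom).
#' @return Upper-tail probability in (0, 1].
#' @export
module_pvalue <- function(sds, n) {
  stopifnot(all(sds >= 0), all(n >= 1))
  stats::pchisq(sds, df = n, lower.tail = FALSE)
}

#' Score and rank modules by differential expression
#'
#' Computes SDS and chi-square p per module and ranks ascending by p. Ties
#' are broken by larger SDS, then module id, for determinism. The top `K`
#' modules are flagged as top-ranked modules (TRMs).
#'
#' @param modules named list of gene vectors (names become module ids;
#'   unnamed lists get ids "m1", "m2", ...).
#' @param t_scores from [gene_t_scores()].
#' @param K how many top modules to flag (default 100, capped at the module
#'   count).
#' @return data.frame `module_id`, `size`, `SDS`, `p_value`, `rank`,
#'   `is_TRM`, ordered by rank, with the gene lists in attribute `genes`.
#' @export
rank_modules <- function(modules, t_scores, K = 100) {
  if (!length(modules)) stop("no modules to rank")
  if (is.null(names(modules)))
    names(modules) <- paste0("m", seq_along(modules))
  K <- min(K, length(modules))
  sds <- vapply(modules, module_sds, 0, t_scores = t_scores)
  n <- lengths(modules)
  p <- module_pvalue(sds, n)
  ord <- order(p, -sds, names(modules))
  df <- data.frame(module_id = names(modules)[ord], size = n[ord],
                   SDS = sds[ord], p_value = p[ord],
                   rank = seq_along(ord),
                   is_TRM = seq_along(ord) <= K,
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "genes") <- modules[ord]
  df
}

#' Genes in the top-ranked modules
#' @param ranked output of [rank_modules()].
#' @return Sorted character vector: union of genes of modules with
#'   `is_TRM = TRUE`.
#' @export
trm_genes <- function(ranked) {
  sort(unique(unlist(attr(ranked, "genes")[ranked$is_TRM],
                     use.names = FALSE)))
}

#' Single-gene t-test ranking (top-ranked genes, the module comparator)
#'
#' Ranks genes by two-sided t-test p-value (Welch by default) and returns
#' the top `M` gene symbols. Invariant to swapping the class labels.
#'
#' @param study an ExpressionStudy.
#' @param M number of genes to return (0 gives an empty vector).
#' @param var_equal see [gene_t_scores()].
#' @return Character vector of `M` gene symbols, most significant first.
#' @export
rank_genes_ttest <- function(study, M, var_equal = FALSE) {
  if (M > length(study$genes)) stop("M exceeds the gene count")
  if (M == 0) return(character())
  t <- gene_t_scores(study, var_equal = var_equal)
  p <- 2 * stats::pt(abs(t), df = attr(t, "df"), lower.tail = FALSE)
  ord <- order(p, -abs(t), names(t))
  names(t)[ord][seq_len(M)]
}

#' Write a ranked-module table as TSV
#' @param ranked output of [rank_modules()].
#' @param path output path.
#' @export
write_ranked_modules <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
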