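#' Fisher test for mutation enrichment of one module
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table crossing module
#' membership with mutation status over a gene universe. The universe should
#' be the genes that could have entered modules (all genes appearing in any
#' GO network of the dataset).
#'
#' @param genes module member genes (must lie within `universe`).
#' @param mutated set of mutated gene symbols.
#' @param universe the background gene set.
#' @param alpha significance cutoff for calling a mutated module (MM).
#' @return List with the table counts `a` (mutated in module), `b`, `c`,
#'   `d`, `fisher_p` and `is_MM` (fisher_p <= alpha).
#' @export
module_mutation_test <- function(genes, mutated, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty gene universe")
  out <- setdiff(genes, universe)
  if (length(out))
    stop("module gene(s) outside the universe: ",
         paste(out, collapse = ", "))
  mutated <- intersect(mutated, universe)
  a <- length(intersect(genes, mutated))
  b <- length(genes) - a
  c <- length(mutated) - a
  d <- length(universe) - a - b - c
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                          alternative = "greater")$p.value
  list(a = a, b = b, c = c, d = d, fisher_p = p, is_MM = p <= alpha)
}

#' Mutation-enrichment results for a set of modules
#'
#' @param modules named list of gene vectors.
#' @param mutated set of mutated gene symbols.
#' @param universe background gene set.
#' @param alpha MM cutoff (default 0.05, uncorrected as is conventional for
#'   this screen).
#' @param adjust "none" (default) or "BH" to apply Benjamini-Hochberg before
#'   the cutoff.
#' @return data.frame `module_id`, `size`, `n_mutated`, `fisher_p`, `is_MM`.
#' @export
module_mutation_tests <- function(modules, mutated, universe, alpha = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(names(modules)))
    names(modules) <- paste0("m", seq_along(modules))
  res <- lapply(modules, module_mutation_test, mutated = mutated,
                universe = universe, alpha = alpha)
  p <- vapply(res, `[[`, 0, "fisher_p")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(module_id = names(modules), size = lengths(modules),
             n_mutated = vapply(res, `[[`, 0L, "a"),
             fisher_p = unname(p), is_MM = unname(p <= alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Core modules: mutation-enriched members of the top-ranked set
#'
#' @param ranked output of [rank_modules()].
#' @param mm output of [module_mutation_tests()] covering the same modules.
#' @return data.frame of the core modules (both `is_TRM` and `is_MM`), with
#'   columns from both tables and the gene lists in attribute `genes`.
#' @export
core_modules <- function(ranked, mm) {
  if (!all(ranked$module_id %in% mm$module_id))
    stop("mutation results do not cover all ranked modules")
  merged <- merge(ranked, mm[, c("module_id", "n_mutated", "fisher_p",
                                 "is_MM")], by = "module_id")
  merged <- merged[order(merged$rank), , drop = FALSE]
  core <- merged[merged$is_TRM & merged$is_MM, , drop = FALSE]
  rownames(core) <- NULL
  attr(core, "genes") <- attr(ranked, "genes")[core$module_id]
  core
}

#' Mutated-module enrichment score
#'
#' Ratio of the MM fraction among top-ranked modules to the MM fraction
#' among the remaining modules. Values above 1 indicate that differential
#' expression concentrates the mutation-enriched modules.
#'
#' @param is_TRM,is_MM logical vectors over the same modules.
#' @return The ratio; `Inf` (with a warning) when no non-TRM module is an
#'   MM but some TRM is; `NaN` when neither group has an MM.
#' @export
mm_enrichment_score <- function(is_TRM, is_MM) {
  stopifnot(length(is_TRM) == length(is_MM))
  if (!any(is_TRM) || all(is_TRM))
    stop("both TRM and non-TRM groups must be non-empty")
  f_trm <- mean(is_MM[is_TRM])
  f_rest <- mean(is_MM[!is_TRM])
  if (f_rest == 0 && f_trm > 0) {
    warning("no mutated module outside the TRMs; score is +Inf")
    return(Inf)
  }
  if (f_rest == 0 && f_trm == 0) return(NaN)
  f_trm / f_rest
}

#' Gene-level mutated-fraction ratio (single-gene comparator)
#'
#' Ratio of the mutated-gene fraction in one gene set (e.g. TRM genes) to
#' that in another (e.g. equally many top t-test genes).
#'
#' @param genes_a,genes_b non-empty gene sets.
#' @param mutated mutated gene symbols.
#' @return The ratio; `NaN` when neither set contains a mutated gene; `Inf`
#'   (warning) when only the second set lacks one.
#' @export
mutated_gene_fraction_ratio <- function(genes_a, genes_b, mutated) {
  if (!length(genes_a) || !length(genes_b)) stop("both gene sets non-empty")
  fa <- mean(genes_a %in% mutated)
  fb <- mean(genes_b %in% mutated)
  if (fb == 0 && fa == 0) return(NaN)
  if (fb == 0) {
    warning("no mutated gene in the comparison set; ratio is +Inf")
    return(Inf)
  }
  fa / fb
}

#' Write a core-module table as TSV
#' @param core output of [core_modules()].
#' @param path output path.
#' @export
write_core_modules <- function(core, path) {
  df <- core
  df$genes <- vapply(attr(core, "genes"), paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
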