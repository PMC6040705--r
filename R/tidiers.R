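#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a center comparison
#'
#' One row per (metric, test): the Kruskal-Wallis and randomized-block
#' ANOVA results stacked, plus the pairwise comparisons when
#' `pairwise = TRUE`.
#'
#' @param x A [compare_centers()] object.
#' @param pairwise Include the pairwise rows.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `test`, `statistic`,
#'   `p_value` (pairwise rows add `center_a`, `center_b`, `conf_low`,
#'   `conf_high`).
#' @method tidy center_comparison
#' @export
tidy.center_comparison <- function(x, pairwise = FALSE, ...) {
  out <- dplyr::bind_rows(
    dplyr::mutate(x$kruskal[, c("metric", "statistic", "p_value")],
                  test = "kruskal_wallis", .after = "metric"),
    dplyr::mutate(x$anova[, c("metric", "statistic", "p_value")],
                  test = "block_anova", .after = "metric"))
  if (pairwise) {
    pw <- dplyr::mutate(
      x$pairwise[, c("metric", "center_a", "center_b", "mean_diff",
                     "conf_low", "conf_high", "p_value")],
      test = "paired_t", .after = "metric")
    out <- dplyr::bind_rows(out, pw)
  }
  out
}

#' Glance at a center comparison
#'
#' @param x A [compare_centers()] object.
#' @param alpha Significance level used for the significant-metric counts.
#' @param ... Unused.
#' @return A one-row tibble: number of centers, shared samples, metrics,
#'   and how many metrics each omnibus test flags at `alpha`.
#' @method glance center_comparison
#' @export
glance.center_comparison <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_centers = length(x$centers),
    n_shared_samples = length(x$shared_samples),
    n_metrics = nrow(x$kruskal),
    n_sig_kruskal = sum(x$kruskal$p_value < alpha, na.rm = TRUE),
    n_sig_anova = sum(x$anova$p_value < alpha, na.rm = TRUE))
}

#' Tidy a prioritization result
#'
#' @param x A [prioritize_lof()] result.
#' @param ... Unused.
#' @return A tibble with one row per variant: key columns, `retained`,
#'   and the exclusion `reason` (NA for retained variants).
#' @method tidy prioritization
#' @export
tidy.prioritization <- function(x, ...) {
  tibble::as_tibble(x)[, c("chrom", "pos", "ref", "alt", "gene",
                           "retained", "reason", "case_alt_count",
                           "parent_alt_count", "replicate_concordance")]
}

#' Glance at a prioritization result
#'
#' @param x A [prioritize_lof()] result.
#' @param ... Unused.
#' @return A one-row tibble: input, retained, and per-reason exclusion
#'   counts.
#' @method glance prioritization
#' @export
glance.prioritization <- function(x, ...) {
  led <- attr(x, "ledger")
  tibble::tibble(n_input = nrow(x),
                 n_retained = sum(x$retained),
                 n_excluded_lof = sum(x$reason == "lof", na.rm = TRUE),
                 n_excluded_rarity = sum(x$reason == "rarity", na.rm = TRUE),
                 n_excluded_case = sum(x$reason == "case_occurrence",
                                       na.rm = TRUE),
                 n_excluded_parental = sum(x$reason == "parental",
                                           na.rm = TRUE),
                 n_excluded_replication = sum(x$reason == "replication",
                                              na.rm = TRUE))
}
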