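#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline facet_wrap labs scale_y_log10
NULL

#' Plot a k-mer multiplicity spectrum
#'
#' Distinct-canonical-k-mer counts against multiplicity on a log count
#' scale; the error tail sits at low multiplicity and the main peak
#' tracks k-mer-space coverage.
#'
#' @param object A [kmer_spectrum()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmer_spectrum
#' @export
autoplot.kmer_spectrum <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$multiplicity, y = .data$n_kmers)) +
    geom_col(width = 1, fill = "steelblue") +
    scale_y_log10() +
    labs(x = "23-mer multiplicity", y = "distinct canonical 23-mers",
         title = "k-mer multiplicity spectrum")
}

#' Plot a windowed copy-number profile
#'
#' Copy number along the genome per sample, with the diploid baseline at
#' 2 marked.
#'
#' @param object A [compute_cn()] profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cn_profile
#' @export
autoplot.cn_profile <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = (.data$start + .data$end) / 2, y = .data$cn)) +
    geom_point(size = 0.4, alpha = 0.6) +
    geom_hline(yintercept = 2, linetype = "dashed", colour = "grey40") +
    facet_wrap(~sample) +
    labs(x = "genomic position (bp)", y = "copy number",
         title = "Window copy-number profile")
}

#' Plot pairwise call-set concordance metrics
#'
#' Bar panel of precision, sensitivity and F-measure for a pairwise
#' call-set comparison.
#'
#' @param object A [genotype_concordance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance
#' @export
autoplot.concordance <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("precision", "sensitivity", "f_measure")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = NULL, title = "Genotype concordance") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
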