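#' Flag read pairs carrying adapter sequence or uncalled bases
#'
#' A pair is unclean when either mate contains any of the adapter
#' sequences as an exact substring, carries an adapter prefix of at least
#' `min_prefix` bp at its 3' end (partial read-through), or contains an N.
#' Adapters are only detected, never removed: downstream alignment-free QC
#' works on the raw reads.
#'
#' @param pairs Read-pair tibble with `read1`, `read2` columns.
#' @param adapters Character vector of adapter sequences.
#' @param min_prefix Minimum adapter-prefix length checked at read 3' ends.
#' @return The input tibble with logical columns `has_adapter`, `has_n`,
#'   `clean` added; the clean fraction is `mean(out$clean)`.
#' @export
#' @examples
#' p <- tibble::tibble(read1 = c("ACGTACGT", "ACGTAGATCGGAAGAG"),
#'                     read2 = c("TTTTTTTT", "ACGTACGT"))
#' scan_adapters_and_ns(p, "AGATCGGAAGAGC", min_prefix = 8)
scan_adapters_and_ns <- function(pairs, adapters, min_prefix = 12) {
  if (length(adapters) == 0) abort("adapter list must be non-empty.")
  hit <- rep(FALSE, nrow(pairs))
  for (ad in adapters) {
    hit <- hit |
      stringi::stri_detect_fixed(pairs$read1, ad) |
      stringi::stri_detect_fixed(pairs$read2, ad)
    if (nchar(ad) > min_prefix) {
      for (plen in min_prefix:(nchar(ad) - 1L)) {
        pref <- substr(ad, 1L, plen)
        hit <- hit |
          stringi::stri_endswith_fixed(pairs$read1, pref) |
          stringi::stri_endswith_fixed(pairs$read2, pref)
      }
    }
  }
  has_n <- stringi::stri_detect_fixed(pairs$read1, "N") |
    stringi::stri_detect_fixed(pairs$read2, "N")
  dplyr::mutate(pairs, has_adapter = hit, has_n = has_n,
                clean = !hit & !has_n)
}

#' Mean-quality read filtration over pairs
#'
#' A read is retained iff its mean Phred quality is greater than or equal
#' to `min_mean_q` (the boundary value itself is retained).  The reported
#' retention fraction counts pairs in which *both* mates are retained.
#'
#' @param pairs Read-pair tibble with `qual1`, `qual2` Phred+33 quality
#'   string columns.
#' @param min_mean_q Minimum mean Phred quality for a read to survive.
#' @return The input tibble with `mean_q1`, `mean_q2`, `retained` columns
#'   added; `frac_pairs_retained = mean(out$retained)`.
#' @export
quality_filter_pairs <- function(pairs, min_mean_q = 20) {
  if (any(nchar(pairs$qual1) != nchar(pairs$read1 %||% pairs$qual1)) ||
      any(nchar(pairs$qual2) != nchar(pairs$read2 %||% pairs$qual2))) {
    abort("malformed quality strings: length differs from read length.")
  }
  mq1 <- mean_phred(pairs$qual1)
  mq2 <- mean_phred(pairs$qual2)
  dplyr::mutate(pairs, mean_q1 = mq1, mean_q2 = mq2,
                retained = mq1 >= min_mean_q & mq2 >= min_mean_q)
}

#' Raw-read QC report: the five sample-level quality parameters
#'
#' Computes, from a set of read pairs, the five parameters used to assess
#' and compare raw sequencing quality across centers:
#'
#' 1. fraction of read pairs without adapters or Ns (library preparation
#'    and sequencing quality);
#' 2. fraction of read pairs with both reads retained after mean-Q20
#'    filtration (sequencing quality);
#' 3. fraction of 23-mers with errors (sequencing error rate);
#' 4. estimated mean coverage (from the 23-mer spectrum, non-repetitive
#'    regions only);
#' 5. variance coefficient of coverage (sd / mean; uniformity of
#'    coverage).
#'
#' The k-mer spectrum is computed from quality-retained reads, and the
#' inclusion gate of [qc_gate()] is applied to the finished report.
#'
#' @param pairs Read-pair tibble (`read1`, `qual1`, `read2`, `qual2`).
#' @param adapters Character vector of adapter sequences.
#' @param read_length Read length in bp.
#' @param k k-mer length for the spectrum.
#' @param min_mean_q Mean-quality retention threshold.
#' @param ... Gate thresholds passed on to [qc_gate()].
#' @return A one-row tibble of class `qc_report` with the five parameters,
#'   `coverage_mode`, `pass`, and a `failed_criteria` list-column; the
#'   spectrum is attached as attribute `"spectrum"`.
#' @export
read_qc_report <- function(pairs, adapters, read_length = 150, k = 23,
                           min_mean_q = 20, ...) {
  scanned <- scan_adapters_and_ns(pairs, adapters)
  filtered <- quality_filter_pairs(pairs, min_mean_q = min_mean_q)
  kept <- filtered[filtered$retained, ]
  spectrum <- kmer_spectrum(kept, k = k)
  cov <- coverage_stats(spectrum, read_length = read_length)

  report <- tibble::tibble(
    frac_pairs_clean = mean(scanned$clean),
    frac_pairs_retained = mean(filtered$retained),
    frac_kmers_error = kmer_error_fraction(spectrum),
    est_mean_coverage = cov$est_mean_coverage,
    coverage_mode = cov$coverage_mode,
    variance_coefficient = cov$variance_coefficient
  )
  report <- qc_gate(report, ...)
  attr(report, "spectrum") <- spectrum
  class(report) <- c("qc_report", class(report))
  report
}

#' Sample-inclusion gate on raw-read QC parameters
#'
#' Applies the four inclusion criteria used to decide whether a sequenced
#' sample can enter further analysis (a failing sample requires additional
#' sequencing):
#'
#' * fraction of read pairs without adapters or Ns >= 0.95;
#' * fraction of read pairs with both reads retained >= 0.95;
#' * fraction of k-mers with errors <= 0.15;
#' * mode of coverage >= 27.
#'
#' Threshold comparisons are inclusive exactly as stated (`>=` / `<=`).
#'
#' @param report A one-row tibble with columns `frac_pairs_clean`,
#'   `frac_pairs_retained`, `frac_kmers_error`, `coverage_mode` (e.g. from
#'   [read_qc_report()]).
#' @param min_clean,min_retained,max_kmer_error,min_coverage_mode The four
#'   gate thresholds.
#' @return The report with logical `pass` and list-column
#'   `failed_criteria` (names of violated rules; empty when passing).
#' @export
#' @examples
#' r <- tibble::tibble(frac_pairs_clean = 0.994, frac_pairs_retained = 0.989,
#'                     frac_kmers_error = 0.076, coverage_mode = 31)
#' qc_gate(r)$pass
qc_gate <- function(report, min_clean = 0.95, min_retained = 0.95,
                    max_kmer_error = 0.15, min_coverage_mode = 27) {
  failed <- character(0)
  if (report$frac_pairs_clean < min_clean) failed <- c(failed, "pairs_without_adapters_or_ns")
  if (report$frac_pairs_retained < min_retained) failed <- c(failed, "pairs_retained_after_filtration")
  if (report$frac_kmers_error > max_kmer_error) failed <- c(failed, "kmer_error_fraction")
  if (report$coverage_mode < min_coverage_mode) failed <- c(failed, "mode_of_coverage")
  report$pass <- length(failed) == 0
  report$failed_criteria <- list(failed)
  report
}
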