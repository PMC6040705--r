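#' Canonical k-mer multiplicity spectrum of a read set
#'
#' Counts canonical 23-mers (the lexicographic minimum of each k-mer and
#' its reverse complement, so counting is strand-agnostic) across all
#' reads and tabulates the number of distinct canonical k-mers at each
#' multiplicity.  k-mers containing an N are skipped.  The spectrum is the
#' basis of the coverage and sequencing-error estimates used in raw-read
#' quality control: its main peak tracks sequencing depth in k-mer space
#' and its low-multiplicity tail tracks sequencing errors.
#'
#' @param reads A read-pair tibble (as from [sim_read_pairs()]`$pairs`,
#'   with `read1`/`read2` columns) or a plain character vector of reads.
#' @param k k-mer length; 23 throughout this package.
#' @return A tibble of class `kmer_spectrum` with columns `multiplicity`
#'   and `n_kmers` (distinct canonical k-mers seen that many times), and
#'   attributes `k` and `total_kmers` (total counted k-mer instances).
#' @export
#' @examples
#' sp <- kmer_spectrum(c("ACGTACGTACGTACGTACGTACGTACGT"), k = 23)
#' sp
kmer_spectrum <- function(reads, k = 23) {
  if (is.data.frame(reads)) reads <- c(reads$read1, reads$read2)
  k <- as.integer(k)
  if (all(nchar(reads) < k)) {
    warn("all reads shorter than k; spectrum is empty.")
    return(new_kmer_spectrum(tibble::tibble(multiplicity = integer(),
                                            n_kmers = integer()), k, 0))
  }
  km <- str_kmers(reads, k)
  km <- km[!stringi::stri_detect_fixed(km, "N")]
  canon <- canonical(km)
  dt <- data.table::data.table(kmer = canon)
  mult <- dt[, .N, by = "kmer"]$N
  spec <- data.table::data.table(multiplicity = mult)[, .N, by = "multiplicity"]
  spec <- spec[order(multiplicity)]
  new_kmer_spectrum(
    tibble::tibble(multiplicity = spec$multiplicity, n_kmers = spec$N),
    k, length(canon))
}

new_kmer_spectrum <- function(tbl, k, total) {
  structure(tbl, k = k, total_kmers = total,
            class = c("kmer_spectrum", class(tbl)))
}

#' Coverage estimates from a k-mer spectrum
#'
#' Derives the three coverage figures of raw-read QC from the 23-mer
#' spectrum, restricted to the non-repetitive part of the genome:
#'
#' * the error boundary `m` is the first local minimum of the spectrum
#'   scanning upward in multiplicity (smallest multiplicity whose count is
#'   below both neighbours) -- k-mers at or below `m` are attributed to
#'   sequencing error;
#' * the k-mer coverage mode `M` is the multiplicity with the highest
#'   count above `m`;
#' * mean and standard deviation are weighted moments of the spectrum over
#'   the non-repetitive window `(m, 2M - m]`, which excludes both the
#'   error tail and the repeat tail symmetrically about the mode.
#'
#' All coverage figures are converted from k-mer space to base space by
#' the factor `L / (L - k + 1)` (a read of length `L` contributes
#' `L - k + 1` k-mers, so expected k-mer coverage is `C (L - k + 1) / L`),
#' and corrected for error loss by `1 / (1 - f)`, `f` the error k-mer
#' fraction: only error-free k-mer instances contribute to the signal
#' peaks, so without the correction a sequencing error rate `e` would
#' deflate every coverage figure by `(1 - e)^k`.  The variance
#' coefficient (sd / mean) is scale-free and unaffected by either
#' conversion.
#'
#' @param spectrum A [kmer_spectrum()].
#' @param read_length Read length `L` in bp used for the space conversion.
#' @return A one-row tibble: `error_boundary`, `kmer_mode`,
#'   `coverage_mode`, `est_mean_coverage`, `coverage_sd`,
#'   `variance_coefficient`.
#' @export
#' @examples
#' sp <- tibble::tibble(multiplicity = 30L, n_kmers = 1000L)
#' sp <- wgsbakeoff:::new_kmer_spectrum(sp, 23L, 30000)
#' coverage_stats(sp, read_length = 150)
coverage_stats <- function(spectrum, read_length = 150) {
  k <- attr(spectrum, "k") %||% 23L
  if (nrow(spectrum) == 0) abort("empty spectrum: cannot estimate coverage.")
  dense <- integer(max(spectrum$multiplicity))
  dense[spectrum$multiplicity] <- spectrum$n_kmers

  m <- error_boundary(dense)
  above <- seq_along(dense) > m
  if (!any(dense[above] > 0)) {
    abort("no coverage peak above the error boundary: spectrum looks like pure error.")
  }
  M <- which(above & dense == max(dense[above]))[1]
  if ((m > 0 && M <= m) || (m == 0L && M == 1L)) {
    abort("no coverage peak above the error boundary: spectrum looks like pure error.")
  }
  hi <- max(2L * M - m, M)
  win <- seq_len(length(dense))
  win <- win[win > m & win <= hi]
  wts <- dense[win]
  mean_k <- sum(win * wts) / sum(wts)
  sd_k <- sqrt(sum(wts * (win - mean_k)^2) / sum(wts))

  # base-space conversion plus error-loss correction: a k-mer instance is
  # counted in the signal peaks only if error-free, so the spectrum mean
  # underestimates coverage by the error k-mer fraction f; dividing by
  # (1 - f) restores total coverage (exact when errors are uniform)
  total <- attr(spectrum, "total_kmers") %||% sum(seq_along(dense) * dense)
  f <- if (m > 0) sum(seq_len(m) * dense[seq_len(m)]) / total else 0
  conv <- read_length / (read_length - k + 1) / (1 - f)
  tibble::tibble(
    error_boundary = m,
    kmer_mode = M,
    coverage_mode = M * conv,
    est_mean_coverage = mean_k * conv,
    coverage_sd = sd_k * conv,
    variance_coefficient = ifelse(mean_k > 0, sd_k / mean_k, 0)
  )
}

# first strict local minimum scanning upward; 0 when there is none
# (e.g. no error tail at all)
error_boundary <- function(dense) {
  n <- length(dense)
  if (n < 3) return(0L)
  for (i in 2:(n - 1)) {
    if (dense[i] < dense[i - 1] && dense[i] < dense[i + 1]) return(i)
  }
  0L
}

#' Fraction of k-mer instances attributed to sequencing error
#'
#' The fraction of all counted k-mer instances whose multiplicity is at or
#' below the spectrum's error boundary (see [coverage_stats()]).  This is
#' the raw-read QC estimate of the sequencing error rate.
#'
#' @inheritParams coverage_stats
#' @return A single numeric fraction in \[0, 1\].
#' @export
kmer_error_fraction <- function(spectrum) {
  if (nrow(spectrum) == 0) return(0)
  dense <- integer(max(spectrum$multiplicity))
  dense[spectrum$multiplicity] <- spectrum$n_kmers
  m <- error_boundary(dense)
  if (m == 0L) return(0)
  total <- attr(spectrum, "total_kmers") %||%
    sum(spectrum$multiplicity * spectrum$n_kmers)
  idx <- seq_len(m)
  sum(idx * dense[idx]) / total
}
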