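#' Simulate per-window read-depth profiles with planted duplications
#'
#' Produces a per-sample table of sequencing depth in non-overlapping
#' windows (1 kbp by default).  Baseline windows are drawn around the
#' diploid depth `mean_depth` with copy-number dispersion
#' `config$dispersion`; windows inside a planted segmental duplication are
#' scaled by `cn / 2` for carrier samples.
#'
#' @param reference A [sim_reference()] or named character vector.
#' @param config A [sim_config()]; `config$planted_sds` (tibble with
#'   `seqnames`, `start`, `end`, `cn` and optional `samples`, a
#'   comma-separated carrier list, `NA` meaning all samples) defines the
#'   duplications.
#' @param samples Character vector of sample ids; defaults to the
#'   [cohort_design()] of `config`.
#' @return A tibble with columns `seqnames`, `start`, `end` (0-based
#'   half-open windows), `sample`, `depth`, plus the truth copy number
#'   `cn_truth` for reconciliation in tests.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 30000, dispersion = 0.1,
#'   planted_sds = tibble::tibble(seqnames = "chr1", start = 10000,
#'                                end = 22000, cn = 4, samples = NA))
#' d <- sim_depth_profile(sim_reference(cfg), cfg)
#' head(d)
sim_depth_profile <- function(reference, config = sim_config(),
                              samples = cohort_design(config)$sample) {
  seqs <- as_reference(reference)
  set.seed(config$seed + 3L)
  w <- config$window_size

  windows <- dplyr::bind_rows(lapply(names(seqs), function(sn) {
    n <- nchar(seqs[[sn]])
    starts <- seq(0L, n - 1L, by = w)
    tibble::tibble(seqnames = sn, start = starts,
                   end = pmin(starts + w, n))
  }))
  # truncated trailing windows below half size are dropped
  windows <- windows[windows$end - windows$start >= w %/% 2L, ]

  grid <- tidyr::crossing(windows, sample = samples)
  grid$cn_truth <- 2
  sds <- config$planted_sds
  if (!is.null(sds) && nrow(sds) > 0) {
    for (i in seq_len(nrow(sds))) {
      carriers <- if (is.null(sds$samples) || is.na(sds$samples[i])) samples
                  else strsplit(sds$samples[i], ",", fixed = TRUE)[[1]]
      inside <- grid$seqnames == sds$seqnames[i] &
        grid$start >= sds$start[i] & grid$end <= sds$end[i] &
        grid$sample %in% carriers
      grid$cn_truth[inside] <- sds$cn[i]
    }
  }
  noise <- if (config$dispersion > 0)
    rnorm(nrow(grid), 0, config$dispersion) else 0
  grid$depth <- pmax((grid$cn_truth + noise) * config$mean_depth / 2, 0)
  dplyr::arrange(grid, .data$sample, .data$seqnames, .data$start)
}
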