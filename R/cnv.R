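#' Window copy-number profile from read depth
#'
#' Converts per-window depth to copy number against control regions:
#' `cn = 2 * depth / mean(control depth)` per sample, so the mean copy
#' number over control windows is exactly 2 (the diploid baseline).
#' Control windows are all windows not overlapping `exclude` (called or
#' planted duplications, masked regions); the per-sample control mean and
#' standard deviation of `cn` are kept for the dispersion-corrected
#' duplication threshold.
#'
#' @param depth Tibble `seqnames`, `start`, `end`, `sample`, `depth`
#'   (e.g. from [sim_depth_profile()] or an external per-window depth
#'   table).
#' @param exclude Optional interval tibble; overlapping windows are
#'   excluded from the control set (but still receive a `cn` value).
#' @return The input with a `cn` column and logical `control`, of class
#'   `cn_profile`; per-sample control statistics (`control_mean_depth`,
#'   `mean_cn`, `sd_cn`) in attribute `"control_stats"`.
#' @export
compute_cn <- function(depth, exclude = NULL) {
  d <- depth
  d$control <- TRUE
  if (!is.null(exclude) && nrow(exclude) > 0) {
    hit <- rep(FALSE, nrow(d))
    for (sn in unique(d$seqnames)) {
      sel <- d$seqnames == sn
      ex <- exclude[exclude$seqnames == sn, ]
      if (nrow(ex) == 0) next
      q <- IRanges::IRanges(d$start[sel] + 1L, d$end[sel])
      s <- IRanges::IRanges(ex$start + 1L, ex$end)
      hit[sel] <- IRanges::countOverlaps(q, s) > 0L
    }
    d$control <- !hit
  }
  stats <- d |>
    dplyr::filter(.data$control) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(control_mean_depth = mean(.data$depth), .groups = "drop")
  if (any(stats$control_mean_depth <= 0)) {
    abort("zero mean depth in control windows; cannot normalize.")
  }
  d <- d |>
    dplyr::left_join(stats, by = "sample") |>
    dplyr::mutate(cn = 2 * .data$depth / .data$control_mean_depth) |>
    dplyr::select(-"control_mean_depth")
  ctl <- d |>
    dplyr::filter(.data$control) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(mean_cn = mean(.data$cn), sd_cn = sd(.data$cn),
                     .groups = "drop") |>
    dplyr::left_join(stats, by = "sample")
  out <- structure(d, control_stats = ctl,
                   class = c("cn_profile", class(d)))
  out
}

#' Call segmental duplications from a copy-number profile
#'
#' A segmental duplication is a run of windows whose copy number exceeds
#' the control mean plus `k_sigma` control standard deviations (the
#' dispersion correction), merged when consecutive in the profile; a
#' genomic gap where windows are absent (e.g. masked sequence) is
#' bridged up to `bridge` windows' worth of bp, but a measured
#' below-threshold window always breaks a run.  Merged runs are emitted
#' when they span at least `min_span` bp of genomic coordinates.
#'
#' @param profile A [compute_cn()] profile.
#' @param min_span Minimum genomic span in bp of a reported duplication.
#' @param k_sigma Dispersion multiplier for the detection threshold
#'   `mean_cn + k_sigma * sd_cn`.
#' @param bridge Number of missing/gap windows bridged when merging.
#' @return A tibble of duplications: `sample`, `seqnames`, `start`, `end`,
#'   `n_windows`, `mean_cn`, `threshold`.
#' @export
call_segmental_duplications <- function(profile, min_span = 10000,
                                        k_sigma = 3, bridge = 1) {
  ctl <- attr(profile, "control_stats")
  if (is.null(ctl)) abort("profile lacks control statistics; run compute_cn() first.")
  win <- median(profile$end - profile$start)

  flagged <- profile |>
    dplyr::left_join(ctl, by = "sample") |>
    dplyr::group_by(.data$sample, .data$seqnames) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(threshold = .data$mean_cn + k_sigma * .data$sd_cn,
                  above = .data$cn > .data$threshold,
                  win_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$above)
  if (nrow(flagged) == 0) {
    return(tibble::tibble(sample = character(), seqnames = character(),
                          start = integer(), end = integer(),
                          n_windows = integer(), mean_cn = numeric(),
                          threshold = numeric()))
  }
  out <- flagged |>
    dplyr::group_by(.data$sample, .data$seqnames) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(gap = .data$start - dplyr::lag(.data$end),
                  rank_gap = .data$win_rank - dplyr::lag(.data$win_rank),
                  # windows merge when adjacent in the profile; a genomic
                  # gap is bridged only where windows are absent (masked),
                  # up to `bridge` windows' worth of sequence
                  run = cumsum(is.na(.data$gap) | .data$rank_gap > 1L |
                                 .data$gap > bridge * win)) |>
    dplyr::group_by(.data$sample, .data$seqnames, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(), mean_cn = mean(.data$cn),
                     threshold = .data$threshold[1], .groups = "drop") |>
    dplyr::filter(.data$end - .data$start >= min_span) |>
    dplyr::select("sample", "seqnames", "start", "end", "n_windows",
                  "mean_cn", "threshold") |>
    dplyr::arrange(.data$sample, .data$seqnames, .data$start)
  out
}

#' Duplication regions shared by cases and absent from healthy samples
#'
#' Finds genomic regions covered by a called segmental duplication in at
#' least `min_cases` case samples while sharing no base with any
#' duplication called in a healthy sample -- the patient-specific shared
#' duplication comparison.
#'
#' @param sd_calls Duplication tibble from
#'   [call_segmental_duplications()] over all samples.
#' @param design A [cohort_design()] table assigning `role` to samples.
#' @param min_cases Minimum number of distinct case samples whose
#'   duplications must cover a region.
#' @return A tibble of case-specific regions: `seqnames`, `start`, `end`,
#'   `n_cases`.
#' @export
case_specific_sds <- function(sd_calls, design, min_cases = 2) {
  healthy <- design$sample[design$role != "case"]
  cases <- design$sample[design$role == "case"]
  if (length(healthy) == 0) {
    abort("design has no healthy samples; a case-only comparison needs them.")
  }
  case_sd <- sd_calls[sd_calls$sample %in% cases, ]
  healthy_sd <- sd_calls[sd_calls$sample %in% healthy, ]
  if (nrow(case_sd) == 0) {
    return(tibble::tibble(seqnames = character(), start = integer(),
                          end = integer(), n_cases = integer()))
  }
  out <- lapply(unique(case_sd$seqnames), function(sn) {
    cs <- case_sd[case_sd$seqnames == sn, ]
    # count distinct case samples covering each base
    per_sample <- lapply(split(cs, cs$sample), function(d)
      IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end)))
    wd <- max(cs$end)
    cov <- Reduce(`+`, lapply(per_sample, IRanges::coverage, width = wd))
    sl <- IRanges::slice(cov, lower = min_cases, rangesOnly = TRUE)
    if (length(sl) == 0) return(NULL)
    n_cases_per <- vapply(seq_along(sl), function(i) {
      sum(vapply(per_sample, function(ir)
        length(IRanges::findOverlaps(sl[i], ir)) > 0, logical(1)))
    }, integer(1))
    keep <- tibble::tibble(seqnames = sn,
                           start = IRanges::start(sl) - 1L,
                           end = IRanges::end(sl),
                           n_cases = n_cases_per)
    hs <- healthy_sd[healthy_sd$seqnames == sn, ]
    if (nrow(hs) > 0) {
      h <- IRanges::IRanges(hs$start + 1L, hs$end)
      hitsick <- IRanges::countOverlaps(sl, h) > 0
      keep <- keep[!hitsick, , drop = FALSE]
    }
    keep
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    tibble::tibble(seqnames = character(), start = integer(),
                   end = integer(), n_cases = integer())
  } else {
    dplyr::arrange(res, .data$seqnames, .data$start)
  }
}
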