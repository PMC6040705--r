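#' Hard filter for SNVs with a step-by-step ledger
#'
#' Applies the fixed SNV quality filter: site `QUAL > 40`, per-sample
#' `GQ > 20`, `DP > 10` and `SP < 20` (strict inequalities exactly as
#' stated), then removes variants overlapping the repeat mask.  The
#' per-sample FORMAT thresholds are applied as: a site is retained iff
#' every non-missing sample passes (`mode = "all"`); `mode = "any"`
#' retains a site when at least one sample passes.  A missing FORMAT
#' value fails its criterion.  Each step's input and output counts are
#' recorded in a ledger attached as attribute `"ledger"` (see
#' [filter_ledger()]).
#'
#' @param calls Call-set tibble with `qual`, `gq`, `dp`, `sp` columns.
#' @param repeat_mask Optional mask tibble of repeat regions to exclude.
#' @param min_qual,min_gq,min_dp,max_sp Filter thresholds.
#' @param mode `"all"` (default) or `"any"` sample must pass the
#'   per-sample FORMAT thresholds.
#' @return The filtered call-set tibble with attribute `"ledger"`.
#' @export
snv_hard_filter <- function(calls, repeat_mask = NULL, min_qual = 40,
                            min_gq = 20, min_dp = 10, max_sp = 20,
                            mode = c("all", "any")) {
  mode <- match.arg(mode)
  agg <- if (mode == "all") function(x) all(x) else function(x) any(x)
  site_count <- function(d) nrow(dplyr::distinct(d, .data$chrom, .data$pos,
                                                 .data$ref, .data$alt))
  ledger <- list()
  log_step <- function(step, n_in, n_out, rule) {
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      step = step, n_in = n_in, n_out = n_out, rule = rule)
  }

  n0 <- site_count(calls)
  snv <- dplyr::filter(calls, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L,
                       !stringi::stri_detect_fixed(.data$alt, ","))
  log_step("snv_only", n0, site_count(snv), "keep single-nucleotide variants")

  q <- dplyr::filter(snv, !is.na(.data$qual) & .data$qual > min_qual)
  log_step("site_quality", site_count(snv), site_count(q),
           paste0("QUAL > ", min_qual))

  fmt_pass <- function(d, col, test, label) {
    keys <- d |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(pass = agg(test(.data[[col]])), .groups = "drop") |>
      dplyr::filter(.data$pass)
    out <- dplyr::semi_join(d, keys,
                            by = c("chrom", "pos", "ref", "alt"))
    log_step(label, site_count(d), site_count(out),
             paste0(mode, " samples: ", label))
    out
  }
  g <- fmt_pass(q, "gq", function(x) !is.na(x) & x > min_gq,
                paste0("GQ > ", min_gq))
  d <- fmt_pass(g, "dp", function(x) !is.na(x) & x > min_dp,
                paste0("DP > ", min_dp))
  s <- fmt_pass(d, "sp", function(x) !is.na(x) & x < max_sp,
                paste0("SP < ", max_sp))

  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0) {
    hit <- overlaps_mask(s$chrom, s$pos, nchar(s$ref), repeat_mask)
    out <- s[!hit, , drop = FALSE]
    log_step("repeat_mask", site_count(s), site_count(out),
             "remove variants in repeat regions")
  } else {
    out <- s
  }
  attr(out, "ledger") <- dplyr::bind_rows(ledger)
  out
}

#' Six-step long-indel filter with a ledger
#'
#' Sequentially filters a (normalized) call set down to confidently
#' called long indels:
#'
#' 1. caller PASS flag (`filter == "PASS"`);
#' 2. successfully normalized records (normalization itself is
#'    [normalize_calls()]; records dropped there never reach this filter);
#' 3. indel length -- the absolute difference between reference- and
#'    alternative-allele lengths -- at least `min_len` and at most
#'    `max_len` bp (both bounds inclusive);
#' 4. site quality `QUAL > min_qual` (strict);
#' 5. minimal per-sample genotype quality over non-missing samples
#'    `GQ > min_gq` (strict);
#' 6. no overlap with the combined low-complexity / low-mappability mask.
#'
#' @param calls Normalized call-set tibble.
#' @param mask Optional merged mask tibble (low-complexity union
#'   low-mappability).
#' @param min_len,max_len Inclusive indel length bounds in bp.
#' @param min_qual,min_gq Quality thresholds (strict `>`).
#' @return The retained long-indel records with attribute `"ledger"`.
#' @export
long_indel_filter <- function(calls, mask = NULL, min_len = 20,
                              max_len = 100, min_qual = 40, min_gq = 20) {
  site_count <- function(d) nrow(dplyr::distinct(d, .data$chrom, .data$pos,
                                                 .data$ref, .data$alt))
  ledger <- list()
  log_step <- function(step, n_in, n_out, rule) {
    ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      step = step, n_in = n_in, n_out = n_out, rule = rule)
  }

  n0 <- site_count(calls)
  p <- if ("filter" %in% names(calls)) {
    dplyr::filter(calls, .data$filter == "PASS")
  } else calls
  log_step("caller_pass", n0, site_count(p), "caller FILTER == PASS")

  len_diff <- abs(nchar(p$ref) - nchar(p$alt))
  l <- p[len_diff >= min_len & len_diff <= max_len, , drop = FALSE]
  log_step("long_indel", site_count(p), site_count(l),
           paste0("|len(ref) - len(alt)| in [", min_len, ", ", max_len, "]"))

  q <- dplyr::filter(l, !is.na(.data$qual) & .data$qual > min_qual)
  log_step("site_quality", site_count(l), site_count(q),
           paste0("QUAL > ", min_qual))

  keys <- q |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(min_gq_obs = suppressWarnings(
      min(.data$gq, na.rm = TRUE)), .groups = "drop") |>
    dplyr::filter(is.finite(.data$min_gq_obs), .data$min_gq_obs > min_gq)
  g <- dplyr::semi_join(q, keys, by = c("chrom", "pos", "ref", "alt"))
  log_step("genotype_quality", site_count(q), site_count(g),
           paste0("min sample GQ > ", min_gq))

  if (!is.null(mask) && nrow(mask) > 0) {
    hit <- overlaps_mask(g$chrom, g$pos, nchar(g$ref), mask)
    out <- g[!hit, , drop = FALSE]
    log_step("region_mask", site_count(g), site_count(out),
             "outside low-complexity and low-mappability regions")
  } else {
    out <- g
  }
  attr(out, "ledger") <- dplyr::bind_rows(ledger)
  out
}

#' Retrieve the filter ledger of a filtered call set
#'
#' @param x A tibble returned by [snv_hard_filter()],
#'   [long_indel_filter()] or [prioritize_lof()].
#' @return A tibble with columns `step`, `n_in`, `n_out`, `rule`.
#' @export
filter_ledger <- function(x) {
  attr(x, "ledger")
}

#' Overlap (Venn) counts of variant sets across centers
#'
#' Counts, for 2 or 3 call sets keyed by normalized variant key, the
#' number of variants in every region of the Venn diagram, plus the
#' percentage each region represents of each contributing set.
#'
#' @param callsets Named list of call-set tibbles (or of character key
#'   vectors).
#' @return A tibble with one row per Venn region: `region` (set names
#'   joined by `&`), `n`, and per-set percentage columns.
#' @export
#' @examples
#' callset_overlap(list(A = c("k1", "k2", "k3"), B = c("k2", "k3", "k4"),
#'                      C = "k3"))
callset_overlap <- function(callsets) {
  if (length(callsets) < 2) abort("need at least two call sets.")
  keys <- lapply(callsets, function(x) {
    if (is.data.frame(x)) unique(variant_key(x)) else unique(as.character(x))
  })
  nm <- names(keys) %||% paste0("set", seq_along(keys))
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(k) universe %in% k,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  region <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  counts <- table(region)
  out <- tibble::tibble(region = names(counts), n = as.integer(counts))
  for (s in nm) {
    in_set <- vapply(strsplit(out$region, "&", fixed = TRUE),
                     function(r) s %in% r, logical(1))
    out[[paste0("pct_", s)]] <-
      ifelse(in_set, 100 * out$n / length(keys[[s]]), 0)
  }
  dplyr::arrange(out, dplyr::desc(nchar(.data$region)), .data$region)
}
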