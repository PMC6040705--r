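#' Per-variant genotype replication concordance across call sets
#'
#' For every variant, over all individuals, compares genotypes between
#' every unordered pair of replicate call sets in which both genotypes
#' are non-missing, and returns the fraction of concordant comparisons.
#' Comparisons are pooled over individuals (a single individual
#' contributes at most `choose(n_replicates, 2)` pairs, too few on its
#' own).
#'
#' @param replicates Named list of call-set tibbles (>= 2), or one long
#'   tibble with a `center` column.
#' @param samples Optional subset of samples to compare.
#' @return A tibble per variant: `chrom`, `pos`, `ref`, `alt`, `n_pairs`,
#'   `n_concordant`, `concordance`.
#' @export
replicate_concordance <- function(replicates, samples = NULL) {
  if (is.data.frame(replicates)) {
    long <- replicates
    if (!"center" %in% names(long)) abort("long input needs a `center` column.")
  } else {
    if (length(replicates) < 2) abort("need at least two replicate call sets.")
    nm <- names(replicates) %||% paste0("rep", seq_along(replicates))
    long <- dplyr::bind_rows(stats::setNames(replicates, nm), .id = "center")
  }
  if (!is.null(samples)) long <- dplyr::filter(long, .data$sample %in% samples)
  long <- dplyr::filter(long, !is.na(.data$a1), !is.na(.data$a2))
  if (nrow(long) == 0) abort("no genotypes to compare.")

  centers <- unique(long$center)
  pairs <- utils::combn(centers, 2, simplify = FALSE)
  per_pair <- lapply(pairs, function(p) {
    x <- long[long$center == p[1], ]
    y <- long[long$center == p[2], ]
    j <- dplyr::inner_join(
      dplyr::select(x, "chrom", "pos", "ref", "alt", "sample", "a1", "a2"),
      dplyr::select(y, "chrom", "pos", "ref", "alt", "sample", "a1", "a2"),
      by = c("chrom", "pos", "ref", "alt", "sample"), suffix = c("_x", "_y"))
    dplyr::mutate(j, concordant = gt_equal(.data$a1_x, .data$a2_x,
                                           .data$a1_y, .data$a2_y))
  })
  dplyr::bind_rows(per_pair) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_concordant = sum(.data$concordant),
                     concordance = mean(.data$concordant),
                     .groups = "drop")
}

#' Replication-based prioritization of rare loss-of-function variants
#'
#' Applies the prioritization filter chain to an annotated variant table,
#' attributing each excluded variant to the first failing step:
#'
#' 1. `lof`: high-confidence loss-of-function annotation;
#' 2. `rarity`: every *present* population MAF at most `maf_max`
#'    (a variant absent from a database passes -- absence is evidence of
#'    rarity, not of commonness);
#' 3. `case_occurrence`: alternative-allele count over case samples at
#'    least `min_case_alt`, or at least one homozygous-alternative case;
#' 4. `parental`: zero alternative alleles in the healthy parents,
#'    relaxed to at most `parent_max_alt_if_child_carries` when the trio
#'    child carries the variant;
#' 5. `replication`: genotype replication concordance (pooled over
#'    individuals and replicate pairs) at least `concordance_min`.
#'
#' Genotype counting uses the first replicate call set.
#'
#' @param annotations Annotation tibble (one row per variant, as from
#'   [sim_annotations()] or an external TSV): columns `chrom`, `pos`,
#'   `ref`, `alt`, `lof_confidence`, `maf_1000g`, `maf_exac`,
#'   `maf_gnomad`.
#' @param replicates Named list of >= 2 replicate call-set tibbles.
#' @param design A [cohort_design()] table.
#' @param maf_max Population MAF ceiling.
#' @param min_case_alt Minimum case alternative-allele count.
#' @param parent_max_alt Maximum parental alternative alleles ordinarily.
#' @param parent_max_alt_if_child_carries Parental ceiling when the trio
#'   child carries at least one alternative allele.
#' @param concordance_min Replication concordance floor.
#' @return An object of class `prioritization`: a tibble with one row per
#'   input variant (`retained`, `reason`, `case_alt_count`,
#'   `parent_alt_count`, `has_hom_case`, `child_carries`,
#'   `replicate_concordance`), with a step ledger in attribute
#'   `"ledger"` (see [filter_ledger()]).
#' @export
prioritize_lof <- function(annotations, replicates, design,
                           maf_max = 0.01, min_case_alt = 2,
                           parent_max_alt = 0,
                           parent_max_alt_if_child_carries = 2,
                           concordance_min = 0.98) {
  if (!all(design$role %in% c("case", "parent"))) {
    abort("unknown sample role in design; expected 'case' or 'parent'.")
  }
  cases <- design$sample[design$role == "case"]
  parents <- design$sample[design$role == "parent"]
  child <- design$sample[!is.na(design$father)]
  base <- replicates[[1]]

  doses <- base |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      case_alt_count = sum(allele_dose(.data$a1, .data$a2)[
        .data$sample %in% cases], na.rm = TRUE),
      parent_alt_count = sum(allele_dose(.data$a1, .data$a2)[
        .data$sample %in% parents], na.rm = TRUE),
      has_hom_case = any(.data$sample %in% cases & .data$a1 == 1L &
                           .data$a2 == 1L, na.rm = TRUE),
      child_carries = any(.data$sample %in% child &
                            allele_dose(.data$a1, .data$a2) >= 1L,
                          na.rm = TRUE),
      .groups = "drop")
  conc <- replicate_concordance(replicates)

  res <- annotations |>
    dplyr::left_join(doses, by = c("chrom", "pos", "ref", "alt")) |>
    dplyr::left_join(dplyr::select(conc, "chrom", "pos", "ref", "alt",
                                   replicate_concordance = "concordance"),
                     by = c("chrom", "pos", "ref", "alt"))

  pass_lof <- res$lof_confidence == "high"
  pass_maf <- (is.na(res$maf_1000g) | res$maf_1000g <= maf_max) &
    (is.na(res$maf_exac) | res$maf_exac <= maf_max) &
    (is.na(res$maf_gnomad) | res$maf_gnomad <= maf_max)
  pass_case <- !is.na(res$case_alt_count) &
    (res$case_alt_count >= min_case_alt | res$has_hom_case)
  parent_cap <- ifelse(!is.na(res$child_carries) & res$child_carries,
                       parent_max_alt_if_child_carries, parent_max_alt)
  pass_parent <- !is.na(res$parent_alt_count) &
    res$parent_alt_count <= parent_cap
  pass_conc <- !is.na(res$replicate_concordance) &
    res$replicate_concordance >= concordance_min

  steps <- list(lof = pass_lof, rarity = pass_maf,
                case_occurrence = pass_case, parental = pass_parent,
                replication = pass_conc)
  reason <- rep(NA_character_, nrow(res))
  alive <- rep(TRUE, nrow(res))
  ledger <- list()
  for (st in names(steps)) {
    fail_now <- alive & !steps[[st]]
    reason[fail_now] <- st
    n_in <- sum(alive)
    alive <- alive & steps[[st]]
    ledger[[length(ledger) + 1L]] <- tibble::tibble(
      step = st, n_in = n_in, n_out = sum(alive),
      rule = switch(st,
        lof = "high-confidence loss-of-function",
        rarity = paste0("all present MAFs <= ", maf_max),
        case_occurrence = paste0("case alt alleles >= ", min_case_alt,
                                 " or a homozygous case"),
        parental = paste0("parent alt alleles <= ", parent_max_alt,
                          " (<= ", parent_max_alt_if_child_carries,
                          " if the trio child carries)"),
        replication = paste0("replication concordance >= ", concordance_min)))
  }
  res$retained <- alive
  res$reason <- reason
  out <- structure(res, ledger = dplyr::bind_rows(ledger),
                   class = c("prioritization", class(res)))
  out
}

#' Shortlist report for retained variants
#'
#' One row per retained variant with the standard report columns:
#' chromosome, coordinates, rs id, reference/alternative alleles, number
#' of affected transcripts, most severe consequence, novelty, Mendelian
#' transmission error in the trio (computed at that site via
#' [mendel_errors()]), liver expression, known disease associations, and
#' pathogenicity prediction.  Annotation fields are passed through;
#' missing annotation appears as `NA`.
#'
#' @param result A [prioritize_lof()] result.
#' @param callset Call set used for the trio Mendel flag (typically the
#'   first replicate).
#' @param design A [cohort_design()] with the trio bindings.
#' @return A tibble with the 11 report columns; header-only when nothing
#'   was retained.
#' @export
shortlist_report <- function(result, callset, design) {
  trio_row <- design[!is.na(design$father), ]
  cols <- c("chrom", "pos", "rs_id", "ref", "alt", "n_transcripts",
            "consequence", "novel")
  kept <- result[result$retained, , drop = FALSE]
  if (nrow(kept) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), rs_id = character(),
      ref = character(), alt = character(), n_transcripts = integer(),
      consequence = character(), novel = logical(),
      mendel_error = logical(), liver_expression = logical(),
      known_association = character(), pathogenicity = character()))
  }
  mendel_flag <- vapply(seq_len(nrow(kept)), function(i) {
    if (nrow(trio_row) == 0) return(NA)
    site <- callset[callset$chrom == kept$chrom[i] &
                      callset$pos == kept$pos[i] &
                      callset$ref == kept$ref[i] &
                      callset$alt == kept$alt[i], ]
    trio_ids <- c(trio_row$sample[1], trio_row$father[1], trio_row$mother[1])
    if (nrow(site) == 0 || !all(trio_ids %in% site$sample)) return(NA)
    me <- mendel_errors(site, trio_ids[1], trio_ids[2], trio_ids[3])
    me$n_errors > 0
  }, logical(1))
  for (c in setdiff(c(cols, "liver_expression", "known_association",
                      "pathogenicity"), names(kept))) {
    kept[[c]] <- NA
  }
  tibble::tibble(
    chrom = kept$chrom, pos = kept$pos, rs_id = kept$rs_id,
    ref = kept$ref, alt = kept$alt, n_transcripts = kept$n_transcripts,
    consequence = kept$consequence, novel = kept$novel,
    mendel_error = mendel_flag,
    liver_expression = kept$liver_expression,
    known_association = kept$known_association,
    pathogenicity = kept$pathogenicity)
}
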