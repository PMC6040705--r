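#' Genotype-level concordance between two call sets
#'
#' Compares a query call set against a baseline per sample: a variant
#' matches iff its normalized key (`chrom`, `pos`, `ref`, `alt`) is
#' present in both sets *and* the unphased genotype of the sample agrees.
#' Missing genotypes never match.  Precision is matches over query calls,
#' sensitivity matches over baseline calls, and the F-measure their
#' harmonic mean -- so swapping baseline and query exchanges precision and
#' sensitivity and leaves F unchanged.
#'
#' @param baseline,query Call-set tibbles (long form: `chrom`, `pos`,
#'   `ref`, `alt`, `sample`, `a1`, `a2`, ...), already normalized.
#' @param samples Samples to compare; default is the intersection.
#' @return A one-row tibble of class `concordance`: `n_baseline`,
#'   `n_query`, `n_match`, `precision`, `sensitivity`, `f_measure`, with
#'   the per-sample breakdown in attribute `"per_sample"`.
#' @export
#' @examples
#' cs <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "C",
#'                      sample = "s1", a1 = 0L, a2 = 1L)
#' genotype_concordance(cs, cs)$f_measure
genotype_concordance <- function(baseline, query, samples = NULL) {
  shared <- intersect(unique(baseline$sample), unique(query$sample))
  samples <- samples %||% shared
  if (length(samples) == 0) abort("no shared samples between the call sets.")

  b <- baseline |>
    dplyr::filter(.data$sample %in% samples, !is.na(.data$a1), !is.na(.data$a2))
  q <- query |>
    dplyr::filter(.data$sample %in% samples, !is.na(.data$a1), !is.na(.data$a2))
  joined <- dplyr::inner_join(
    b, q, by = c("chrom", "pos", "ref", "alt", "sample"),
    suffix = c("_b", "_q"))
  match <- gt_equal(joined$a1_b, joined$a2_b, joined$a1_q, joined$a2_q)

  per_sample <- dplyr::bind_rows(lapply(samples, function(s) {
    nb <- sum(b$sample == s); nq <- sum(q$sample == s)
    nm <- sum(match[joined$sample == s])
    tibble::tibble(sample = s, n_baseline = nb, n_query = nq, n_match = nm,
                   precision = ifelse(nq > 0, nm / nq, NA_real_),
                   sensitivity = ifelse(nb > 0, nm / nb, NA_real_))
  }))
  nb <- nrow(b); nq <- nrow(q); nm <- sum(match)
  p <- ifelse(nq > 0, nm / nq, NA_real_)
  s <- ifelse(nb > 0, nm / nb, NA_real_)
  out <- tibble::tibble(n_baseline = nb, n_query = nq, n_match = nm,
                        precision = p, sensitivity = s,
                        f_measure = ifelse(p + s > 0, 2 * p * s / (p + s), 0))
  attr(out, "per_sample") <- per_sample
  class(out) <- c("concordance", class(out))
  out
}

#' Concordance of a call set with microarray genotypes
#'
#' The fraction of microarray sites genotyped identically by the
#' sequencing call set, over the compared samples.  A site absent from
#' the call set counts as discordant by default (the comparison measures
#' detection *and* genotype agreement); with `absent_as_ref = TRUE` an
#' absent site is instead treated as a homozygous-reference call, which
#' then agrees with a homozygous-reference array genotype.
#'
#' @param callset Call-set tibble.
#' @param array Microarray genotype tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `a1`, `a2`); sites must be SNVs.
#' @param samples Samples to compare; default is the intersection.
#' @param absent_as_ref Treat sites missing from the call set as
#'   homozygous-reference calls rather than as discordant.
#' @return A one-row tibble: `concordance`, `n_sites`, `n_concordant`,
#'   with a per-sample breakdown in attribute `"per_sample"`.
#' @export
array_concordance <- function(callset, array, samples = NULL,
                              absent_as_ref = FALSE) {
  if (any(nchar(array$ref) != 1 | nchar(array$alt) != 1)) {
    abort("microarray sites must be SNVs.")
  }
  shared <- intersect(unique(callset$sample), unique(array$sample))
  samples <- samples %||% shared
  if (length(samples) == 0) abort("no shared samples between call set and array.")

  a <- dplyr::filter(array, .data$sample %in% samples)
  joined <- dplyr::left_join(
    a, dplyr::select(callset, "chrom", "pos", "ref", "alt", "sample",
                     wgs_a1 = "a1", wgs_a2 = "a2"),
    by = c("chrom", "pos", "ref", "alt", "sample"))
  found <- !is.na(joined$wgs_a1)
  conc <- found & gt_equal(joined$a1, joined$a2, joined$wgs_a1, joined$wgs_a2)
  if (absent_as_ref) {
    conc <- conc | (!found & joined$a1 == 0L & joined$a2 == 0L)
  }
  per_sample <- joined |>
    dplyr::mutate(concordant = conc) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     n_concordant = sum(.data$concordant),
                     concordance = mean(.data$concordant))
  out <- tibble::tibble(concordance = mean(conc), n_sites = length(conc),
                        n_concordant = sum(conc))
  attr(out, "per_sample") <- per_sample
  out
}

# vectorized Mendelian-violation rule on allele pairs: a trio genotype is
# a violation iff no assignment of one child allele to each parent is
# consistent with the parental genotypes
is_mendel_violation <- function(c1, c2, f1, f2, m1, m2) {
  in_f <- function(a) a == f1 | a == f2
  in_m <- function(a) a == m1 | a == m2
  ok <- (in_f(c1) & in_m(c2)) | (in_f(c2) & in_m(c1))
  !ok
}

#' Mendelian inheritance errors in a trio
#'
#' Counts, over all sites where child and both parents have non-missing
#' genotypes, the sites whose trio genotypes violate Mendelian
#' transmission: no assignment of one child allele to each parent is
#' consistent with the parental genotypes.  The rule operates on allele
#' indices, so split multiallelic records are handled transparently.
#'
#' @param callset Call-set tibble.
#' @param child,father,mother Sample ids of the trio members.
#' @return A one-row tibble: `n_errors`, `n_tested`, `rate`; violating
#'   site keys are attached as attribute `"violations"`.
#' @export
#' @examples
#' cs <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "G", alt = "GC",
#'                      sample = c("c", "f", "m"),
#'                      a1 = c(1L, 0L, 0L), a2 = c(1L, 0L, 1L))
#' mendel_errors(cs, "c", "f", "m")
mendel_errors <- function(callset, child, father, mother) {
  trio <- c(child, father, mother)
  if (!all(trio %in% callset$sample)) {
    abort("child, father and mother must all be present in the call set.")
  }
  wide <- callset |>
    dplyr::filter(.data$sample %in% trio) |>
    dplyr::mutate(gt = paste(.data$a1, .data$a2)) |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample", "a1", "a2") |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = c("a1", "a2"))
  c1 <- wide[[paste0("a1_", child)]];  c2 <- wide[[paste0("a2_", child)]]
  f1 <- wide[[paste0("a1_", father)]]; f2 <- wide[[paste0("a2_", father)]]
  m1 <- wide[[paste0("a1_", mother)]]; m2 <- wide[[paste0("a2_", mother)]]
  complete <- !is.na(c1) & !is.na(c2) & !is.na(f1) & !is.na(f2) &
    !is.na(m1) & !is.na(m2)
  viol <- complete & is_mendel_violation(c1, c2, f1, f2, m1, m2)
  out <- tibble::tibble(n_errors = sum(viol), n_tested = sum(complete),
                        rate = ifelse(sum(complete) > 0,
                                      sum(viol) / sum(complete), NA_real_))
  attr(out, "violations") <- wide[viol, c("chrom", "pos", "ref", "alt")]
  out
}

#' Alternative-allele count spectrum of a call set
#'
#' For each biallelic variant, sums the alternative-allele dose over all
#' samples with non-missing genotypes and tabulates the result.
#' Multiallelic variants (several distinct alt alleles at one position)
#' are excluded.
#'
#' @param callset Call-set tibble.
#' @return A tibble `alt_count`, `n_variants` over counts `1..2N`.
#' @export
allele_count_spectrum <- function(callset) {
  multi <- callset |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1L)
  counts <- callset |>
    dplyr::anti_join(multi, by = c("chrom", "pos")) |>
    dplyr::filter(!stringi::stri_detect_fixed(.data$alt, ",")) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(alt_count = sum(allele_dose(.data$a1, .data$a2),
                                     na.rm = TRUE), .groups = "drop") |>
    dplyr::filter(.data$alt_count > 0L)
  counts |>
    dplyr::count(.data$alt_count, name = "n_variants") |>
    dplyr::arrange(.data$alt_count)
}

#' Mismatches between two HLA typing tables
#'
#' Compares two typings (e.g. sequence-derived vs molecular) per sample
#' and gene.  Alleles are truncated to the requested field resolution
#' (two fields by default, e.g. `13:01:01 -> 13:01`), and the mismatch
#' count per (sample, gene) is `2 - |maximum matching|` between the two
#' unordered allele pairs, found by enumerating both assignments of the
#' 2x2 comparison.
#'
#' @param a,b Typing tibbles with columns `sample`, `gene`, `allele1`,
#'   `allele2`.
#' @param resolution Number of colon-separated fields compared.
#' @return A tibble `sample`, `gene`, `mismatches` (0..2), one row per
#'   (sample, gene) present in both tables; the total is attached as
#'   attribute `"total"`.
#' @export
#' @examples
#' a <- tibble::tibble(sample = "s", gene = "DRB1",
#'                     allele1 = "03:01:01", allele2 = "13:01:01")
#' b <- tibble::tibble(sample = "s", gene = "DRB1",
#'                     allele1 = "03:01:01", allele2 = "15:01:01")
#' hla_mismatch_count(a, b)
hla_mismatch_count <- function(a, b, resolution = 2) {
  trunc_allele <- function(x) {
    parts <- stringi::stri_split_fixed(x, ":")
    vapply(parts, function(p) paste(head(p, resolution), collapse = ":"),
           character(1))
  }
  joined <- dplyr::inner_join(a, b, by = c("sample", "gene"),
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("no shared (sample, gene) pairs to compare.")
  mm <- mapply(function(a1, a2, b1, b2) {
    pair_mismatches(trunc_allele(c(a1, a2)), trunc_allele(c(b1, b2)))
  }, joined$allele1_a, joined$allele2_a, joined$allele1_b, joined$allele2_b)
  out <- tibble::tibble(sample = joined$sample, gene = joined$gene,
                        mismatches = as.integer(mm))
  attr(out, "total") <- sum(out$mismatches)
  out
}

# 2 - size of the maximum matching between two unordered allele pairs
pair_mismatches <- function(x, y) {
  m1 <- (x[1] == y[1]) + (x[2] == y[2])
  m2 <- (x[1] == y[2]) + (x[2] == y[1])
  2L - max(m1, m2)
}
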