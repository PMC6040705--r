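test_that("pairwise genotype concordance obeys its counting identities", {
  gts <- list(s1 = list(c(0, 1), c(1, 1), c(0, 1), c(0, 0)))
  baseline <- mk_callset(pos = c(10, 20, 30, 40), ref = "A", alt = "C",
                         gts = gts)
  # query: 3 genotype-matched, 1 genotype-mismatched, 1 extra site
  query <- mk_callset(pos = c(10, 20, 30, 40, 50), ref = "A", alt = "C",
                      gts = list(s1 = list(c(1, 0), c(1, 1), c(0, 1),
                                           c(0, 1), c(0, 0))))
  res <- genotype_concordance(baseline, query)
  expect_equal(res$n_baseline, 4L)
  expect_equal(res$n_query, 5L)
  expect_equal(res$n_match, 3L)
  expect_equal(res$precision, 0.6)
  expect_equal(res$sensitivity, 0.75)
  expect_equal(res$f_measure, 2 / 3)

  # swap symmetry: precision and sensitivity exchange, F unchanged
  swapped <- genotype_concordance(query, baseline)
  expect_equal(swapped$precision, res$sensitivity)
  expect_equal(swapped$sensitivity, res$precision)
  expect_equal(swapped$f_measure, res$f_measure)

  # self-concordance is exactly 1
  self <- genotype_concordance(baseline, baseline)
  expect_equal(c(self$precision, self$sensitivity, self$f_measure),
               c(1, 1, 1))

  # unphased matching: 0/1 equals 1/0 (first query genotype above matched)
  expect_equal(res$n_match, 3L)

  disjoint <- dplyr::mutate(query, sample = "other")
  expect_error(genotype_concordance(baseline, disjoint), "no shared samples")
})

test_that("precision/sensitivity swap holds on simulated replicate pairs", {
  cfg <- sim_config(genome_length = 30000, n_sites = 400, seed = 61,
                    per_center_discordance = 0.02, center_drop_rate = 0.01)
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  ab <- genotype_concordance(cs$centers[[1]], cs$centers[[2]])
  ba <- genotype_concordance(cs$centers[[2]], cs$centers[[1]])
  expect_equal(ab$precision, ba$sensitivity)
  expect_equal(ab$sensitivity, ba$precision)
})

test_that("microarray concordance counts corrupted and absent sites correctly", {
  gts <- lapply(1:2, function(i) list(c(0, 1)))
  names(gts) <- c("s1", "s2")
  calls <- mk_callset(pos = 1:500, ref = "A", alt = "G",
                      gts = list(s1 = rep(list(c(0, 1)), 500),
                                 s2 = rep(list(c(1, 1)), 500)))
  array <- dplyr::select(calls, "chrom", "pos", "ref", "alt", "sample",
                         "a1", "a2")
  expect_equal(array_concordance(calls, array)$concordance, 1)

  # corrupt 30 of 1000 (sample, site) genotypes in the call set
  corrupted <- calls
  corrupted$a1[1:30] <- 1L - corrupted$a1[1:30]
  expect_equal(array_concordance(corrupted, array)$concordance, 0.970)

  # an array site absent from the call set is discordant by default,
  # but hom-ref agreement is allowed with absent_as_ref = TRUE
  array2 <- dplyr::bind_rows(
    array,
    tibble::tibble(chrom = "chr1", pos = 9999L, ref = "A", alt = "G",
                   sample = c("s1", "s2"), a1 = c(0L, 0L), a2 = c(1L, 0L)))
  res <- array_concordance(calls, array2)
  expect_equal(res$n_concordant, 1000L)
  expect_equal(res$n_sites, 1002L)
  res_ref <- array_concordance(calls, array2, absent_as_ref = TRUE)
  expect_equal(res_ref$n_concordant, 1001L) # the hom-ref absent site now agrees

  expect_error(array_concordance(calls,
                                 dplyr::mutate(array, sample = "zz")),
               "no shared samples")
  expect_error(array_concordance(calls,
                                 dplyr::mutate(array, alt = "GG")),
               "SNVs")
})

test_that("array concordance reconciles with the simulator corruption log", {
  cfg <- sim_config(genome_length = 40000, n_sites = 800, seed = 62,
                    per_center_discordance = 0.01)
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  ct <- names(cs$centers)[1]
  res <- array_concordance(cs$centers[[ct]], cs$array)
  lg <- cs$corruption_log
  array_keys <- unique(paste(cs$array$chrom, cs$array$pos))
  n_bad <- sum(lg$center == ct &
                 paste(lg$chrom, lg$pos) %in% array_keys)
  expect_equal(res$n_sites - res$n_concordant, n_bad)
})

test_that("the Mendel rule matches exhaustive brute-force enumeration", {
  gt3 <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  n_viol <- 0L
  for (cg in gt3) for (fg in gt3) for (mg in gt3) {
    calls <- mk_callset(pos = 1, ref = "A", alt = "T",
                        gts = list(kid = list(cg), dad = list(fg),
                                   mom = list(mg)))
    got <- mendel_errors(calls, "kid", "dad", "mom")$n_errors == 1L
    expect_equal(got, mendel_violates_oracle(cg, fg, mg),
                 info = paste("child", paste(cg, collapse = "/"),
                              "father", paste(fg, collapse = "/"),
                              "mother", paste(mg, collapse = "/")))
    n_viol <- n_viol + as.integer(got)
  }
  expect_equal(n_viol, 12L)
})

test_that("Mendel counting excludes missing genotypes and finds planted errors", {
  # published-style violating site: child hom-alt, father hom-ref, mother het
  calls <- mk_callset(pos = c(1, 2, 3), ref = "G", alt = "GC",
                      gts = list(kid = list(c(1, 1), c(0, 0), c(0, 1)),
                                 dad = list(c(0, 0), c(0, 0), c(NA, NA)),
                                 mom = list(c(0, 1), c(0, 0), c(0, 1))))
  res <- mendel_errors(calls, "kid", "dad", "mom")
  expect_equal(res$n_tested, 2L)  # missing-father site excluded
  expect_equal(res$n_errors, 1L)
  expect_equal(attr(res, "violations")$pos, 1L)

  expect_error(mendel_errors(calls, "kid", "dad", "nobody"), "present")

  # simulated: recovered Mendel rate within 3 SE of the planted rate
  cfg <- sim_config(genome_length = 50000, n_sites = 2000, seed = 63,
                    mendel_error_rate = 0.02,
                    planted_causal = c(trio_case1 = 0))
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  me <- mendel_errors(cs$truth, "trio_case1", "trio_father", "trio_mother")
  expect_equal(me$n_errors, nrow(cs$mendel_error_log))
})

test_that("allele count spectra sum doses and exclude multiallelic sites", {
  calls <- mk_callset(
    pos = c(1, 1, 2, 3), ref = "A",
    alt = c("C", "G", "C", "C"),
    gts = list(s1 = list(c(0, 1), c(0, 0), c(0, 1), c(1, 1)),
               s2 = list(c(0, 0), c(0, 1), c(0, 0), c(1, 1))))
  sp <- allele_count_spectrum(calls)
  # pos 1 is multiallelic (two alts) and excluded; pos 2 het in one of two
  # samples -> count 1; pos 3 hom-alt in all -> count 2N = 4
  expect_equal(sp$alt_count, c(1L, 4L))
  expect_equal(sp$n_variants, c(1L, 1L))
})

test_that("HLA mismatches are maximum-matching counts at 2-field resolution", {
  mk_typing <- function(a1, a2) {
    tibble::tibble(sample = "s", gene = "DRB1", allele1 = a1, allele2 = a2)
  }
  expect_equal(hla_mismatch_count(mk_typing("03:01", "13:01"),
                                  mk_typing("03:01", "13:01"))$mismatches, 0L)
  expect_equal(hla_mismatch_count(mk_typing("03:01", "13:01"),
                                  mk_typing("03:01", "15:01"))$mismatches, 1L)
  # homozygous vs heterozygous sharing one allele: one mismatch, found by
  # trying both assignments of the 2x2 comparison
  expect_equal(hla_mismatch_count(mk_typing("13:01", "13:01"),
                                  mk_typing("13:01", "15:01"))$mismatches, 1L)
  # three-field input truncated to two fields before matching
  expect_equal(hla_mismatch_count(mk_typing("13:01:01", "15:01:01"),
                                  mk_typing("13:01:02", "15:01:04"))$mismatches,
               0L)

  # the bundled synthetic sequence-derived typing differs from the
  # published molecular typing by exactly its 3 planted mismatches
  pub <- published_cohort_callset()$table
  molecular <- tibble::tibble(sample = pub$sample, gene = "DRB1",
                              allele1 = pub$hla_drb1_1,
                              allele2 = pub$hla_drb1_2)
  wgs <- readr::read_tsv(
    system.file("extdata", "hla_typing_wgs_synthetic.tsv",
                package = "wgsbakeoff"),
    col_types = readr::cols(.default = readr::col_character()))
  mm <- hla_mismatch_count(molecular, wgs)
  expect_equal(attr(mm, "total"), 3L)
  expect_equal(sum(mm$mismatches > 0), 3L)
})
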