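test_that("replication concordance pools pairwise genotype comparisons", {
  ten <- paste0("s", 1:10)
  base <- mk_callset(pos = 1, ref = "A", alt = "C",
                     gts = setNames(rep(list(list(c(0, 1))), 10), ten))
  # identical genotypes across 4 replicates: concordance 1
  reps4 <- list(a = base, b = base, c = base, d = base)
  expect_equal(replicate_concordance(reps4)$concordance, 1)

  # one discordant genotype in one individual across 3 replicates:
  # that individual contributes 1/3 concordant pairs -> 28/30 overall
  broken <- base
  broken$a1[broken$sample == "s1"] <- 1L
  broken$a2[broken$sample == "s1"] <- 1L
  reps3 <- list(a = base, b = base, c = broken)
  res <- replicate_concordance(reps3)
  expect_equal(res$n_pairs, 30L)
  expect_equal(res$n_concordant, 28L)
  expect_equal(res$concordance, 28 / 30)
  expect_lt(res$concordance, 0.98)

  # two replicates, all concordant
  expect_equal(replicate_concordance(list(a = base, b = base))$concordance, 1)
  # missing genotypes drop out of the denominators
  miss <- base
  miss$a1[miss$sample == "s2"] <- NA_integer_
  res_m <- replicate_concordance(list(a = base, b = miss))
  expect_equal(res_m$n_pairs, 9L)

  expect_error(replicate_concordance(list(a = base)), "at least two")
})

mk_prio_fixture <- function() {
  design <- tibble::tibble(
    sample = c("mom", "dad", "kid", paste0("case", 2:8)),
    role = c("parent", "parent", rep("case", 8)),
    father = c(NA, NA, "dad", rep(NA, 7)),
    mother = c(NA, NA, "mom", rep(NA, 7)))
  # published-pattern causal at pos 100: kid 1/1, mom 0/1, dad 0/0,
  # case2 0/1, everyone else 0/0
  gt_of <- function(s, pos) {
    if (pos == 100) {
      switch(s, kid = c(1, 1), mom = c(0, 1), case2 = c(0, 1), c(0, 0))
    } else if (pos == 200) {
      c(0, 1)                      # common in everyone incl. parents
    } else if (pos == 300) {
      # parent-carried with a non-carrier child, but seen in two cases
      if (s %in% c("mom", "case3", "case4")) c(0, 1) else c(0, 0)
    } else {
      c(0, 0)
    }
  }
  pos <- c(100L, 200L, 300L, 400L)
  gts <- lapply(design$sample, function(s) lapply(pos, gt_of, s = s))
  names(gts) <- design$sample
  calls <- mk_callset(pos = pos, ref = "G", alt = c("GC", "A", "T", "C"),
                      gts = gts)
  ann <- tibble::tibble(
    chrom = "chr1", pos = pos, ref = "G", alt = c("GC", "A", "T", "C"),
    gene = c("FTCD_like", "G2", "G3", "G4"),
    consequence = "frameshift_variant",
    lof_confidence = c("high", "high", "high", "none"),
    maf_1000g = c(NA, 0.004, 0.001, NA),
    maf_exac = c(NA, 0.002, NA, NA),
    maf_gnomad = c(0.006, 0.05, 0.002, 0.001),
    rs_id = NA_character_, n_transcripts = 2L, novel = TRUE,
    liver_expression = TRUE, known_association = NA_character_,
    pathogenicity = "Pathogenic")
  list(design = design, calls = calls, ann = ann)
}

test_that("the prioritization chain retains the planted pattern and logs reasons", {
  fx <- mk_prio_fixture()
  reps <- list(a = fx$calls, b = fx$calls, c = fx$calls)
  res <- prioritize_lof(fx$ann, reps, fx$design)

  # causal-pattern variant retained: 2 carrier cases (one hom, one het),
  # mother's allele tolerated because the child carries
  caus <- res[res$pos == 100, ]
  expect_true(caus$retained)
  expect_equal(caus$case_alt_count, 3L)
  expect_true(caus$has_hom_case)
  expect_equal(caus$parent_alt_count, 1L)

  # pos 200 fails the MAF ceiling first (gnomAD 0.05)
  expect_equal(res$reason[res$pos == 200], "rarity")
  # pos 300 is parent-carried with a non-carrier child
  expect_equal(res$reason[res$pos == 300], "parental")
  # pos 400 is not LoF
  expect_equal(res$reason[res$pos == 400], "lof")

  # ledger conservation: retained + per-reason exclusions = input
  gl <- glance(res)
  expect_equal(gl$n_retained + sum(is.na(res$reason) == FALSE), gl$n_input)
  led <- filter_ledger(res)
  expect_equal(led$n_in[-1], led$n_out[-nrow(led)])

  # a replication failure at the causal site excludes it
  broken <- fx$calls
  broken$a1[broken$pos == 100 & broken$sample == "case3"] <- 1L
  res2 <- prioritize_lof(fx$ann, list(a = fx$calls, b = fx$calls,
                                      c = broken), fx$design)
  expect_false(res2$retained[res2$pos == 100])
  expect_equal(res2$reason[res2$pos == 100], "replication")
})

test_that("relaxing thresholds never shrinks the retained set", {
  cfg <- sim_config(genome_length = 40000, n_sites = 500, seed = 101,
                    per_center_discordance = 0.005, lof_fraction = 0.3)
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  ann <- sim_annotations(cs$truth, cfg, causal = cs$causal,
                         maf_range = c(0.001, 0.2), maf_missing_rate = 0.2)
  des <- cohort_design(cfg)
  strict <- prioritize_lof(ann, cs$centers, des, maf_max = 0.01,
                           min_case_alt = 2)
  looser_maf <- prioritize_lof(ann, cs$centers, des, maf_max = 0.05,
                               min_case_alt = 2)
  looser_case <- prioritize_lof(ann, cs$centers, des, maf_max = 0.01,
                                min_case_alt = 1)
  key <- function(r) paste(r$chrom, r$pos, r$ref, r$alt)[r$retained]
  expect_true(all(key(strict) %in% key(looser_maf)))
  expect_true(all(key(strict) %in% key(looser_case)))
})

test_that("shortlist reports carry the 11 columns and the trio Mendel flag", {
  fx <- mk_prio_fixture()
  reps <- list(a = fx$calls, b = fx$calls, c = fx$calls)
  res <- prioritize_lof(fx$ann, reps, fx$design)
  sl <- shortlist_report(res, fx$calls, fx$design)
  expect_equal(nrow(sl), 1L)
  expect_equal(names(sl),
               c("chrom", "pos", "rs_id", "ref", "alt", "n_transcripts",
                 "consequence", "novel", "mendel_error", "liver_expression",
                 "known_association", "pathogenicity"))
  # kid 1/1, dad 0/0, mom 0/1 at the causal site: a transmission error
  expect_true(sl$mendel_error)

  # empty retained set gives a header-only table
  none <- prioritize_lof(dplyr::mutate(fx$ann, lof_confidence = "none"),
                         reps, fx$design)
  expect_equal(nrow(shortlist_report(none, fx$calls, fx$design)), 0L)
})
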