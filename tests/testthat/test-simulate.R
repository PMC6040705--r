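test_that("reference simulation is deterministic and plants its features", {
  cfg <- sim_config(genome_length = 50000, seed = 1)
  r1 <- sim_reference(cfg)
  r2 <- sim_reference(cfg)
  expect_identical(r1$sequences, r2$sequences)
  expect_equal(unname(nchar(r1$sequences)), 50000)

  # planted duplicate occurs at least twice verbatim
  dup <- r1$truth[r1$truth$label == "duplication_source", ]
  seg <- substr(r1$sequences[[dup$seqnames]], dup$start + 1L, dup$end)
  expect_gte(stringi::stri_count_fixed(r1$sequences[[dup$seqnames]], seg), 2L)

  # planted homopolymer interval has the configured length
  hp <- r1$truth[r1$truth$label == "homopolymer", ]
  expect_equal(hp$end - hp$start, 10L)
  run <- substr(r1$sequences[[hp$seqnames]], hp$start + 1L, hp$end)
  expect_equal(run, strrep("A", 10))

  expect_error(sim_reference(sim_config(genome_length = 1500)),
               "too short")
})

test_that("read simulation hits pair count, zero-noise exactness, and geometry checks", {
  cfg <- sim_config(genome_length = 20000, coverage = 10, seed = 2,
                    base_error_rate = 0, adapter_rate = 0, n_rate = 0,
                    low_q_read_rate = 0)
  ref <- sim_reference(cfg)
  rd <- sim_read_pairs(ref, cfg)
  expected_pairs <- 10 * 20000 / (2 * 150)
  expect_lt(abs(nrow(rd$pairs) - expected_pairs) / expected_pairs, 0.01)

  # zero noise: every read is an exact substring of the reference strand
  # or of its reverse complement
  genome <- ref$sequences[[1]]
  rc <- stringi::stri_reverse(chartr("ACGT", "TGCA", genome))
  some <- rd$pairs[sample.int(nrow(rd$pairs), 50), ]
  fwd1 <- stringi::stri_detect_fixed(genome, some$read1)
  rev1 <- stringi::stri_detect_fixed(rc, some$read1)
  fwd2 <- stringi::stri_detect_fixed(genome, some$read2)
  rev2 <- stringi::stri_detect_fixed(rc, some$read2)
  expect_true(all(fwd1 | rev1))
  expect_true(all(fwd2 | rev2))

  expect_error(
    sim_read_pairs(ref, sim_config(genome_length = 20000,
                                   insert_size_mean = 100)),
    "invalid pair geometry")
})

test_that("adapter injection frequency reconciles with the draw log", {
  cfg <- sim_config(genome_length = 50000, coverage = 30, seed = 3,
                    adapter_rate = 0.006, base_error_rate = 0)
  rd <- sim_read_pairs(sim_reference(cfg), cfg)
  n <- nrow(rd$pairs)
  observed <- mean(rd$log$adapter)
  se <- sqrt(0.006 * 0.994 / n)
  expect_lt(abs(observed - 0.006), 4 * se)
  # and the scanner finds exactly the unclean pairs the log says exist
  scanned <- scan_adapters_and_ns(rd$pairs, cfg$adapter_seq)
  expect_identical(scanned$clean, !(rd$log$adapter | rd$log$has_n))
})

test_that("replicate call sets reproduce the configured discordance structure", {
  # zero noise: replicates identical to truth, no Mendel errors
  cfg0 <- sim_config(genome_length = 30000, n_sites = 500, seed = 4,
                     per_center_discordance = 0, mendel_error_rate = 0,
                     planted_causal = c(trio_case1 = 0))
  ref0 <- sim_reference(cfg0)
  cs0 <- sim_callsets(ref0, cohort_design(cfg0), cfg0)
  for (ct in names(cs0$centers)) {
    expect_identical(cs0$centers[[ct]]$a1, cs0$truth$a1)
    expect_identical(cs0$centers[[ct]]$a2, cs0$truth$a2)
  }
  expect_equal(nrow(cs0$corruption_log), 0L)
  trio <- cfg0$trio
  me <- mendel_errors(cs0$truth, trio[["child"]], trio[["father"]],
                      trio[["mother"]])
  expect_equal(me$n_errors, 0L)

  # nonzero discordance: observed corrupted fraction within 3 SE of target,
  # and the corruption log reconciles exactly with truth-vs-replicate diffs
  cfg1 <- sim_config(genome_length = 50000, n_sites = 1000, seed = 5,
                     per_center_discordance = 0.01)
  cs1 <- sim_callsets(sim_reference(cfg1), cohort_design(cfg1), cfg1)
  for (ct in names(cs1$centers)) {
    rep_cs <- cs1$centers[[ct]]
    diff <- which(!(rep_cs$a1 == cs1$truth$a1 & rep_cs$a2 == cs1$truth$a2))
    lg <- cs1$corruption_log[cs1$corruption_log$center == ct, ]
    expect_equal(length(diff), nrow(lg))
    expect_setequal(paste(rep_cs$chrom[diff], rep_cs$pos[diff],
                          rep_cs$sample[diff]),
                    paste(lg$chrom, lg$pos, lg$sample))
    n_gt <- nrow(cs1$truth)
    se <- sqrt(0.01 * 0.99 / n_gt)
    expect_lt(abs(nrow(lg) / n_gt - 0.01), 3 * se + 1e-9)
  }
})

test_that("the planted causal variant carries the configured genotype pattern", {
  cfg <- sim_config(genome_length = 30000, n_sites = 300, seed = 6)
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  at_causal <- dplyr::semi_join(cs$truth, cs$causal,
                                by = c("chrom", "pos", "ref", "alt"))
  gt <- setNames(paste0(at_causal$a1 + 1, "/", at_causal$a2 + 1),
                 at_causal$sample)
  # published-style pattern: child hom-alt, mother het, father hom-ref,
  # one unrelated case het, everyone else hom-ref
  expect_equal(unname(gt["trio_case1"]), "2/2")
  expect_equal(unname(gt["trio_mother"]), "1/2")
  expect_equal(unname(gt["trio_father"]), "1/1")
  expect_equal(sum(gt == "1/2"), 2L)   # mother + one unrelated case
  expect_equal(sum(gt == "2/2"), 1L)
  # and it is an insertion relative to the reference base
  expect_equal(nchar(cs$causal$ref), 1L)
  expect_equal(nchar(cs$causal$alt), 2L)
})

test_that("depth profiles place planted duplications and honour zero dispersion", {
  sds <- tibble::tibble(seqnames = "chr1", start = 10000L, end = 25000L,
                        cn = 4, samples = NA)
  cfg <- sim_config(genome_length = 40000, dispersion = 0, seed = 7,
                    planted_sds = sds)
  d <- sim_depth_profile(sim_reference(cfg), cfg)
  inside <- d$start >= 10000 & d$end <= 25000
  expect_true(all(d$depth[inside] == 60))
  expect_true(all(d$depth[!inside] == 30))
})

test_that("annotation tables flag LoF at the configured rate and mark the causal", {
  cfg <- sim_config(genome_length = 50000, n_sites = 1000, seed = 8,
                    lof_fraction = 0.05)
  cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
  ann <- sim_annotations(cs$truth, cfg, causal = cs$causal)
  n_lof <- sum(ann$lof_confidence == "high")
  n <- nrow(ann)
  se <- sqrt(0.05 * 0.95 * n)
  expect_lt(abs(n_lof - 0.05 * n), 4 * se)

  caus <- dplyr::semi_join(ann, cs$causal, by = c("chrom", "pos", "ref", "alt"))
  expect_equal(caus$lof_confidence, "high")
  mafs <- c(caus$maf_1000g, caus$maf_exac, caus$maf_gnomad)
  expect_true(all(is.na(mafs) | mafs < 0.01))

  # lof_fraction = 0: only the causal is flagged
  cfg0 <- sim_config(genome_length = 50000, n_sites = 500, seed = 9,
                     lof_fraction = 0)
  cs0 <- sim_callsets(sim_reference(cfg0), cohort_design(cfg0), cfg0)
  ann0 <- sim_annotations(cs0$truth, cfg0, causal = cs0$causal)
  expect_equal(sum(ann0$lof_confidence == "high"), 1L)
})

test_that("simulator output is byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 20000, n_sites = 200, coverage = 5,
                    seed = 10)
  ref <- sim_reference(cfg)
  a <- sim_read_pairs(ref, cfg)
  b <- sim_read_pairs(ref, cfg)
  expect_identical(a$pairs, b$pairs)
  x <- sim_callsets(ref, cohort_design(cfg), cfg)
  y <- sim_callsets(ref, cohort_design(cfg), cfg)
  expect_identical(x$truth, y$truth)
  expect_identical(x$centers, y$centers)
})
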