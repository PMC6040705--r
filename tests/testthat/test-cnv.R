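mk_depth <- function(depths, sample = "s1", width = 1000L) {
  n <- length(depths)
  tibble::tibble(seqnames = "chr1",
                 start = seq(0L, by = width, length.out = n),
                 end = seq(width, by = width, length.out = n),
                 sample = sample, depth = depths)
}

test_that("copy-number normalization is exact against control windows", {
  prof <- compute_cn(mk_depth(rep(30, 50)))
  expect_true(all(prof$cn == 2))
  ctl <- attr(prof, "control_stats")
  expect_equal(ctl$mean_cn, 2)
  expect_equal(ctl$sd_cn, 0)

  # a doubled-depth window reads CN 4 against a flat control
  d <- mk_depth(c(rep(30, 49), 60))
  prof2 <- compute_cn(d, exclude = tibble::tibble(
    seqnames = "chr1", start = 49000L, end = 50000L, label = "sd"))
  expect_equal(prof2$cn[50], 4)
  # control mean CN is exactly 2 by construction
  expect_equal(mean(prof2$cn[prof2$control]), 2)

  expect_error(compute_cn(mk_depth(rep(0, 10))), "zero mean depth")
})

test_that("planted copy-number segments are recovered within 5%", {
  sds <- tibble::tibble(seqnames = "chr1", start = 20000L, end = 35000L,
                        cn = 3, samples = NA)
  cfg <- sim_config(genome_length = 60000, dispersion = 0.2, seed = 91,
                    planted_sds = sds)
  d <- sim_depth_profile(sim_reference(cfg), cfg,
                         samples = c("s1", "s2"))
  prof <- compute_cn(d, exclude = sds)
  inside <- prof$start >= 20000 & prof$end <= 35000
  expect_lt(abs(mean(prof$cn[inside]) - 3) / 3, 0.05)
})

test_that("duplication calling applies the span rule and dispersion threshold", {
  # 12 windows at CN 4 over a control of 2 +/- 0.2: one 12 kb call
  set.seed(92)
  base <- pmax(rnorm(100, 30, 3), 1)
  base[41:52] <- base[41:52] * 2
  prof <- compute_cn(mk_depth(base), exclude = tibble::tibble(
    seqnames = "chr1", start = 40000L, end = 52000L, label = "sd"))
  sds <- call_segmental_duplications(prof, min_span = 10000, k_sigma = 3)
  expect_equal(nrow(sds), 1L)
  expect_equal(sds$start, 40000L)
  expect_equal(sds$end, 52000L)
  expect_equal(sds$n_windows, 12L)
  expect_gt(sds$mean_cn, 3)

  # 8 consecutive elevated windows span only 8 kb: below min_span, no call
  short <- pmax(rnorm(100, 30, 3), 1)
  short[41:48] <- short[41:48] * 2
  prof_s <- compute_cn(mk_depth(short), exclude = tibble::tibble(
    seqnames = "chr1", start = 40000L, end = 48000L, label = "sd"))
  expect_equal(nrow(call_segmental_duplications(prof_s)), 0L)

  # flat profile with modest dispersion: no calls at k_sigma = 3
  flat <- compute_cn(mk_depth(pmax(rnorm(100, 30, 1.5), 1)))
  expect_equal(nrow(call_segmental_duplications(flat)), 0L)
})

test_that("a one-window masked gap is bridged inside a duplication", {
  set.seed(93)
  base <- pmax(rnorm(100, 30, 1), 1)
  base[41:52] <- base[41:52] * 2
  base[46] <- 30 # one interior window back at baseline (e.g. masked out)
  d <- mk_depth(base)[-46, ] # window absent entirely
  prof <- compute_cn(d, exclude = tibble::tibble(
    seqnames = "chr1", start = 40000L, end = 52000L, label = "sd"))
  sds <- call_segmental_duplications(prof)
  expect_equal(nrow(sds), 1L)
  expect_equal(sds$start, 40000L)
  expect_equal(sds$end, 52000L)
})

test_that("case-specific duplications exclude anything shared with parents", {
  design <- tibble::tibble(
    sample = c("mom", "dad", "kid", "case2", "case3"),
    role = c("parent", "parent", "case", "case", "case"),
    father = c(NA, NA, "dad", NA, NA),
    mother = c(NA, NA, "mom", NA, NA))
  sd_row <- function(sample, start, end) {
    tibble::tibble(sample = sample, seqnames = "chr1", start = start,
                   end = end, n_windows = (end - start) %/% 1000L,
                   mean_cn = 4, threshold = 2.6)
  }
  sds <- dplyr::bind_rows(
    sd_row("kid", 10000L, 25000L),   # shared by two cases, no parent
    sd_row("case2", 12000L, 26000L),
    sd_row("case3", 50000L, 62000L), # single case only
    sd_row("kid", 80000L, 95000L),   # shared with a parent: excluded
    sd_row("mom", 82000L, 90000L))
  res <- case_specific_sds(sds, design, min_cases = 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 12000L)
  expect_equal(res$end, 25000L)
  expect_equal(res$n_cases, 2L)

  # identical duplication in every sample including parents: nothing left
  all_sd <- dplyr::bind_rows(lapply(design$sample, sd_row,
                                    start = 10000L, end = 22000L))
  expect_equal(nrow(case_specific_sds(all_sd, design)), 0L)

  # with min_cases = 1 the singleton case duplication is reported
  res1 <- case_specific_sds(sds, design, min_cases = 1)
  expect_true(any(res1$start == 50000L))

  no_healthy <- dplyr::filter(design, role == "case")
  expect_error(case_specific_sds(sds, no_healthy), "no healthy samples")
})

test_that("planted duplications are recovered end-to-end from depth profiles", {
  sds <- tibble::tibble(seqnames = "chr1", start = 20000L, end = 34000L,
                        cn = 4, samples = "kid,case2")
  cfg <- sim_config(genome_length = 60000, dispersion = 0.2, seed = 94,
                    planted_sds = sds)
  d <- sim_depth_profile(sim_reference(cfg), cfg,
                         samples = c("kid", "case2", "mom"))
  prof <- compute_cn(d, exclude = sds)
  calls <- call_segmental_duplications(prof)
  expect_setequal(unique(calls$sample), c("kid", "case2"))
  jac <- vapply(c("kid", "case2"), function(s) {
    got <- calls[calls$sample == s, ]
    inter <- pmax(0, pmin(got$end, 34000) - pmax(got$start, 20000))
    sum(inter) / (sum(got$end - got$start) + 14000 - sum(inter))
  }, numeric(1))
  expect_true(all(jac >= 0.9))
})
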