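#' Simulate a truth call set, replicate per-center call sets, and a
#' microarray truth table
#'
#' Draws biallelic variant sites on the reference, assigns founder
#' genotypes under Hardy-Weinberg sampling, derives the trio child's
#' genotype by Mendelian transmission (corrupted at `mendel_error_rate`),
#' and plants one causal variant with a fixed carrier pattern.  Each
#' replicate ("center") call set equals the truth except that genotypes
#' are independently corrupted with probability `per_center_discordance`
#' (a corrupted genotype is resampled uniformly from the other two
#' biallelic diploid genotypes) and a fraction `center_drop_rate` of
#' records is dropped.  The planted causal variant is exempt from
#' corruption: its carrier pattern is definitional truth, emulating a
#' validated variant that replicates across centers.  Every corruption is logged so concordance numbers
#' can be reconciled exactly.  A microarray-style truth table is a uniform
#' random subset of the truth SNV sites.
#'
#' @param reference A [sim_reference()] (or named character vector).
#' @param design A [cohort_design()] table.
#' @param config A [sim_config()].
#' @param centers Character vector of replicate call-set names.
#' @param array_fraction Fraction of truth SNV sites on the microarray.
#' @return A list of class `sim_callsets` with elements `truth` (long
#'   call-set tibble: `chrom`, `pos`, `ref`, `alt`, `qual`, `filter`,
#'   `sample`, `a1`, `a2`, `gq`, `dp`, `sp`), `centers` (named list of
#'   call-set tibbles), `array` (tibble), `corruption_log`,
#'   `mendel_error_log`, and `causal` (single-row site tibble, or NULL).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_sites = 100, seed = 3)
#' cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
#' names(cs$centers)
sim_callsets <- function(reference, design = cohort_design(config),
                         config = sim_config(),
                         centers = c("centerA", "centerB", "centerC"),
                         array_fraction = 0.1) {
  seqs <- as_reference(reference)
  if (config$mendel_error_rate > 0 &&
      !all(config$trio %in% design$sample)) {
    abort("design must contain the full trio when mendel_error_rate > 0.")
  }
  set.seed(config$seed + 2L)

  sites <- draw_sites(seqs, config$n_sites)
  samples <- design$sample
  trio <- config$trio
  n_sites <- nrow(sites)

  # founder genotypes under HWE at a per-site allele frequency
  p_alt <- runif(n_sites, 0.05, 0.5)
  founders <- setdiff(samples, trio[["child"]])
  gt <- list()
  for (s in founders) {
    gt[[s]] <- cbind(a1 = as.integer(runif(n_sites) < p_alt),
                     a2 = as.integer(runif(n_sites) < p_alt))
  }

  # child: one transmitted allele per parent, then planted Mendel errors
  pick <- function(m) m[cbind(seq_len(n_sites), sample(1:2, n_sites, TRUE))]
  child <- cbind(a1 = pick(gt[[trio[["father"]]]]),
                 a2 = pick(gt[[trio[["mother"]]]]))
  mendel_flip <- runif(n_sites) < config$mendel_error_rate
  if (any(mendel_flip)) {
    for (i in which(mendel_flip)) {
      child[i, ] <- corrupt_gt(child[i, 1], child[i, 2])
    }
    # only keep flips that actually violate transmission
    f <- gt[[trio[["father"]]]]; m <- gt[[trio[["mother"]]]]
    viol <- is_mendel_violation(child[, 1], child[, 2],
                                f[, 1], f[, 2], m[, 1], m[, 2])
    mendel_flip <- mendel_flip & viol
  }
  gt[[trio[["child"]]]] <- child

  # planted causal variant: an insertion with a fixed carrier pattern
  pattern <- config$planted_causal %||% default_causal_pattern(design, trio)
  causal_idx <- which.max(sites$pos > max(sites$pos) %/% 2L)
  sites$alt[causal_idx] <- paste0(sites$ref[causal_idx], "C")
  for (s in samples) {
    dose <- if (s %in% names(pattern)) pattern[[s]] else 0L
    gt[[s]][causal_idx, ] <- c(as.integer(dose == 2L), as.integer(dose >= 1L))
  }
  mendel_flip[causal_idx] <- FALSE

  # site-major long table; genotype matrices are column-bound per sample
  # and interleaved so row order is (site 1, sample 1..S), (site 2, ...)
  site_id <- rep(seq_len(n_sites), each = length(samples))
  sample_col <- rep(samples, times = n_sites)
  a1_mat <- vapply(samples, function(s) gt[[s]][, 1], integer(n_sites))
  a2_mat <- vapply(samples, function(s) gt[[s]][, 2], integer(n_sites))
  truth <- tibble::tibble(
    chrom = sites$chrom[site_id],
    pos = sites$pos[site_id],
    ref = sites$ref[site_id],
    alt = sites$alt[site_id],
    qual = sites$qual[site_id],
    filter = "PASS",
    sample = sample_col,
    a1 = as.integer(t(a1_mat))[seq_along(site_id)],
    a2 = as.integer(t(a2_mat))[seq_along(site_id)],
    gq = sites$gq[site_id],
    dp = rpois(length(site_id), config$mean_depth),
    sp = round(runif(length(site_id), 0, 10), 1)
  )

  # replicate call sets with independent genotype corruption
  center_sets <- list()
  logs <- list()
  for (ct in centers) {
    cs <- truth
    hit <- runif(nrow(cs)) < config$per_center_discordance
    # the planted causal carrier pattern is definitional truth (it emulates
    # a validated, fully replicating variant): never corrupted
    hit <- hit & !(cs$chrom == sites$chrom[causal_idx] &
                     cs$pos == sites$pos[causal_idx])
    if (any(hit)) {
      new_gt <- t(mapply(corrupt_gt, cs$a1[hit], cs$a2[hit]))
      logs[[ct]] <- tibble::tibble(
        center = ct, chrom = cs$chrom[hit], pos = cs$pos[hit],
        ref = cs$ref[hit], alt = cs$alt[hit], sample = cs$sample[hit],
        truth_gt = gt_string(cs$a1[hit], cs$a2[hit]),
        new_gt = gt_string(new_gt[, 1], new_gt[, 2]))
      cs$a1[hit] <- new_gt[, 1]
      cs$a2[hit] <- new_gt[, 2]
    }
    if (config$center_drop_rate > 0) {
      keep_site <- runif(n_sites) >= config$center_drop_rate
      keep_key <- paste(sites$chrom, sites$pos)[keep_site]
      cs <- dplyr::filter(cs, paste(.data$chrom, .data$pos) %in% keep_key)
    }
    center_sets[[ct]] <- cs
  }

  # microarray: random subset of truth SNV sites, error-free genotypes
  snv_idx <- which(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L)
  array_idx <- sort(sample(snv_idx, max(1L, round(array_fraction * length(snv_idx)))))
  array_key <- paste(sites$chrom, sites$pos)[array_idx]
  array <- truth |>
    dplyr::filter(paste(.data$chrom, .data$pos) %in% array_key) |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample", "a1", "a2")

  causal <- sites[causal_idx, c("chrom", "pos", "ref", "alt")]
  structure(list(
    truth = truth,
    centers = center_sets,
    array = array,
    corruption_log = if (length(logs)) dplyr::bind_rows(logs) else
      tibble::tibble(center = character(), chrom = character(), pos = integer(),
                     ref = character(), alt = character(), sample = character(),
                     truth_gt = character(), new_gt = character()),
    mendel_error_log = sites[which(mendel_flip), c("chrom", "pos", "ref", "alt")],
    causal = causal
  ), class = "sim_callsets")
}

draw_sites <- function(seqs, n_sites) {
  lens <- nchar(seqs)
  # sample distinct positions genome-wide, then map back to sequences
  offs <- c(0, cumsum(as.numeric(lens)))
  flat <- sort(sample.int(sum(lens), min(n_sites, sum(lens))))
  chrom_i <- findInterval(flat - 1L, offs[-length(offs)], rightmost.closed = FALSE)
  chrom_i <- pmin(pmax(chrom_i, 1L), length(seqs))
  pos <- as.integer(flat - offs[chrom_i])
  ref <- stringi::stri_sub(seqs[chrom_i], pos, length = 1L)
  ok <- ref %in% c("A", "C", "G", "T")
  chrom_i <- chrom_i[ok]; pos <- pos[ok]; ref <- ref[ok]
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1), USE.NAMES = FALSE)
  tibble::tibble(chrom = names(seqs)[chrom_i], pos = pos, ref = ref, alt = alt,
                 qual = round(runif(length(pos), 50, 2000), 1),
                 gq = sample(30:99, length(pos), replace = TRUE))
}

# resample a biallelic diploid genotype uniformly from the other two
corrupt_gt <- function(a1, a2) {
  states <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  cur <- which(vapply(states, function(s)
    s[1] == min(a1, a2) && s[2] == max(a1, a2), logical(1)))
  states[[sample(setdiff(1:3, cur), 1L)]]
}
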