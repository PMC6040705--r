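#' Simulation configuration for a multi-center sequencing study
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' read geometry and noise rates, the cohort layout (eight affected cases
#' plus the two healthy parents of one of them, forming a parent-offspring
#' trio), per-center genotype corruption, planted segmental duplications and
#' a planted rare causal variant.  The defaults emulate a 30x paired-end
#' 150 bp short-read study with a 400 bp insert.
#'
#' @param genome_length Total reference length in bp.
#' @param n_chromosomes Number of reference sequences the genome is split into.
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   simulator output.
#' @param read_length Read length in bp.
#' @param insert_size_mean,insert_size_sd Fragment (insert) size distribution, bp.
#' @param coverage Target mean fold coverage.
#' @param base_error_rate Per-base substitution error probability.
#' @param adapter_rate Probability a pair reads through into the adapter.
#' @param n_rate Probability a pair carries at least one uncalled (N) base.
#' @param low_q_read_rate Probability a read is emitted in the low-quality
#'   state (mean Phred ~12, below the Q20 retention threshold).
#' @param adapter_seq Adapter sequence injected on read-through.
#' @param n_cases Number of affected (case) samples, including the trio child.
#' @param trio Named character vector with elements `child`, `father`,
#'   `mother` giving the trio sample ids.
#' @param n_sites Number of simulated variant sites.
#' @param per_center_discordance Probability that any single genotype is
#'   corrupted in a replicate (per-center) call set.
#' @param center_drop_rate Fraction of variant records dropped from each
#'   replicate call set.
#' @param mendel_error_rate Probability a trio-child genotype violates
#'   Mendelian transmission in the truth set.
#' @param dispersion Standard deviation of window copy number (CN units)
#'   around the diploid baseline in simulated depth profiles.
#' @param window_size Depth-profile window size in bp.
#' @param mean_depth Mean per-window sequencing depth at copy number 2.
#' @param planted_sds Tibble of planted segmental duplications with columns
#'   `seqnames`, `start`, `end` (0-based half-open), `cn`, and `samples`
#'   (comma-separated carrier sample ids, or `NA` for all samples).
#' @param planted_causal Named integer vector over sample ids giving the
#'   alternative-allele dose (0/1/2) of the planted causal variant; `NULL`
#'   plants the published-style pattern: the trio child homozygous for the
#'   alternative allele, the mother heterozygous, the father homozygous
#'   reference, one unrelated case heterozygous, everyone else
#'   homozygous reference.
#' @param lof_fraction Fraction of background variants flagged as
#'   high-confidence loss-of-function in the simulated annotation table.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, coverage = 10, seed = 7)
#' cfg$read_length
sim_config <- function(genome_length = 50000,
                       n_chromosomes = 1,
                       seed = 1,
                       read_length = 150,
                       insert_size_mean = 400,
                       insert_size_sd = 30,
                       coverage = 30,
                       base_error_rate = 0.001,
                       adapter_rate = 0.006,
                       n_rate = 0.002,
                       low_q_read_rate = 0.01,
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       n_cases = 8,
                       trio = c(child = "trio_case1", father = "trio_father",
                                mother = "trio_mother"),
                       n_sites = 2000,
                       per_center_discordance = 0.01,
                       center_drop_rate = 0,
                       mendel_error_rate = 0.004,
                       dispersion = 0.2,
                       window_size = 1000,
                       mean_depth = 30,
                       planted_sds = NULL,
                       planted_causal = NULL,
                       lof_fraction = 0.05) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    seed = as.integer(seed),
    read_length = as.integer(read_length),
    insert_size_mean = insert_size_mean,
    insert_size_sd = insert_size_sd,
    coverage = coverage,
    base_error_rate = base_error_rate,
    adapter_rate = adapter_rate,
    n_rate = n_rate,
    low_q_read_rate = low_q_read_rate,
    adapter_seq = adapter_seq,
    n_cases = as.integer(n_cases),
    trio = trio,
    n_sites = as.integer(n_sites),
    per_center_discordance = per_center_discordance,
    center_drop_rate = center_drop_rate,
    mendel_error_rate = mendel_error_rate,
    dispersion = dispersion,
    window_size = as.integer(window_size),
    mean_depth = mean_depth,
    planted_sds = planted_sds,
    planted_causal = planted_causal,
    lof_fraction = lof_fraction
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("base_error_rate", "adapter_rate", "n_rate", "low_q_read_rate",
             "per_center_discordance", "center_drop_rate",
             "mendel_error_rate", "lof_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("`", p, "` must be a probability in [0, 1]."))
    }
  }
  if (cfg$coverage <= 0) abort("`coverage` must be positive.")
  if (cfg$genome_length < 10L * cfg$read_length) {
    abort("`genome_length` must be at least 10 * read_length.")
  }
  if (!all(c("child", "father", "mother") %in% names(cfg$trio))) {
    abort("`trio` must name `child`, `father` and `mother` samples.")
  }
  if (!is.null(cfg$planted_sds)) {
    sds <- cfg$planted_sds
    need <- c("seqnames", "start", "end", "cn")
    if (!all(need %in% names(sds))) {
      abort("`planted_sds` needs columns seqnames, start, end, cn.")
    }
    if (any(sds$start < 0) || any(sds$end <= sds$start)) {
      abort("`planted_sds` intervals must be non-empty and non-negative.")
    }
    if (any(sds$end > cfg$genome_length)) {
      abort("planted SD intervals must lie within genome bounds.")
    }
  }
  invisible(cfg)
}

#' Cohort design table for a simulated study
#'
#' Lists the sample ids and roles the simulator and the downstream Mendel
#' and prioritization steps assume: `n_cases` affected samples (the first
#' being the trio child) and two healthy parents bound to the child.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sample`, `role` (`"case"` or `"parent"`),
#'   `father`, `mother` (`NA` except for the trio child).
#' @export
#' @examples
#' cohort_design(sim_config())
cohort_design <- function(config = sim_config()) {
  trio <- config$trio
  cases <- c(trio[["child"]],
             paste0("case", seq_len(config$n_cases)[-1]))
  tibble::tibble(
    sample = c(trio[["mother"]], trio[["father"]], cases),
    role = c("parent", "parent", rep("case", length(cases))),
    father = c(NA, NA, trio[["father"]], rep(NA, length(cases) - 1L)),
    mother = c(NA, NA, trio[["mother"]], rep(NA, length(cases) - 1L))
  )
}

default_causal_pattern <- function(design, trio) {
  pattern <- setNames(rep(0L, nrow(design)), design$sample)
  pattern[trio[["child"]]] <- 2L
  pattern[trio[["mother"]]] <- 1L
  pattern[trio[["father"]]] <- 0L
  other_cases <- setdiff(design$sample[design$role == "case"], trio[["child"]])
  if (length(other_cases) > 0) pattern[other_cases[1]] <- 1L
  pattern
}
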