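#' Simulate a per-variant annotation table
#'
#' Assigns each variant of a call set a gene id, a consequence class, a
#' high-confidence loss-of-function (LoF) flag, and three population
#' minor-allele-frequency columns (each possibly missing, i.e. absent
#' from that database).  The planted causal variant is always flagged
#' high-confidence LoF and given MAFs satisfying the downstream rarity
#' rule (absent from two databases, 0.006 in the third).
#'
#' @param callset A call-set tibble (e.g. `sim_callsets()$truth`).
#' @param config A [sim_config()]; `lof_fraction` controls the fraction of
#'   background variants flagged high-confidence LoF.
#' @param causal Single-row tibble identifying the causal variant
#'   (`chrom`, `pos`, `ref`, `alt`), or `NULL`.
#' @param maf_range Range the three population MAFs of background variants
#'   are drawn from.
#' @param maf_missing_rate Probability each MAF column is absent (`NA`).
#' @return A tibble with one row per distinct variant: `chrom`, `pos`,
#'   `ref`, `alt`, `rs_id`, `gene`, `consequence`, `n_transcripts`,
#'   `lof_confidence` (`"high"`/`"none"`), `maf_1000g`, `maf_exac`,
#'   `maf_gnomad`, `novel`, `liver_expression`, `known_association`,
#'   `pathogenicity`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_sites = 50)
#' cs <- sim_callsets(sim_reference(cfg), cohort_design(cfg), cfg)
#' ann <- sim_annotations(cs$truth, cfg, causal = cs$causal)
#' table(ann$lof_confidence)
sim_annotations <- function(callset, config = sim_config(), causal = NULL,
                            maf_range = c(0.02, 0.5),
                            maf_missing_rate = 0.1) {
  if (nrow(callset) == 0) abort("call set is empty.")
  set.seed(config$seed + 4L)
  sites <- dplyr::distinct(callset, .data$chrom, .data$pos, .data$ref, .data$alt)
  n <- nrow(sites)

  draw_maf <- function() {
    m <- runif(n, maf_range[1], maf_range[2])
    m[runif(n) < maf_missing_rate] <- NA_real_
    m
  }
  consequences <- c("stop_gained", "frameshift_variant",
                    "splice_donor_variant", "missense_variant",
                    "synonymous_variant", "intron_variant")
  ann <- sites |>
    dplyr::mutate(
      rs_id = ifelse(runif(n) < 0.8, sprintf("rs%07d", sample.int(9999999L, n)),
                     NA_character_),
      gene = sprintf("GENE%03d", 1L + (dplyr::row_number() - 1L) %/% 5L),
      consequence = sample(consequences, n, replace = TRUE),
      n_transcripts = sample(1:8, n, replace = TRUE),
      lof_confidence = ifelse(runif(n) < config$lof_fraction, "high", "none"),
      maf_1000g = draw_maf(),
      maf_exac = draw_maf(),
      maf_gnomad = draw_maf(),
      liver_expression = runif(n) < 0.4,
      known_association = ifelse(runif(n) < 0.02, "GWAS", NA_character_),
      pathogenicity = sample(c("Benign", "VOUS", "Pathogenic"), n,
                             replace = TRUE, prob = c(0.7, 0.25, 0.05))
    ) |>
    dplyr::mutate(novel = is.na(.data$rs_id))

  if (!is.null(causal) && nrow(causal) == 1) {
    i <- which(ann$chrom == causal$chrom & ann$pos == causal$pos &
                 ann$ref == causal$ref & ann$alt == causal$alt)
    if (length(i) == 1) {
      ann$lof_confidence[i] <- "high"
      ann$consequence[i] <- "frameshift_variant"
      ann$maf_1000g[i] <- NA_real_
      ann$maf_exac[i] <- NA_real_
      ann$maf_gnomad[i] <- 0.006
      ann$rs_id[i] <- NA_character_
      ann$novel[i] <- TRUE
      ann$liver_expression[i] <- TRUE
      ann$pathogenicity[i] <- "Pathogenic"
    }
  }
  ann
}
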