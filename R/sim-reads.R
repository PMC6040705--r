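#' Simulate paired-end reads with controlled noise
#'
#' Draws fragments of normally distributed insert size uniformly from the
#' reference and emits read pairs (read 1 forward from the fragment start,
#' read 2 reverse-complemented from the fragment end).  Noise is injected
#' per the configuration: per-base substitution errors, adapter
#' read-through (the read 3' end is overwritten with a prefix of the
#' adapter), uncalled N bases, and a two-state quality model (high ~Q35,
#' low ~Q12) in which a configurable fraction of reads falls below the
#' mean-Q20 retention threshold.  Every injection is logged so tests can
#' reconcile observed fractions against the draw log exactly.
#'
#' @param reference A [sim_reference()], named character vector, or
#'   `DNAStringSet`.
#' @param config A [sim_config()].
#' @return A list of class `sim_reads` with elements `pairs` (tibble:
#'   `pair_id`, `read1`, `qual1`, `read2`, `qual2`) and `log` (tibble per
#'   pair: origin `seqnames`/`start`/`insert`, and injection flags
#'   `adapter`, `has_n`, `low_q1`, `low_q2`, `n_errors`).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 5000, coverage = 5, seed = 2)
#' rd <- sim_read_pairs(sim_reference(cfg), cfg)
#' nrow(rd$pairs)
sim_read_pairs <- function(reference, config = sim_config()) {
  seqs <- as_reference(reference)
  L <- config$read_length
  if (config$insert_size_mean < L) {
    abort("insert_size_mean smaller than read_length: invalid pair geometry.")
  }
  if (sum(nchar(seqs)) == 0) abort("reference is empty.")
  set.seed(config$seed + 1L)

  lens <- nchar(seqs)
  n_pairs <- round(config$coverage * sum(lens) / (2 * L))
  chrom_idx <- sample.int(length(seqs), n_pairs, replace = TRUE,
                          prob = lens / sum(lens))
  insert <- pmin(pmax(round(rnorm(n_pairs, config$insert_size_mean,
                                  config$insert_size_sd)), L),
                 lens[chrom_idx])
  start <- floor(runif(n_pairs) * (lens[chrom_idx] - insert + 1)) + 1L

  frag_end <- start + insert - 1L
  read1 <- stringi::stri_sub(seqs[chrom_idx], start, length = L)
  read2 <- revcomp(stringi::stri_sub(seqs[chrom_idx],
                                     frag_end - L + 1L, frag_end))

  # per-base substitution errors
  n_err1 <- rbinom(n_pairs, L, config$base_error_rate)
  n_err2 <- rbinom(n_pairs, L, config$base_error_rate)
  read1 <- inject_errors(read1, n_err1)
  read2 <- inject_errors(read2, n_err2)

  # adapter read-through: overwrite the 3' tail of both mates
  adapter <- runif(n_pairs) < config$adapter_rate
  if (any(adapter)) {
    alen <- pmin(sample(12:34, sum(adapter), replace = TRUE),
                 nchar(config$adapter_seq))
    ad <- substr(rep(config$adapter_seq, sum(adapter)), 1L, alen)
    stringi::stri_sub(read1[adapter], from = L - alen + 1L, to = L) <- ad
    stringi::stri_sub(read2[adapter], from = L - alen + 1L, to = L) <- ad
  }

  # uncalled bases
  has_n <- runif(n_pairs) < config$n_rate
  if (any(has_n)) {
    npos <- sample.int(L, sum(has_n), replace = TRUE)
    stringi::stri_sub(read1[has_n], from = npos, length = 1L) <- "N"
  }

  # two-state quality model
  low_q1 <- runif(n_pairs) < config$low_q_read_rate
  low_q2 <- runif(n_pairs) < config$low_q_read_rate
  q_hi <- phred_string(35L, L)
  q_lo <- phred_string(12L, L)
  qual1 <- ifelse(low_q1, q_lo, q_hi)
  qual2 <- ifelse(low_q2, q_lo, q_hi)

  pair_id <- sprintf("pair%06d", seq_len(n_pairs))
  structure(list(
    pairs = tibble::tibble(pair_id = pair_id, read1 = read1, qual1 = qual1,
                           read2 = read2, qual2 = qual2),
    log = tibble::tibble(pair_id = pair_id,
                         seqnames = names(seqs)[chrom_idx],
                         start = start, insert = insert,
                         adapter = adapter, has_n = has_n,
                         low_q1 = low_q1, low_q2 = low_q2,
                         n_errors = n_err1 + n_err2)
  ), class = "sim_reads")
}

# substitute n[i] random positions of read i with a different base
inject_errors <- function(reads, n_err) {
  which_err <- which(n_err > 0L)
  if (length(which_err) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  for (i in which_err) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(bases, b), 1L),
                      character(1), USE.NAMES = FALSE)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}
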