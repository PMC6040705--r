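#' Simulate a reference genome with planted repeat features
#'
#' Generates a random nucleotide reference split into `n_chromosomes`
#' sequences, and plants (a) one exact duplicated segment long enough to
#' defeat read-length mappability, and (b) one homopolymer run, so the
#' masking stages have true positives to find.  Truth intervals of all
#' planted features are returned alongside the sequences.
#'
#' @param config A [sim_config()].
#' @param dup_length Length in bp of the planted exact duplication; must be
#'   at least twice the read length to guarantee fully repeated read-length
#'   windows inside it.
#' @param homopolymer_length Length in bp of the planted homopolymer run.
#' @return A list of class `sim_reference` with elements
#'   `sequences` (named character vector) and `truth` (tibble of 0-based
#'   half-open feature intervals with a `label` column:
#'   `"duplication_source"`, `"duplication_copy"`, `"homopolymer"`).
#' @export
#' @examples
#' ref <- sim_reference(sim_config(genome_length = 20000))
#' nchar(ref$sequences)
#' ref$truth
sim_reference <- function(config = sim_config(),
                          dup_length = 400,
                          homopolymer_length = 10) {
  set.seed(config$seed)
  gl <- config$genome_length
  nchr <- config$n_chromosomes
  if (gl < 4L * dup_length + 4L * homopolymer_length) {
    abort("genome too short to host the requested planted features.")
  }
  lens <- diff(round(seq(0, gl, length.out = nchr + 1L)))
  seqs <- vapply(lens, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(nchr))

  # plant features on the first (longest) chromosome
  s1 <- seqs[[1]]
  n1 <- nchar(s1)
  src_start <- max(1L, n1 %/% 10L)                    # 1-based
  src <- substr(s1, src_start, src_start + dup_length - 1L)
  copy_start <- n1 %/% 2L
  substr(s1, copy_start, copy_start + dup_length - 1L) <- src

  hp_start <- n1 - n1 %/% 5L
  hp <- strrep("A", homopolymer_length)
  # guard the flanks so the run is maximal
  substr(s1, hp_start - 1L, hp_start + homopolymer_length) <-
    paste0("C", hp, "C")
  seqs[[1]] <- s1

  truth <- tibble::tibble(
    seqnames = names(seqs)[1],
    start = c(src_start - 1L, copy_start - 1L, hp_start - 1L),
    end = c(src_start - 1L + dup_length, copy_start - 1L + dup_length,
            hp_start - 1L + homopolymer_length),
    label = c("duplication_source", "duplication_copy", "homopolymer")
  )

  structure(list(sequences = seqs, truth = truth), class = "sim_reference")
}
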