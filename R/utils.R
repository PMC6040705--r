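#' @importFrom rlang %||% abort warn
#' @importFrom stats rbinom rnorm rpois runif setNames median sd
#' @importFrom utils head tail
NULL

# reverse complement of plain character DNA (IUPAC ACGTN only)
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# canonical form: lexicographic min of k-mer and its reverse complement
canonical <- function(x) {
  pmin(x, revcomp(x))
}

# all k-length substrings of each sequence, flattened; attr $seq gives the
# index of the originating sequence, attr $start the 1-based start
str_kmers <- function(seqs, k) {
  n <- nchar(seqs)
  usable <- n - k + 1L
  usable[usable < 0L] <- 0L
  idx <- rep.int(seq_along(seqs), usable)
  start <- sequence(usable)
  km <- stringi::stri_sub(seqs[idx], from = start, length = k)
  structure(km, seq = idx, start = start)
}

# coerce the various reference shapes (sim_reference list, DNAStringSet,
# named character) to a named character vector of sequences
as_reference <- function(reference) {
  if (is.list(reference) && !is.null(reference$sequences)) {
    reference <- reference$sequences
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (!is.character(reference)) {
    abort("`reference` must be a named character vector, DNAStringSet, or sim_reference().")
  }
  if (is.null(names(reference))) {
    names(reference) <- paste0("chr", seq_along(reference))
  }
  reference
}

# logical run -> 0-based half-open intervals tibble
runs_to_intervals <- function(flag, seqname, label = NA_character_) {
  if (!any(flag)) {
    return(tibble::tibble(seqnames = character(), start = integer(),
                          end = integer(), label = character()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(seqnames = seqname,
                 start = starts[keep] - 1L,
                 end = ends[keep],
                 label = label)
}

empty_mask <- function(label = NA_character_) {
  tibble::tibble(seqnames = character(), start = integer(),
                 end = integer(), label = character())
}

# per-seqname IRanges list from a 0-based half-open interval tibble
mask_to_iranges <- function(mask) {
  split(IRanges::IRanges(start = mask$start + 1L, end = mask$end),
        factor(mask$seqnames, levels = unique(mask$seqnames)))
}

iranges_to_mask <- function(irl, label = NA_character_) {
  pieces <- lapply(names(irl), function(sn) {
    ir <- irl[[sn]]
    tibble::tibble(seqnames = sn,
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir),
                   label = label)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) empty_mask() else out
}

# mean Phred (+33) quality per quality string
mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

phred_string <- function(q, len) {
  strrep(intToUtf8(33L + q), len)
}

# genotype string from allele index pair (unphased, sorted); NA -> "./."
gt_string <- function(a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  out <- paste0(lo, "/", hi)
  out[is.na(a1) | is.na(a2)] <- "./."
  out
}

# do two unphased diploid genotypes agree (missing never matches)?
gt_equal <- function(a1, a2, b1, b2) {
  !is.na(a1) & !is.na(a2) & !is.na(b1) & !is.na(b2) &
    (pmin(a1, a2) == pmin(b1, b2)) & (pmax(a1, a2) == pmax(b1, b2))
}

# number of copies of `allele` in an unphased genotype (NA if missing)
allele_dose <- function(a1, a2, allele = 1L) {
  (a1 == allele) + (a2 == allele)
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

# let data.table syntax work inside this package without importing it fully
.datatable.aware <- TRUE
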