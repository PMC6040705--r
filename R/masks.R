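#' Low-mappability mask from read-length k-mer uniqueness
#'
#' For each genome position, considers all `read_len`-mers covering it and
#' the fraction of them that are unique in the reference; positions where
#' that ratio falls below `min_unique_ratio` are masked.  "Unique" is
#' operationalized as exact canonical-sequence uniqueness: a window is
#' unique iff its canonical form (lexicographic minimum of the window and
#' its reverse complement) occurs exactly once in the canonical
#' window multiset of the whole reference.  This is deterministic and
#' oracle-verifiable, and a strict proxy for unique alignability of exact
#' repeats.
#'
#' @param reference A [sim_reference()], named character vector, or
#'   `DNAStringSet`.
#' @param read_len Window length in bp (151 matches typical short reads).
#' @param min_unique_ratio Positions with a unique-window ratio strictly
#'   below this value are masked.
#' @return A mask tibble (`seqnames`, `start`, `end`, `label`) with
#'   0-based half-open intervals, sorted and disjoint.  Sequences shorter
#'   than `read_len` are wholly masked with a warning.
#' @export
#' @examples
#' ref <- c(chrA = strrep("ACGTTGCA", 40))
#' mappability_mask(ref, read_len = 31)
mappability_mask <- function(reference, read_len = 151,
                             min_unique_ratio = 0.5) {
  seqs <- as_reference(reference)
  L <- as.integer(read_len)

  short <- nchar(seqs) < L
  if (any(short)) {
    warn(paste("sequences shorter than read_len are wholly masked:",
               paste(names(seqs)[short], collapse = ", ")))
  }

  # canonical multiset over the whole reference
  long <- seqs[!short]
  km <- str_kmers(long, L)
  canon <- canonical(km)
  dt <- data.table::data.table(kmer = canon)
  counts <- dt[, .N, by = "kmer"]
  uniq <- counts[counts$N == 1L, ]$kmer
  is_unique <- canon %in% uniq

  seq_idx <- attr(km, "seq")
  out <- vector("list", length(seqs))
  for (i in seq_along(long)) {
    sn <- names(long)[i]
    n <- nchar(long[[i]])
    u <- as.integer(is_unique[seq_idx == i])     # indexed by window start
    cu <- c(0L, cumsum(u))
    p <- seq_len(n)
    lo <- pmax(1L, p - L + 1L)
    hi <- pmin(p, n - L + 1L)
    ratio <- (cu[hi + 1L] - cu[lo]) / (hi - lo + 1L)
    out[[which(names(seqs) == sn)]] <-
      runs_to_intervals(ratio < min_unique_ratio, sn, "mappability")
  }
  for (sn in names(seqs)[short]) {
    out[[which(names(seqs) == sn)]] <- tibble::tibble(
      seqnames = sn, start = 0L, end = nchar(seqs[[sn]]),
      label = "mappability")
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty_mask("mappability") else res
}

#' Low-complexity mask: homopolymers, DUST windows, external repeats
#'
#' Builds the low-complexity mask as the union of three components, each
#' interval extended by `flank` bp on both sides, clipped to the sequence
#' bounds, and merged:
#'
#' 1. maximal homopolymer runs of at least `min_homopolymer` bp;
#' 2. windows flagged by a DUST complexity scan (window `dust_window`,
#'    step `dust_step`): the score is `sum(c_t * (c_t - 1) / 2) / (k - 1)`
#'    over the window's trinucleotide counts `c_t` (`k` triplets); windows
#'    scoring above `dust_threshold` are masked;
#' 3. an optional external BED of repeat/microsatellite annotations (as
#'    produced by repeat annotation tools, which this package does not
#'    re-implement).
#'
#' @inheritParams mappability_mask
#' @param flank Flank in bp added to each side of every interval.
#' @param min_homopolymer Minimum homopolymer run length masked.
#' @param dust_window,dust_step,dust_threshold DUST scan parameters.
#' @param repeat_bed Optional mask tibble (or path to a BED file) of
#'   externally annotated repeat regions.
#' @return A merged mask tibble labelled `"complexity"`.
#' @export
#' @examples
#' ref <- c(chr1 = paste0(strrep("ACGTTGCA", 10), "AAAAAAAA",
#'                        strrep("TTGACGCA", 10)))
#' low_complexity_mask(ref)
low_complexity_mask <- function(reference, flank = 10, min_homopolymer = 7,
                                dust_window = 64, dust_step = 32,
                                dust_threshold = 2, repeat_bed = NULL) {
  seqs <- as_reference(reference)
  pieces <- list()
  for (sn in names(seqs)) {
    s <- seqs[[sn]]
    n <- nchar(s)
    # homopolymer runs
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_homopolymer & r$values %in% c("A", "C", "G", "T")
    if (any(keep)) {
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        seqnames = sn,
        start = (ends - r$lengths)[keep],
        end = ends[keep],
        label = "homopolymer")
    }
    # DUST windows
    if (n >= dust_window) {
      starts <- unique(c(seq(1L, n - dust_window + 1L, by = dust_step),
                         n - dust_window + 1L))
      flagged <- starts[vapply(starts, function(st) {
        dust_score(substr(s, st, st + dust_window - 1L)) > dust_threshold
      }, logical(1))]
      if (length(flagged)) {
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          seqnames = sn, start = flagged - 1L,
          end = flagged - 1L + dust_window, label = "dust")
      }
    }
  }
  if (!is.null(repeat_bed)) {
    if (is.character(repeat_bed)) repeat_bed <- read_bed(repeat_bed)
    repeat_bed$label <- "repeat"
    pieces[[length(pieces) + 1L]] <- repeat_bed
  }
  if (length(pieces) == 0L) return(empty_mask("complexity"))
  core <- dplyr::bind_rows(pieces)
  core$start <- pmax(core$start - as.integer(flank), 0L)
  lens <- setNames(nchar(seqs), names(seqs))
  core$end <- pmin(core$end + as.integer(flank),
                   unname(lens[core$seqnames]))
  merged <- merge_masks(core)
  merged$label <- "complexity"
  merged
}

# DUST complexity score of one window: triplet-count clustering statistic
dust_score <- function(window) {
  n <- nchar(window)
  if (n < 4L) return(0)
  tri <- stringi::stri_sub(window, 1:(n - 2L), length = 3L)
  tri <- tri[!stringi::stri_detect_fixed(tri, "N")]
  k <- length(tri)
  if (k < 2L) return(0)
  cts <- table(tri)
  sum(cts * (cts - 1) / 2) / (k - 1)
}

#' Merge genome masks into a canonical sorted-disjoint mask
#'
#' Set union of any number of interval masks; overlapping and adjacent
#' intervals are collapsed.  Idempotent: `merge_masks(m, m)` equals
#' `merge_masks(m)`.
#'
#' @param ... Mask tibbles (`seqnames`, `start`, `end`, 0-based half-open).
#' @param label Label assigned to the merged intervals.
#' @return A sorted disjoint mask tibble.
#' @export
#' @examples
#' m <- tibble::tibble(seqnames = "chr1", start = c(0L, 5L), end = c(10L, 20L),
#'                     label = NA)
#' merge_masks(m)
merge_masks <- function(..., label = "merged") {
  masks <- dplyr::bind_rows(...)
  if (nrow(masks) == 0L) return(empty_mask(label))
  irl <- mask_to_iranges(masks)
  merged <- lapply(irl, IRanges::reduce)
  out <- iranges_to_mask(merged, label)
  dplyr::arrange(out, .data$seqnames, .data$start)
}

#' Subtract intervals from a mask
#'
#' Set difference: removes from `mask` every base covered by `intervals`.
#'
#' @param mask,intervals Mask tibbles (0-based half-open).
#' @return A sorted disjoint mask tibble with the label of `mask`.
#' @export
subtract_mask <- function(mask, intervals) {
  if (nrow(mask) == 0L) return(mask)
  if (nrow(intervals) == 0L) return(merge_masks(mask, label = mask$label[1]))
  lab <- mask$label[1] %||% "merged"
  all_sn <- unique(mask$seqnames)
  out <- lapply(all_sn, function(sn) {
    a <- mask[mask$seqnames == sn, ]
    b <- intervals[intervals$seqnames == sn, ]
    ia <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    ib <- if (nrow(b)) IRanges::IRanges(b$start + 1L, b$end) else IRanges::IRanges()
    d <- IRanges::setdiff(ia, ib)
    tibble::tibble(seqnames = sn, start = IRanges::start(d) - 1L,
                   end = IRanges::end(d), label = lab)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty_mask(lab) else
    dplyr::arrange(res, .data$seqnames, .data$start)
}

# does each (chrom, pos [1-based], ref) record overlap the mask?
overlaps_mask <- function(chrom, pos, ref_len, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (sn in unique(chrom)) {
    sel <- chrom == sn
    msk <- mask[mask$seqnames == sn, ]
    if (nrow(msk) == 0L) next
    q <- IRanges::IRanges(pos[sel], pos[sel] + ref_len[sel] - 1L)
    s <- IRanges::IRanges(msk$start + 1L, msk$end)
    hit[sel] <- IRanges::countOverlaps(q, s) > 0L
  }
  hit
}
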