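#' Normalize variant records: split multiallelics, left-align, trim
#'
#' Brings a call set to the canonical representation all comparisons key
#' on:
#'
#' 1. multiallelic records (comma-separated `alt`) are split into
#'    biallelic records, with per-sample allele indices re-coded so that
#'    the split-out alternative allele is 1 and every other allele 0;
#' 2. indels are trimmed to their minimal representation and left-aligned
#'    to the smallest equivalent position, extending into the reference
#'    through repeat tracts as needed;
#' 3. records whose `ref` allele does not match the reference sequence at
#'    `pos` are dropped and logged (attribute `"dropped"`).
#'
#' Normalization is idempotent: applying it twice equals applying it once.
#'
#' @param calls Call-set tibble (long form); `pos` is 1-based.
#' @param reference A [sim_reference()], named character vector, or
#'   `DNAStringSet`.
#' @return The normalized call-set tibble, sorted by position, with
#'   dropped-record keys in attribute `"dropped"`.
#' @export
#' @examples
#' ref <- c(chr1 = "GGCACACACATT")
#' calls <- tibble::tibble(chrom = "chr1", pos = 8L, ref = "ACA", alt = "A",
#'                         sample = "s1", a1 = 0L, a2 = 1L)
#' # shifts to the leftmost equivalent representation, pos 2 GCA>G
#' normalize_calls(calls, ref)[, c("pos", "ref", "alt")]
normalize_calls <- function(calls, reference) {
  seqs <- as_reference(reference)
  if (!all(calls$chrom %in% names(seqs))) {
    abort("call set refers to sequences absent from the reference.")
  }
  attr(calls, "dropped") <- NULL # never chain drop logs across passes

  # --- split multiallelic records -------------------------------------
  is_multi <- stringi::stri_detect_fixed(calls$alt, ",")
  out <- calls[!is_multi, , drop = FALSE]
  if (any(is_multi)) {
    multi <- calls[is_multi, , drop = FALSE]
    sites <- dplyr::distinct(multi, .data$chrom, .data$pos, .data$ref, .data$alt)
    split_rows <- lapply(seq_len(nrow(sites)), function(i) {
      st <- sites[i, ]
      alts <- strsplit(st$alt, ",", fixed = TRUE)[[1]]
      rows <- multi[multi$chrom == st$chrom & multi$pos == st$pos &
                      multi$ref == st$ref & multi$alt == st$alt, ]
      dplyr::bind_rows(lapply(seq_along(alts), function(j) {
        r <- rows
        r$alt <- alts[j]
        r$a1 <- ifelse(is.na(rows$a1), NA_integer_,
                       as.integer(rows$a1 == j))
        r$a2 <- ifelse(is.na(rows$a2), NA_integer_,
                       as.integer(rows$a2 == j))
        r
      }))
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(split_rows))
  }

  # --- reference check and left-alignment, per distinct record --------
  sites <- dplyr::distinct(out, .data$chrom, .data$pos, .data$ref, .data$alt)
  norm <- lapply(seq_len(nrow(sites)), function(i) {
    st <- sites[i, ]
    seq <- seqs[[st$chrom]]
    obs <- substr(seq, st$pos, st$pos + nchar(st$ref) - 1L)
    if (!identical(obs, st$ref)) {
      return(NULL) # reference mismatch: drop
    }
    la <- left_align(seq, st$pos, st$ref, st$alt)
    tibble::tibble(chrom = st$chrom, pos = st$pos, ref = st$ref,
                   alt = st$alt, new_pos = la$pos, new_ref = la$ref,
                   new_alt = la$alt)
  })
  dropped <- sites[vapply(norm, is.null, logical(1)),
                   c("chrom", "pos", "ref", "alt")]
  map <- dplyr::bind_rows(norm)

  res <- out |>
    dplyr::inner_join(map, by = c("chrom", "pos", "ref", "alt")) |>
    dplyr::mutate(pos = .data$new_pos, ref = .data$new_ref,
                  alt = .data$new_alt) |>
    dplyr::select(-"new_pos", -"new_ref", -"new_alt") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  attr(res, "dropped") <- dropped
  res
}

# left-align + trim one (pos [1-based], ref, alt) against the sequence
left_align <- function(seq, pos, ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt)) # SNVs are untouched
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  repeat {
    if (nchar(ref) > 0 && nchar(alt) > 0 && last(ref) == last(alt)) {
      if (nchar(ref) > 1L && nchar(alt) > 1L) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      } else if (pos > 1L) {
        base <- substr(seq, pos - 1L, pos - 1L)
        pos <- pos - 1L
        ref <- paste0(base, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(base, substr(alt, 1L, nchar(alt) - 1L))
      } else break
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
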