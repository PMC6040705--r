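# shared builders and independent oracles for the test suite

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal long-form call set builder; gts is a named list sample -> list of
# c(a1, a2) per site (NA allowed)
mk_callset <- function(pos, ref, alt, gts, chrom = "chr1", qual = 100,
                       filter = "PASS", gq = 60L, dp = 30L, sp = 1) {
  n <- length(pos)
  rows <- lapply(names(gts), function(s) {
    g <- gts[[s]]
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   qual = qual, filter = filter, sample = s,
                   a1 = vapply(g, function(x) as.integer(x[1]), integer(1)),
                   a2 = vapply(g, function(x) as.integer(x[2]), integer(1)),
                   gq = gq, dp = dp, sp = sp)
  })
  dplyr::bind_rows(rows)
}

# brute-force Mendel oracle: a trio genotype is consistent iff the child's
# unordered genotype appears among all father-allele x mother-allele children
mendel_violates_oracle <- function(child, father, mother) {
  possible <- list()
  for (fa in father) for (ma in mother) {
    possible[[length(possible) + 1L]] <- sort(c(fa, ma))
  }
  !any(vapply(possible, function(p) identical(p, sort(child)), logical(1)))
}

# brute-force mappability oracle: per-position unique-coverage ratio from
# direct substring counting (forward strand + reverse complement)
mappability_oracle <- function(seq, read_len, min_unique_ratio = 0.5) {
  n <- nchar(seq)
  rc_seq <- stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
  n_win <- n - read_len + 1L
  uniq <- logical(n_win)
  for (s in seq_len(n_win)) {
    w <- substr(seq, s, s + read_len - 1L)
    cnt <- stringi::stri_count_fixed(seq, w, overlap = TRUE) +
      stringi::stri_count_fixed(rc_seq, w, overlap = TRUE)
    uniq[s] <- cnt == 1L
  }
  masked <- logical(n)
  for (p in seq_len(n)) {
    lo <- max(1L, p - read_len + 1L)
    hi <- min(p, n_win)
    masked[p] <- mean(uniq[lo:hi]) < min_unique_ratio
  }
  masked
}

# independent minimal left-aligned representation of a single indel:
# apply the variant, then trim the longest common suffix (leaving one base
# per allele), then the longest common prefix (leaving one base per allele)
normalize_oracle <- function(seq, pos, ref, alt) {
  x <- seq
  y <- paste0(substr(seq, 1, pos - 1L), alt,
              substr(seq, pos + nchar(ref), nchar(seq)))
  nx <- nchar(x); ny <- nchar(y)
  s <- 0L
  while (s < min(nx, ny) - 1L &&
         substr(x, nx - s, nx - s) == substr(y, ny - s, ny - s)) {
    s <- s + 1L
  }
  p <- 0L
  while (p < min(nx, ny) - s - 1L &&
         substr(x, p + 1L, p + 1L) == substr(y, p + 1L, p + 1L)) {
    p <- p + 1L
  }
  list(pos = p + 1L,
       ref = substr(x, p + 1L, nx - s),
       alt = substr(y, p + 1L, ny - s))
}

# read the bundled published worked-example genotype table as a call set
# (allele coding in the table: 1 = reference allele, 2 = insertion allele)
published_cohort_callset <- function() {
  tab <- readr::read_tsv(
    system.file("extdata", "aih_cohort_genotypes.tsv",
                package = "wgsbakeoff"),
    col_types = readr::cols(.default = readr::col_character()))
  al <- stringi::stri_split_fixed(tab$ftcd_gt, "/")
  calls <- tibble::tibble(
    chrom = "chr21", pos = 1000L, ref = "G", alt = "GC",
    qual = 500, filter = "PASS", sample = tab$sample,
    a1 = vapply(al, function(x) as.integer(x[1]) - 1L, integer(1)),
    a2 = vapply(al, function(x) as.integer(x[2]) - 1L, integer(1)),
    gq = 60L, dp = 30L, sp = 1)
  list(calls = calls, table = tab)
}
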