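#' Read and write the plain-text formats used by the pipeline
#'
#' Thin wrappers around Biostrings and readr for the formats the pipeline
#' consumes and produces: FASTA references, (gzipped) paired FASTQ, BED
#' interval masks, and TSV tables (QC metrics, cohort designs, variant
#' annotations, HLA typings).  VCF is handled by
#' [write_callset_vcf()] / [read_callset_vcf()].
#'
#' @param reference,pairs,mask,x Objects to write (see the individual
#'   functions).
#' @param path,r1_path,r2_path File paths; FASTQ paths ending in `.gz`
#'   are compressed.
#' @name bakeoff-io
NULL

#' @rdname bakeoff-io
#' @export
write_fasta <- function(reference, path) {
  seqs <- as_reference(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname bakeoff-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname bakeoff-io
#' @export
write_fastq <- function(pairs, r1_path, r2_path) {
  write_one <- function(ids, seqs, quals, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  write_one(pairs$pair_id, pairs$read1, pairs$qual1, r1_path)
  write_one(pairs$pair_id, pairs$read2, pairs$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' @rdname bakeoff-io
#' @export
read_fastq <- function(r1_path, r2_path) {
  read_one <- function(path) {
    lines <- readLines(path)
    list(id = sub("^@", "", lines[seq(1, length(lines), by = 4)]),
         seq = lines[seq(2, length(lines), by = 4)],
         qual = lines[seq(4, length(lines), by = 4)])
  }
  r1 <- read_one(r1_path)
  r2 <- read_one(r2_path)
  tibble::tibble(pair_id = sub("\\s.*$", "", r1$id),
                 read1 = r1$seq, qual1 = r1$qual,
                 read2 = r2$seq, qual2 = r2$qual)
}

#' @rdname bakeoff-io
#' @export
write_bed <- function(mask, path) {
  readr::write_tsv(mask[, c("seqnames", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname bakeoff-io
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("seqnames", "start", "end"),
                       col_types = "cii", comment = "#")
  x$label <- "bed"
  tibble::as_tibble(x)
}

#' Write / read a call set as VCF
#'
#' `write_callset_vcf()` serializes a long call-set tibble as a minimal
#' VCF v4.2 file with `GT:GQ:DP:SP` FORMAT fields; `read_callset_vcf()`
#' parses one back into the long tibble (using the vcfR package).
#'
#' @param calls Long call-set tibble.
#' @param path File path.
#' @return `write_callset_vcf()` the path, invisibly;
#'   `read_callset_vcf()` a long call-set tibble.
#' @export
write_callset_vcf <- function(calls, path) {
  samples <- unique(calls$sample)
  sites <- calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$qual, .data$filter) |>
    dplyr::arrange(.data$chrom, .data$pos)
  gt_tab <- calls |>
    dplyr::mutate(fmt = paste(gt_string(.data$a1, .data$a2), .data$gq,
                              .data$dp, .data$sp, sep = ":")) |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample", "fmt") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fmt")
  tab <- dplyr::left_join(sites, gt_tab,
                          by = c("chrom", "pos", "ref", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=SP,Number=1,Type=Float,Description=\"Strand bias P-value\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- apply(tab, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]],
            r[["qual"]], r[["filter"]], ".", "GT:GQ:DP:SP",
            unname(r[samples])), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_callset_vcf
#' @export
read_callset_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_callset_vcf() needs the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  sp <- vcfR::extract.gt(v, element = "SP", as.numeric = TRUE)
  samples <- colnames(gt)
  long <- dplyr::bind_rows(lapply(samples, function(s) {
    al <- stringi::stri_split_regex(gt[, s], "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(al, `[`, character(1), 1)))
    a2 <- suppressWarnings(as.integer(vapply(al, function(x)
      if (length(x) > 1) x[2] else NA_character_, character(1))))
    tibble::tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   qual = as.numeric(fix$QUAL), filter = fix$FILTER,
                   sample = s, a1 = a1, a2 = a2,
                   gq = as.integer(gq[, s]), dp = as.integer(dp[, s]),
                   sp = as.numeric(sp[, s]))
  }))
  dplyr::arrange(long, .data$chrom, .data$pos)
}
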