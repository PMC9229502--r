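#' Strip version suffixes from Ensembl-style identifiers
#'
#' GTF and proteome-derived files disagree on whether identifiers carry a
#' trailing ".N" version. Attachment of protein features to transcripts uses
#' normalized identifiers; the default normalizer removes one trailing
#' ".<digits>".
#'
#' @param x character vector of identifiers.
#' @return character vector with version suffixes removed.
#' @export
#' @examples
#' normalize_id(c("ENSP00000386175.2", "P000001"))
normalize_id <- function(x) {
  sub("\\.[0-9]+$", "", x)
}

## Strip a leading "chr" so that region lists and annotation built on
## different chromosome-naming dialects still compare.
norm_chrom <- function(x) {
  sub("^chr", "", x)
}

## Write a table atomically: temp file in the same directory, then rename.
write_tsv_atomic <- function(dt, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  data.table::fwrite(dt, tmp, sep = "\t", quote = FALSE, na = "NA")
  file.rename(tmp, path)
  invisible(path)
}

write_lines_atomic <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

## 0-based half-open intervals -> IRanges (1-based closed) and back.
to_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

to_granges <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(seqnames = chrom, ranges = to_iranges(start0, end0),
                         strand = strand)
}

## Benjamini-Hochberg wrapper kept in one place so every module adjusts the
## same way (NA p-values are excluded from the family and returned as NA).
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

## 2x2 chi-square used throughout (Yates continuity correction by default,
## matching the common default of the stack used for the original analyses).
chisq_2x2 <- function(a, b, c, d, correct = TRUE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, low_expected = TRUE))
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(res$statistic), p = res$p.value,
       low_expected = any(res$expected < 5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
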