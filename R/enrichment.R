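## Per-feature enrichment between two genomic-region lists.
##
## Regions from a "target" list (e.g. differentially spliced events) and a
## "background" list (control events) are intersected with the projected
## feature spans of the store. For each signature accession a 2x2 table of
## regions-with vs regions-without the accession, per list, is tested by
## chi-square (Yates continuity correction by default) and adjusted across
## accessions with Benjamini-Hochberg. The fold change is the target-list
## frequency over the pooled target+background frequency, which never
## divides by zero.

#' Read a BED file into a region table
#'
#' BED is native to the internal convention (0-based half-open). Requires
#' at least 3 columns; a 4th column is kept as the region name; a strand
#' column, if present, is ignored for overlap.
#'
#' @param path path to a BED file.
#' @return data.table with `chrom`, `start`, `end`, `name`, `region_idx`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  if (!length(lineno))
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      region_idx = integer()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3L)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": fewer than 3 columns",
         call. = FALSE)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]],
         ": start/end not a valid half-open interval", call. = FALSE)
  data.table(
    chrom = vapply(parts, `[`, "", 1L),
    start = start, end = end,
    name = ifelse(n_fields >= 4L,
                  vapply(parts, function(p) if (length(p) >= 4L) p[4L]
                         else "", ""), ""),
    region_idx = seq_along(parts))
}

#' Annotate regions with overlapping protein features
#'
#' One output row per (region, feature instance) whose span overlaps the
#' region by at least 1 nt; regions without any overlap appear once with
#' empty feature fields. Chromosome names are compared after stripping a
#' "chr" prefix on either side.
#'
#' @param store an `AnnotationStore`.
#' @param regions data.table from [read_bed()] (or with the same columns).
#' @param tools member databases to keep (`NULL` = all).
#' @return data.table of overlaps.
#' @export
annotate_regions <- function(store, regions, tools = NULL) {
  regions <- as.data.table(regions)
  if (!"region_idx" %in% names(regions))
    regions[, region_idx := .I]
  f <- store$features
  if (!is.null(tools)) f <- f[f$tool %in% tools]
  base <- regions[, .(region_idx, chrom, start, end, name)]
  if (nrow(regions) == 0L) {
    out <- base[, `:=`(feature_uid = character(0), tool = character(0),
                       signature_acc = character(0),
                       interpro_acc = character(0), gene_id = character(0),
                       transcript_id = character(0),
                       span_start = integer(0), span_end = integer(0))]
    return(out[])
  }
  if (nrow(f) == 0L) {
    out <- copy(base)[, `:=`(feature_uid = NA_character_,
                             tool = NA_character_,
                             signature_acc = NA_character_,
                             interpro_acc = NA_character_,
                             gene_id = NA_character_,
                             transcript_id = NA_character_,
                             span_start = NA_integer_,
                             span_end = NA_integer_)]
    return(out[])
  }
  q <- to_granges(norm_chrom(regions$chrom), regions$start, regions$end)
  s <- to_granges(norm_chrom(f$chrom), f$span_start, f$span_end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s,
                                                       minoverlap = 1L))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- cbind(base[qh],
                f[sh, .(feature_uid, tool, signature_acc, interpro_acc,
                        gene_id, transcript_id, span_start, span_end)])
  nohit <- setdiff(seq_len(nrow(regions)), unique(qh))
  if (length(nohit)) {
    blank <- copy(base[nohit])[, `:=`(feature_uid = NA_character_,
                                      tool = NA_character_,
                                      signature_acc = NA_character_,
                                      interpro_acc = NA_character_,
                                      gene_id = NA_character_,
                                      transcript_id = NA_character_,
                                      span_start = NA_integer_,
                                      span_end = NA_integer_)]
    rows <- rbind(rows, blank)
  }
  setorder(rows, region_idx, span_start, na.last = TRUE)
  rows[]
}

#' Count distinct regions overlapped per feature accession
#'
#' A region counts at most once per accession even if it overlaps several
#' instances of it.
#'
#' @param annotated output of [annotate_regions()].
#' @param mode `"distinct"` (default) counts distinct regions;
#'   `"raw"` counts (region, instance) overlap rows.
#' @return data.table of (tool, signature_acc, interpro_acc, count).
#' @export
feature_region_counts <- function(annotated, mode = c("distinct", "raw")) {
  mode <- match.arg(mode)
  a <- annotated[!is.na(annotated$signature_acc)]
  if (nrow(a) == 0L)
    return(data.table(tool = character(), signature_acc = character(),
                      interpro_acc = character(), count = integer()))
  a[, .(interpro_acc = {
    v <- interpro_acc[nzchar(interpro_acc)]
    if (length(v)) v[1L] else ""
  },
  count = if (mode == "distinct") uniqueN(region_idx) else .N),
  by = .(tool, signature_acc)]
}

#' Fold change of enrichment
#'
#' Target-list frequency over the pooled target+background frequency:
#' `FC = (c_t/n_t) / ((c_t+c_b)/(n_t+n_b))`. Finite whenever
#' `c_t + c_b >= 1`.
#'
#' @param c_t,c_b counts of target/background regions with the feature.
#' @param n_t,n_b total region counts per list.
#' @return numeric fold change (vectorized).
#' @export
fold_change <- function(c_t, n_t, c_b, n_b) {
  stopifnot(all(n_t >= 1), all(n_b >= 1), all(c_t + c_b >= 1))
  (c_t / n_t) / ((c_t + c_b) / (n_t + n_b))
}

#' Test per-accession feature enrichment of target vs background regions
#'
#' @param store an `AnnotationStore`.
#' @param target,background region tables ([read_bed()] output).
#' @param tools member databases to keep (`NULL` = all).
#' @param correct apply Yates continuity correction (default TRUE).
#' @param count_mode `"distinct"` or `"raw"`, see
#'   [feature_region_counts()].
#' @return data.table of enrichment rows sorted by q then descending fold
#'   change, with attribute `summary` (n_t, n_b, accession count, top <= 5
#'   rows). Rows where any expected count is below 5 are flagged
#'   `low_expected`.
#' @export
enrich <- function(store, target, background, tools = NULL, correct = TRUE,
                   count_mode = "distinct") {
  n_t <- nrow(target); n_b <- nrow(background)
  if (n_t == 0L || n_b == 0L)
    stop("target and background lists must both be non-empty",
         call. = FALSE)
  ann_t <- annotate_regions(store, target, tools = tools)
  ann_b <- annotate_regions(store, background, tools = tools)
  ct <- feature_region_counts(ann_t, mode = count_mode)
  cb <- feature_region_counts(ann_b, mode = count_mode)
  rows <- merge(ct, cb, by = c("tool", "signature_acc"), all = TRUE,
                suffixes = c("_t", "_b"))
  if (nrow(rows) == 0L) {
    out <- data.table(tool = character(), signature_acc = character(),
                      interpro_acc = character(), c_t = integer(),
                      c_b = integer(), n_t = integer(), n_b = integer(),
                      chi2 = numeric(), p = numeric(), q = numeric(),
                      fold_change = numeric(), low_expected = logical())
    attr(out, "summary") <- list(n_t = n_t, n_b = n_b, n_accessions = 0L,
                                 top = out)
    return(out)
  }
  rows[is.na(count_t), count_t := 0L]
  rows[is.na(count_b), count_b := 0L]
  rows[, interpro_acc := fifelse(!is.na(interpro_acc_t), interpro_acc_t,
                                 fifelse(!is.na(interpro_acc_b),
                                         interpro_acc_b, ""))]
  rows <- rows[count_t + count_b >= 1L]
  tests <- lapply(seq_len(nrow(rows)), function(i)
    chisq_2x2(rows$count_t[i], n_t - rows$count_t[i],
              rows$count_b[i], n_b - rows$count_b[i], correct = correct))
  out <- rows[, .(tool, signature_acc, interpro_acc, c_t = count_t,
                  c_b = count_b, n_t = n_t, n_b = n_b)]
  out[, `:=`(chi2 = vapply(tests, `[[`, 0, "chi2"),
             p = vapply(tests, `[[`, 0, "p"),
             low_expected = vapply(tests, `[[`, TRUE, "low_expected"))]
  out[, q := bh_adjust(p)]
  out[, fold_change := fold_change(c_t, n_t, c_b, n_b)]
  setorder(out, q, -fold_change, signature_acc, na.last = TRUE)
  setcolorder(out, c("tool", "signature_acc", "interpro_acc", "c_t", "c_b",
                     "n_t", "n_b", "chi2", "p", "q", "fold_change",
                     "low_expected"))
  attr(out, "summary") <- list(n_t = n_t, n_b = n_b,
                               n_accessions = nrow(out),
                               top = head(out, 5L))
  out[]
}
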