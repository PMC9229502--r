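## GO-slim scan: per term, are the domains of its member genes more often
## alternative than the genomic average?

#' Read a GO term membership table
#'
#' Tab-separated rows of (term_id, term_name, gene_id); duplicate
#' (term, gene) rows collapse to one membership; malformed rows (missing
#' fields) are skipped with a warning.
#'
#' @param path path to the TSV (no header, or a header starting with
#'   "term").
#' @return data.table with one row per (term_id, term_name, gene_id).
#' @export
read_go_sets <- function(path) {
  if (!file.exists(path)) stop("GO file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = "character")
  if (nrow(dt) == 0L)
    return(data.table(term_id = character(), term_name = character(),
                      gene_id = character()))
  if (ncol(dt) < 3L) stop("GO table needs 3 columns", call. = FALSE)
  if (grepl("^term", dt[[1L]][1L], ignore.case = TRUE)) dt <- dt[-1L]
  out <- data.table(term_id = dt[[1L]], term_name = dt[[2L]],
                    gene_id = dt[[3L]])
  bad <- !nzchar(out$term_id) | !nzchar(out$gene_id) | is.na(out$gene_id)
  if (any(bad)) {
    warning(sum(bad), " malformed GO row(s) skipped", call. = FALSE)
    out <- out[!bad]
  }
  unique(out, by = c("term_id", "gene_id"))
}

#' Scan GO terms for excess alternative domains
#'
#' (gene, accession) units are tallied as alternative/constitutive per term
#' and compared against the genome-wide tallies by chi-square (Yates
#' correction), with Benjamini-Hochberg adjustment across terms. Terms
#' whose genes carry no classified domain are excluded from the BH family
#' (p and q are `NA`).
#'
#' @param go_sets data.table from [read_go_sets()].
#' @param status_table classification table (e.g. from
#'   [classify_all_genes()]).
#' @param std standard kind to filter on; the headline analyses use
#'   `"overlap_cds"`. `NULL` uses the table as given.
#' @param mode `"genome"` (default) compares each term against the overall
#'   genomic tallies (term included); `"complement"` compares against all
#'   units outside the term.
#' @return data.table of term rows sorted by alternative fraction
#'   descending, with attribute `genome` holding the genome-wide tallies.
#' @export
go_alternative_scan <- function(go_sets, status_table, std = NULL,
                                mode = c("genome", "complement")) {
  mode <- match.arg(mode)
  units <- domain_units(status_table, std = std)
  A <- sum(units$status == "alternative")
  C <- sum(units$status == "constitutive")
  terms <- unique(as.data.table(go_sets)[, .(term_id, term_name)])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- go_sets$gene_id[go_sets$term_id == terms$term_id[i]]
    u <- units[units$gene_id %in% genes]
    a <- sum(u$status == "alternative")
    c0 <- sum(u$status == "constitutive")
    if (a + c0 == 0L)
      return(data.table(term_id = terms$term_id[i],
                        term_name = terms$term_name[i],
                        n_domains = 0L, n_alternative = 0L,
                        fraction = NA_real_, chi2 = NA_real_,
                        p = NA_real_))
    ref <- if (mode == "genome") c(A, C) else c(A - a, C - c0)
    ts <- chisq_2x2(a, c0, ref[1L], ref[2L])
    data.table(term_id = terms$term_id[i], term_name = terms$term_name[i],
               n_domains = a + c0, n_alternative = a,
               fraction = a / (a + c0), chi2 = ts$chi2, p = ts$p)
  })
  out <- rbindlist(rows)
  out[, q := bh_adjust(p)]
  setorder(out, -fraction, term_id, na.last = TRUE)
  attr(out, "genome") <- list(n_alternative = A, n_constitutive = C,
                              fraction = if (A + C) A / (A + C) else
                                NA_real_)
  out[]
}
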