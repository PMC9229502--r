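## Reciprocal-best-hit homology from BioMart-style identity tables, and
## cross-species comparison of alternative/constitutive domain status.

#' Read a BioMart-style ortholog-candidate identity table
#'
#' Expects tab-separated columns: query gene, target gene, percent identity
#' of the query (an optional fourth percent-identity-of-target column is
#' kept if present). A header row is detected and skipped.
#'
#' @param path path to the TSV.
#' @return data.table with `query_gene`, `target_gene`, `pct_identity`.
#' @export
read_identity_tsv <- function(path) {
  if (!file.exists(path))
    stop("identity table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 3L)
    stop("identity table needs at least 3 columns", call. = FALSE)
  out <- data.table(query_gene = as.character(dt[[1L]]),
                    target_gene = as.character(dt[[2L]]),
                    pct_identity = as.numeric(dt[[3L]]))
  out[!is.na(pct_identity)]
}

#' Best hit per query gene
#'
#' For each query the target with the highest query identity wins; ties are
#' broken by the lexicographically smallest target id so the result is
#' deterministic.
#'
#' @param rows data.table from [read_identity_tsv()].
#' @return data.table with one row per query: `query_gene`, `target_gene`,
#'   `pct_identity`.
#' @export
best_hits <- function(rows) {
  r <- as.data.table(rows)
  if (nrow(r) == 0L) return(r[, .(query_gene, target_gene, pct_identity)])
  setorder(r, query_gene, -pct_identity, target_gene)
  r[, .SD[1L], by = query_gene,
    .SDcols = c("target_gene", "pct_identity")]
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is kept iff b is a's best hit and a is b's best hit.
#'
#' @param bh_ab best hits of species A queries against species B.
#' @param bh_ba best hits of species B queries against species A.
#' @return data.table of `gene_a`, `gene_b` sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(bh_ab, bh_ba) {
  ab <- as.data.table(bh_ab)[, .(gene_a = query_gene, gene_b = target_gene)]
  ba <- as.data.table(bh_ba)[, .(gene_b = query_gene, gene_a = target_gene)]
  pairs <- merge(ab, ba, by = c("gene_a", "gene_b"))
  setorder(pairs, gene_a)
  pairs[]
}

## Collapse a classification table to one row per (gene, accession): the
## unit is alternative when ANY group of that accession in the gene is
## alternative (one alternative instance suffices to alter the protein).
domain_units <- function(status_table, std = NULL, tools = NULL) {
  s <- as.data.table(status_table)
  if (!is.null(std)) s <- s[s$standard == std]
  if (!is.null(tools)) s <- s[s$tool %in% tools]
  if (nrow(s) == 0L)
    return(data.table(gene_id = character(), signature_acc = character(),
                      status = character()))
  s[, .(status = if (any(status == "alternative")) "alternative" else
    "constitutive"), by = .(gene_id, signature_acc)]
}

#' Compare domain status between homologous gene pairs
#'
#' The unit of counting is (gene pair, signature accession). A unit is
#' "common" when the accession is classified in both genes of a pair,
#' species-specific when classified in exactly one. For common units a 2x2
#' of status-in-A x status-in-B is tallied; species-specific units are
#' tallied by status. A chi-square compares the alternative fraction of
#' species-specific vs common units, per species.
#'
#' @param pairs data.table from [reciprocal_best_hits()].
#' @param status_a,status_b classification tables (from
#'   [classify_all_genes()] or read back from TSV), already restricted to
#'   one standard or restricted here via `std`.
#' @param std standard kind to filter on (e.g. `"overlap_cds"`); `NULL`
#'   uses the tables as given.
#' @return a `ConservationSummary`: list with `common` (2x2 matrix,
#'   rows = status in A, cols = status in B), `a_specific`, `b_specific`
#'   (named counts), `n_units`, `skipped_pairs`, and `tests` (per-species
#'   chi-square of specific vs common alternative fractions).
#' @export
compare_domain_status <- function(pairs, status_a, status_b, std = NULL) {
  ua <- domain_units(status_a, std = std)
  ub <- domain_units(status_b, std = std)
  genes_a <- unique(ua$gene_id); genes_b <- unique(ub$gene_id)
  lv <- c("alternative", "constitutive")
  common <- matrix(0L, 2, 2, dimnames = list(A = lv, B = lv))
  a_spec <- c(alternative = 0L, constitutive = 0L)
  b_spec <- c(alternative = 0L, constitutive = 0L)
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% genes_a) || !(gb %in% genes_b)) { skipped <- skipped + 1L
      next }
    da <- ua[ua$gene_id == ga]; db <- ub[ub$gene_id == gb]
    sa <- setNames(da$status, da$signature_acc)
    sb <- setNames(db$status, db$signature_acc)
    shared <- intersect(names(sa), names(sb))
    for (acc in shared) common[sa[[acc]], sb[[acc]]] <-
        common[sa[[acc]], sb[[acc]]] + 1L
    for (acc in setdiff(names(sa), shared)) a_spec[[sa[[acc]]]] <-
        a_spec[[sa[[acc]]]] + 1L
    for (acc in setdiff(names(sb), shared)) b_spec[[sb[[acc]]]] <-
        b_spec[[sb[[acc]]]] + 1L
  }
  ## alternative fraction: species-specific vs common (status in that
  ## species for the common side)
  common_a <- c(alternative = sum(common["alternative", ]),
                constitutive = sum(common["constitutive", ]))
  common_b <- c(alternative = sum(common[, "alternative"]),
                constitutive = sum(common[, "constitutive"]))
  tests <- list(
    a = chisq_2x2(a_spec[["alternative"]], a_spec[["constitutive"]],
                  common_a[["alternative"]], common_a[["constitutive"]]),
    b = chisq_2x2(b_spec[["alternative"]], b_spec[["constitutive"]],
                  common_b[["alternative"]], common_b[["constitutive"]]))
  structure(list(common = common, a_specific = a_spec,
                 b_specific = b_spec,
                 n_units = sum(common) + sum(a_spec) + sum(b_spec),
                 skipped_pairs = skipped, tests = tests),
            class = "ConservationSummary")
}

#' @export
print.ConservationSummary <- function(x, ...) {
  cat("ConservationSummary:", sum(x$common), "common units,",
      sum(x$a_specific), "A-specific,", sum(x$b_specific),
      "B-specific (", x$skipped_pairs, "pairs skipped )\n")
  print(x$common)
  invisible(x)
}

#' Per-accession splicing potential and its cross-species correlation
#'
#' For every accession the fraction of alternative (gene, accession) units
#' per species is computed; accessions observed fewer than `min_count`
#' times in either species are excluded; Pearson and Spearman correlations
#' are reported over the retained accessions.
#'
#' @param status_a,status_b classification tables.
#' @param min_count minimum units per species (default 50).
#' @param std standard kind to filter on, or `NULL`.
#' @return list with `table` (accession, n/fraction per species) and
#'   `pearson`, `spearman` (`estimate`, `p`; `NA` when fewer than 3
#'   accessions are retained).
#' @export
splicing_potential <- function(status_a, status_b, min_count = 50,
                               std = NULL) {
  stopifnot(min_count >= 1)
  frac <- function(units) units[, .(n = .N,
                                    frac_alt = mean(status == "alternative")),
                                by = signature_acc]
  fa <- frac(domain_units(status_a, std = std))
  fb <- frac(domain_units(status_b, std = std))
  tab <- merge(fa, fb, by = "signature_acc", suffixes = c("_a", "_b"))
  tab <- tab[n_a >= min_count & n_b >= min_count]
  setorder(tab, signature_acc)
  if (nrow(tab) < 3L) {
    cor_na <- list(estimate = NA_real_, p = NA_real_)
    return(list(table = tab, pearson = cor_na, spearman = cor_na,
                n_retained = nrow(tab)))
  }
  pe <- stats::cor.test(tab$frac_alt_a, tab$frac_alt_b, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(tab$frac_alt_a, tab$frac_alt_b, method = "spearman",
                    exact = FALSE))
  list(table = tab,
       pearson = list(estimate = unname(pe$estimate), p = pe$p.value),
       spearman = list(estimate = unname(sp$estimate), p = sp$p.value),
       n_retained = nrow(tab))
}
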