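## Classification of protein-feature groups as alternative or constitutive.
##
## Feature instances of the same tool and signature accession whose genomic
## spans (hull of projected blocks, introns included) overlap by at least
## one nucleotide are "common" across transcripts; groups are the connected
## components of that overlap relation. Each group is then classified under
## one of three candidate-transcript standards:
##   coding      - all coding transcripts of the gene
##   cds_ratio   - coding transcripts whose CDS length is at least a
##                 threshold fraction of the gene's longest CDS (the
##                 longest-CDS "major isoform" always qualifies)
##   overlap_cds - coding transcripts whose CDS genomic span (first CDS
##                 base to last, introns included) fully contains the
##                 group's span; candidates vary per feature
## A group is constitutive when every candidate transcript carries a member
## instance, otherwise alternative. Non-coding transcripts never count:
## including them would make every feature alternative.

#' Construct a classification standard
#'
#' @param kind one of `"coding"`, `"cds_ratio"`, `"overlap_cds"`.
#' @param threshold CDS length-ratio cutoff in `[0, 1]`; required for (and
#'   only for) `cds_ratio`.
#' @return a `Standard` object.
#' @export
standard <- function(kind = c("coding", "cds_ratio", "overlap_cds"),
                     threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "cds_ratio") {
    if (is.null(threshold) || threshold < 0 || threshold > 1)
      stop("cds_ratio standard needs a threshold in [0, 1]", call. = FALSE)
  } else if (!is.null(threshold)) {
    stop("threshold only applies to the cds_ratio standard", call. = FALSE)
  }
  structure(list(kind = kind, threshold = threshold), class = "Standard")
}

#' @export
format.Standard <- function(x, ...) {
  if (x$kind == "cds_ratio") sprintf("cds_ratio(%g)", x$threshold) else x$kind
}

#' @export
print.Standard <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

default_standards <- function(threshold = 0.5) {
  list(standard("coding"), standard("cds_ratio", threshold),
       standard("overlap_cds"))
}

#' Group common feature instances within a gene
#'
#' Two instances are directly common iff they share the tool and signature
#' accession and their spans overlap by at least 1 nt; groups are the
#' connected components of this relation (transitive merge).
#'
#' @param gene_features data.table of projected feature rows (one gene).
#' @return the same rows with `group_id` added, plus attribute `groups`:
#'   one row per group with its span hull.
#' @export
group_common_features <- function(gene_features) {
  f <- as.data.table(gene_features)
  if (nrow(f) == 0L) {
    out <- copy(f)[, group_id := character(0)]
    attr(out, "groups") <- data.table(group_id = character(),
                                      tool = character(),
                                      signature_acc = character(),
                                      hull_start = integer(),
                                      hull_end = integer())
    return(out)
  }
  f <- copy(f)
  f[, group_id := NA_character_]
  grp_rows <- list()
  for (key in unique(paste(f$tool, f$signature_acc, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    idx <- which(f$tool == parts[1L] & f$signature_acc == parts[2L])
    ir <- to_iranges(f$span_start[idx], f$span_end[idx])
    ## connected components of interval overlap = membership in the
    ## overlap-only reduction (min.gapwidth = 0 keeps abutting spans apart)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    gid <- sprintf("%s:%s:%s:g%d", f$gene_id[idx[1L]], parts[1L],
                   parts[2L], comp)
    f$group_id[idx] <- gid
    grp_rows[[key]] <- data.table(
      group_id = sprintf("%s:%s:%s:g%d", f$gene_id[idx[1L]], parts[1L],
                         parts[2L], seq_along(red)),
      tool = parts[1L], signature_acc = parts[2L],
      hull_start = IRanges::start(red) - 1L,
      hull_end = IRanges::end(red))
  }
  attr(f, "groups") <- rbindlist(grp_rows)
  f
}

#' Candidate transcripts of a gene under a standard
#'
#' @param store an `AnnotationStore`.
#' @param gene_id gene identifier.
#' @param std a [standard()] object.
#' @param group_hull numeric length-2 `c(start, end)` (0-based half-open);
#'   required for the `overlap_cds` standard.
#' @param inclusive for `cds_ratio`, whether the comparison is
#'   `ratio >= threshold` (default) or strict `>`.
#' @return character vector of transcript ids (empty when the gene has no
#'   coding transcript).
#' @export
candidate_transcripts <- function(store, gene_id, std, group_hull = NULL,
                                  inclusive = TRUE) {
  gid <- gene_id  # distinct symbol: data.table i-expressions see columns first
  tx <- store$transcripts[store$transcripts$gene_id == gid]
  tx <- tx[tx$is_coding]
  if (nrow(tx) == 0L) return(character(0))
  switch(std$kind,
    coding = tx$transcript_id,
    cds_ratio = {
      ratio <- tx$cds_length / max(tx$cds_length)
      keep <- if (inclusive) ratio >= std$threshold else
        ratio > std$threshold
      ## the longest-CDS major isoform(s) always qualify
      keep <- keep | ratio == 1
      tx$transcript_id[keep]
    },
    overlap_cds = {
      if (is.null(group_hull))
        stop("overlap_cds candidates require the feature group hull",
             call. = FALSE)
      tx$transcript_id[tx$cds_span_start <= group_hull[1L] &
                         tx$cds_span_end >= group_hull[2L]]
    })
}

#' Classify every feature group of a gene under a set of standards
#'
#' One record per (group x standard). A group is constitutive iff every
#' candidate transcript carries a member instance. Under `overlap_cds`,
#' members are counted among candidates only (a member whose transcript's
#' CDS span does not contain the group hull does not count as present).
#' Groups whose candidate set is empty are omitted and reported via the
#' `omitted` attribute.
#'
#' @param store an `AnnotationStore`.
#' @param gene_id gene identifier (must exist in the store).
#' @param standards list of [standard()] objects; default all three with
#'   ratio threshold 0.5.
#' @param tools member databases to keep (`NULL` = all).
#' @return data.table with columns gene_id, tool, signature_acc,
#'   interpro_acc, group_id, hull_start, hull_end, standard, threshold,
#'   n_candidates, n_present, status.
#' @export
classify_gene <- function(store, gene_id, standards = default_standards(),
                          tools = NULL) {
  if (!gene_id %in% store$genes$gene_id)
    stop("unknown gene: ", gene_id, call. = FALSE)
  gid <- gene_id
  f <- store$features[store$features$gene_id == gid]
  if (!is.null(tools)) f <- f[f$tool %in% tools]
  empty <- data.table(gene_id = character(), tool = character(),
                      signature_acc = character(),
                      interpro_acc = character(), group_id = character(),
                      hull_start = integer(), hull_end = integer(),
                      standard = character(), threshold = numeric(),
                      n_candidates = integer(), n_present = integer(),
                      status = character())
  if (nrow(f) == 0L) return(empty)
  grouped <- group_common_features(f)
  groups <- attr(grouped, "groups")
  members <- grouped[, .(tx = list(unique(transcript_id)),
                         ipr = {
                           v <- interpro_acc[nzchar(interpro_acc)]
                           if (length(v)) v[1L] else ""
                         }),
                     by = group_id]
  groups <- merge(groups, members, by = "group_id", sort = FALSE)

  out <- list(); omitted <- character(0)
  for (i in seq_len(nrow(groups))) {
    g <- groups[i]
    mem <- g$tx[[1L]]
    for (std in standards) {
      cand <- candidate_transcripts(store, gene_id, std,
                                    group_hull = c(g$hull_start, g$hull_end))
      if (length(cand) == 0L) {
        omitted <- c(omitted, paste0(g$group_id, "/", format(std)))
        next
      }
      n_present <- length(intersect(cand, mem))
      out[[length(out) + 1L]] <- data.table(
        gene_id = gene_id, tool = g$tool, signature_acc = g$signature_acc,
        interpro_acc = g$ipr, group_id = g$group_id,
        hull_start = g$hull_start, hull_end = g$hull_end,
        standard = std$kind,
        threshold = if (is.null(std$threshold)) NA_real_ else std$threshold,
        n_candidates = length(cand), n_present = n_present,
        status = if (n_present == length(cand)) "constitutive" else
          "alternative")
    }
  }
  res <- if (length(out)) rbindlist(out) else empty
  setorder(res, tool, signature_acc, group_id, standard)
  attr(res, "omitted") <- omitted
  res
}

#' Classify all genes of a store into a domain status table
#'
#' @inheritParams classify_gene
#' @return data.table of classification records for every gene that has at
#'   least one projected feature.
#' @export
classify_all_genes <- function(store, standards = default_standards(),
                               tools = NULL) {
  genes <- unique(store$features$gene_id)
  if (!is.null(tools))
    genes <- unique(store$features[store$features$tool %in% tools]$gene_id)
  rbindlist(lapply(sort(genes), function(g)
    classify_gene(store, g, standards = standards, tools = tools)))
}

#' Annotate a single gene: feature table, classification table, diagram
#'
#' @param store an `AnnotationStore`.
#' @param query gene id (preferred) or gene name (accepted when unique).
#' @param threshold CDS length-ratio threshold (default 0.5).
#' @param tools member databases to keep (`NULL` = all).
#' @return list with `feature_table` (one row per transcript x feature
#'   instance, with APPRIS flag), `classification_table` (one row per
#'   group x standard) and `diagram_model` (per-transcript exon boxes, CDS
#'   sub-boxes and feature bars spanning the encoding exons and their
#'   intervening introns).
#' @export
annotate_gene <- function(store, query, threshold = 0.5, tools = NULL) {
  gid <- resolve_gene(store, query)
  tx <- store$transcripts[store$transcripts$gene_id == gid]
  f <- store$features[store$features$gene_id == gid]
  if (!is.null(tools)) f <- f[f$tool %in% tools]

  ap <- setNames(tx$appris_principal, tx$transcript_id)
  feature_table <- f[, .(transcript_id, appris_principal =
                           unname(ap[transcript_id]),
                         tool, signature_acc, interpro_acc, description,
                         aa_start, aa_end, chrom, strand, span_start,
                         span_end, truncated)]
  setorder(feature_table, transcript_id, span_start)

  classification_table <- classify_gene(
    store, gid, standards = default_standards(threshold), tools = tools)

  exons <- merge(store$exons, tx[, .(transcript_id)], by = "transcript_id")
  cds <- merge(store$cds, tx[, .(transcript_id)], by = "transcript_id")
  diagram_model <- list(
    gene_id = gid,
    transcripts = tx[, .(transcript_id, is_coding, cds_length,
                         appris_principal)],
    exons = exons, cds = cds,
    features = f[, .(transcript_id, tool, signature_acc, span_start,
                     span_end)])
  list(feature_table = feature_table,
       classification_table = classification_table,
       diagram_model = diagram_model)
}

resolve_gene <- function(store, query) {
  if (query %in% store$genes$gene_id) return(query)
  hit <- store$genes[!is.na(store$genes$name) & store$genes$name == query]
  if (nrow(hit) == 1L) return(hit$gene_id)
  if (nrow(hit) > 1L)
    stop("ambiguous gene name '", query, "'; candidates: ",
         paste(hit$gene_id, collapse = ", "), call. = FALSE)
  stop("unknown gene: ", query, call. = FALSE)
}
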