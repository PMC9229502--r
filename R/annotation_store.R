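## Annotation store: genes/transcripts/exons/CDS parsed from GTF, protein
## features parsed from InterProScan TSV, APPRIS principal flags, and the
## projection of amino-acid feature coordinates onto genomic blocks.
##
## Internal coordinate convention: 0-based half-open [start, end) on every
## table. GTF (1-based inclusive) is converted on read and on write.

#' Read an Ensembl-dialect GTF into an annotation store
#'
#' Parses gene, transcript, exon and CDS records. Transcripts without CDS
#' lines are kept with `is_coding = FALSE`. Records on unplaced contigs are
#' kept verbatim. Coordinates are converted from GTF 1-based inclusive to
#' the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return an object of class `AnnotationStore` with data.tables `genes`,
#'   `transcripts`, `exons`, `cds` and (initially empty) `features`,
#'   `blocks`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,     # 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type  = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md))
      as.character(md$transcript_id) else NA_character_,
    gene_name = if ("gene_name" %in% names(md))
      as.character(md$gene_name) else NA_character_,
    biotype = if ("gene_biotype" %in% names(md))
      as.character(md$gene_biotype) else NA_character_,
    protein_id = if ("protein_id" %in% names(md))
      as.character(md$protein_id) else NA_character_
  )

  exons <- dt[type == "exon", .(transcript_id, start, end)]
  setorder(exons, transcript_id, start)
  cds <- dt[type == "CDS", .(transcript_id, start, end, protein_id)]
  setorder(cds, transcript_id, start)

  ## transcript table: from transcript lines if present, else from exons
  tx_src <- dt[type == "transcript"]
  if (nrow(tx_src) == 0L) {
    tx_src <- dt[type == "exon",
                 .(chrom = chrom[1L], strand = strand[1L],
                   gene_id = gene_id[1L]),
                 by = transcript_id]
  }
  transcripts <- tx_src[, .(transcript_id, gene_id, chrom, strand)]
  transcripts <- unique(transcripts, by = "transcript_id")
  cds_info <- cds[, .(cds_length = sum(end - start),
                      cds_span_start = min(start),
                      cds_span_end = max(end),
                      protein_id = {
                        p <- protein_id[!is.na(protein_id)]
                        if (length(p)) p[1L] else NA_character_
                      }),
                  by = transcript_id]
  transcripts <- merge(transcripts, cds_info, by = "transcript_id",
                       all.x = TRUE, sort = FALSE)
  transcripts[is.na(cds_length), cds_length := 0L]
  transcripts[, is_coding := cds_length > 0L]
  transcripts[, appris_principal := FALSE]

  gene_src <- dt[type == "gene"]
  if (nrow(gene_src) > 0L) {
    genes <- gene_src[, .(gene_id, name = gene_name, chrom, strand, biotype)]
    genes <- unique(genes, by = "gene_id")
  } else {
    genes <- transcripts[, .(name = NA_character_, chrom = chrom[1L],
                             strand = strand[1L], biotype = NA_character_),
                         by = gene_id]
  }
  setorder(genes, gene_id)
  setorder(transcripts, gene_id, transcript_id)

  store <- list(
    genes = genes,
    transcripts = transcripts,
    exons = exons,
    cds = cds[, .(transcript_id, start, end)],
    features = empty_feature_table(),
    blocks = data.table(feature_uid = character(), start = integer(),
                        end = integer()),
    unattached = empty_feature_table()
  )
  class(store) <- "AnnotationStore"
  store
}

## Light pre-scan of raw GTF lines so structural problems are reported with
## a line number (rtracklayer does not keep them).
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("GTF parse error at line ", i, ": fewer than 9 fields",
           call. = FALSE)
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || e < s)
      stop("GTF parse error at line ", i, ": end < start", call. = FALSE)
    if (!grepl("gene_id", f[9L], fixed = TRUE))
      stop("GTF parse error at line ", i, ": missing gene_id attribute",
           call. = FALSE)
    if (f[3L] %in% c("transcript", "exon", "CDS") &&
        !grepl("transcript_id", f[9L], fixed = TRUE))
      stop("GTF parse error at line ", i,
           ": missing transcript_id attribute", call. = FALSE)
  }
  invisible(TRUE)
}

empty_feature_table <- function() {
  data.table(feature_uid = character(), transcript_id = character(),
             gene_id = character(), protein_id = character(),
             tool = character(), signature_acc = character(),
             interpro_acc = character(), description = character(),
             aa_start = integer(), aa_end = integer(),
             truncated = logical(), chrom = character(),
             strand = character(), span_start = integer(),
             span_end = integer())
}

#' Read InterProScan tabular output
#'
#' Expects the standard InterProScan TSV dialect: protein accession, MD5,
#' sequence length, analysis (member database), signature accession,
#' signature description, start, stop, score, status, date, InterPro
#' accession, InterPro description, ... Missing optional trailing columns
#' are tolerated. An InterPro accession of `-` is stored as the empty
#' string. Rows with stop < start are rejected with a warning.
#'
#' @param path path to the TSV file.
#' @param tools optional character vector of member databases to keep
#'   (e.g. `"Pfam"`); `NULL` keeps all.
#' @return data.table of protein-coordinate features (`aa_start`, `aa_end`
#'   1-based inclusive).
#' @export
read_interproscan_tsv <- function(path, tools = NULL) {
  if (!file.exists(path))
    stop("InterProScan file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.table(protein_id = character(), tool = character(),
                      signature_acc = character(), interpro_acc = character(),
                      description = character(), aa_start = integer(),
                      aa_end = integer()))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                      colClasses = "character"),
    error = function(e) stop("cannot parse InterProScan TSV: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L)
    return(data.table(protein_id = character(), tool = character(),
                      signature_acc = character(), interpro_acc = character(),
                      description = character(), aa_start = integer(),
                      aa_end = integer()))
  if (ncol(dt) < 8L)
    stop("InterProScan TSV needs at least 8 columns (through stop)",
         call. = FALSE)
  get_col <- function(i) if (ncol(dt) >= i) dt[[i]] else
    rep(NA_character_, nrow(dt))
  out <- data.table(
    protein_id = dt[[1L]],
    tool = dt[[4L]],
    signature_acc = dt[[5L]],
    description = get_col(6L),
    aa_start = as.integer(dt[[7L]]),
    aa_end = as.integer(dt[[8L]]),
    interpro_acc = get_col(12L)
  )
  out[is.na(interpro_acc) | interpro_acc == "-", interpro_acc := ""]
  out[is.na(description), description := ""]
  bad <- which(is.na(out$aa_start) | is.na(out$aa_end) |
                 out$aa_end < out$aa_start | out$aa_start < 1L)
  if (length(bad)) {
    warning(length(bad), " InterProScan row(s) rejected (stop < start or ",
            "non-numeric coordinates)", call. = FALSE)
    out <- out[-bad]
  }
  if (!is.null(tools)) out <- out[tool %in% tools]
  setcolorder(out, c("protein_id", "tool", "signature_acc", "interpro_acc",
                     "description", "aa_start", "aa_end"))
  out[]
}

#' Read an APPRIS principal-isoform list
#'
#' Transcripts labelled `PRINCIPAL:*` map to `TRUE`; anything else
#' (including transcripts absent from the file) is `FALSE`. Malformed rows
#' are skipped with a warning.
#'
#' @param path path to a tab-separated file with a transcript-id column and
#'   an APPRIS label column.
#' @param transcript_col,label_col column indices; `label_col = NULL`
#'   auto-detects the column containing `PRINCIPAL`/`ALTERNATIVE` labels.
#' @return named logical vector keyed by normalized transcript id.
#' @export
read_appris <- function(path, transcript_col = 1L, label_col = NULL) {
  if (!file.exists(path)) stop("APPRIS file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = "character")
  if (nrow(dt) == 0L) return(setNames(logical(0), character(0)))
  if (is.null(label_col)) {
    hits <- vapply(dt, function(col)
      any(grepl("^(PRINCIPAL|ALTERNATIVE|MINOR)", col)), logical(1))
    label_col <- if (any(hits)) which(hits)[1L] else 2L
  }
  if (ncol(dt) < max(transcript_col, label_col))
    stop("APPRIS file has fewer columns than expected", call. = FALSE)
  tx <- normalize_id(dt[[transcript_col]])
  lab <- dt[[label_col]]
  bad <- !nzchar(tx) | is.na(lab) | !nzchar(lab)
  if (any(bad)) {
    warning(sum(bad), " malformed APPRIS row(s) skipped", call. = FALSE)
    tx <- tx[!bad]; lab <- lab[!bad]
  }
  setNames(grepl("^PRINCIPAL", lab), tx)
}

#' Project an amino-acid interval onto genomic blocks through a CDS
#'
#' Amino acid i (1-based) occupies CDS nucleotide offsets `[3(i-1), 3i)`
#' counted 5' to 3' along the coding sequence: from the leftmost CDS base on
#' the + strand, from the rightmost on the - strand. The offset range is
#' mapped through the ordered CDS blocks into one or more genomic blocks.
#'
#' Features whose final codon extends at most 2 nt past an
#' annotated-incomplete CDS are truncated and flagged; anything further past
#' the CDS is an error.
#'
#' @param aa_start,aa_end 1-based inclusive amino-acid coordinates.
#' @param cds_blocks data.table with 0-based half-open `start`, `end`
#'   columns, sorted by `start`.
#' @param strand `"+"` or `"-"`.
#' @return list with `blocks` (data.table of 0-based half-open genomic
#'   blocks sorted by start), `span_start`, `span_end`, `truncated`.
#' @export
project_aa_to_genomic <- function(aa_start, aa_end, cds_blocks, strand) {
  aa_start <- as.integer(aa_start); aa_end <- as.integer(aa_end)
  stopifnot(aa_start >= 1L, aa_end >= aa_start, strand %in% c("+", "-"))
  bl <- as.data.table(cds_blocks)[order(start)]
  len <- bl$end - bl$start
  L <- sum(len)
  if (L == 0L) stop("transcript has no CDS", call. = FALSE)
  off0 <- 3L * (aa_start - 1L)
  off1 <- 3L * aa_end
  truncated <- FALSE
  if (off0 >= L || off1 > L + 2L)
    stop("feature outside CDS (aa ", aa_start, "-", aa_end,
         " vs CDS length ", L, ")", call. = FALSE)
  if (off1 > L) { off1 <- L; truncated <- TRUE }

  ## coding-order block list: left-to-right on +, right-to-left on -
  ord <- if (strand == "+") seq_len(nrow(bl)) else rev(seq_len(nrow(bl)))
  cum <- 0L
  gs <- integer(0); ge <- integer(0)
  for (k in ord) {
    blen <- len[k]
    lo <- max(off0, cum); hi <- min(off1, cum + blen)
    if (lo < hi) {
      if (strand == "+") {
        gs <- c(gs, bl$start[k] + (lo - cum))
        ge <- c(ge, bl$start[k] + (hi - cum))
      } else {
        gs <- c(gs, bl$end[k] - (hi - cum))
        ge <- c(ge, bl$end[k] - (lo - cum))
      }
    }
    cum <- cum + blen
  }
  blocks <- data.table(start = gs, end = ge)[order(start)]
  list(blocks = blocks, span_start = min(blocks$start),
       span_end = max(blocks$end), truncated = truncated)
}

#' Attach protein features to a store and project them onto the genome
#'
#' Feature rows are matched to transcripts by normalized protein id (falling
#' back to the transcript id itself for pipelines that report transcript
#' accessions). Unmatched rows are kept in `store$unattached` and reported.
#'
#' @param store an `AnnotationStore` from [read_gtf()].
#' @param feats data.table from [read_interproscan_tsv()].
#' @param id_normalizer function applied to ids on both sides before
#'   matching; default strips Ensembl-style version suffixes.
#' @return the store with `features` and `blocks` populated and a fresh
#'   interval index.
#' @export
attach_features <- function(store, feats, id_normalizer = normalize_id) {
  stopifnot(inherits(store, "AnnotationStore"))
  tx <- store$transcripts
  key <- id_normalizer(tx$protein_id)
  key[is.na(key)] <- ""
  by_protein <- setNames(tx$transcript_id, key)
  by_tx <- setNames(tx$transcript_id, id_normalizer(tx$transcript_id))

  if (nrow(feats) == 0L) {
    store$features <- empty_feature_table()
    store$blocks <- data.table(feature_uid = character(), start = integer(),
                               end = integer())
    return(build_feature_index(store))
  }

  fid <- id_normalizer(feats$protein_id)
  tx_id <- unname(by_protein[fid])
  miss <- is.na(tx_id)
  tx_id[miss] <- unname(by_tx[fid[miss]])
  attached <- !is.na(tx_id)
  if (any(!attached))
    warning(sum(!attached), " feature row(s) reference unknown proteins; ",
            "kept in store$unattached", call. = FALSE)

  f <- copy(feats)[, transcript_id := tx_id]
  store$unattached <- f[!attached][, `:=`(feature_uid = NA_character_,
                                          gene_id = NA_character_)]
  f <- f[attached]
  f <- merge(f, tx[, .(transcript_id, gene_id, chrom, strand, is_coding)],
             by = "transcript_id", sort = FALSE)
  noncoding <- !f$is_coding
  if (any(noncoding)) {
    warning(sum(noncoding), " feature row(s) attached to non-coding ",
            "transcripts dropped", call. = FALSE)
    f <- f[!noncoding]
  }

  n <- nrow(f)
  blocks_list <- vector("list", n)
  span_start <- integer(n); span_end <- integer(n); trunc <- logical(n)
  cds_by_tx <- split(store$cds, by = "transcript_id", keep.by = FALSE)
  for (i in seq_len(n)) {
    pr <- project_aa_to_genomic(f$aa_start[i], f$aa_end[i],
                                cds_by_tx[[f$transcript_id[i]]],
                                f$strand[i])
    blocks_list[[i]] <- pr$blocks
    span_start[i] <- pr$span_start; span_end[i] <- pr$span_end
    trunc[i] <- pr$truncated
  }
  f[, `:=`(feature_uid = sprintf("F%06d", seq_len(n)),
           span_start = span_start, span_end = span_end,
           truncated = trunc)]
  store$features <- f[, .(feature_uid, transcript_id, gene_id, protein_id,
                          tool, signature_acc, interpro_acc, description,
                          aa_start, aa_end, truncated, chrom, strand,
                          span_start, span_end)]
  store$blocks <- rbindlist(lapply(seq_len(n), function(i)
    data.table(feature_uid = f$feature_uid[i], blocks_list[[i]])))
  build_feature_index(store)
}

## Interval index over feature spans; seqnames are normalized ("chr"
## stripped) so the index is dialect-agnostic.
build_feature_index <- function(store) {
  f <- store$features
  store$feature_gr <- if (nrow(f))
    to_granges(norm_chrom(f$chrom), f$span_start, f$span_end) else
      GenomicRanges::GRanges()
  store
}

#' Apply APPRIS principal flags to a store
#' @param store an `AnnotationStore`.
#' @param appris named logical vector from [read_appris()].
#' @return the store with `transcripts$appris_principal` set.
#' @export
apply_appris <- function(store, appris) {
  key <- normalize_id(store$transcripts$transcript_id)
  flag <- unname(appris[key])
  flag[is.na(flag)] <- FALSE
  store$transcripts[, appris_principal := flag]
  store
}

#' Build a complete annotation store from the three input files
#'
#' @param gtf,interpro_tsv paths; `appris` path or `NULL`.
#' @param tools member databases to keep (`NULL` = all).
#' @return `AnnotationStore` with a `summary` attribute: per-tool feature
#'   counts and mean features per coding transcript.
#' @export
build_store <- function(gtf, interpro_tsv, appris = NULL, tools = NULL) {
  store <- read_gtf(gtf)
  feats <- read_interproscan_tsv(interpro_tsv, tools = tools)
  store <- attach_features(store, feats)
  if (!is.null(appris)) store <- apply_appris(store, read_appris(appris))
  if (!any(store$transcripts$is_coding))
    warning("store contains no coding transcripts", call. = FALSE)
  n_coding <- sum(store$transcripts$is_coding)
  per_tool <- if (nrow(store$features))
    store$features[, .N, by = tool] else data.table(tool = character(),
                                                    N = integer())
  attr(store, "summary") <- list(
    n_genes = nrow(store$genes),
    n_transcripts = nrow(store$transcripts),
    n_coding_transcripts = n_coding,
    n_features = nrow(store$features),
    features_per_tool = per_tool,
    mean_features_per_transcript =
      if (n_coding) nrow(store$features) / n_coding else NA_real_)
  store
}

#' Query features overlapping a genomic window
#'
#' Uses the store's interval index; overlap is by feature span (hull of the
#' projected blocks, introns included), requiring at least 1 nt in common.
#'
#' @param store an `AnnotationStore`.
#' @param chrom chromosome name ("chr" prefix ignored for matching).
#' @param start,end 0-based half-open window.
#' @return data.table of feature rows.
#' @export
query_features <- function(store, chrom, start, end) {
  f <- store$features
  if (nrow(f) == 0L) return(f)
  gr <- store$feature_gr
  if (is.null(gr)) gr <- build_feature_index(store)$feature_gr
  q <- GenomicRanges::GRanges(norm_chrom(chrom), to_iranges(start, end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, gr, minoverlap = 1L))
  f[sort(unique(S4Vectors::subjectHits(hits)))]
}

#' @export
print.AnnotationStore <- function(x, ...) {
  cat("AnnotationStore:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$features), "projected features\n")
  invisible(x)
}

#' Write a store's gene models back out as GTF
#'
#' Inverse of [read_gtf()] for gene/transcript/exon/CDS records: internal
#' 0-based half-open intervals are converted back to 1-based inclusive.
#'
#' @param store an `AnnotationStore`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(store, path) {
  lines <- character(0)
  tx_by_gene <- split(store$transcripts, by = "gene_id")
  for (gid in store$genes$gene_id) {
    g <- store$genes[store$genes$gene_id == gid]
    txs <- tx_by_gene[[gid]]
    ex_all <- store$exons[store$exons$transcript_id %in% txs$transcript_id]
    lines <- c(lines, paste(g$chrom, "altfeat", "gene",
                            min(ex_all$start) + 1L, max(ex_all$end), ".",
                            g$strand, ".",
                            gtf_attr(gene_id = gid,
                                     gene_name = if (is.na(g$name)) "" else
                                       g$name,
                                     gene_biotype = if (is.na(g$biotype))
                                       "" else g$biotype),
                            sep = "\t"))
    for (tid in txs$transcript_id) {
      ex <- store$exons[store$exons$transcript_id == tid]
      cd <- store$cds[store$cds$transcript_id == tid]
      pid <- txs$protein_id[txs$transcript_id == tid]
      lines <- c(lines,
                 paste(g$chrom, "altfeat", "transcript",
                       min(ex$start) + 1L, max(ex$end), ".", g$strand, ".",
                       gtf_attr(gene_id = gid, transcript_id = tid),
                       sep = "\t"),
                 paste(g$chrom, "altfeat", "exon", ex$start + 1L, ex$end,
                       ".", g$strand, ".",
                       gtf_attr(gene_id = gid, transcript_id = tid),
                       sep = "\t"))
      if (nrow(cd))
        lines <- c(lines,
                   paste(g$chrom, "altfeat", "CDS", cd$start + 1L, cd$end,
                         ".", g$strand, "0",
                         gtf_attr(gene_id = gid, transcript_id = tid,
                                  protein_id = if (is.na(pid)) "" else pid),
                         sep = "\t"))
    }
  }
  write_lines_atomic(lines, path)
}

#' Serialize a store to a directory of TSV files
#' @param store an `AnnotationStore`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_atomic(store$genes, file.path(dir, "genes.tsv"))
  write_tsv_atomic(store$transcripts, file.path(dir, "transcripts.tsv"))
  write_tsv_atomic(store$exons, file.path(dir, "exons.tsv"))
  write_tsv_atomic(store$cds, file.path(dir, "cds.tsv"))
  write_tsv_atomic(store$features, file.path(dir, "features.tsv"))
  write_tsv_atomic(store$blocks, file.path(dir, "feature_blocks.tsv"))
  s <- attr(store, "summary")
  if (!is.null(s)) {
    man <- data.table(tool = s$features_per_tool$tool,
                      n_features = s$features_per_tool$N)
    write_tsv_atomic(man, file.path(dir, "manifest.tsv"))
  }
  invisible(dir)
}

#' Load a store serialized with [write_store()]
#' @param dir directory written by [write_store()].
#' @return an `AnnotationStore`.
#' @export
load_store <- function(dir) {
  rd <- function(f, classes = NULL)
    data.table::fread(file.path(dir, f), sep = "\t",
                      colClasses = classes, na.strings = "NA")
  store <- list(
    genes = rd("genes.tsv"),
    transcripts = rd("transcripts.tsv"),
    exons = rd("exons.tsv"),
    cds = rd("cds.tsv"),
    features = rd("features.tsv"),
    blocks = rd("feature_blocks.tsv"),
    unattached = empty_feature_table())
  for (nm in c("genes", "transcripts", "features"))
    for (col in names(store[[nm]]))
      if (is.logical(store[[nm]][[col]]) && nm == "genes")
        store[[nm]][[col]] <- as.character(store[[nm]][[col]])
  if (nrow(store$features) == 0L) store$features <- empty_feature_table()
  class(store) <- "AnnotationStore"
  build_feature_index(store)
}
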