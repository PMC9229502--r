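## Synthetic fixtures with a machine-readable truth manifest.
##
## Every simulated gene is drawn from a five-transcript template that
## reproduces the canonical isoform structures: a full-length isoform (T1),
## an exon-skipping isoform (T2), an alternative-TSS isoform (T3), a
## short-CDS isoform whose CDS length ratio falls below 0.5 (T4), and a
## non-coding intron-retention isoform (T5). Every exon's CDS chunk has a
## length divisible by 3 and every alternative CDS start is offset by a
## multiple of 3, so all transcripts share the reading frame at any shared
## genomic position. Feature windows are planted codon-aligned inside a
## single CDS chunk: each member instance then projects to exactly the
## planted window, the group hull equals the window, and the true
## alternative/constitutive status under each standard follows from set
## logic over the designed CDS structures -- independent of the package's
## grouping and classification code.

## Template in gene-relative, +-strand coordinates (0-based half-open).
## CDS chunk lengths: 99, 201, 201, 201, 102 (all divisible by 3).
fig1_template <- function() {
  iv <- function(...) {
    v <- c(...)
    if (!length(v))
      return(data.table(start = integer(), end = integer()))
    m <- matrix(as.integer(v), ncol = 2, byrow = TRUE)
    data.table(start = m[, 1L], end = m[, 2L])
  }
  list(
    span = 4300L,
    exons = list(
      T1 = iv(0, 200, 1000, 1201, 2000, 2201, 3000, 3201, 4000, 4300),
      T2 = iv(0, 200, 1000, 1201, 3000, 3201, 4000, 4300),
      T3 = iv(1039, 1201, 2000, 2201, 3000, 3201, 4000, 4300),
      T4 = iv(0, 200, 1000, 1260),
      T5 = iv(0, 200, 1000, 2201)),
    cds = list(
      T1 = iv(101, 200, 1000, 1201, 2000, 2201, 3000, 3201, 4000, 4102),
      T2 = iv(101, 200, 1000, 1201, 3000, 3201, 4000, 4102),
      T3 = iv(1039, 1201, 2000, 2201, 3000, 3201, 4000, 4102),
      T4 = iv(101, 200, 1000, 1201),
      T5 = iv()),
    ## chunk universe for feature placement = T1's CDS blocks
    chunks = iv(101, 200, 1000, 1201, 2000, 2201, 3000, 3201, 4000, 4102))
}

#' Simulation configuration
#'
#' @param n_genes number of genes (gene 1 always carries the full
#'   five-transcript template on the + strand).
#' @param transcripts_per_gene integer range for the number of coding
#'   transcripts drawn from the template (clamped to `[1, 4]`; T1 is
#'   always present).
#' @param frac_noncoding probability that a gene also carries the
#'   non-coding isoform T5.
#' @param features_per_gene integer range of planted features per gene.
#' @param accessions signature-accession alphabet.
#' @param tools member database label used for every planted feature.
#' @param p_member probability that an encoding transcript carries a
#'   planted feature instance.
#' @param p_constitutive probability that a plant is forced onto every
#'   encoding transcript.
#' @param thresholds CDS length-ratio grid at which true statuses are
#'   recorded in the manifest.
#' @param seed RNG seed; identical (config, seed) gives byte-identical
#'   files.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_genes = 8L, transcripts_per_gene = c(2L, 4L),
                       frac_noncoding = 0.4,
                       features_per_gene = c(1L, 3L),
                       accessions = sprintf("PF%05d", 1:8),
                       tools = "Pfam", p_member = 0.7,
                       p_constitutive = 0.25,
                       thresholds = c(0.25, 0.5, 0.75), seed = 1L) {
  stopifnot(n_genes >= 0, frac_noncoding >= 0, frac_noncoding <= 1,
            p_member > 0, p_member <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 transcripts_per_gene = as.integer(transcripts_per_gene),
                 frac_noncoding = frac_noncoding,
                 features_per_gene = as.integer(features_per_gene),
                 accessions = accessions, tools = tools,
                 p_member = p_member, p_constitutive = p_constitutive,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "SimConfig")
}

## Shift/reflect a relative interval table to absolute coordinates.
place_intervals <- function(iv, offset, strand, span) {
  if (nrow(iv) == 0L) return(copy(iv))
  out <- if (strand == "+")
    data.table(start = offset + iv$start, end = offset + iv$end)
  else
    data.table(start = offset + span - iv$end,
               end = offset + span - iv$start)
  setorder(out, start)
  out
}

## Build one gene instance from the template.
make_gene <- function(gene_id, name, chrom, offset, strand, tx_names,
                      tmpl) {
  tx <- list()
  for (t in tx_names) {
    ex <- place_intervals(tmpl$exons[[t]], offset, strand, tmpl$span)
    cd <- place_intervals(tmpl$cds[[t]], offset, strand, tmpl$span)
    tid <- paste0(gene_id, ".", tolower(t))
    tx[[tid]] <- list(template = t, exons = ex, cds = cd,
                      coding = nrow(cd) > 0L,
                      cds_length = if (nrow(cd)) sum(cd$end - cd$start)
                      else 0L,
                      protein_id = if (nrow(cd)) paste0(gene_id, "_P",
                                                        tolower(t)) else "")
  }
  chunks <- place_intervals(tmpl$chunks, offset, strand, tmpl$span)
  list(gene_id = gene_id, name = name, chrom = chrom, strand = strand,
       offset = offset, transcripts = tx, chunks = chunks)
}

## Coding offset (0-based, 5'->3') of genomic window [ws, we) within a
## transcript's CDS; NA when the window is not fully inside one CDS block.
coding_offset <- function(cds, strand, ws, we) {
  hit <- which(cds$start <= ws & cds$end >= we)
  if (!length(hit)) return(NA_integer_)
  b <- hit[1L]
  if (strand == "+")
    sum(cds$end[seq_len(b - 1L)] - cds$start[seq_len(b - 1L)]) +
      (ws - cds$start[b])
  else {
    after <- which(cds$start > cds$start[b])
    sum(cds$end[after] - cds$start[after]) + (cds$end[b] - we)
  }
}

## Plant one feature of `acc` in gene `g`: choose a codon-aligned window in
## chunk `chunk_i`, a member subset of the encoding transcripts, and derive
## the true status under every standard from the designed CDS structures.
plant_feature <- function(g, acc, ipr, tool, chunk_i, cfg) {
  ch <- g$chunks[chunk_i]
  max_aa <- (ch$end - ch$start) %/% 3L
  aa_len <- sample(5:min(20L, max_aa), 1L)
  k_max <- max_aa - aa_len
  ws <- ch$start + 3L * sample.int(k_max + 1L, 1L) - 3L
  we <- ws + 3L * aa_len

  coding_tx <- names(g$transcripts)[vapply(g$transcripts, `[[`, TRUE,
                                           "coding")]
  encoders <- coding_tx[vapply(coding_tx, function(t) {
    !is.na(coding_offset(g$transcripts[[t]]$cds, g$strand, ws, we))
  }, TRUE)]
  stopifnot(length(encoders) >= 1L)
  if (stats::runif(1) < cfg$p_constitutive) {
    members <- encoders
  } else {
    members <- encoders[stats::runif(length(encoders)) < cfg$p_member]
    if (!length(members)) members <- sample(encoders, 1L)
  }

  ## per-member amino-acid coordinates (exact by codon alignment)
  aa <- lapply(members, function(t) {
    off <- coding_offset(g$transcripts[[t]]$cds, g$strand, ws, we)
    stopifnot(off %% 3L == 0L)
    list(transcript = t, aa_start = off %/% 3L + 1L,
         aa_end = off %/% 3L + aa_len)
  })

  ## truth by set logic on the designed structures
  cds_len <- vapply(coding_tx, function(t)
    g$transcripts[[t]]$cds_length, 0L)
  ratios <- cds_len / max(cds_len)
  span_of <- function(t) {
    cd <- g$transcripts[[t]]$cds
    c(min(cd$start), max(cd$end))
  }
  overlap_cand <- coding_tx[vapply(coding_tx, function(t) {
    sp <- span_of(t); sp[1L] <= ws && sp[2L] >= we
  }, TRUE)]
  status_of <- function(cand)
    if (length(cand) && all(cand %in% members)) "constitutive" else
      "alternative"
  ratio_status <- lapply(cfg$thresholds, function(th)
    status_of(coding_tx[ratios >= th]))
  names(ratio_status) <- as.character(cfg$thresholds)

  list(gene_id = g$gene_id, tool = tool, signature_acc = acc,
       interpro_acc = ipr, chrom = g$chrom, window_start = ws,
       window_end = we, aa_len = aa_len, members = members,
       encoders = encoders, aa = aa,
       status = list(coding = status_of(coding_tx),
                     cds_ratio = ratio_status,
                     overlap_cds = status_of(overlap_cand)),
       candidates = list(coding = coding_tx, overlap_cds = overlap_cand))
}

#' Simulate annotation inputs (GTF, InterProScan TSV, APPRIS) with truth
#'
#' Writes `annotation.gtf`, `interpro.tsv`, `appris.tsv` and
#' `manifest.json` into `out_dir` and returns the truth manifest. Gene 1
#' always carries the complete five-transcript template on the + strand;
#' other genes draw random transcript subsets, strands and feature plants.
#' The APPRIS principal isoform is the longest-CDS transcript (T1).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return the manifest (invisibly a list; also serialized as JSON), with
#'   element `paths` naming the emitted files.
#' @export
simulate_annotation <- function(config = sim_config(),
                                out_dir = tempfile("simann")) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tmpl <- fig1_template()
  chrom <- "S1"

  genes <- list(); plants <- list()
  ipr_of <- function(acc) {
    i <- match(acc, config$accessions)
    if (i %% 2L == 0L) sprintf("IPR%06d", i) else ""
  }
  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("SG%06d", i)
    offset <- 1000L + (i - 1L) * 10000L
    if (i == 1L) {
      tx_names <- c("T1", "T2", "T3", "T4", "T5"); strand <- "+"
    } else {
      strand <- sample(c("+", "-"), 1L)
      rng <- sort(pmin(pmax(config$transcripts_per_gene, 1L), 4L))
      n_cod <- sample(rng[1L]:rng[2L], 1L)
      tx_names <- c("T1", sample(c("T2", "T3", "T4"), n_cod - 1L))
      if (stats::runif(1) < config$frac_noncoding)
        tx_names <- c(tx_names, "T5")
    }
    g <- make_gene(gid, paste0("GENE", i), chrom, offset, strand,
                   tx_names, tmpl)
    genes[[gid]] <- g

    frng <- sort(config$features_per_gene)
    n_feat <- if (frng[2L] > frng[1L]) sample(frng[1L]:frng[2L], 1L) else
      frng[1L]
    n_feat <- min(n_feat, nrow(g$chunks), length(config$accessions))
    if (n_feat > 0L) {
      accs <- sample(config$accessions, n_feat)
      chunk_ids <- sample.int(nrow(g$chunks), n_feat)
      for (k in seq_len(n_feat)) {
        tool <- if (length(config$tools) == 1L) config$tools else
          sample(config$tools, 1L)
        plants[[length(plants) + 1L]] <-
          plant_feature(g, accs[k], ipr_of(accs[k]), tool, chunk_ids[k],
                        config)
      }
    }
  }

  paths <- list(gtf = file.path(out_dir, "annotation.gtf"),
                interpro = file.path(out_dir, "interpro.tsv"),
                appris = file.path(out_dir, "appris.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_sim_gtf(genes, paths$gtf)
  write_sim_interpro(genes, plants, paths$interpro)
  write_sim_appris(genes, paths$appris)

  gene_man <- lapply(genes, function(g) {
    list(gene_id = g$gene_id, name = g$name, chrom = g$chrom,
         strand = g$strand,
         transcripts = lapply(g$transcripts, function(t)
           list(template = t$template, coding = t$coding,
                cds_length = t$cds_length, n_exons = nrow(t$exons),
                n_cds = nrow(t$cds), protein_id = t$protein_id)))
  })
  manifest <- list(
    config = unclass(config),
    genes = gene_man,
    features = plants,
    totals = list(
      n_genes = length(genes),
      n_transcripts = sum(vapply(genes, function(g)
        length(g$transcripts), 0L)),
      n_exon_rows = sum(vapply(genes, function(g)
        sum(vapply(g$transcripts, function(t) nrow(t$exons), 0L)), 0)),
      n_cds_rows = sum(vapply(genes, function(g)
        sum(vapply(g$transcripts, function(t) nrow(t$cds), 0L)), 0)),
      n_feature_rows = sum(vapply(plants, function(p)
        length(p$members), 0L)),
      n_plants = length(plants)),
    paths = paths)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

gtf_attr <- function(...) {
  kv <- list(...)
  kv <- kv[vapply(kv, nzchar, TRUE)]
  paste(vapply(names(kv), function(k)
    sprintf('%s "%s";', k, kv[[k]]), ""), collapse = " ")
}

write_sim_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    tx_all <- g$transcripts
    g_start <- min(vapply(tx_all, function(t) min(t$exons$start), 0L))
    g_end <- max(vapply(tx_all, function(t) max(t$exons$end), 0L))
    lines <- c(lines, paste(g$chrom, "altfeat_sim", "gene", g_start + 1L,
                            g_end, ".", g$strand, ".",
                            gtf_attr(gene_id = g$gene_id,
                                     gene_name = g$name,
                                     gene_biotype = "protein_coding"),
                            sep = "\t"))
    for (tid in names(tx_all)) {
      t <- tx_all[[tid]]
      lines <- c(lines, paste(g$chrom, "altfeat_sim", "transcript",
                              min(t$exons$start) + 1L, max(t$exons$end),
                              ".", g$strand, ".",
                              gtf_attr(gene_id = g$gene_id,
                                       transcript_id = tid,
                                       gene_name = g$name),
                              sep = "\t"))
      for (j in seq_len(nrow(t$exons)))
        lines <- c(lines, paste(g$chrom, "altfeat_sim", "exon",
                                t$exons$start[j] + 1L, t$exons$end[j],
                                ".", g$strand, ".",
                                gtf_attr(gene_id = g$gene_id,
                                         transcript_id = tid),
                                sep = "\t"))
      for (j in seq_len(nrow(t$cds)))
        lines <- c(lines, paste(g$chrom, "altfeat_sim", "CDS",
                                t$cds$start[j] + 1L, t$cds$end[j],
                                ".", g$strand, "0",
                                gtf_attr(gene_id = g$gene_id,
                                         transcript_id = tid,
                                         protein_id = t$protein_id),
                                sep = "\t"))
    }
  }
  write_lines_atomic(lines, path)
}

write_sim_interpro <- function(genes, plants, path) {
  rows <- character(0)
  for (p in plants) {
    g <- genes[[p$gene_id]]
    for (a in p$aa) {
      t <- g$transcripts[[a$transcript]]
      prot_len <- t$cds_length %/% 3L
      rows <- c(rows, paste(
        paste0(t$protein_id, ".1"),   # versioned: exercises the normalizer
        "md5na", prot_len, p$tool, p$signature_acc,
        paste0(p$signature_acc, " domain"), a$aa_start, a$aa_end,
        "1.0E-10", "T", "01-01-2026", ifelse(nzchar(p$interpro_acc),
                                             p$interpro_acc, "-"),
        ifelse(nzchar(p$interpro_acc),
               paste0(p$interpro_acc, " entry"), "-"),
        sep = "\t"))
    }
  }
  write_lines_atomic(rows, path)
}

write_sim_appris <- function(genes, path) {
  rows <- character(0)
  for (g in genes) {
    for (tid in names(g$transcripts)) {
      t <- g$transcripts[[tid]]
      if (!t$coding) next
      lab <- if (t$template == "T1") "PRINCIPAL:1" else "ALTERNATIVE:2"
      rows <- c(rows, paste(tid, lab, sep = "\t"))
    }
  }
  write_lines_atomic(rows, path)
}

#' Simulate target/background region lists with a planted enrichment
#'
#' Target regions overlap the planted accession's instances at
#' `fold * base_rate`; background regions at `base_rate`. A further,
#' equal-rate share of both lists overlaps other accessions (null
#' signal); the remainder falls in feature-free intergenic zones.
#'
#' @param ann_manifest manifest from [simulate_annotation()].
#' @param out_dir output directory.
#' @param n_target,n_background region counts (default 200 each).
#' @param planted_acc accession to enrich (default: the first planted
#'   accession).
#' @param fold enrichment fold of the planted accession in the target list.
#' @param base_rate background overlap rate for the planted accession.
#' @param p_other rate at which regions overlap a non-planted accession.
#' @param seed RNG seed.
#' @return manifest list (paths, planted accession, realized counts);
#'   writes `target.bed` and `background.bed`.
#' @export
simulate_regions <- function(ann_manifest, out_dir = tempfile("simreg"),
                             n_target = 200L, n_background = 200L,
                             planted_acc = NULL, fold = 4,
                             base_rate = 0.1, p_other = 0.3, seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- ann_manifest$features
  if (!length(feats)) stop("annotation manifest has no planted features",
                           call. = FALSE)
  accs <- vapply(feats, `[[`, "", "signature_acc")
  if (is.null(planted_acc)) planted_acc <- accs[1L]
  p_t <- fold * base_rate
  if (p_t > 0.95) stop("requested fold incompatible with base_rate ",
                       "(target rate would exceed 1)", call. = FALSE)
  planted <- feats[accs == planted_acc]
  others <- feats[accs != planted_acc]
  chrom <- planted[[1L]]$chrom
  n_genes <- ann_manifest$totals$n_genes

  overlap_region <- function(f) {
    lo <- max(0L, f$window_start - 30L)
    hi <- max(lo, f$window_end - 15L)
    rs <- sample(lo:hi, 1L)
    c(rs, rs + 60L)
  }
  empty_region <- function() {
    gi <- sample.int(n_genes, 1L)
    zone_lo <- 1000L + (gi - 1L) * 10000L + 5300L
    rs <- sample(zone_lo:(zone_lo + 3000L), 1L)
    c(rs, rs + 60L)
  }
  draw_list <- function(n, p_plant) {
    kind <- character(n); s <- integer(n); e <- integer(n)
    for (i in seq_len(n)) {
      u <- stats::runif(1)
      if (u < p_plant) {
        r <- overlap_region(planted[[sample.int(length(planted), 1L)]])
        kind[i] <- "planted"
      } else if (u < p_plant + p_other && length(others)) {
        r <- overlap_region(others[[sample.int(length(others), 1L)]])
        kind[i] <- "other"
      } else {
        r <- empty_region()
        kind[i] <- "empty"
      }
      s[i] <- r[1L]; e[i] <- r[2L]
    }
    data.table(chrom = chrom, start = s, end = e,
               name = sprintf("r%04d_%s", seq_len(n), kind), kind = kind)
  }
  tgt <- draw_list(n_target, p_t)
  bgd <- draw_list(n_background, base_rate)
  paths <- list(target = file.path(out_dir, "target.bed"),
                background = file.path(out_dir, "background.bed"))
  write_lines_atomic(with(tgt, paste(chrom, start, end, name, sep = "\t")),
                     paths$target)
  write_lines_atomic(with(bgd, paste(chrom, start, end, name, sep = "\t")),
                     paths$background)
  invisible(list(paths = paths, planted_acc = planted_acc, fold = fold,
                 base_rate = base_rate, n_target = n_target,
                 n_background = n_background,
                 planted_in_target = sum(tgt$kind == "planted"),
                 planted_in_background = sum(bgd$kind == "planted")))
}

#' Simulate identity tables (RBH truth) and a GO membership table
#'
#' Identity tables plant `n_pairs` reciprocal best hits plus one-way and
#' tied decoys that must not survive the RBH filter. The GO table groups
#' the genes of an annotation manifest into terms whose true
#' alternative-domain tallies (Overlap CDS standard) are recorded in the
#' returned manifest.
#'
#' @param out_dir output directory.
#' @param n_pairs planted reciprocal pairs.
#' @param n_decoys one-way decoy queries per species.
#' @param ann_manifest optional manifest from [simulate_annotation()]; when
#'   supplied a `go.tsv` is emitted over its genes.
#' @param n_terms GO terms to emit.
#' @param seed RNG seed.
#' @return manifest list: `pairs` (data.table gene_a/gene_b),
#'   `tie_decoy`, `go_terms` (per-term true tallies), `paths`.
#' @export
simulate_identity_and_go <- function(out_dir = tempfile("simhom"),
                                     n_pairs = 50L, n_decoys = 20L,
                                     ann_manifest = NULL, n_terms = 6L,
                                     seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ha <- sprintf("HSG%04d", seq_len(n_pairs))
  mb <- sprintf("MMG%04d", seq_len(n_pairs))
  id_hi <- round(stats::runif(n_pairs, 70, 95), 1)
  ab <- data.table(query = ha, target = mb, ident = id_hi)
  ba <- data.table(query = mb, target = ha, ident = id_hi)
  ## sub-optimal noise rows for a subset of pairs
  noisy <- which(stats::runif(n_pairs) < 0.5)
  if (length(noisy)) {
    alt_t <- mb[(noisy %% n_pairs) + 1L]
    ab <- rbind(ab, data.table(query = ha[noisy], target = alt_t,
                               ident = pmax(5, id_hi[noisy] - 10)))
  }
  ## one-way decoys: their best hit is a paired gene whose own best hit
  ## lies elsewhere, so reciprocity fails
  if (n_decoys > 0L) {
    hd <- sprintf("HSD%04d", seq_len(n_decoys))
    md <- sprintf("MMD%04d", seq_len(n_decoys))
    ab <- rbind(ab, data.table(query = hd,
                               target = mb[(seq_len(n_decoys) %% n_pairs) +
                                             1L],
                               ident = round(stats::runif(n_decoys, 40,
                                                          60), 1)))
    ba <- rbind(ba, data.table(query = md,
                               target = ha[(seq_len(n_decoys) %% n_pairs) +
                                             1L],
                               ident = round(stats::runif(n_decoys, 40,
                                                          60), 1)))
  }
  ## tie decoy: equal identities; the documented tie-break (smallest
  ## target id) must pick MMT0001, whose own best hit lies elsewhere, so
  ## the tie never becomes a pair
  tie_q <- "HST0001"
  ab <- rbind(ab, data.table(query = tie_q, target = c("MMT0001",
                                                       "MMT0002"),
                             ident = c(66, 66)))
  ba <- rbind(ba, data.table(query = c("MMT0001", "MMT0002"),
                             target = "HSZ0001", ident = c(80, 80)))
  expected_pairs <- data.table(gene_a = ha, gene_b = mb)
  setorder(expected_pairs, gene_a)

  paths <- list(ab = file.path(out_dir, "identity_ab.tsv"),
                ba = file.path(out_dir, "identity_ba.tsv"),
                go = file.path(out_dir, "go.tsv"))
  hdr <- "query_gene\ttarget_gene\tpct_identity_query"
  write_lines_atomic(c(hdr, with(ab, paste(query, target, ident,
                                           sep = "\t"))), paths$ab)
  write_lines_atomic(c(hdr, with(ba, paste(query, target, ident,
                                           sep = "\t"))), paths$ba)

  go_terms <- NULL
  if (!is.null(ann_manifest)) {
    units <- true_domain_units(ann_manifest, standard = "overlap_cds")
    gene_alt <- units[, .(frac = mean(status == "alternative")), by = gene_id]
    setorder(gene_alt, -frac, gene_id)
    n_g <- nrow(gene_alt)
    pick <- list(
      `GO:0000001` = gene_alt$gene_id[seq_len(ceiling(n_g / 2))],  # high-alt
      `GO:0000002` = gene_alt$gene_id[(n_g - ceiling(n_g / 2) + 1L):n_g])
    extra <- max(0L, n_terms - length(pick))
    for (k in seq_len(extra)) {
      sz <- sample(2:max(2L, n_g - 1L), 1L)
      pick[[sprintf("GO:%07d", k + 2L)]] <- sample(gene_alt$gene_id, sz)
    }
    rows <- character(0); go_terms <- list()
    for (tid in names(pick)) {
      gs <- sort(pick[[tid]])
      nm <- paste0("term_", sub("GO:", "", tid))
      rows <- c(rows, paste(tid, nm, gs, sep = "\t"))
      u <- units[units$gene_id %in% gs]
      go_terms[[tid]] <- list(term_id = tid, term_name = nm,
                              genes = gs, n_domains = nrow(u),
                              n_alternative = sum(u$status ==
                                                    "alternative"))
    }
    write_lines_atomic(rows, paths$go)
  }
  invisible(list(pairs = expected_pairs, tie_decoy = tie_q,
                 tie_expected_best = "MMT0001", go_terms = go_terms,
                 paths = paths))
}

#' True (gene, accession) domain-status units from a truth manifest
#'
#' Collapses the manifest's planted per-group statuses to one row per
#' (gene, accession) with the any-alternative rule, mirroring
#' `domain_units()` on classifier output but computed from the planted
#' truth alone.
#'
#' @param ann_manifest manifest from [simulate_annotation()].
#' @param standard `"coding"`, `"overlap_cds"`, or `"cds_ratio"`.
#' @param threshold threshold for `cds_ratio` (must be on the manifest's
#'   recorded grid).
#' @return data.table of gene_id, signature_acc, status.
#' @export
true_domain_units <- function(ann_manifest, standard = "overlap_cds",
                              threshold = 0.5) {
  rows <- rbindlist(lapply(ann_manifest$features, function(p) {
    st <- if (standard == "cds_ratio")
      p$status$cds_ratio[[as.character(threshold)]] else
        p$status[[standard]]
    data.table(gene_id = p$gene_id, signature_acc = p$signature_acc,
               status = st)
  }))
  rows[, .(status = if (any(status == "alternative")) "alternative" else
    "constitutive"), by = .(gene_id, signature_acc)]
}
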