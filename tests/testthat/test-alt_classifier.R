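# Grouping of common features and alternative/constitutive classification.

# Minimal feature rows for grouping tests (only the columns grouping uses).
feat_rows <- function(spans, acc = "PF00001", tool = "Pfam",
                      tx = NULL) {
  n <- nrow(spans)
  data.table::data.table(
    feature_uid = sprintf("F%03d", seq_len(n)),
    transcript_id = tx %||% sprintf("T%d", seq_len(n)),
    gene_id = "G1", tool = tool, signature_acc = acc,
    interpro_acc = "", span_start = spans$start, span_end = spans$end)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
sp <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.table::data.table(start = m[, 1], end = m[, 2])
}

test_that("grouping follows accession and transitive span overlap", {
  # identical spans, same accession -> one group of two
  g <- group_common_features(feat_rows(sp(100, 200, 100, 200)))
  expect_equal(length(unique(g$group_id)), 1L)

  # [100,200), [150,250), [400,500) -> {1,2} merge transitively, {3} apart
  g <- group_common_features(feat_rows(sp(100, 200, 150, 250, 400, 500)))
  expect_equal(g$group_id[1], g$group_id[2])
  expect_false(g$group_id[3] == g$group_id[1])
  expect_equal(nrow(attr(g, "groups")), 2L)

  # abutting spans ([100,200) vs [200,300)) share no nucleotide -> apart
  g <- group_common_features(feat_rows(sp(100, 200, 200, 300)))
  expect_equal(length(unique(g$group_id)), 2L)

  # identical spans, different accessions -> accession partitions first
  f <- rbind(feat_rows(sp(100, 200), acc = "PF00001"),
             feat_rows(sp(100, 200), acc = "PF00002"))
  g <- group_common_features(f)
  expect_equal(length(unique(g$group_id)), 2L)

  # chain a-b-c where a and c do not overlap directly still merges
  g <- group_common_features(feat_rows(sp(0, 10, 8, 20, 18, 30)))
  expect_equal(length(unique(g$group_id)), 1L)
  hull <- attr(g, "groups")
  expect_equal(hull$hull_start, 0L)
  expect_equal(hull$hull_end, 30L)
})

fig1_store <- function(seed = 1) {
  man <- simulate_annotation(sim_config(n_genes = 1, seed = seed),
                             tempfile())
  list(man = man,
       store = build_store(man$paths$gtf, man$paths$interpro,
                           man$paths$appris))
}

test_that("candidate standards reproduce the five-transcript scenario", {
  fx <- fig1_store()
  store <- fx$store
  tid <- function(t) paste0("SG000001.", t)

  cand <- candidate_transcripts(store, "SG000001", standard("coding"))
  expect_setequal(cand, tid(c("t1", "t2", "t3", "t4")))  # t5 non-coding

  cand <- candidate_transcripts(store, "SG000001",
                                standard("cds_ratio", 0.5))
  expect_setequal(cand, tid(c("t1", "t2", "t3")))  # 0.5 removes t4

  # overlap_cds containment on a toy hull: a window inside the last coding
  # exon is only covered by transcripts whose CDS span reaches it
  tx <- store$transcripts[transcript_id == tid("t4")]
  hull <- c(tx$cds_span_end + 500L, tx$cds_span_end + 520L)
  cand <- candidate_transcripts(store, "SG000001",
                                standard("overlap_cds"),
                                group_hull = hull)
  expect_true(all(store$transcripts[transcript_id %in% cand,
                                    cds_span_end] >= hull[2]))
  expect_false(tid("t4") %in% cand)
})

test_that("cds_ratio threshold comparison is inclusive and keeps ties", {
  fx <- fig1_store()
  store <- fx$store
  # ratio of t2 is exactly 603/804 = 0.75; inclusive comparison keeps it
  cand <- candidate_transcripts(store, "SG000001",
                                standard("cds_ratio", 0.75))
  expect_true("SG000001.t2" %in% cand)
  cand_strict <- candidate_transcripts(store, "SG000001",
                                       standard("cds_ratio", 0.75),
                                       inclusive = FALSE)
  expect_false("SG000001.t2" %in% cand_strict)
  # the major isoform always qualifies, even at threshold 1
  expect_true("SG000001.t1" %in%
                candidate_transcripts(store, "SG000001",
                                      standard("cds_ratio", 1)))
})

test_that("classify_gene counts presence among candidates", {
  fx <- fig1_store()
  cls <- classify_gene(fx$store, "SG000001")
  expect_true(all(cls$status %in% c("constitutive", "alternative")))
  expect_true(all(cls$n_present <= cls$n_candidates))
  expect_true(all(cls$n_candidates >= 1))
  # constitutive <=> full presence
  expect_equal(cls$status == "constitutive",
               cls$n_present == cls$n_candidates)
  # unknown gene -> lookup error
  expect_error(classify_gene(fx$store, "NOPE"), "unknown gene")
})

test_that("single coding transcript genes are constitutive everywhere", {
  # restrict a simulated gene's features to instances on t1 only by
  # building a store from a one-transcript GTF
  dir <- tempfile()
  man <- simulate_annotation(sim_config(n_genes = 1, seed = 3), dir)
  gtf <- readLines(man$paths$gtf)
  keep <- !grepl("transcript_id \"SG000001\\.(t2|t3|t4|t5)\"", gtf)
  gtf1 <- tempfile(fileext = ".gtf")
  writeLines(gtf[keep], gtf1)
  ipr <- data.table::fread(man$paths$interpro, header = FALSE)
  ipr <- ipr[V1 == "SG000001_Pt1.1"]
  ipr1 <- tempfile()
  data.table::fwrite(ipr, ipr1, sep = "\t", col.names = FALSE)
  store <- build_store(gtf1, ipr1)
  cls <- classify_gene(store, "SG000001")
  expect_gt(nrow(cls), 0)
  expect_true(all(cls$status == "constitutive"))
  expect_true(all(cls$n_candidates == 1L))
})

test_that("classification is invariant under input row order", {
  man <- simulate_annotation(sim_config(n_genes = 3, seed = 13),
                             tempfile())
  store <- build_store(man$paths$gtf, man$paths$interpro,
                       man$paths$appris)
  ref <- classify_all_genes(store)

  # shuffle feature rows (and the GTF record order) and rebuild
  set.seed(99)
  ipr <- readLines(man$paths$interpro)
  ipr2 <- tempfile(); writeLines(sample(ipr), ipr2)
  store2 <- build_store(man$paths$gtf, ipr2, man$paths$appris)
  cls2 <- classify_all_genes(store2)
  cols <- c("gene_id", "tool", "signature_acc", "standard", "threshold",
            "n_candidates", "n_present", "status")
  expect_equal(ref[, ..cols], cls2[, ..cols])
})

test_that("annotate_gene resolves queries and assembles the three outputs", {
  fx <- fig1_store()
  res <- annotate_gene(fx$store, "SG000001", threshold = 0.5)
  expect_named(res, c("feature_table", "classification_table",
                      "diagram_model"))
  # name-based lookup resolves to the same gene
  res2 <- annotate_gene(fx$store, "GENE1")
  expect_equal(res2$classification_table, res$classification_table)
  # APPRIS principal flag marks t1 rows
  ft <- res$feature_table
  expect_true(all(ft[transcript_id == "SG000001.t1"]$appris_principal))
  expect_false(any(ft[transcript_id != "SG000001.t1"]$appris_principal))
  # three standards per group
  expect_setequal(unique(res$classification_table$standard),
                  c("coding", "cds_ratio", "overlap_cds"))
  # diagram model carries exon, CDS and feature geometry
  dm <- res$diagram_model
  expect_gt(nrow(dm$exons), 0)
  expect_gt(nrow(dm$cds), 0)
  expect_gt(nrow(dm$features), 0)
  expect_error(annotate_gene(fx$store, "NOPE"), "unknown gene")
})

test_that("threshold monotonicity: constitutive survives larger thresholds", {
  for (seed in 1:5) {
    man <- simulate_annotation(sim_config(n_genes = 4, seed = seed),
                               tempfile())
    store <- build_store(man$paths$gtf, man$paths$interpro,
                         man$paths$appris)
    ths <- c(0.25, 0.5, 0.75)
    cls <- classify_all_genes(store, standards = lapply(ths, function(t)
      standard("cds_ratio", t)))
    wide <- data.table::dcast(cls,
                              gene_id + signature_acc + group_id ~ threshold,
                              value.var = "status")
    for (i in seq_len(length(ths) - 1)) {
      lo <- as.character(ths[i]); hi <- as.character(ths[i + 1])
      expect_true(all(wide[[hi]][wide[[lo]] == "constitutive"] ==
                        "constitutive"))
    }
    # candidate sets shrink monotonically
    for (g in unique(cls$gene_id)) {
      cands <- lapply(ths, function(t)
        candidate_transcripts(store, g, standard("cds_ratio", t)))
      for (i in seq_len(length(ths) - 1))
        expect_true(all(cands[[i + 1]] %in% cands[[i]]))
    }
  }
})
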