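# GTF/InterProScan/APPRIS readers and the amino-acid -> genomic projection.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

toy_gtf <- function() {
  write_tmp(c(
    paste("chr1\tsrc\tgene\t101\t500\t.\t+\t.",
          'gene_id "G1"; gene_name "FOO"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1\tsrc\ttranscript\t101\t500\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    paste("chr1\tsrc\texon\t101\t130\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    paste("chr1\tsrc\texon\t201\t500\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1";', sep = "\t"),
    paste("chr1\tsrc\tCDS\t101\t130\t.\t+\t0",
          'gene_id "G1"; transcript_id "T1"; protein_id "P1";',
          sep = "\t"),
    paste("chr1\tsrc\ttranscript\t101\t400\t.\t+\t.",
          'gene_id "G1"; transcript_id "T2";', sep = "\t"),
    paste("chr1\tsrc\texon\t101\t400\t.\t+\t.",
          'gene_id "G1"; transcript_id "T2";', sep = "\t")), ext = ".gtf")
}

test_that("read_gtf parses genes/transcripts and converts coordinates", {
  store <- read_gtf(toy_gtf())
  expect_s3_class(store, "AnnotationStore")
  expect_equal(nrow(store$genes), 1L)
  expect_equal(nrow(store$transcripts), 2L)
  expect_equal(sort(store$transcripts$is_coding), c(FALSE, TRUE))
  # GTF 101-130 (1-based inclusive) -> [100, 130), length 30
  ex <- store$exons[transcript_id == "T1"][order(start)]
  expect_equal(ex$start[1], 100L)
  expect_equal(ex$end[1], 130L)
  expect_equal(ex$end[1] - ex$start[1], 30L)
  expect_equal(store$transcripts[transcript_id == "T1"]$cds_length, 30L)
})

test_that("read_gtf reports structural errors with line numbers", {
  bad <- write_tmp(c(
    paste("chr1\tsrc\texon\t200\t100\t.\t+\t.",
          'gene_id "G1"; transcript_id "T1";', sep = "\t")), ext = ".gtf")
  expect_error(read_gtf(bad), "line 1.*end < start")
  bad2 <- write_tmp(c(
    paste("chr1\tsrc\texon\t100\t200\t.\t+\t.", 'gene_id "G1";',
          sep = "\t")), ext = ".gtf")
  expect_error(read_gtf(bad2), "line 1.*transcript_id")
})

test_that("read_interproscan_tsv maps fields, filters tools, rejects bad rows", {
  f <- write_tmp(c(
    "P1\tmd5\t100\tPfam\tPF00001\tdesc one\t10\t60\t1e-5\tT\tdate\tIPR000001\tipr desc",
    "P1\tmd5\t100\tPfam\tPF00002\tdesc two\t5\t20\t1e-5\tT\tdate\t-\t-",
    "P2\tmd5\t80\tPRINTS\tPR00001\tdesc\t1\t40\t1e-5\tT\tdate\tIPR000002\tx"))
  all_rows <- read_interproscan_tsv(f)
  expect_equal(nrow(all_rows), 3L)
  expect_equal(all_rows$aa_start[1], 10L)
  expect_equal(all_rows$aa_end[1], 60L)
  expect_equal(all_rows$interpro_acc[2], "")   # "-" stored as empty

  pfam <- read_interproscan_tsv(f, tools = "Pfam")
  expect_equal(nrow(pfam), 2L)
  expect_true(all(pfam$tool == "Pfam"))

  bad <- write_tmp(c("P1\tmd5\t100\tPfam\tPF00001\td\t60\t10\t.\tT\td"))
  expect_warning(res <- read_interproscan_tsv(bad), "rejected")
  expect_equal(nrow(res), 0L)

  # short rows (no trailing InterPro columns) are tolerated
  short <- write_tmp(c("P1\tmd5\t100\tPfam\tPF00003\td\t3\t9"))
  res <- read_interproscan_tsv(short)
  expect_equal(res$interpro_acc, "")
})

test_that("read_appris maps PRINCIPAL labels and defaults to FALSE", {
  f <- write_tmp(c("ENST0001\tPRINCIPAL:1", "ENST0002\tALTERNATIVE:2"))
  ap <- read_appris(f)
  expect_true(ap[["ENST0001"]])
  expect_false(ap[["ENST0002"]])
  store <- read_gtf(toy_gtf())
  ap2 <- read_appris(write_tmp(c("T1\tPRINCIPAL:2")))
  store <- apply_appris(store, ap2)
  expect_equal(store$transcripts[order(transcript_id)]$appris_principal,
               c(TRUE, FALSE))
})

test_that("projection matches spec examples", {
  # + strand, single CDS block [100,130), aa 1..1 -> first codon
  one <- data.table::data.table(start = 100L, end = 130L)
  pr <- project_aa_to_genomic(1, 1, one, "+")
  expect_equal(pr$blocks, data.table::data.table(start = 100L, end = 103L))

  # + strand, CDS [100,110)+[200,220), aa 2..5 -> offsets [3,15):
  # 7 nt from the first block, 5 nt from the second (12 nt = 4 codons)
  two <- data.table::data.table(start = c(100L, 200L),
                                end = c(110L, 220L))
  pr <- project_aa_to_genomic(2, 5, two, "+")
  expect_equal(pr$blocks,
               data.table::data.table(start = c(103L, 200L),
                                      end = c(110L, 205L)))
  expect_identical(pr$blocks, oracle_project(2, 5, two, "+"))

  # - strand, single block [100,130), aa 1..2 -> offsets [0,6) -> [124,130)
  pr <- project_aa_to_genomic(1, 2, one, "-")
  expect_equal(pr$blocks, data.table::data.table(start = 124L, end = 130L))
  expect_identical(pr$blocks, oracle_project(1, 2, one, "-"))
})

test_that("projection truncates incomplete terminal codons and rejects overshoot", {
  cds <- data.table::data.table(start = 0L, end = 10L)  # 10 nt, 3 full aa
  pr <- project_aa_to_genomic(1, 4, cds, "+")           # 3*4=12 > 10, by 2
  expect_true(pr$truncated)
  expect_equal(sum(pr$blocks$end - pr$blocks$start), 10L)
  expect_error(project_aa_to_genomic(1, 5, cds, "+"), "outside CDS")
  expect_error(project_aa_to_genomic(5, 6, cds, "+"), "outside CDS")
})

test_that("projection equals brute-force enumeration on random structures", {
  set.seed(101)
  for (i in 1:300) {
    cds <- random_cds()
    strand <- sample(c("+", "-"), 1)
    n_aa <- sum(cds$end - cds$start) %/% 3L
    if (n_aa < 1L) next
    a0 <- sample(n_aa, 1)
    a1 <- a0 + sample.int(n_aa - a0 + 1L, 1) - 1L
    pr <- project_aa_to_genomic(a0, a1, cds, strand)
    expect_identical(pr$blocks, oracle_project(a0, a1, cds, strand))
    expect_false(pr$truncated)
    expect_equal(sum(pr$blocks$end - pr$blocks$start),
                 3L * (a1 - a0 + 1L))
    # blocks sorted, disjoint, inside the CDS
    expect_true(all(diff(pr$blocks$start) > 0))
    expect_true(all(pr$blocks$start < pr$blocks$end))
  }
})

test_that("projection is symmetric under coordinate reflection", {
  set.seed(7)
  for (i in 1:50) {
    cds <- random_cds()
    C <- max(cds$end) + 17L
    mirrored <- data.table::data.table(start = C - rev(cds$end),
                                       end = C - rev(cds$start))
    n_aa <- sum(cds$end - cds$start) %/% 3L
    if (n_aa < 1L) next
    a0 <- sample(n_aa, 1)
    a1 <- a0 + sample.int(n_aa - a0 + 1L, 1) - 1L
    fwd <- project_aa_to_genomic(a0, a1, cds, "+")$blocks
    rev_ <- project_aa_to_genomic(a0, a1, mirrored, "-")$blocks
    expect_equal(rev_,
                 data.table::data.table(start = C - rev(fwd$end),
                                        end = C - rev(fwd$start)))
  }
})

test_that("build_store attaches features through the id normalizer", {
  man <- simulate_annotation(sim_config(n_genes = 2, seed = 5),
                             tempfile())
  store <- build_store(man$paths$gtf, man$paths$interpro,
                       man$paths$appris)
  expect_equal(nrow(store$features), man$totals$n_feature_rows)
  expect_equal(nrow(store$genes), man$totals$n_genes)
  expect_equal(nrow(store$transcripts), man$totals$n_transcripts)
  expect_equal(nrow(store$exons), man$totals$n_exon_rows)
  expect_equal(nrow(store$cds), man$totals$n_cds_rows)
  s <- attr(store, "summary")
  expect_equal(s$n_features, man$totals$n_feature_rows)

  # empty InterProScan file -> valid store with 0 features
  empty <- tempfile(); file.create(empty)
  store0 <- build_store(man$paths$gtf, empty, man$paths$appris)
  expect_equal(nrow(store0$features), 0L)

  # unknown protein ids land in unattached with a warning
  stray <- tempfile()
  writeLines("NOPE\tmd5\t50\tPfam\tPF09999\td\t1\t10", stray)
  expect_warning(s2 <- build_store(man$paths$gtf, stray), "unknown")
  expect_equal(nrow(s2$unattached), 1L)
})

test_that("interval index equals brute force on random queries", {
  man <- simulate_annotation(sim_config(n_genes = 5, seed = 11),
                             tempfile())
  store <- build_store(man$paths$gtf, man$paths$interpro,
                       man$paths$appris)
  set.seed(12)
  chrom_max <- max(store$features$span_end) + 1000L
  for (i in 1:200) {
    w <- sample(10:5000, 1)
    s0 <- sample.int(chrom_max, 1)
    got <- sort(query_features(store, "S1", s0, s0 + w)$feature_uid)
    f <- store$features
    want <- sort(f$feature_uid[f$span_start < s0 + w & f$span_end > s0])
    expect_identical(got, want)
  }
})

test_that("store round-trips through write_store/load_store", {
  man <- simulate_annotation(sim_config(n_genes = 3, seed = 9),
                             tempfile())
  store <- build_store(man$paths$gtf, man$paths$interpro,
                       man$paths$appris)
  dir <- tempfile()
  write_store(store, dir)
  back <- load_store(dir)
  expect_equal(back$features$feature_uid, store$features$feature_uid)
  expect_equal(back$transcripts$cds_length, store$transcripts$cds_length)
  expect_equal(nrow(back$blocks), nrow(store$blocks))
  # classification is identical on the reloaded store
  expect_equal(classify_all_genes(back), classify_all_genes(store))
})

test_that("GTF write-then-read preserves every interval", {
  man <- simulate_annotation(sim_config(n_genes = 3, seed = 21),
                             tempfile())
  store <- read_gtf(man$paths$gtf)
  out <- tempfile(fileext = ".gtf")
  write_gtf(store, out)
  back <- read_gtf(out)
  setorder_all <- function(s) {
    data.table::setorder(s$exons, transcript_id, start)
    data.table::setorder(s$cds, transcript_id, start)
    s
  }
  store <- setorder_all(store); back <- setorder_all(back)
  expect_equal(back$exons, store$exons)
  expect_equal(back$cds, store$cds)
  expect_equal(sort(back$transcripts$transcript_id),
               sort(store$transcripts$transcript_id))
})
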