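# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: projection by per-nucleotide enumeration,
# overlap by all-pairs scan, BH by the literal step-up recursion, and the
# Yates chi-square from its textbook formula.

# Per-nucleotide enumeration of the CDS coordinate map: list every coding
# genomic position 5'->3', index the codon range into it, and re-run the
# positions into blocks.
oracle_project <- function(aa_start, aa_end, cds_blocks, strand) {
  pos <- unlist(mapply(function(s, e) s:(e - 1L), cds_blocks$start,
                       cds_blocks$end, SIMPLIFY = FALSE))
  pos <- sort(pos)
  if (strand == "-") pos <- rev(pos)
  idx <- (3L * (aa_start - 1L) + 1L):(3L * aa_end)
  idx <- idx[idx <= length(pos)]
  g <- sort(pos[idx])
  breaks <- c(0L, which(diff(g) != 1L), length(g))
  data.table::data.table(start = g[breaks[-length(breaks)] + 1L],
                         end = g[breaks[-1L]] + 1L)
}

# All-pairs half-open interval overlap scan.
oracle_overlaps <- function(regions, features) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(features))) {
      if (sub("^chr", "", regions$chrom[i]) ==
          sub("^chr", "", features$chrom[j]) &&
          regions$start[i] < features$span_end[j] &&
          regions$end[i] > features$span_start[j])
        hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# Literal BH step-up: q_(i) = min over j >= i of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Yates-corrected chi-square on a 2x2 from the textbook formula.
oracle_chisq_yates <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((pmax(abs(m - e) - 0.5, 0))^2 / e)
  list(chi2 = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Random CDS structures for projection stress tests: 1-5 blocks with gaps,
# lengths not necessarily divisible by 3.
random_cds <- function() {
  n <- sample(1:5, 1)
  lens <- sample(3:60, n, replace = TRUE)
  gaps <- sample(1:50, n, replace = TRUE)
  start <- cumsum(c(sample(1:100, 1), head(lens + gaps, -1)))
  data.table::data.table(start = start, end = start + lens)
}

# Small fully hand-built store (bypasses the readers) for unit tests.
toy_store <- function(features = NULL) {
  dir <- tempfile("toy")
  man <- simulate_annotation(sim_config(n_genes = 2, seed = 42), dir)
  build_store(man$paths$gtf, man$paths$interpro, man$paths$appris)
}
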