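---
title: "Classifying alternatively included protein features across isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying alternatively included protein features across isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most multi-exon genes produce several transcript isoforms, and the protein
products of those isoforms can differ in which functional features —
Pfam/SMART/PRINTS domains, motifs, binding sites — they contain. A domain
encoded by an alternative exon is a candidate point of regulation: its
inclusion or exclusion rewires the protein. `altfeat` answers, per gene,
which predicted protein features are *constitutive* (encoded by every
candidate isoform) and which are *alternative* (encoded by only some), and
builds the companion analyses that sit on top of that classification:
region-list enrichment, cross-species conservation of domain status, and
GO-slim scans.

Inputs are the standard products of an annotation pipeline: an
Ensembl-dialect GTF (genes, transcripts, exons, CDS), InterProScan tabular
output (features in protein coordinates), and an APPRIS principal-isoform
list. Running InterProScan or APPRIS is out of scope — their outputs are
consumed as files.

## From amino acids to the genome

InterProScan reports features in 1-based amino-acid coordinates on a
protein. Internally every genomic interval is 0-based half-open. Amino
acid $i$ occupies CDS nucleotide offsets $[3(i-1), 3i)$ counted 5'→3'
along the coding sequence — from the leftmost CDS base on the + strand,
from the rightmost on the − strand. The offset range of a feature is
mapped through the transcript's ordered CDS blocks into one or more
genomic blocks; the *span* of a feature is the hull of its blocks,
introns included, which is what diagrams draw and what all overlap
operations use.

Ensembl contains CDS models without annotated start/stop whose length is
not divisible by 3. These transcripts are kept: protein length is
$\lfloor L/3 \rfloor$, and a feature whose final codon extends at most
2 nt past the CDS end is truncated and flagged rather than rejected;
anything further out is an error. Rejecting incomplete models outright
would bias which transcripts can carry features.

Identifier dialects differ between GTF and proteome-derived files
(`ENSP000….2` vs `ENSP000…`). Attachment of feature rows to transcripts
goes through a configurable id normalizer whose default strips one
trailing `.N` version suffix; rows that still match nothing are kept in
an `unattached` table and reported, never silently dropped.

## Grouping and the three standards

Feature instances on different transcripts are the *same* feature when
they share the member database and signature accession and their genomic
spans overlap by at least 1 nt; groups are the connected components of
this relation (transitive merge). Two deliberate choices here: grouping
never merges across accessions (distinct domains stay distinct even when
they overlap), and overlap is judged on spans, not exon-level blocks,
matching how features are drawn across intervening introns.

Each group is classified under three candidate-transcript standards:

* **coding** — all coding transcripts of the gene. Non-coding isoforms
  are always excluded: counting them would make every feature
  alternative.
* **cds_ratio(t)** — coding transcripts whose CDS length is at least a
  fraction *t* of the gene's longest CDS (that longest-CDS transcript is
  the *major isoform* and always qualifies; ties at ratio 1 all qualify).
  The comparison is inclusive (≥), so *t* = 1 keeps exactly the
  length-tied major isoforms; a strict `>` is available via
  `inclusive = FALSE`. Default *t* = 0.5.
* **overlap_cds** — coding transcripts whose CDS genomic span (first CDS
  base to last, introns included) entirely contains the group's span.
  Candidates vary per feature within a gene; this standard is the closest
  proxy for regulation by alternative splicing, since an alternative
  region is usually flanked by constitutive ones.

A group is **constitutive** iff every candidate transcript carries a
member instance, else **alternative**. Under `overlap_cds` the group hull
can (rarely) extend beyond a member's own CDS span when overlapping
instances of unequal extent merge; in that case presence is counted among
candidates only, keeping `n_present ≤ n_candidates` well defined. A
corollary: under `cds_ratio` a feature carried only by below-threshold
transcripts has `n_present = 0` — the classification is still
"alternative", and no positivity of `n_present` is assumed anywhere.

Because candidate sets shrink as *t* grows and the major isoform never
drops out, a group constitutive at *t* is constitutive at every larger
threshold; the suite asserts this monotonicity on every fixture.

## Enrichment between region lists

Given a target list (e.g. differentially spliced events) and a background
list, each region is annotated with every feature whose span overlaps it
by ≥ 1 nt ("chr" prefixes are normalized away). Per accession, the 2×2
table is regions-with vs regions-without the accession in each list — a
region counts at most once per accession however many instances it
touches, which keeps counts bounded by list sizes and the contingency
table valid (raw per-instance counting is available as an option). The
test is a chi-square with Yates continuity correction (configurable off;
the upstream stack's common default), BH-adjusted across accessions.
Cells with expected counts below 5 do not suppress the row; they set a
`low_expected` flag. The fold change

$$FC = \frac{c_t/n_t}{(c_t+c_b)/(n_t+n_b)}$$

is the target frequency over the pooled frequency, finite whenever the
accession is seen at all; it satisfies
$n_t\,FC_t + n_b\,FC_b = n_t + n_b$ under list swap.

## Homology and GO scans

Orthology is reciprocal best hit: per query, the target with the highest
query identity (ties broken by lexicographically smallest target id, so
results are deterministic and order-independent); a pair survives iff
each member is the other's best. Domain-status comparison counts
(gene pair, accession) units: an accession is one unit per gene however
many groups it forms, and a unit is alternative if *any* group of that
accession in the gene is alternative — one alternative instance suffices
to alter the protein. Both conventions are configurable through
`domain_units()`-style reprocessing but are the defaults everywhere,
including the splicing-potential correlation (Pearson + Spearman over
accessions passing a ≥ `min_count` filter in both species, undefined
below 3 retained accessions).

The GO scan compares each term's unit tallies against the genome-wide
tallies (term included — "genomic average" read literally; the
complement comparison is an option and differs negligibly for small
terms). Terms with zero units are excluded from the BH family rather
than given p = 1.

## What the synthetic fixtures emulate

Every simulated gene instantiates a five-transcript template: full-length
T1, exon-skipping T2, alternative-TSS T3, a short-CDS T4 whose length
ratio (300/804 ≈ 0.37) falls below the 0.5 default, and a non-coding
intron-retention T5. Gene 1 of every fixture carries the complete
template on the + strand; other genes draw random transcript subsets and
strands. This reproduces the isoform structures the classification
standards were designed around — it does **not** emulate realistic exon
counts, sequence content, domain-length distributions, or inter-gene
variation in transcript number, so a green fixture test establishes
correctness of the coordinate arithmetic and the classification logic,
not calibration on real annotation.

Two invariants make planted truth exact rather than approximate. Every
exon's CDS chunk is a multiple of 3 nt and every alternative CDS start is
offset by a multiple of 3, so all isoforms share reading frame at shared
positions; feature windows are then planted codon-aligned inside a single
CDS chunk. Consequently each member instance projects to exactly the
planted window, the group hull equals the window, and the true status
under each standard is plain set logic over the designed CDS spans —
computed in the generator without touching the classifier, projector or
grouper. The classifier must recover it for 100% of groups across 100
seeds; that test is diagnostic, not tautological.

Planted enrichment draws 200 + 200 regions with the planted accession at
4× the background rate of 0.1 — large enough that the Yates-corrected
test has essentially full power, which is what makes the ≥ 95/100
detection criterion meaningful rather than marginal. Identity fixtures
plant 50 reciprocal pairs plus one-way decoys and an equal-identity tie
whose lexicographic winner's own best hit lies elsewhere, exercising the
tie-break without changing the pair count.

## Numerical and degenerate-input choices

* Coordinates: 0-based half-open internally; GTF converted at the
  boundary, BED native; overlap everywhere means ≥ 1 shared nucleotide,
  so abutting intervals do not group or annotate.
* Genes with no coding transcript classify nothing; the caller is told
  rather than given empty-candidate records.
* Identity/pair ties: lexicographic, documented, asserted.
* BH is applied only over defined p-values; q is NA where p is NA.
* Region overlap is strandless (feature spans are strand-resolved, but
  genomic-coordinate comparison of regions ignores strand).
* All TSV outputs are written atomically (temp file, then rename), and
  re-running any subcommand on identical inputs and seed is
  byte-identical.

## Known limitations

Genome-scale claims (fractions of alternative domains in real human and
mouse annotation, ortholog counts from real BioMart tables) require full
Ensembl + InterProScan inputs and are deliberately outside the test
surface; the package provides the operations, not the downloads. The
diagram renderer is a plain base-graphics sketch meant for quick
inspection, not publication figures.
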