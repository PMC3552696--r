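---
title: "lincmir: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincmir: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lincmir discovers long intergenic non-coding RNAs (lincRNAs) ab initio from
strand-specific RNA-seq alignments and screens for miRNA-mediated
repression through reverse expression correlation. This vignette describes
the models and procedures the package implements, the assumptions behind
them, the synthetic-data generator that makes the whole pipeline testable,
and the numerical and design choices a user or maintainer should know
about.

## The discovery funnel

Candidate loci are genomic regions carrying the K4-K36 chromatin signature
(promoter H3K4me3 followed by gene-body H3K36me3) collected from two
sources: regions called natively in the target assembly and regions lifted
over from a second species. The pipeline narrows them in three steps, each
with a strict printed threshold:

1. **Gene distance.** The two source tracks are merged by coordinate union
   (`merge_and_exclude()`); any merged region overlapping or closer than
   `min_gene_distance` to a known gene is dropped. "Near" is not a
   universally fixed number; the default of 5,000 bp follows the convention
   of the chromatin-signature lincRNA catalogs, is exposed as a parameter,
   and a gap of exactly 5,000 bp is kept.
2. **Transcriptional activity.** RNA polymerase II ChIP tags are assigned
   to regions by their 5' position (single-point assignment, so a tag is
   never counted twice) and normalized to RPKM (reads per kilobase per
   million tags); regions strictly above 0.1 RPKM survive
   (`rpolii_filter()`).
3. **Coding potential.** A codon substitution frequency (CSF) score slides
   a 90-base (30-codon) window in 3-base steps across all six reading
   frames of a codon-resolved alignment; each window sums a log-odds
   matrix over its (reference codon, aligned codon) pairs, and the region
   score is the maximum over windows and frames (`csf_score()`). Regions
   scoring strictly above 20 are excluded as likely unannotated
   protein-coding genes. Regions shorter than one window are scored over
   their maximal in-frame stretch and flagged. The log-odds matrix is an
   input artifact: training a mammalian CSF model from whole-genome
   alignments is out of scope, and the generator emits a matched synthetic
   matrix (identity `+1`, substitution `-1`, gap `-1`) whose lookup
   semantics are the same as a trained table's.

## Transcript assembly

Within each surviving region, putative exons are maximal intervals of
nonzero read coverage; intervals separated by fewer than 10 bases are
merged (iterated to a fixpoint, which is order-independent), and intervals
supported by at least 8 distinct reads are kept. "Contains at least 8
reads" is interpreted as *overlapped by* 8 distinct reads, which is robust
to read ends straddling the exon boundary.

Splice donor (GT, or CT for Crick-strand introns, read off the reference)
and acceptor (AG / AC) dinucleotides are searched within 25 bases of the
natural intron boundaries of each exon pair. Every motif-compatible
(donor, acceptor) pair with intron length between 70 and 100,000 bases
yields one junction-library entry: the exonic flank upstream of the donor
concatenated with the flank downstream of the acceptor, stored in
*transcript orientation* (minus-strand entries are reverse-complemented)
so that strand-specific reads match directly. The flank length is
`read_length - 1`, the smallest value such that any junction-spanning read
fits entirely within an entry.

Genome-unmapped reads are matched against the library ungapped with at
most 2 mismatches, requiring an 8-base overhang on both sides of the
junction point; each read supports at most one junction (fewest
mismatches; ties between junctions are dropped). Exact matches are
resolved through a hash of all anchor-compatible windows; reads without an
exact match fall back to a mismatch scan behind a pigeonhole prefilter
(with at most 2 mismatches over 3 disjoint chunks, one chunk must match
exactly). The anchor and mismatch policy is not dictated by any standard;
both are parameters.

Supported junctions connect exons into transcripts: exons are nodes,
junctions edges, and each connected component becomes one transcript with
exon boundaries refined to the junction coordinates (best-supported
junction wins per exon side) and strand taken from the junction motifs.
This connected-component assembler is a declared simplification of full
statistical segmentation of the read graph; its adequacy is not assumed
but measured — on generator output at the default depth it recovers
planted multi-exon structures exactly (all exon coordinates equal) in
more than 90% of cases, which the acceptance suite checks.

## Seed-match target prediction

Because a noncoding transcript is untranslated end to end, sites are
predicted over the entire spliced sequence. Site classes follow the
TargetScan convention, anchored on the miRNA seed (positions 2-7, extended
2-8): `7mer-m8` is the reverse complement of positions 2-8; `7mer-A1` is
the reverse complement of positions 2-7 followed by an A on the
transcript; `8mer` satisfies both. Each occurrence is reported once under
its most specific class, all overlapping occurrences are reported (no
greedy masking), and the (miRNA, lincRNA) *pair* list is distinct from the
*site* list. U and T are interchangeable internally. Sites are
back-projected through the exon map to genomic blocks (a site may cross a
junction), and every site gets a length-matched control interval 100 bases
upstream on the transcript; sites whose control would run off the
transcript are dropped from the paired comparison and counted.
Thermodynamic (accessibility / free-energy) site scoring is a non-goal.

## Expression quantification

A read counts for a feature when any aligned block overlaps the feature's
exonic bases on the same strand, at most once per feature; reads ambiguous
between two features count for both (no EM rescue — declared and logged).
RPKM is `count / (exonic_kb) / (mapped_millions)`. miRNA abundance is
quantified on the annotated precursor locus — the ~80-120 nt hairpin is
what bulk RNA-seq can see — and the package deliberately makes no claim
about mature-miRNA abundance. The detectability filter keeps features
above 0.5 RPKM in strictly more than 15 of the 20 samples, counted
globally over both conditions.

## The repression model

For each candidate pair the target's counts are modeled as

$$\ln E[y_s] = \beta_0 + \beta_1 x_{1s} + \beta_2 x_{2s}
  + \beta_3 x_{1s} x_{2s} + \ln M_s$$

with $x_1$ the miRNA's natural-log reads per million, $x_2$ the condition
(normal 0, tumor 1), $\ln M$ the log total mapped reads as offset, and
quasi-Poisson variance $\phi\mu$. The fit is iteratively reweighted least
squares (deviance tolerance $10^{-8}$, at most 100 iterations;
non-converged pairs are flagged and excluded); $\phi$ is the Pearson
$\chi^2$ over the residual degrees of freedom; coefficients are tested
with two-sided t statistics on those degrees of freedom. If the
interaction is not significant at 0.05 the pair is refit without it and
$\beta_1$ is tested in the reduced model, with $\phi$ re-estimated on the
reduced fit's own residual degrees of freedom. Pairs eligible for fitting
are those with a predicted seed match whose two members both pass the
detectability filter.

"Reverse correlation" is operationalized as $\beta_1 < 0$ *and*
Benjamini-Hochberg FDR below 0.2 on the $\beta_1$ p-values — the sign
requirement is implied rather than stated by the convention the procedure
follows, and making it explicit costs nothing when the test is two-sided.
FDR is computed separately per family (gene-miRNA vs lincRNA-miRNA) by
default, since the two families are reported separately; pooling is a
switch. `fit_pair()` returns a classed object with the usual `print`,
`summary`, `coef`, `vcov`, `predict`, `residuals`, `simulate` and `plot`
methods; `simulate()` draws from a negative binomial moment-matched to
$\phi\mu$ (plain Poisson when $\phi \le 1$), the same convention the
generator uses, because the quasi-Poisson family fixes only the first two
moments and the NB is the standard realization.

## Conservation scoring

Conservation of a genomic window is summarized by a rate multiplier
$\omega$: all branch lengths of a fixed phylogenetic tree are scaled by a
single shared $\omega$ and the Jukes-Cantor likelihood of the window's
alignment columns is maximized over $\omega \in [0, 10]$ by bounded 1-D
optimization (tolerance $10^{-6}$), with Felsenstein pruning and pattern
compression. Smaller $\omega$ means more conserved. Gaps and Ns are
missing data (marginalized); columns with fewer than two informative taxa
or gaps in more than half the taxa are skipped and tallied; a block with
no observable substitution returns exactly $\omega = 0$ (the boundary
optimum). This deliberately replaces a full phylogenetic scoring model
(HKY with per-site rate posteriors): every downstream use here is ordinal
— rank-sum and signed-rank comparisons between site classes — for which a
consistent monotone estimator suffices. $\omega$ is reported relative to
the input tree's scale (rescaling the tree by $1/c$ rescales $\omega$ by
$c$). On two taxa the estimate equals the closed-form JC distance divided
by the tree path length, which the tests exploit as an oracle.

Sites of reverse-correlated pairs are compared to other predicted sites
(two-sided rank-sum) and to their own upstream controls (paired
signed-rank); exact distributions are used when sample sizes permit and
no ties occur, the normal approximation otherwise.

## The synthetic-data generator

The generator produces every input the pipeline consumes — genome FASTA,
known-gene and candidate-region BED, per-sample spliced alignments
(BED12), raw FASTQ records, pre-miRNA annotations and mature miRNA FASTA,
ChIP tags, CSF alignments and matrix, MAF plus newick tree — with planted
truth tables sufficient to score every stage. Its defaults are the study
conditions: 10 normal + 10 tumor samples, 50 candidate regions (15 with a
planted 3-5-exon lincRNA, 8 near genes, 5 coding-like, 22 background), 10
miRNAs, 10 planted repressed pairs with $\beta = (\beta_0, -0.8, 0.3, 0)$
and $\phi = 1.5$, 50-base reads, and a 5-taxon alignment. Everything is
deterministic given the seed: identical configurations produce
byte-identical files, and the op-level streams are decoupled by fixed
small offsets from the one seed.

Choices the source conventions do not fix, made once:

* **Depth.** The sequencing depth of the reference design is not stated;
  the generator exposes `mean_depth` (default 50,000 mapped reads per
  sample) rather than guessing, and sizes lincRNA abundance so each
  transcript draws roughly 600 reads per sample. At that depth every
  transcript position is covered with high probability, which is what
  makes *exact* recovery of planted exon boundaries a fair target for the
  assembler; read starts are uniform over the spliced transcript with no
  forced terminal reads.
* **Overdispersion** is realized as negative binomial with variance
  $\phi\mu$ — the quasi-Poisson family names no unique law, and NB matched
  by moments is the standard choice.
* **miRNA covariate.** $x_1$ is drawn per sample from a normal law (mean
  9 ln-RPM ≈ 8,000 reads per million, s.d. 1) shared across a miRNA's
  pairs, mirroring one miRNA targeting many transcripts; precursor counts
  are generated from that abundance so the pipeline re-derives $x_1$ from
  data.
* **Reads** are emitted pre-aligned: exon-contained reads as single-block
  BED12 records (what a genomic aligner maps), junction-spanning reads as
  raw sequence+quality records (what it leaves unmapped) — simulating an
  aligner is out of scope. Every true junction is guaranteed at least one
  well-anchored spanning read. A configurable fraction of decoy records
  carries planted QC defects (N runs, low-quality tails) to exercise the
  QC rules; defects are planted on decoys, not on junction reads, so QC
  cannot silently delete junction evidence.
* **Conservation structure.** Rate multipliers are 0.2 at repressed-pair
  seed sites, 0.6 at other planted sites, 0.8 over remaining lincRNA
  exonic bases and 1.0 elsewhere, so the pipeline's two conservation
  comparisons have a true ordered signal; the reference taxon hangs off
  the tree root on a zero-length branch so its alignment row equals the
  genome. Eight-column sites make $\hat\omega$ noisy; the ordering is
  recovered by the rank tests across sites, not per site.
* **Coordinates** are 1-based closed in memory — the GRanges convention
  used by the entire R interval stack this package builds on — and
  0-based half-open on disk in BED, with the shift handled at the I/O
  boundary.

What the generator does **not** emulate: sequencing error inside junction
reads (the mismatch path of the matcher is exercised by dedicated tests
instead), positional coverage bias, isoform mixtures, color-space error
profiles, mapping ambiguity, and genome-scale repeat structure. Passing
the end-to-end checks therefore demonstrates that the machinery is
correct under the generative assumptions, not that the biological
conclusions of any particular dataset are reproduced.

## QC rules

Raw reads pass three ordered rules: more than two N bases discards the
read; a 5-base window scanned 5' to 3' truncates the read at the first
base of the first window whose mean quality falls strictly below 20
(window sums are compared as integers, so the boundary is exact); a
surviving length under 35 discards it. "Truncated at that position" is
read as cutting at the offending window's first base — the entire
detected low-quality region is removed — and the N rule runs first
because it is listed first. Reads shorter than the window pass the scan
untruncated. Under this prefix-cut rule, whether the scan restarts after
truncation is moot.

## Problem sizes and runtime

The test and acceptance workloads are sized for a single CPU: oracle
equivalence runs ~285 random instances per operation; model calibration
uses 500 recovery replicates and 2,000 null replicates at n = 200;
$\omega$ consistency uses 10,000 columns on the 5-taxon tree; the
end-to-end check is one full default-scale run (about one million reads)
plus 20 repeated count-level cohorts for pair-call sensitivity and
empirical FDR. Pair-call operating characteristics depend only on the
count model, so the repeated cohorts run the counts → quantification →
GLM → FDR path; the full read-level pipeline is exercised by the single
complete run that also feeds the assembly, site-recall and conservation
checks.

## Known limitations

* The assembler cannot separate overlapping isoforms or same-component
  alternative structures; it returns one transcript per connected
  component.
* Single-exon transcripts get no strand from junction motifs; downstream
  seed scanning treats them as plus-strand.
* $\hat\omega$ at a 7-8 base site is a high-variance estimate; only rank
  comparisons across many sites are meaningful, which is how the pipeline
  uses it.
* The quasi-Poisson t-tests are asymptotic in the number of samples; at
  n = 20 they are adequate (and standard) but not exact.
* Pre-miRNA counts proxy mature miRNA abundance imperfectly; conclusions
  about specific pairs need orthogonal validation.
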