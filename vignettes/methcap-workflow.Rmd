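---
title: "Methods: quality control and group-level analysis of MethylCap-seq cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and group-level analysis of MethylCap-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcapr)
```

## The assay and the analysis problem

MethylCap-seq (and the closely related MBD-seq) enriches methylated DNA
fragments with the methyl-CpG binding domain of MBD2 and sequences the
captured fragments as short single-end reads. Two failure modes dominate in
practice: an unsuccessful capture reaction, which yields a library that looks
like ordinary input DNA, and a low-complexity library, whose methylation
calls would not reproduce on resequencing. Both must be caught *before*
group-level statistics, because spurious samples inflate noise in every
downstream comparison. methcapr implements the complete desk-side workflow:
per-sample experimental QC with an exclusion policy, genomic binning with
depth normalisation, multi-group differential methylation, a global
per-sample methylation summary (GMI), filtered hierarchical clustering with
bootstrap support, and genome-browser track export.

All coordinates in the package are 0-based half-open (the BED convention);
SAM input (1-based) is converted on ingestion.

## Read processing

Reads arrive as SAM (we consume the aligner's output; running the aligner is
out of scope) or as pre-filtered 6-column BED. Unmapped and secondary SAM
records are always dropped; with `unique_only = TRUE` records with mapping
quality 0 — the common multi-mapper convention — are dropped too. PCR
duplicates are removed by keeping the first read per (chromosome, strand, 5'
position) key, the standard single-end semantics; the duplicate key
deliberately ignores the 3' end because trimming can vary read length within
a duplicate family. Deduplication precedes extension.

Each read is then extended to the average fragment length from its 5' end
(`extend_reads()`, default 300 bp, configurable): a 36-bp read stands in for
a ~300-bp captured fragment, and every overlap-based quantity downstream
(binning, enrichment, coverage) is computed on fragments, not raw reads.
Extended intervals are clipped at chromosome boundaries.

## Experimental QC

Four metrics are computed per sample (`compute_qc()`):

* **Alignment rate** — uniquely aligned reads / pass-filter reads, using the
  sequencer's library totals.
* **Saturation** — a Pearson-correlation estimate of library complexity. The
  deduplicated reads are split at random into two halves; each half is
  binned (500 bp, unextended) and the correlation of the two count vectors
  is traced along a subsample grid ending at the full halves. The value at
  fraction 1 is the *observed* saturation; the *estimated* saturation
  resamples each half with replacement up to the full library size, which
  projects the correlation expected if the library were sequenced twice as
  deep. The literature names only "a Pearson correlation coefficient
  estimation of library complexity"; the bipartition, the grid, and
  doubling-by-resampling are this package's reconstruction, fixed
  and seeded so results are reproducible. Thresholding uses the estimated
  value; both are reported. Saturation uses unextended reads: extension
  correlates neighbouring bins mechanically and would flatter low-complexity
  libraries.
* **CpG enrichment** — the CpG frequency inside extended read intervals
  divided by the genome-wide CpG frequency. A dimer must lie fully inside
  an interval to count. Non-captured input DNA scores near 1, successful
  captures well above it; the simulation-based tests verify both regimes.
* **CpG coverage (5x)** — the fraction of genomic CpG sites overlapped by at
  least five extended reads.

The exclusion policy (`qc_flag()`): a metric passes at `>=` its threshold;
an incomputable metric (e.g. saturation on a degenerate track) counts as a
failure; a sample is excluded when it fails **two or more** metrics. Valid
samples occasionally fail one. Defaults: enrichment 1.4 and saturation 0.5
(the published operating points), alignment rate 0.5 and 5x coverage 0.05.
The latter two have no published value — reference lines in the original
figures are not machine-readable — so they are plainly labelled
configuration, not literature constants.

## Binning and feature extraction

`count_bins()` counts extended reads into fixed 500-bp bins — a resolution
that smooths statistically while resolving CpG islands — crediting a read to
*every* bin its fragment overlaps. The alternative (5'-bin assignment) was
rejected because extension exists precisely so that fragments covering a bin
contribute to it. Counts are scaled to reads per million (rpm = count x 1e6 /
total reads) so samples of different depth are comparable. Tracks persist in
a compact binary format (magic `MCBC`, little-endian, counts as u32, rpm as
f32, trailing CRC32) that round-trips bit-exactly; a plain-text export
exists for interoperability.

Feature-level values (`extract_feature_counts()`) sum the rpm of all bins a
locus overlaps; partial overlaps count fully. This is the simplest rule
consistent with interrogating a binned track by feature and is stated here
so users can compare against length-weighted alternatives.

## Differential methylation

Methylation is compared per locus across predefined groups with rank-based
tests: Wilcoxon rank-sum for two groups, Kruskal–Wallis beyond. Tests are
two-sided (hyper- and hypomethylation are equally interesting); the exact
Wilcoxon null is used up to a combined n of 20 without ties, the
tie-corrected normal approximation with continuity correction otherwise.
Loci whose values are identical across all samples return p = 1 rather than
NaN so that multiple-testing adjustment stays well defined. Adjustment is
Benjamini–Hochberg, applied **within** a feature class (promoters are one
family, islands another); adjusting across classes jointly would couple
unrelated analyses. The α default is 0.05.

## Global Methylation Indicator

Every 500-bp bin is classified by its CpG content, counting a dimer that
straddles the boundary into the *earlier* bin (so no dimer is counted twice
and none is lost — classification over a chromosome conserves its CpG
total, which is tested). A dimer whose C is the final base of a chromosome
does not exist in sequence and is not a site. Classes above 30 are pooled
into the top class: bins with more than 30 CpGs are rare, and their
singleton classes would otherwise contribute wildly unstable means. The
Methylation Distribution is the mean rpm per bin within each class; the GMI
is the area under that curve by the trapezoidal rule, interpolating linearly
across empty classes. Class 0 (CpG-free bins) is part of the curve. The AUC
estimator, the cap, and empty-class handling are this package's documented
choices; the source literature specifies none of them. Groups of GMIs are
compared with a Welch two-sample t-test (robust to unequal variances; "a
t-test" is all the literature pins down).

## Clustering

Loci are filtered by **strict** thresholds — mean rpm > `min_avg_rpm` AND
CV > `min_cv` — matching the published "avg rpm > 10 and CV > 5" notation.
The mean filter removes poorly captured, noisy loci; the CV filter keeps the
loci that actually vary between samples. Optionally each locus is rescaled
by its mean (row mean exactly 1 afterwards), which lets the Pearson
correlation weight low- and high-rpm loci evenly; raw values weight high-rpm
loci more. Both modes are exposed because the right choice depends on the
features of interest. Samples are clustered on the Pearson correlation
distance (1 − r) with McQuitty/WPGMA linkage by default. The agglomeration
is implemented in the package with a deterministic tie-break (the smallest
pair of cluster indices wins) so dendrograms reproduce across platforms;
it is verified against the reference `stats::hclust` implementation on
random matrices.

Cluster confidence comes from resampling loci with replacement and
reclustering (`bootstrap_support()`). With a single scale the plain
bootstrap proportion is reported; with a multiscale grid an approximately
unbiased (AU) p-value is fitted per node by the standard two-parameter
probit regression (signed distance and curvature) of `qnorm(1 − bp)` on
`sqrt(r)` and `1/sqrt(r)`. Cluster identity across replicates is exact
leaf-set equality. Numerical replication of any specific bootstrap
package's AU values is a non-goal; the contract is the method.

Because many dendrograms are produced (feature classes x filter settings),
`track_groups()` cuts a reference dendrogram, colours its k largest clusters
(blue/red for k = 2, in left-to-right dendrogram order), and carries those
colours onto the leaves of every other dendrogram; leaves outside the
tracked clusters are black. Conservation of a grouping across dendrograms
is evidence it is not an artefact of one filter setting.

## Visualization tracks

`export_bedgraph()` writes standard 4-column bedGraph (optionally
run-length-merged, optionally zero-suppressed). The discretized heatmap
track percentile-ranks a sample's binned rpm (midrank convention for ties),
maps rank to one of L levels (`min(floor(rank x L), L - 1)`, default L = 10,
white-to-red), and emits one interval row per bin; stacking rows across
samples builds the cohort heatmap. Ranks are computed per sample over the
genome-wide bin set by default — so a deep and a shallow library are
directly comparable — with a region-restricted mode for locus views. The
discretization depends only on the ordering of rpm values, never their
scale, which is tested under random monotone transforms. The original
web-service track formats are replaced by documented flat-file dialects;
serving infrastructure is out of scope.

## The simulator: what it emulates, and what it does not

No study data accompany the methodology, so `sim_config()` /
`simulate_genome()` / `simulate_methylome()` / `simulate_reads()` /
`simulate_cohort()` generate the full study: a single-chromosome reference
built from dinucleotide slots (CpG islands at high slot density on a
CpG-poor background; non-CpG slots never end in C, so the realised CpG
density equals the configured one exactly); a methylome that methylates each
CpG independently by compartment; and libraries whose fragment start
weights are `1 + enrichment_strength x (methylated CpGs in the fragment
window)` — strength 0 gives the uniform "input" library. Defaults: 2 Mb
genome, 100 islands of 1 kb, island slot density 0.15 vs background 0.01,
island methylation 0.8 vs background 0.05, 36-bp reads, 300-bp fragments,
200,000 reads — a deliberately small but structurally faithful rendition of
a capture experiment. All randomness flows from one master seed with
documented per-sample derivation, so any single library is regenerable.

The weight model is the simplest monotone stand-in for capture chemistry; it
is a test fixture, not a claim about MBD binding. Note that fragment weights
are renormalised per library, so rpm is a *relative* measure exactly as in
real enrichment sequencing: hypomethylating the designated loci of one group
shifts reads onto that group's remaining loci, and unperturbed loci can show
modest compensatory differences. Group comparisons on simulated cohorts
exhibit this compositional coupling deliberately. The simulator has no
sequencing errors, base-quality structure, GC amplification bias, mappability
gaps, or paired ends. Tests passing on it therefore demonstrate the
*algorithms* — calibration of enrichment regimes, statistical honesty of the
tests, recovery of planted group structure — not robustness to every
artefact of real libraries.

## Numerical and design notes

* Degenerate inputs: all-equal loci give p = 1; zero-variance sample columns
  abort clustering with the sample named; empty readsets make enrichment
  incomputable (a QC failure) and coverage 0; an all-zero track has rpm 0
  and GMI 0.
* rpm is stored as 32-bit floats in the binary codec; a round trip
  reproduces counts exactly and rpm at f32 precision, and write-read-write
  is byte-stable.
* Bootstrap replicates whose resampled matrix has a zero-variance sample are
  dropped from the support denominator rather than counted as failures.
* Test problem sizes are chosen to exercise cohort-scale behaviour at desk
  scale: 2 Mb genomes and 200k reads for the enrichment calibration; 200 kb
  genomes and 8k reads per sample for the 5+5-sample GMI and clustering
  recovery batteries (20 and 10 seed replicates respectively); 2,000 loci
  for null-uniformity checks.

## Known limitations

Single-end data only; no covariate adjustment or paired designs in the
differential module (rank tests on groups are the contract); no negative
binomial count model; promoter definitions are not derived from gene models
(users supply feature BED files); the QC alignment-rate and coverage
thresholds are conventions to be tuned per project. The published clinical
cohort figures (exclusion counts, the 2.70 +/- 0.35 enrichment of a specific
ovarian cancer dataset) depend on patient data that were never deposited and
are not reproducible here; what the package can and does verify is the
behaviour of each method on data with known ground truth.
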