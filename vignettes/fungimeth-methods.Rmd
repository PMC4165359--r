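---
title: "Methods: models, parameters and design choices in fungimeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in fungimeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fungimeth` analyses whole-genome bisulfite sequencing (WGBS) of
repeat-rich fungal genomes, where cytosine methylation acts as a
transposon-silencing system. This vignette explains the statistical
models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable convention exists. None of
the numbers quoted here are empirical claims about real genomes; they
are the properties of the package's own models, and each one is
exercised by the test suite or by `scripts/acceptance.R`.

## The methylation-level estimator

Bisulfite treatment converts unmethylated cytosine to uracil (read as
T) while 5-methylcytosine is protected. After alignment, a cytosine
covered by `n` informative reads with `#C` unconverted and `#T`
converted observations has estimated methylation level

$$\hat m = \frac{\#C}{\#C + \#T},$$

the fraction of cells methylated at that position. The estimator is
binomial: at true level $m$ and depth $n$ its standard error is
$\sqrt{m(1-m)/n}$, which the acceptance checks verify empirically at
$n \approx 30$. Two systematic effects are modelled:

* **Incomplete conversion.** An unmethylated C escapes conversion with
  probability $\varepsilon$ (default 0.005), so the apparent level is
  $m + (1-m)\varepsilon$ — an upward bias of at most $\varepsilon$.
  Conversion efficiency of a real library should be measured (e.g. from
  an unmethylated spike-in) and passed as `error_rate` to the caller.
* **Coverage filtering.** Levels are reported only at sites with at
  least `min_coverage = 4` informative reads. Below that the estimator
  is too coarse (multiples of 1/3 or worse) to be useful.

Counting is strand-aware: Watson-origin reads vote at plus-strand C
positions (C methylated, T unmethylated), Crick-origin reads vote at
minus-strand cytosines through their plus-strand projection (G
methylated, A unmethylated). Any other base is a mismatch and casts no
vote — counting mismatches as unmethylated would deflate levels by the
sequencing error rate, so they are excluded instead.

Context is classified from the reference, not the reads: CG if the next
base on the cytosine's strand is G, else CHG if the base after that is
G, else CHH (H = A, C or T). Sites whose neighbors are off-contig or N
are "unknown" and excluded from context-stratified summaries. The
classifier is tested exhaustively against a brute-force oracle over all
4^5 5-mers on both strands.

**Calling a site "methylated".** A bulk statistic like "fraction of
covered cytosines methylated" needs a per-site call rule. The package's
default is a one-sided binomial test of `#C` against the non-conversion
rate with Benjamini–Hochberg control across sites (`fdr = 0.05`), which
is standard WGBS practice; a naive `level > 0` mode is provided for
sensitivity analysis. Per-context bulk means are site-weighted (every
covered site counts once), not read-weighted; the read-weighted
alternative is available at the feature level.

## Feature-level summaries

Feature methylation defaults to the **site-mean** (average of per-site
levels inside the feature, per context), with **read-weighted**
($\sum \#C / \sum(\#C+\#T)$) as an option; the site-mean treats every
cytosine equally regardless of its depth and is the convention used by
the differential caller's mean-level filter.

Meta-plots rescale each feature body to `body_bins` relative bins
(default 20) and cut flanks of `flank` bases (default 1000) into fixed
100-bp bins; minus-strand features are mirrored so bin 1 is always the
5' end. A site in a feature shorter than `body_bins` bases overlaps
several relative bins and contributes to each proportionally, so short
features neither error nor distort the profile. Bin values are
per-feature means averaged across features without weighting, so large
features do not dominate.

The gene-proximity profile splits genes at expression quartiles
(top/bottom 25% of RPKM among genes with RPKM > 0, nearest-rank ties)
and collects CG methylation of TE cytosines within 1 kb of gene ends.
Tiled 100-bp distance windows are used rather than a sliding average —
tiled windows keep every site in exactly one bin, which makes the
companion t-tests independent of the plotting grid. TEs overlapping a
gene are excluded because their distance is undefined. Welch's
unequal-variance t-test is used here and everywhere a two-sample
comparison is reported, since group variances are never assumed equal.

## Differential methylation

For two samples called on the same genome, per-site
$\Delta m = m_A - m_B$ is computed at sites with valid levels and
matching context in both samples. For each feature with at least
`min_sites = 4` eligible sites in a context class (CG and CHG+CHH are
analyzed separately), the mean $\Delta m$ is standardized against the
across-feature distribution of mean $\Delta m$ of the same feature kind
and class:

$$z = \frac{\overline{\Delta m} - \mu}{\sigma}.$$

A feature is called differentially methylated when $|z| > 1.96$ *and*
its feature-level mean methylation differs by at least 20 percentage
points (TEs) or 10 (genes) — the reduced gene cut reflects their much
weaker absolute methylation. Two genuinely open conventions were
settled as follows:

* **Reference distribution for z.** The across-feature empirical
  distribution was chosen (a feature is extreme relative to how much
  features of its kind move genome-wide). The within-feature
  alternative — mean over its standard error — is exposed via
  `z_mode = "within-feature"` but is not the default: it conflates
  site count with effect size.
* **Standardization scope.** Global per kind (all TEs together), not
  per TE subclass: subclasses can be small enough to make $\sigma$
  unstable.

Because $z$ is standardized against the empirical distribution, a pure
null run flags $|z| > 1.96$ at very close to 5% of features before the
mean-difference filter, and essentially none after it — both properties
are asserted on simulations with 550 features.

## Copy-number variation

Read depth is averaged in fixed windows (default 100 kb, truncated at
contig ends) and normalized by each sample's total mapped bases, so a
genome without copy-number differences has ratios centered at 0
regardless of library sizes. The reported statistic is the natural log
ratio $\ln(d_A/d_B)$; windows with $|\ln\text{ratio}| \ge 0.3$ are
marked and adjacent marked windows of equal sign merge into maximal
regions. Natural log was chosen to match the fold interpretation
$\ln 2 \approx 0.69$ for a duplication; with the 0.3 cut, a ~1.35-fold
change is the detection floor. Note that normalization couples regions
to the rest of the genome: a fold-2 amplification occupying share $s$
of the genome yields an in-region ratio of $\ln(2/(1+s))$, a shrinkage
of about 0.05 when $s = 5\%$. No GC correction or HMM segmentation is
applied — threshold-and-merge on 100-kb windows is deliberately simple
and transparent, and both the merged-region count and the raw
significant-window count are reported because the two can differ.
Feature enrichment assigns features to CNV space by midpoint, and the
methylation comparison between CNV and non-CNV TEs uses the two-sample
Kolmogorov–Smirnov test, which is sensitive to distribution shape, not
just the mean.

## Composite RIP index

Repeat-induced point mutation (RIP) converts CpA to TpA within repeats,
leaving a dinucleotide skew. The composite index is

$$\mathrm{CRI} = \frac{TpA}{ApT} -
  \frac{CpA + TpG}{ApC + GpT},$$

product minus substrate: the first ratio scores accumulated RIP
products against a local-density baseline, the second the depletion of
targets and their reverse complements. Counts are overlapping
dinucleotides on the given strand; pairs containing N are skipped.
Zero denominators make the score undefined (`defined = FALSE`) rather
than ±Inf, and windowed summaries skip undefined windows. A useful
identity: reverse complementation maps TpA↔TpA, ApT↔ApT, CpA↔TpG and
ApC↔GpT, so the CRI is exactly strand-invariant; the `symmetrized`
option therefore returns the same value and exists only so
strand-handling is explicit in the interface. Per-repeat scores use
the repeat's annotated strand. The package also provides
`rip_mutate()`, which applies C→T at CpA (and G→A at TpG, the other
strand's CpA) at a given probability; the CRI responds monotonically to
the mutation load, which the tests check at p = 0, 0.25, 0.5, 0.75.

## Expression and its association with methylation

RPKM is $10^9 \cdot \text{count} / (\text{length} \cdot
\text{total mapped})$ with gene length the union of exon intervals
(overlaps counted once) and TE length the full element; `RPKM ≥ 1`
defines "expressed". Counts are expected to contain only reads fully
contained in a single feature — reads spanning boundaries are the
counter's concern, not this package's. Fold-changes between conditions
use a pseudocount of 0.25 RPKM so that silent TEs (RPKM 0 in both
conditions) have log2 fold-change exactly 0 instead of being dropped;
0.25 is a quarter of the expressed threshold, small enough not to mask
real induction. Expression is log2-scaled everywhere. The
demethylation-response analysis bins TEs at a 5-percentage-point delta
methylation cut by default, with arbitrary bin edges available since
finer response strata are study-specific.

## The synthetic-data generator

The generator produces the study conditions the analyses assume:

* **Genome organization** — scaffolds alternate gene blocks and TE
  islands. The default TE fraction is 0.58 (a heavily repetitive
  genome); island size defaults to 30 kb and the block length is
  derived from the island size and TE fraction so realized occupancy
  tracks the target within ±5 points. TE subclasses are sampled with
  Gypsy LTR retrotransposons dominant (weight 0.5). A configurable 10%
  of TEs are placed inside gene blocks within 1 kb of a gene so
  proximity analyses have signal. Gene lengths are ~1.5 kb with 1–3
  exons; sequences are i.i.d. with 46% GC.
* **Methylome** — TE cytosines draw CG levels from a spike-and-slab
  mixture (components near 0.92 and 0.03) mixed to hit the configured
  mean of 0.80 while keeping the CG landscape bimodal (little mass in
  (0.1, 0.8)); TE non-CG levels are a broad beta with mean 0.30;
  non-TE cytosines draw from low-mean betas (CG 0.01, non-CG 0.005).
* **Reads** — uniform starts on both strands at `coverage` per strand
  (default 15, i.e. ~30X informative depth per cytosine, since only one
  strand informs each site); per-read Bernoulli methylation at the
  site's true level; conversion failure 0.005 and uniform sequencing
  error 0.001 by default — the real study's conversion efficiency is
  not published, so these are conventional Illumina-era values and are
  configurable. Reads carry true coordinates: alignment is out of
  scope, so the generator emits what a perfect aligner would report.
* **Expression** — negative-binomial counts (dispersion 2) with
  methylation-independent log-normal gene rates and TE rates declining
  log-linearly in CG methylation (slope 4), giving the inverse
  methylation–expression relation. Only the direction and monotonicity
  of this effect matter to the analyses.
* **CNV planting** — extra reads drawn from the same bisulfite model
  multiply depth by `fold` in chosen regions of one sample
  (`fold < 1` thins instead), with a truth table recording
  $\ln(\text{fold})$.

Everything is driven by R's RNG from a single seed per operation, and
reruns are byte-identical. What the generator does **not** emulate:
PCR duplicates, M-bias along reads, quality scores, mapping ambiguity
in repeats, GC-coverage bias, diploid genotypes, or chimeric reads.
Passing tests therefore demonstrate that the estimators recover truth
under clean-alignment assumptions, not robustness to those artifacts —
on real data the upstream aligner and its QC carry that burden.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GFF3 and SAM convert at
  the boundary (1-based inclusive), BED and bedGraph are native.
* Text outputs print floating point at fixed 6 decimals so reruns are
  byte-identical; counts round-trip exactly, and levels are recomputed
  from counts on read-back.
* Empty contexts, features without eligible sites, and enrichment with
  an empty non-CNV complement are reported as missing (NA, or an
  explicit `infinite` flag), never as 0 or ±Inf.
* Zero variance of mean deltas (e.g. a sample compared to itself) makes
  z undefined: no calls, with a warning.
* Quartile ties use nearest-rank (`type = 1`) quantiles.

## Problem sizes used in validation

The test-suite and acceptance-script simulations use genomes of 50 kb
to 2 Mb for methylome statistics (≥10⁴ cytosines per stratum, enough
for the ±0.005 and ±0.02 recovery tolerances), 550 features with 10 CG
sites at 30X for the differential caller, and a 10-Mb single-scaffold
genome at 20X combined depth for CNV recovery of a 500-kb planted
amplification. These sizes were chosen so every binomial/Gaussian
tolerance in the checks sits at 3 or more standard errors from its
threshold; the full validation completes in a few minutes on one CPU.

## Known limitations

* The DMR procedure is strictly feature-based; no smoothing-based
  segmentation of unannotated regions.
* CNV detection has no GC-bias correction and assumes two comparable
  WGBS libraries.
* The CRI is computed per repeat copy, not per family consensus;
  family-level scoring requires an external consensus build.
* Low-coverage samples (~1X) are out of scope: the ≥4-read filter
  would discard nearly everything, and no special pooling mode is
  provided.
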