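---
title: "Methods: segmentation, differential testing, and bidirectional 5hmC analysis"
author: "dipseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, differential testing, and bidirectional 5hmC analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipseqr)
```

dipseqr analyses DNA immunoprecipitation sequencing (DIP-Seq) of
5-methylcytosine (MeDIP, "5mC") and 5-hydroxymethylcytosine (hMeDIP,
"5hmC"). The input is the mapped 5' coordinates of uniquely-mapping
single-end tags per library; the pipeline segments regions enriched above
background, tests them for condition differences (irradiated vs sham pools),
annotates them to genes, and quantifies the class of genes that carry both
up- and down-regulated hydroxymethylation regions (DHRs) along their bodies.
All coordinates are 0-based half-open throughout (BED convention); no
conversion ever happens inside the pipeline.

This vignette records the statistical model behind each stage, the
parameters that matter and their defaults, the numerical conventions, and
what the synthetic-data generator does and does not emulate. Every figure of
merit mentioned here is computed by the test suite or by
`scripts/acceptance.R`; the vignette states no number that the code does not
produce.

## Sliding-window segmentation with a Monte-Carlo background

Tags are counted in windows of `window_bp` (default 1000 bp — the window
width at which iterative tuning on the original data maximized the number of
enriched regions) sliding at `window_step_bp` (default 500 bp; the original
description says "sliding" without a step, and half-overlap balances
boundary resolution against cost). A tag contributes to every window whose
interval contains it. Trailing windows truncated by the chromosome end are
kept, flagged, and their counts rescaled to full-window width before
significance lookup.

The null model redraws every tag position uniformly within its chromosome,
preserving per-chromosome tag counts, and re-counts all windows; pooling
`n_permutations` such draws (default 100) gives the empirical null
distribution of window counts. Only the bin membership of a redrawn tag
matters for counting, so when the step divides the window the redraw is
generated directly as multinomial step-bin counts and windows are rolling
sums — distributionally identical to resampling positions, and much faster.
The empirical upper-tail probability uses the add-one estimator

$$\hat p(c) = \frac{1 + \#\{N^{perm} \ge c\}}{n_{draws} + 1},$$

so p-values lie in (0, 1] and the smallest attainable p is
$1/(n_{draws}+1)$ (about $2.5\times10^{-7}$ at the default geometry and 100
permutations on a 2 x 10 Mb genome).

Windows with $\hat p \le \alpha$ (default $10^{-3}$) are merged when they
overlap or lie within `merge_gap_bp` (default: one window). A region's p is
its best window p; its extent is the union of its windows. Two further
conventions:

* **Discreteness.** Window counts are integers, so only a discrete set of
  significance levels is attainable. Calibration therefore has to be judged
  against the level the discrete test actually realizes at a chosen
  $\alpha$ — the largest attainable $p \le \alpha$ — not against $\alpha$
  itself; the calibration checks in the test suite do exactly that.
* **Minimum region width.** With overlapping windows a region is only
  reported if it spans at least `window_bp + step_bp`, i.e. is supported by
  two windows. A single isolated significant window is indistinguishable
  from a count fluctuation; demanding two overlapping supporting windows
  suppresses these singleton calls (the dominant false-positive mode in
  recovery experiments) while leaving any real region wider than one window
  untouched. With non-overlapping windows the constraint is vacuous and
  disabled.

For region discovery in the recovery analyses we run $\alpha = 10^{-4}$:
at the default geometry this admits roughly two false windows genome-wide
(before the width filter) against 40 planted regions, and per-window power
against a 5-fold enrichment over a background of 5 tags/window is about
0.97. Tags are counted by their 5' position without fragment extension;
an extension would only smooth counts at the window scale already used.

## Negative-binomial differential testing

Per-library enriched regions are merged per mark into a test universe
(interval union); tags are counted per region per library, and counts are
normalized by median-of-ratios size factors (geometric mean rescaled to 1;
total-count ratios as fallback when no region is positive everywhere, with
a warning). Counts are modelled as
$K_{ij} \sim \mathrm{NB}(\mu_{ij} = s_j q_{c(j)},\ \alpha)$ with
size factor $s_j$ and condition mean $q_c$.

**Dispersion.** Per region, a method-of-moments estimate is obtained from
within-condition variability of normalized counts; a mean-dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$ is fitted across regions and the per-region
working dispersion is the trend value at the region's mean (argument
`shrink`). With two pools per condition the per-region moment estimate has
about two degrees of freedom and is extremely noisy; using the trend value
pools that information. The conservative alternative — the maximum of trend
and moment estimate — is available (`shrink = "maximum"`) but measurably
under-rejects in null simulations at this replication level and costs real
sensitivity, so it is not the default. `shrink = "none"` keeps the raw
moment estimates.

**Test statistic.** The reported effect is
$\log_2\!\big((\bar q_B + 0.5)/(\bar q_A + 0.5)\big)$ (pseudocount 0.5
avoids infinite fold-changes at zero counts; "up" means higher in the
irradiated condition). The p-value is a Wald-type test on the normalized
mean-difference scale,

$$z = \frac{\max(|\bar q_B - \bar q_A| - c,\ 0)}
            {\sqrt{\widehat{\mathrm{Var}}(\bar q_A) + \widehat{\mathrm{Var}}(\bar q_B)}},
\qquad
\widehat{\mathrm{Var}}(\bar q_c) = \frac{1}{n_c^2}\sum_{j \in c}
  \left(\frac{q_c}{s_j} + \alpha q_c^2\right),$$

where $c$ is half the lattice spacing of the statistic (a continuity
correction). The mean-difference parameterization with this correction was
chosen over the more usual log-fold-change Wald because, in the Poisson
limit that admits an exact answer, the exact conditional test is a binomial
on the treatment sum given the total; the corrected difference-scale normal
approximation tracks that exact test to within $|\Delta p| \lesssim 0.003$
at typical region counts, whereas the log-scale Wald deviates by up to 0.09.
At four libraries the asymptotics that would justify the log scale have no
bite, and agreement with the exact small-sample answer is the more useful
property. Regions with all-zero counts are dropped and reported via an
attribute. Equal condition means give $p = 1$ exactly.

**Multiple testing.** Region q-values are Benjamini-Hochberg
(`bh_adjust()`, a named wrapper over `stats::p.adjust`); significance means
FDR-adjusted q below 0.01. For the expression analysis, `storey_qvalue()`
estimates the null proportion $\pi_0$ from the census of p-values above a
$\lambda$ grid (0.05–0.95), smoothed with a cubic spline and read off at
$\lambda_{max}$, clipped into (0, 1]; q-values are the BH step-up tail
ratios scaled by $\hat\pi_0$, monotonized from the largest p downward. With
$\pi_0 = 1$ this reduces to BH exactly.

## Gene annotation

* **Nearest TSS.** A region is annotated to the gene whose TSS is closest to
  the region midpoint, if within `tss_window_bp` (default 50 kb — a 100 kb
  window centered on the TSS). One gene per region; the signed distance is
  measured along the gene's strand (negative = upstream). The midpoint
  anchor is a package choice (the source describes the window but not the
  anchor); midpoints make the rule symmetric for wide regions. Equidistant
  candidates resolve by ascending (chromosome, gene start, gene id), making
  annotation fully deterministic.
* **Gene-body membership.** Intragenic analyses (DHR density,
  bidirectional detection) annotate by midpoint-in-body
  (`annotate_intragenic()`): inside long genes the relevant regions lie far
  beyond any TSS window, so nearest-TSS annotation is the wrong tool there.
* **Context classes.** The exclusive label uses the precedence
  TSS-proximal (midpoint within 25 kb of a TSS) > intragenic (midpoint in a
  body) > boundary (region covers a gene edge) > intergenic; because the
  classes genuinely overlap, boolean flags for each class are returned
  alongside the label.
* **Top-N selection.** `select_top_regions()` filters q < 0.01, ranks by p,
  truncates to 2000, breaking rank ties by ascending coordinate.
* **Class enrichment.** Overlap of regions with labelled interval classes
  (repeat families and the like) is scored as the fraction of region base
  pairs in the class versus a null that re-places each region uniformly on
  its own chromosome with length preserved; two-sided empirical p with
  add-one correction.

## Bidirectional DHR analysis

The analysis asks whether the same genes carry both significantly increased
and significantly decreased 5hmC regions, and how those DHRs distribute
along gene bodies.

* **Gene sets.** Up- and down-DHR gene sets come from intragenic annotation
  of tested regions; for density analyses the inclusive tier p < 0.1 is
  used (the permissive threshold of the original analysis), while headline
  significance stays at q < 0.01. The overlap of the two sets is scored by
  the upper-tail hypergeometric probability given the gene universe — all
  genes in the analysis, not only the long-gene tier, which exists solely
  for the density normalization below. An empty intersection has p = 1 by
  the tail convention.
* **Density bins.** Genes shorter than 200 kb are removed (length
  normalization), and DHR midpoints are counted in four 50 kb bins laid out
  from the TSS along the direction of transcription. Upstream flanks are
  excluded: "distal to the gene start" is read as into the gene body.
  Counts per fixed-width bin are reported (equivalent to rates up to a
  constant).
* **Permutation test.** Density differences between gene classes
  (bidirectional vs up-only/down-only/no-DHR controls) use a label-shuffle
  test: per-bin statistic = difference of class means, global statistic =
  sum of per-bin differences, two-sided empirical p with add-one correction,
  BH across bins. When the number of distinct label splits does not exceed
  the permutation budget the test enumerates all splits exactly.
* **Density vs significance.** Per gene, the significance score is
  $-\log_{10}$ of its best DHR p-value; density is total intragenic DHR
  count over gene length; association is Spearman rank correlation. Zero
  variance in either variable is reported as rho = 0 with a warning rather
  than NA, so downstream tabulation never silently drops the gene class.

## Integration

* **Gene-set overlap.** Two-sided Fisher exact tests on the 2x2 table from
  a stated universe; odds ratio with Haldane correction (+0.5 per cell) only
  when a cell is zero; families of direction pairs are BH-adjusted together.
  The default universe is the genes carrying at least one tested region in
  either dataset; `all_genes` is available, and the choice is always
  explicit in the call.
* **In-silico pooling.** Replicates pool by tag multiset union;
  pool-then-count equals sum-of-counts exactly. Pooled pairs are compared
  per region by a two-sided Fisher exact test on region tags vs remaining
  tags per library. This pooled-comparison statistic is a documented
  package choice: the original pooled-sample analysis references an earlier
  study whose procedure is not described in the text available here.
* **K-means profiles.** Gene-level features (signed $-\log_{10}$ best q per
  mark, mean normalized level per mark) are standardized per dimension and
  clustered with `stats::kmeans`, best of 25 random starts, labels
  canonicalized by descending cluster size. The default k = 4 covers the
  up/down x 5mC/5hmC quadrants; a mean-silhouette report over k = 2..8 is
  available because the original figure shows at least three clusters but
  states no k.
* **Metagene profiles.** Per gene: 50 fixed-width bins per 10 kb flank and
  100 bins over the body rescaled to unit length, minus-strand genes
  flipped; bin densities are divided by the genome-wide median 1 kb window
  density ("median-normalized"), so a uniform library sits at 1.0
  everywhere. Rows sort by descending expression; heatmap colors cap at the
  80% quantile. Flank width and bin counts are package defaults (none are
  stated in the source).

## The synthetic-data generator

`simulate_genome()` / `simulate_dipseq()` / `simulate_rnaseq()` generate
the desk-scale study system: 2 chromosomes x 10 Mb, 200 non-overlapping
genes (20% at 220–350 kb — the long-gene tier is drawn as an exact fraction
so genome occupancy is bounded for every seed), background 5 tags/kb,
5x enrichment folds, 4x condition folds, NB dispersion 0.05, 2 replicate
pools per condition, and library depth equal to the integral of the
intensity field (~10^5 tags per library) unless fixed explicitly. The
sequencing-scale depth of a real experiment (tens of millions of tags) is
deliberately not simulated; all power statements in the tests are relative
to this desk scale.

Tags are drawn from a piecewise-constant intensity: uniform background;
`enrichment_fold` inside planted enriched regions; an extra
`differential_fold` in the favored condition inside differential regions
(every differential region is also an enriched region); expression-coupled
profiles (5mC dips to 0.25x around active TSSs and rises in low-expression
bodies; 5hmC scales 1/1.6/2.5x across expression tertiles of gene bodies).
Planted bidirectional genes are long genes with up- and down-regulated
5hmC regions in distinct 50 kb body bins; up-only/down-only genes provide
the contrast classes. Replicate variability enters as a Gamma(1/disp, disp)
factor per planted region per library, i.e. gamma-Poisson mixing, so region
counts are NB — the same family the differential test assumes, which makes
parameter recovery a fair test. RNA-Seq counts are NB per gene with means
proportional to expression level; a configurable fraction (default 0.5) of
the 5hmC-up genes is made differentially expressed, enriching the
5hmC-up / RNA-up overlap.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: fragment-length autocorrelation between
tags (tags are independent draws; real DIP fragments correlate over
~100–300 bp), mappability and GC/CpG-density bias (no sequence exists at
all), antibody efficiency differences between marks, and biological
replicate structure beyond gamma intensity noise. Recovery rates on this
generator measure the pipeline's statistical machinery, not robustness to
those artefacts.

## Problem sizes and numerical conventions

The test suite and the acceptance script run, by design, at: background-only
calibration on 2 x 10 Mb with ~10^5 tags and 100 permutations; recovery of
40 planted regions per scenario; 200 random tables for the Poisson-limit
oracle; 2500 null regions for type-I calibration; 8 planted bidirectional
genes end-to-end; 5000 uniform p-values for the $\pi_0$ check. These sizes
were chosen so each property is measured with useful resolution while the
whole suite stays interactive.

Conventions worth knowing when extending the package: empirical p-values
always use add-one estimators and therefore never return 0; permutation
tests switch to exact enumeration when the split count allows; all
tie-breaks (TSS assignment, top-N ranking, cluster labels) are documented
deterministic orders; zero-variance rows in row-scaling become 0; and every
stochastic function takes an explicit seed, so a fixed seed reproduces every
object byte-for-byte.

## Known limitations

* No input/IgG subtraction, mappability or GC correction — none is
  described for the original analysis, and none is implemented.
* The NB model fits unpaired two-group designs only; no covariates.
* The pooled-sample Fisher comparison is a stand-in for an earlier study's
  unspecified procedure and is flagged as such in its documentation.
* With two pools per condition, dispersion information comes almost entirely
  from the trend; regions whose true dispersion far exceeds the trend will
  be anti-conservative. The `shrink = "maximum"` option trades sensitivity
  for protection against exactly this.
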