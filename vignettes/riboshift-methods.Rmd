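---
title: "Methods: translatome shift statistics and condensate assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome shift statistics and condensate assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboshift)
```

# Scope

`riboshift` implements the computational core of a motor-neuron study of
ALS-linked RNA-binding-protein dysfunction: when a protein such as FUS
mislocalizes to the cytoplasm it sequesters translational regulators (notably
FMRP) into condensates, and the translational output of the regulator's
target mRNAs drops. The package quantifies that chain of evidence at four
levels — differential translatome statistics, CLIP-target cumulative-shift
testing, in-vitro condensate partitioning, kinetic rate assays, and axonal
puncta scoring — and ships synthetic-data generators with recorded ground
truth so every stage can be validated by recovery of planted effects.

Everything here runs on simulated inputs or on user-supplied tables/images;
the package does not perform read alignment, peak calling, or image
deconvolution.

# Differential translatome model

Input is a gene-by-sample matrix of RiboTag-style counts with a two-level
design (`control` vs `mutant`; the motivating design used 4-5 littermate
embryos per genotype).

**Normalization.** Median-of-ratios size factors: for each gene observed in
all samples, each sample's count is divided by the gene's geometric mean;
the per-sample median of those ratios is the size factor, rescaled so the
factors have geometric mean 1. `baseMean` is the mean of normalized counts.

**Test.** Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. Per gene, $\alpha$ is estimated by method of moments
from the within-group variances of normalized counts (pooled over both
groups, floored at $10^{-8}$), the effect is
$\log_2\!\big((\mu_{mut}+pc)/(\mu_{ctl}+pc)\big)$ with pseudocount
$pc = 0.5$ (which keeps zero-count groups finite), and its standard error
comes from the delta method. The Wald ratio is referred to a *t*
distribution with $n_1+n_2-2$ degrees of freedom rather than the standard
normal: with 4-5 samples per group the method-of-moments dispersion is noisy
enough that the normal reference produces visibly anti-conservative null
p-values, while the *t* reference keeps them uniform (this calibration is
asserted by the test suite on simulated nulls). The reported `stat` column
is the signed normal quantile of the resulting p-value, so
`p == 2 * pnorm(-abs(stat))` holds exactly and the p-to-z conversion below
inverts it.

This is deliberately *not* a reimplementation of shrinkage-based tools
(no dispersion shrinkage, no outlier filtering, no fold-change moderation):
the package validates itself by calibration and recovery properties on data
with known truth, not by numeric identity with any external pipeline.

**Signed z-scores.** Each nominal two-sided p-value is converted to
$z = \mathrm{sign}(\log_2 FC)\,\Phi^{-1}(1-p/2)$, with p clipped below
$10^{-300}$. The conversion uses the nominal (not adjusted) p-value.
Multiple testing uses Benjamini-Hochberg, with significance conventionally
at FDR 10%.

**Cross-contrast comparison.** Two contrasts are compared by the Pearson
correlation of their z-scores over shared genes, and genes are classed
`both` / `A_only` / `B_only` / `neither` by `padj < 0.1` in each contrast.
The published rule ("<0.1 in one and >0.1 in the other") leaves equality
undefined; equality resolves to the non-significant side.

# CLIP-target shift analysis

**Target definition.** Binding peaks (BED, 0-based half-open) are annotated
against gene-model intervals (1-based inclusive, converted internally)
labelled `five_prime_utr`, `cds`, `three_prime_utr` or `intron`. A peak
carries a label if it overlaps the interval by at least one base; strand
must agree when both records are stranded, and `.` matches anything (the
sources are silent on strand handling, so the permissive convention is
used). `mature_only` selection keeps genes with at least one mature-mRNA
peak — appropriate for RBPs that mostly bind introns in pre-mRNA — while
`any` serves gene-level target lists (e.g. published HITS-CLIP gene sets,
which arrive as identifiers rather than peaks).

**Expression matching.** Target and non-target genes are both restricted to
a log10 base-mean window, by default $(2.5,\ 4.25)$ with strict
inequalities, so the two sets are compared at similar abundance. No 1:1
pairing beyond the shared window is attempted: the motivating analysis
describes a shared expression filter, not pair matching. The non-target set
is every windowed gene outside the target set.

**KS test.** The two z-score samples are compared by the two-sample
Kolmogorov-Smirnov statistic, $D = \sup_z |F_T(z) - F_N(z)|$ evaluated at
the pooled sample points (which handles ties exactly), with the asymptotic
p-value $p = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2 n_e D^2}$ at effective size
$n_e = n_T n_N/(n_T+n_N)$. The vectors here have hundreds to thousands of
entries, where the asymptotic form is accurate; no exact small-sample
enumeration is provided. A direction is called only when $p < \alpha$
(default 0.05): `down` when the target median z is below the non-target
median (leftward ECDF shift; translational depletion of targets), `up` for
the opposite.

# Droplet partition quantification

The in-vitro partitioning pipeline mirrors the standard ImageJ workflow:

1. optional subtraction of a protein-free blank (clamped at zero);
2. Otsu threshold on a 256-bin histogram of the scaffold (condensate-forming
   protein) channel — masks are defined by the scaffold and client
   enrichment is measured within them, which the source protocol implies but
   does not state; both channels are configurable;
3. 8-connected component labelling; per component the area, equivalent
   radius $\sqrt{A/\pi}$, perimeter and circularity $4\pi A/P^2$;
4. particle filter: radius $> 1\ \mu m$ and circularity in $[0.5, 1.0]$
   inclusive, with circularity clamped at 1.0 before filtering (discrete
   contours can exceed 1);
5. background = mean intensity in circular, droplet-free ROIs of diameter
   $5\ \mu m$; the published protocol picks one ROI manually, so placement
   here is seeded-random and 5 ROIs are averaged to reduce variance;
6. per-droplet enrichment ratio = mean client intensity inside the
   component / background mean. Enrichment can be computed on raw or
   blank-subtracted intensities (both supported; the protocol does not pin
   this down per figure).

**Perimeter estimator.** The perimeter is the marching-squares contour
length with Proffitt-Rosen corner-corrected weights (0.948 per axis-aligned
unit segment, 0.95 per diagonal half-segment). Perimeter estimators on
rasters are discretization-sensitive, so the estimator is named and frozen:
with this choice a rasterized disk of radius 2 um at 0.1 um/px has
circularity about 0.97 (raw marching squares gives 0.87, which would push
legitimate round droplets toward the gate boundary), a 10:1 ellipse about
0.23, safely outside the gate.

# Kinetic assays

**Generator.** Both assays use the saturating-exponential form
$s(t) = P\,(1 - e^{-k t / P})$, whose initial slope is exactly the
configured rate $k$; the protocols only constrain the early phase, so the
simplest saturating curve is used. Turbidity samples every 35 s for 20 min
from $t=0$; luminescence samples 10-min end points from 10 to 50 min (the
reaction pre-incubates before the first reading, so fitting starts at the
first end point, not at zero).

**Fitting.** `fit_rate()` is ordinary least squares on the windowed points;
the turbidity convention is the 0-5 min window (delta-absorbance/min),
luminescence uses all end points. Defaults place the plateau far above the
signal reached within the fit window (turbidity 0.01 OD/min against a 1.0
OD plateau) so the early-phase OLS slope is within a few percent of the
true initial rate; users fitting strongly saturating data should shrink the
window accordingly.

**Apparent Csat.** The cited prior procedure is not restated in the
motivating work, so a transparent stand-in is used and flagged as such:
points with rate above a noise floor (3 x the SD of the lowest-concentration
replicates when available, otherwise 0, configurable) are fitted linearly
and the x-intercept $-b_0/b_1$ is the apparent saturation concentration,
flagged `extrapolated` when it falls outside the tested range. On synthetic
rate curves $\max(0, k(c - c^*))$ plus noise this recovers $c^*$ within one
concentration-grid step (asserted in the test suite).

**Normalization.** Condition rates are divided by the mean control rate, so
the control condition reports exactly 1.

# Axonal puncta

Detection is an automated stand-in for manual spot counting: Otsu threshold,
8-connected components, minimum-area filter. The PLA size gate keeps areas
in $[0.05, 3.00]$ inclusive and is interpreted in $\mu m^2$ (the source
text writes the gate in "um" but reports puncta sizes in $\mu m^2$, e.g.
0.26 um^2). Linear density counts puncta whose centroid lies within a
corridor distance of the axon polyline, per 100 um of polyline length.
Colocalization classes use the punctum's pixel-overlap fraction with the
second-channel mask: `full` at $\ge 0.80$, `negative` at $\le 0.05$,
`partial` between. Published panels define full/partial only pictorially, so
these thresholds are explicit conventions, exposed as arguments. Group
summaries rescale each axon's density by 100 / mean(control), and the
cross-group comparison is delegated to `stats::kruskal.test` rather than
re-derived.

# Synthetic data: what it emulates, and what it does not

Each generator is a pure function of its configuration plus seed
(bit-reproducible), and each returns the planted truth alongside the data so
downstream stages are scored without re-deriving truth from the raw data.

* **Counts** (`simulate_counts`): NB counts with log10-normal abundances
  (mean 3, SD 0.7 — mass centred in the 2.5-4.25 analysis window), common
  dispersion 0.05, uniform size factors in [0.8, 1.25], and a planted
  multiplicative effect ($2^{\delta}$, default $\delta=-0.5$) on a flagged
  20% target subset in the mutant group. Genes are independent; there is no
  count outlier process, batch structure, or dispersion trend. Null
  calibration shown on these simulations therefore demonstrates calibration
  under independence, not robustness to correlated or contaminated real
  libraries.
* **Droplet fields** (`simulate_droplet_field`): non-overlapping disks
  (radius 1.5-3 um) at 0.2 um/px, scaffold 400/100 inside/outside, Gaussian
  blur of 1 px and additive Gaussian noise — no point-spread model, shot
  noise, uneven illumination, or droplet-on-droplet contact. Recovery of
  planted ratios validates the measurement chain, not optical realism.
* **Kinetics** (`simulate_kinetics`): the saturating-exponential above with
  i.i.d. Gaussian read noise; no lag phase or nucleation stochasticity.
* **Axon images** (`simulate_axon_image`): a straight horizontal corridor
  (2 um wide, 0.1 um/px) with disk puncta of area 0.15-0.4 um^2 and planted
  overlap composition (default 20% full / 40% partial, the scale reported
  for mutant-FUS-positive FMRP puncta). Full partners cover the channel-1
  punctum with a 2 px margin; partial partners are offset by one radius
  (geometric overlap about 0.4). Real axons curve, vary in width and
  background, and bleed between channels; none of that is modelled.

# Reproducibility and problem sizes

A single pipeline seed fans out deterministically to per-stage seeds
(`stage_seed`), so re-running a stage reproduces the full-run stream;
`run_pipeline()` writes its full configuration, a checksum and per-stage
seeds into `manifest.json`, and repeated runs with the same configuration
are byte-identical. The test suite exercises the statistical claims at the
study's natural scale — 2000 genes with 4-5 samples per group (20-50 seeds
for calibration and recovery rates), droplet fields of 60 x 60 um with
10-12 droplets across planted ratios 1-4, and 10-16 simulated axons of
300-400 um — sizes at which every documented tolerance is met while the
whole suite stays fast.

# Known limitations

* The NB test assumes a two-group design; no covariates, batch terms, or
  multi-factor contrasts.
* The KS p-value is asymptotic; for target sets of only a handful of genes
  an exact test would be preferable.
* The Csat estimator is a declared approximation (linear x-intercept), not
  the cited laboratory procedure.
* Segmentation is 2-D, single-plane; no z-stacks, time series, or
  droplet-within-droplet decomposition.
* Overlap-class thresholds and the background-ROI averaging count are
  conventions; results reported from them should state the settings used.
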