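# riboshift

Statistical and image-quantification toolkit for studies of ALS-linked
RNA-binding-protein dysfunction in motor neurons — in particular, how
cytoplasmically mislocalized FUS sequesters the translational repressor FMRP
into condensates and depresses the translation of FMRP-target mRNAs. It is
aimed at computational biologists analysing RiboTag/TRAP translatome counts,
CLIP target sets, in-vitro phase-separation assays and axonal
immunofluorescence, and at methodologists who want every stage of such a
pipeline testable against planted ground truth.

## What it computes

**Differential translatome.** For a gene x sample count matrix with a
control/mutant design, a self-contained negative-binomial Wald test:
median-of-ratios size factors, method-of-moments dispersion
(Var = mu + alpha mu^2), log2 fold change with pseudocount,
delta-method standard errors, a small-sample *t* reference for the p-value,
and Benjamini-Hochberg FDR. Each nominal p-value is converted to a signed
z-score,

    z = sign(log2FC) * qnorm(1 - p/2),

and two contrasts are compared by the Pearson correlation of their z-scores
and condition-specific classes (padj < 0.1 in one contrast, >= 0.1 in the
other).

**CLIP-target cumulative shift.** Targets are defined from binding peaks
annotated against gene models (BED half-open vs GTF-like 1-based intervals,
strand-aware) and optionally restricted to mature-mRNA binding (5'UTR / CDS /
3'UTR). Target and non-target genes are expression-matched through a strict
log10 base-mean window (default 2.5-4.25) and their z-score ECDFs compared by
the two-sample Kolmogorov-Smirnov statistic

    D = sup_z | F_target(z) - F_nontarget(z) |,

with the asymptotic p-value at effective n = n_T n_N / (n_T + n_N). A
leftward shift of the target ECDF (negative median z difference, p < 0.05)
is reported as translational down-regulation of targets.

**Condensate partitioning.** Otsu segmentation (256-bin) of the scaffold
channel, 8-connected components filtered by equivalent radius > 1 um and
circularity 0.5-1.0, background from droplet-free 5-um circular ROIs, and
per-droplet client enrichment = mean intensity inside / background mean.

**Kinetics.** OLS rates for turbidity (0-5 min window, delta-absorbance/min)
and luciferase translation assays (10-50 min end points), normalization to a
buffer control, and apparent saturation concentration as the x-intercept of
the supra-threshold rate-vs-concentration line.

**Axonal puncta.** Automated detection, the 0.05-3.00 um^2 PLA size gate,
density per 100 um of axon trace, full/partial/negative colocalization
classes by mask-overlap fraction, and control-normalized group summaries.

**Synthetic data.** Generators for all four input classes (counts, droplet
fields, kinetic series, axon images) that record the planted truth, used by
the test suite to verify calibration and recovery end to end.

## Worked example

Simulate a translatome experiment with a 20% target set depleted by
2^-0.5 in the mutant (5 vs 5 samples), test, and run the target-shift
analysis:

```r
library(riboshift)

sim <- simulate_counts(sim_count_config(seed = 42))
de  <- translatome_de(sim$counts)
targets <- sim$ground_truth$gene[sim$ground_truth$is_target]
cumulative_shift(de, targets, window = c(2.5, 4.25))
#> cumulative shift: D = 0.801 , p = 2.32e-127 , direction = down
#>   targets: 283  non-targets: 1167  median z difference: -2.15
sum(de$padj < 0.1)
#> [1] 0
```

The planted per-gene effect is mild enough that no single gene clears the
10% FDR bar, yet the set-level ECDF comparison detects the depletion
decisively (D = 0.80 over 283 expression-matched targets, target median z
2.15 units below non-targets) — the reason cumulative-shift analysis is used
alongside per-gene testing. On the imaging side:

```r
field <- simulate_droplet_field(sim_droplet_config(seed = 1))  # planted ratio 3.5
quantify_droplets(field$image, seed = 2)$enrichment
#> enrichment: 12 droplets, mean ratio = 3.32 (background = 99.94 )
```

The same analyses are scriptable end to end: `run_pipeline(config, out_dir)`
(or `exec/riboshift run-all --seed 4 --out DIR`) chains simulation, testing
and shift analysis, writing `de.tsv`, `shift.json`, ECDF curves and a
manifest with per-stage seeds; identical configuration and seed reproduce
byte-identical outputs.

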