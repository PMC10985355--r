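---
title: "Models and methods behind qgomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qgomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgomics)
```

`qgomics` reproduces, as tested and reusable code, the analysis chain of
a replicated multi-environment drought trial on a crop variety panel:
quantitative-genetic parameter estimation, SNP population genetics,
mixed-model association, candidate-gene windowing, differential
expression, and GWAS-by-transcriptome integration. This vignette
explains each model, the tunable parameters, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Quantitative genetics from ANOVA

Within one trait-by-environment cell the data are modelled as a
randomized complete block design, `value ~ genotype + replicate`, and
variance components come from the expected mean squares:

* genotypic variance `σg² = (MSG − MSE) / r`, with `r` the
  harmonic-mean replicate count; negative estimates are clamped to zero
  and flagged (`varianceComponents()`);
* environmental variance `σe² = MSE`, phenotypic variance
  `σp² = σg² + σe²`.

A genuinely open definitional point is whether the "environmental
variance" of such tables means `MSE` or `MSE/r` (the error variance of
a genotype mean). The package adopts `σe² = MSE`: it makes the
published coefficient-of-variation magnitudes reproducible, and it
keeps `h² = σg²/σp²` equal to `(GCV/PCV)²`, which is how the reference
table's own columns cohere. Users who need the mean-basis definition
can divide `MSE` by `r` before the chain.

Coefficients of variation are `ECV = √MSE/x̄·100`, `GCV = σg/x̄·100`,
`PCV = σp/x̄·100` (all in percent of the trait mean; the square root on
`MSE` keeps the three definitions dimensionally parallel). Broad-sense
heritability is `h² = σg²/σp²·100` and genetic advance under truncation
selection is `GA = k·(h²/100)·σp`, `GAM = GA/x̄·100`, with `k = 1.76`
the standardized selection intensity for keeping the top 10% of a
normal distribution (`selectionIntensity(0.10)` returns the exact
1.75498; the conventional rounded constant is kept as the default so
printed tables reproduce). `GA` is deliberately *not* divided by the
mean — that normalization belongs to `GAM` alone, and only this reading
reproduces the reference table's GA column.

The combined analysis over years and regimes (`combinedAnova()`) fits
`G × Y × E` with replicates nested in year-by-regime cells and treats
year as random: fixed terms are tested against their interaction with
year (`G` vs `G:Y`, `E` vs `Y:E`, `G:E` vs `G:Y:E`) and year-involving
terms against the residual. This is the classical approximate F-test
scheme for a mixed two-factor-by-year trial; no REML refinement or
lattice inter-block recovery is attempted, because block-level data
beyond the replicate label are not modelled (a deliberate
simplification, documented rather than silent).

The bundled `trialSummary()` table carries the published
per-trait-by-environment summaries of the 119-variety trial the
defaults emulate. In the published layout the two CV columns are
printed swapped (the column labelled PCV holds the smaller value);
`trialSummary()` reassigns them so `gcv ≤ pcv`, the ordering the
definitions guarantee, which also makes the printed heritabilities
equal `(gcv/pcv)²·100` up to rounding.

## SNP QC, diversity and linkage disequilibrium

QC (`filterSnps()`) applies call rate ≥ 0.90, biallelic, MAF ≥ 0.05,
missingness ≤ 0.10, in that fixed order with per-stage counts —
thresholds are the field's standard ones; the order is a package
convention so reports are comparable across runs. All boundaries are
inclusive. PIC uses the biallelic form `1 − (p²+q²) − 2p²q²`.

Pairwise r² is the squared Pearson correlation of dosages over samples
with both calls present; D′ comes from EM-estimated haplotype
frequencies on unphased diploid pairs (only the double heterozygote is
phase-ambiguous; the EM splits it between coupling and repulsion), and
is normalized by its allele-frequency maximum.

LD decay (`ldDecay()`) fits the Hill–Weir expectation of r² (with its
small-sample term) to all pairs by least squares over the per-bp rate
ρ, and reports the distance at which the fitted curve falls to half its
value at distance zero. When the observed curve carries no decay signal
(short-range and long-range mean r² within 0.02), no half-decay point
is identifiable and the distance is reported as right-censored; a
binned half-of-maximum fallback covers optimizer failure. The
half-of-fitted-intercept definition is a package choice — published
decay distances rarely state their rule — and is stated on every
output.

Haplotype blocks (`haplotypeBlocks()`) implement the Gabriel
confidence-interval rule on likelihood-profile CIs for |D′| (grid
posterior, 90% interval): a pair is "strong LD" when the CI is
[≥ 0.70, ≥ 0.98], "strong recombination" when the upper bound is
< 0.90, and a candidate span is accepted when at least 95% of its
informative pairs are strong; accepted spans are taken greedily,
longest first, without overlap.

Kinship is the VanRaden centered genomic relationship
`ZZ'/(2Σp(1−p))` with mean imputation of missing dosages for this
computation only; scaled-IBS alternatives differ slightly but the
centered form is the common default of mixed-model software. PCA is an
eigendecomposition of centered dosages with a deterministic sign
convention (largest-magnitude loading positive).

## Association models

The GLM route regresses per-variety means on dosage plus an intercept
and structure covariates, with a two-sided t-test on the dosage
coefficient. Structure covariates default to five principal-component
scores; ancestry proportions from model-based clustering, where a user
has them, can be supplied in their place — PCA covariates are the
package's substitute for that out-of-scope machinery.

The MLM is `y = Xβ + g·a + u + e`, `u ~ N(0, σu²K)`. The variance
ratio is estimated once by REML on the no-marker model through the
spectral decomposition of K and then held fixed for every marker — the
P3D/EMMAX approximation, chosen because it matches the default
behaviour of the field's standard software and reduces each marker test
to weighted least squares in the rotated space. Missing dosages are
mean-imputed there so the sample set stays fixed across markers.
Per-marker explained variance is the nested-model `ΔSSE/SST` for the
GLM and the likelihood-ratio analog `1 − RSS_full/RSS_reduced` on
whitened data for the MLM.

The phenotype entering association is the variety mean per
trait-by-environment — a simple, transparent choice; BLUEs from a
stage-one model would be the natural refinement and are a known
limitation. Significance uses the fixed threshold `p < 10⁻⁴`
(strict inequality), mirroring common practice in panel GWAS of this
size; FDR control is available through `bhAdjust()` but is never the
default. "Stable" SNPs are significant for the same trait in ≥ 2
year-by-regime environments; "pleiotropic" SNPs for ≥ 2 traits. Lead
SNPs within a peak are chosen by smallest p, then smallest position.

## Candidate genes, expression, integration

Candidate genes lie within a window of each lead SNP, distance measured
from the SNP to the nearest gene edge (matching the "x kbp downstream
of gene" phrasing of trial reports, rather than TSS distance), with
upstream/downstream resolved on the gene's strand and unstranded models
treated as plus strand. Both the 200-kbp convention and the LD-decay
estimate (288 kbp by default) are exposed as window presets; windows
are inclusive at the boundary and doubling a window can only add
candidates.

FPKM is `count/(length_kb · libsize_millions)` with library sizes
defaulting to column sums. DEG calling uses a Welch t-test on
`log2(FPKM + 1)` per gene with Benjamini–Hochberg q-values over tested
genes, and the thresholds `|log2FC| ≥ 1`, `Q < 0.05`; the threshold
rule is applied two-sidedly since both directions are reported. The
testing engine behind published threshold-only DEG lists is typically
unstated; the Welch-on-log choice is simple, calibrated at small n
(verified by the null-FDR study), and documented — a
negative-binomial GLM would be a drop-in refinement for counts with
strong mean–variance coupling. "Q value" is read as BH FDR. Genes with
all-zero counts on both sides are excluded from testing.

Enrichment is the one-sided hypergeometric tail per category over the
tested background, BH-adjusted, skipping categories with fewer than two
annotated genes.

Integration builds ±288-kbp intervals around significant SNPs, merges
overlaps (so a dense peak is not double-counted), assigns genes by
overlap, and compares DEG status inside vs outside the intervals with
Fisher's exact test — the merge-then-Fisher procedure is the package's
resolution of an otherwise unstated protocol, and both pieces are
stated in the report. Validated candidates are candidate genes that are
DEGs in at least one drought-vs-control contrast.

## The synthetic-data generators

`simulateGenotypes()` emulates the structure the pipeline assumes:
19 chromosomes (A01–A10, C01–C09), ~29,310 biallelic SNPs, 119
varieties, seven subpopulations. Subpopulation allele frequencies
follow the Balding–Nichols model (Beta around a common ancestral
frequency drawn from U(0.05, 0.95), concentration set by fst, default
0.10). Linkage disequilibrium comes from a latent Gaussian AR(1)
process per haplotype, thresholded at the subpopulation frequency
quantile: the latent correlation between sites is
`exp(−recomb_rate·d)`, so r² declines smoothly and controllably with
distance. A founder-copying scheme was tried first and rejected: with a
founder panel of size K, within-segment r² dilutes toward 1/K, so
either short-range LD is unrealistically weak or the panel is too small
for a realistic frequency spectrum. The knob-to-observable mapping —
Hill–Weir-fitted half-decay ≈ 0.15 × latent correlation length on a
QC-filtered panel — was measured once at design time and frozen, so
`ld_block_len = 288000` (the default) yields a fitted decay distance
near 288 kbp. Mean PIC of a default panel (~0.29) falls inside the
published 0.24–0.38 per-chromosome band.

`simulatePhenotypes()` builds variety genetic values as planted QTN
effects plus a polygenic component constructed from genome-wide
dosages with random weights (so that kinship genuinely explains it),
scaled to hit a target per-environment broad-sense heritability;
observations add environment means, genotype-by-environment noise,
replicate block effects, and plot residuals. QTNs can be restricted to
a subset of environments (drought-specific effects) or shared between
traits (pleiotropy). Truth objects — QTN list, realized per-environment
h², genetic values — are always returned, because the package's
acceptance standard is parameter recovery.

`simulateExpression()` draws negative-binomial counts around
log-normal baselines, multiplies drought samples by `2^lfc` for a
planted DEG fraction, places a configurable share of DEGs within a
window of supplied QTNs, and scales expected counts by gene length and
library size. The default sample sheet mirrors the trial's RNA-seq
design: two high- and two low-yield varieties, leaf and seed tissue,
control vs drought, three replicates.

What the generators do *not* emulate: coalescent genealogies and
recombination hotspots, selection and demography, genotyping error
beyond uniform missingness, field spatial trends, lattice blocks,
isoform-level expression, and batch effects. Tests passing on this
synthetic world therefore certify the estimators and their plumbing —
calibration, recovery, invariances — not robustness to every artifact
of real data. Trial settings the study design leaves unstated
(per-environment error variances, plot-level distributions) were
chosen once to give realistic coefficient-of-variation magnitudes
(residual SDs of a few percent of the trait mean) and never revisited.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: σg² clamps to zero with a
flag; h² is NA when σp² = 0; monomorphic markers are flagged
untestable; LD pairs with fewer than five complete observations are
skipped and counted; non-PSD kinship is ridged with a warning; PCA
truncates at rank with a warning. The EM for haplotype frequencies
starts at linkage equilibrium and iterates to 10⁻¹⁰; the REML ratio is
optimized on log δ over [−10, 10]; D′ CIs use a 0.01 grid.

The verification studies run at the trial's stated scale where that is
the point (119 varieties, 3 replicates; 5,000-SNP structured null
panels pooled over 21 simulations for > 10⁵ tests; 50-simulation
recovery studies) and at desk scale elsewhere (toy oracles on ≤ 20
samples; 800-SNP single-chromosome panels for LD-decay recovery;
300–1,000-gene expression simulations). `runSyntheticStudy()` defaults
to a three-chromosome, 2,000-SNP miniature of the full design so the
end-to-end path stays quick to exercise.

## Known limitations

Variety means (not BLUEs) enter association; per-marker REML (exact
MLM) is not offered; the DEG engine is a t-test, not a count model; D′
CIs condition on estimated allele frequencies; STRUCTURE-style
admixture estimation, neighbor-joining trees, read-level processing,
and external annotation retrieval are out of scope by design.
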