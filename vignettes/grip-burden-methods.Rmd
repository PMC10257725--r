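---
title: "Rare-variant burden analysis of grip strength: models and methods"
author: "gripburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden analysis of grip strength: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripburden)
```

# Scope

`gripburden` implements a complete desk-scale rare-variant collapsing
analysis of a continuous strength phenotype: variant classification and
burden construction, linear burden association with a dense anthropometric
covariate design, multiple-testing control, sex-stratified and
X-chromosome scans, a single-variant GWAS feeding polygenic-score weights,
leave-one-chromosome-out (LOCO) polygenic offsets, a two-step Firth
PheWAS, a PRS-by-rare-carrier additivity model, and a mouse grip-strength
analysis. A synthetic-cohort generator supplies all inputs with known
ground truth. This vignette records the models, the defaults and why they
were chosen, the numerical decisions, and what the tests do and do not
establish.

# Qualifying variants and burden

A rare variant (MAF < 0.1%) qualifies for exactly one of five classes:

* **PTV** — consequence stop-gained, splice-disruptive or frameshift *and*
  LOFTEE high-confidence. Low-confidence calls are excluded outright.
* **missense, CADD > 30 / (20, 30] / [0, 20]** — the bin edges are read
  literally, so CADD = 30 falls in (20, 30] and CADD = 20 in the lowest
  bin. An exact phred of 0 is kept in the lowest bin: scores are
  non-negative, and orphaning the boundary point would break the partition
  property (every qualifying variant in exactly one class). A missense
  variant with a missing CADD score is an error, never a silent bin.
* **synonymous** — the negative-control class.

Genes are stratified at pLI ≥ 0.9 (LoF-intolerant) versus < 0.9; the five
classes crossed with {intolerant, tolerant, all} give the 15 exome-wide
categories of `variant_categories()`. The burden of a sample in a unit is
the *sum of alternate-allele dosages* over qualifying variants — allele
counting, not carrier status — with a carrier-indicator option
(`carrier_indicator = TRUE`) for sensitivity analyses. Missing dosages
contribute zero by default; per-variant mean imputation is available but
off, because zero-filling is deterministic, conservative, and unbiased
under missingness independent of genotype. Gene-set and exome-wide burdens
are exact integer column sums of gene burdens, so conservation
(exome = Σ genes) holds to the last integer and is asserted in the tests.

Genes with fewer than 10 carriers are dropped before gene-level testing;
the boundary is literal (exactly 10 carriers is kept).

# The association model

For burden $b$, phenotype $y$ (kg), covariate matrix $X$ and optional
offset $o$:

$$y_i - o_i = \alpha + \beta b_i + \gamma^\top x_i + \varepsilon_i$$

fitted by OLS with a two-sided t-test on $\beta$ at the residual degrees
of freedom (not a normal approximation — at biobank scale they coincide,
but the t is exact under Gaussian errors at any size). The design is the
intercept, 20 principal components, age, sex, age², age×sex, age²×sex,
height, height², height×sex, height²×sex; the PheWAS design drops the
height block, and sex-stratified fits drop sex and its interactions.
Constant non-intercept columns are an error, as they signal an upstream
filtering mistake rather than something to silently drop.

Scans over many units use a Frisch–Waugh fast path: the phenotype and each
burden column are projected off the covariates once via the design's QR
factorization, after which each per-unit slope, SE and p-value is a pair
of inner products. This is algebraically identical to refitting the full
model per unit, and the test suite verifies equality against `lm()` to
1e-9 on dense and sparse inputs. Burden matrices may be sparse
(`dgCMatrix`) — with MAF < 0.1% they are ~99.9% zeros — and the fast path
never densifies them.

The offset enters by subtraction from the response, so adding any constant
to an offset is absorbed by the intercept and leaves $\beta$ unchanged
(asserted to 1e-10). Offsets can be supplied per chromosome; gene scans
then use the offset for the gene's own chromosome.

## Multiple testing

`bonferroni_threshold(alpha, m)` returns `signif(alpha/m, 2)` — the
conventional printed form (0.05/15 = 0.0033, 0.05/15786 = 3.2e-6) — with
the unrounded value in the `"raw"` attribute; scans declare significance
on the raw value, and both are recoverable because reasonable readers
disagree on which a published threshold means. FDR uses
Benjamini–Hochberg step-up via `stats::p.adjust`; an independent
brute-force step-up implementation lives in the test suite and must agree
exactly.

## Sex-stratified, X-chromosome and overlap analyses

The sex-stratified scan reports per-stratum effects and the heterogeneity
z-score $(\beta_m - \beta_f)/\sqrt{se_m^2 + se_f^2}$. The X scan removes
samples flagged with sex-chromosome aneuploidy and codes male hemizygous
dosages 0/2 by default (a hemizygous allele counted like a homozygote,
matching the female scale under X-inactivation); 0/1 is a flag. GWAS-
catalog overlap maps genes whose body intersects a closed ±500 kb window
around each lead variant (MAF > 0.01), then applies Bonferroni over the
overlap genes actually burden-tested.

## LOCO ridge offsets

Whole-genome-regression offsets are replaced by a transparent
simplification: ridge regression of the covariate-residualized phenotype
on all common variants excluding the target chromosome, one offset vector
per chromosome, with exactly zero weight on the held-out chromosome by
construction. The penalty is chosen once by k-fold (default 5)
cross-validation on the full variant set — per-fold eigendecomposition of
$X^\top X$ makes the grid search cheap — and each per-chromosome model is
then solved in closed form at that penalty. The interface also accepts
externally computed offsets, so predictors from a dedicated whole-genome
regression tool can be dropped in unchanged. Under a null polygenic
signal, cross-validation picks a heavy penalty and the offsets shrink
toward zero (asserted: mean |offset| < 0.05 phenotype SD).

# Two-step PheWAS

Binary traits need ≥ 100 cases (boundary literal); quantitative traits
need ≥ 100 observations and ≥ 12 distinct values, and individuals beyond
5 SDs from the pre-trim trait mean are removed in a single pass —
iterative re-trimming would change n in a rule-dependent way the single
stated rule does not license. Each retained binary trait is screened by
maximum-likelihood logistic regression; pairs with screen p < 0.01, and
pairs whose screen fails to converge or separates, are refit by Firth
regression. Quantitative traits are tested twice, raw and inverse
rank-normal transformed.

**Firth implementation.** The estimate maximizes
$\ell(\beta) + \tfrac12 \log\det I(\beta)$. The modified score
$U^*(\beta) = X^\top(y - \pi + h(\tfrac12 - \pi))$ is exactly the gradient
of that penalized likelihood, so the solver first runs BFGS with this
analytic gradient — near-separated data produces a long flat ridge along
which plain Newton converges only linearly — and then polishes with
Newton steps (Fisher information as the approximate Jacobian, step-size
cap 5, step-halving on the penalized likelihood) to a modified-score
tolerance of 1e-9. When floating-point limit-cycling sets in below a score
of 1e-6 with sub-1e-6 steps, the fit is declared converged at machine
resolution; exceeding the iteration cap is an error. On saturated 2×2
tables the slope provably equals the log odds ratio of the half-corrected
cells, and the suite verifies agreement to better than 1e-6 including
zero cells and complete separation. P-values are Wald by default; a
penalized profile likelihood-ratio option re-maximizes the full penalized
likelihood with the tested coefficient pinned at zero.

# Phenotype derivation

The analysis outcome is the maximum of left- and right-hand grip; a
sample is kept if at least one hand was measured. Exclusions are applied
with first-match audit accounting (COPD, brachial plexus disorder, arm
injury, body weight outside the closed window [30, 200] kg or missing,
grip missing on both hands), so rows in = rows out + Σ removals always.
The weight window is read as closed at both ends — the source rule gives a
range without brackets, and including the endpoints is the reading that
removes fewer measured samples.

Inverse rank-normal transformation uses the Blom offset,
$z_i = \Phi^{-1}((r_i - 0.375)/(n + 0.25))$, with average ranks for ties —
the convention of quantitative-trait GWAS. All-equal input is an error
(degenerate ranks), and missing values pass through untouched.

# PRS and additivity

The holdout split reserves every carrier of a qualifying PTV in the
supplied Mendelian neuromuscular gene list plus an equal-sized random
non-carrier sample as the evaluation set; weights are built only on the
training remainder (an id audit in the tests asserts the hygiene). Weight
building is p-value thresholding of training-GWAS betas — a transparent
stand-in for posterior-shrinkage weight builders, whose output files the
scorer accepts directly. Scoring keeps per-chromosome partial scores
(final score = Σ chromosomes 1–22), reflects dosages (2 − d) when the
weight's effect allele is the genotype's reference allele, and skips and
counts variants missing from the genotypes.

The additivity model adds to the full covariate design: standardized PRS
(standardized on the analysis sample, where the model is fit), dominant-
and recessive-gene carrier indicators (a sample carrying both keeps
both), and the two PRS×carrier interactions. Empty carrier categories are
dropped with a warning rather than producing singular fits. The additivity
verdict is simply whether both interaction p-values clear the chosen
level.

# Mouse grip-strength analysis

Per animal, grip is the mean of three peak pull-force trials divided by
femur length (g/mm); a missing trial is an error because the assay
specifies three. The Box–Cox power is profiled over [−2, 2] for the
linear model `transformed ~ cohort`: a coarse 0.05 grid brackets the
optimum and golden-section refinement locates it, so the estimate matches
a 1e-3 grid search well within 2e-3 (asserted); boundary hits are flagged.
The genotype test is a double GLM — a weighted least-squares mean submodel
(`~ genotype + cohort`, weights 1/φᵢ) alternated with a gamma log-link
dispersion submodel on leverage-corrected squared residuals
(prior weights (1−h)/2) to a relative log-likelihood tolerance of 1e-8.
With an intercept-only dispersion submodel this provably collapses to OLS
(asserted to 1e-4). The dispersion covariate defaults to cohort, with
genotype, both, or intercept-only as options, since the original
analysis names the modelling framework but not the dispersion terms.
Z-scores for visualization standardize cohort-residualized values against
the wildtype mean and SD — residualizing on genotype too would erase the
contrast being visualized — with two-sided Welch t-tests for HET and HOM
against WT (pooled-variance optional).

# The synthetic-cohort generator

`sim_spec()` / `simulate_cohort()` emulate what the analysis assumes, not
a demographic model:

* **Rare genotypes** — Hardy–Weinberg per variant, independent variants,
  MAF uniform on a configurable range capped below 0.1%; stored sparse;
  males hemizygous 0/1 on X-linked variants. Optional missingness as
  explicit NAs.
* **Annotations** — class proportions default to PTV 6.3%, missense
  59.2%, synonymous 34.5%, the observed exome-wide mix of qualifying
  variants; 10% of PTV-consequence variants are labelled LOFTEE
  low-confidence; missense CADD uniform on (0, 40], synonymous below 10 —
  only bin membership matters downstream. pLI is a two-part mixture with
  18% of genes intolerant.
* **Phenotype** — grip strength is a covariate polynomial (defaults
  centred so a 55-year-old female of average height sits near 30 kg, with
  +11 kg for males, −0.25 kg/yr and +0.3 kg/cm) plus Σ effect×(gene's
  qualifying PTV allele count) plus a polygenic component from the common
  variants plus Gaussian noise. `noise_sd` (default 6 kg) is the SD of
  the combined polygenic+environmental residual and `polygenic_h2`
  (default 0.3) its polygenic fraction — the variance decomposition is a
  package choice, configurable, never inferred. Left and right hands are
  the latent value plus independent jitter with SD 5% of the latent SD,
  so taking the hand maximum is a real (if mild) max-of-two distortion,
  exactly as in the field protocol.
* **Exclusion flags** drawn at population-frequency defaults
  (COPD 0.64%, brachial plexus 0.012%, arm injury 1.9%, aneuploidy 0.1%).
* **Binary traits** at stated prevalences, optionally odds-linked to a
  gene's carrier status.
* **Mouse cohorts** with configurable per-genotype counts (default
  24/18/13), ≥ 2 cohorts with additive shifts, between-animal SD 12 g,
  trial SD 8 g, femur ~ N(15.5, 0.4) mm.

What passing tests therefore show: the *estimators* are unbiased,
calibrated and oracle-exact under the generative assumptions the analysis
itself makes. What they cannot show: robustness to linkage disequilibrium
among rare variants, annotation error, site-frequency-spectrum realism,
population stratification beyond Gaussian PCs, or informative
missingness — none of which the generator emulates (common-variant LD is
available as a blockwise autoregressive option but off by default).

# Reference problem sizes

The packaged checks run at these sizes, chosen to keep every experiment
meaningful yet quick on a single CPU: null calibration pools three
effect-free cohorts of 20,000 samples × 2,000 PTV-rich genes (a
single-cohort KS test at α = 0.01 indicts a perfect scan 1% of the time
by design; pooling replicate cohorts tests the same uniformity with more
resolution); effect recovery uses 200 replicate cohorts of 20,000 at the
injected magnitudes −0.25 kg (all genes) and −0.61 kg (single gene);
additivity recovery uses 100 replicates of a 10,000-sample evaluation
set with +0.954 kg/SD PRS and −0.196 kg dominant-carrier truth; the
Firth, BH and Box–Cox oracles use 100 tables, 1,000 p-vectors and 50
mouse cohorts respectively.

# Known limitations

* LOCO offsets come from plain ridge, not the blockwise whole-genome
  regression of dedicated tools; with few simulated common variants this
  is faithful in spirit, not in scale.
* PRS weights are p-threshold betas; no LD-aware shrinkage.
* One gene per variant (canonical-transcript mapping is upstream);
  multi-allelic sites must be pre-split, and the VCF reader rejects them.
* MAF comes from the annotation table by default, so qualifying status is
  deterministic across cohorts; recomputation from the cohort is a flag.
* ICD-10/Phecode curation, tissue-expression and pathway set retrieval
  are inputs (TSV/GMT), never computed.
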