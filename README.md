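# gripburden

Rare-variant collapsing analysis of hand grip strength, packaged as a
tested, desk-scale pipeline. Grip strength is a continuous proxy for
muscular fitness; exome studies ask whether carrying rare (MAF < 0.1%)
protein-truncating or damaging missense alleles in a gene lowers it. The
package implements every stage of such a study — qualifying-variant
classification, burden construction, covariate-adjusted association
testing, phenome-wide association with Firth refitting, polygenic-score
additivity modelling, and the companion mouse grip-strength analysis —
together with a synthetic-cohort generator that provides genotypes,
annotations and phenotypes with known ground-truth effects, so every stage
can be calibrated and power-checked without access-controlled biobank data.

It is written for statistical geneticists and methodologists who want a
transparent, fully testable reference implementation of the collapsing
burden workflow.

## The model

For a unit *u* (a gene, a gene set, or the whole exome restricted to one of
15 variant categories), the per-sample burden is the count of qualifying
rare alleles,

```
b_i(u) = sum over qualifying variants v in u of dosage_iv ,
```

where a variant qualifies if MAF < 0.001 and it falls in the category:
PTV (stop-gained / splice-disruptive / frameshift, LOFTEE high-confidence
only), missense binned by CADD phred (> 30, (20, 30], [0, 20]), or
synonymous — each crossed with a gene stratum by LoF intolerance
(pLI ≥ 0.9, pLI < 0.9, all). The association model is ordinary least
squares,

```
HGS_i − offset_i = α + β b_i(u) + γ' x_i + ε_i ,
```

with covariates x = 20 PCs, age, sex, age², age×sex, age²×sex, height,
height², height×sex, height²×sex, an optional leave-one-chromosome-out
polygenic ridge offset, and a two-sided t-test on β (kg per rare allele).
Gene scans apply a ≥ 10 carrier filter, Bonferroni (0.05 / genes tested)
and Benjamini–Hochberg FDR. The PheWAS screens each trait by maximum-
likelihood logistic regression and refits pairs with screen p < 0.01 by
Firth-penalized logistic regression (finite estimates under separation).
The polygenic-score analysis fits

```
HGS ~ PRS_std + carrier_dom + carrier_rec + PRS_std:carrier_dom + PRS_std:carrier_rec + covariates
```

and reads additivity off the interaction terms. The mouse arm normalizes
trial-mean grip by femur length, Box–Cox transforms it (λ ∈ [−2, 2],
cohort as covariate), tests genotype via a double generalized linear model
(joint mean and dispersion submodels), and reports wildtype-referenced
z-scores with pairwise t-tests.

## Worked example

Simulate a cohort of 20,000 with one deleterious gene (−1.5 kg per
qualifying PTV allele) and scan:

```r
library(gripburden)
spec <- sim_spec(n_samples = 20000, n_genes = 100, variants_per_gene = 12,
                 rare_maf_range = c(1e-4, 9e-4),
                 class_proportions = c(ptv = 0.4, missense = 0.4, synonymous = 0.2),
                 effect_table = c(gene0007 = -1.5), seed = 42)
cohort <- simulate_cohort(spec)
pheno  <- apply_exclusions(cohort$phenotypes)
design <- covariate_design(pheno)
keep   <- match(pheno$sample, cohort$phenotypes$sample)
burden <- gene_burden(cohort$genotypes[keep, ], cohort$variants, "ptv", cohort$genes)
run_gene_scan(burden, pheno$hgs, design, min_carriers = 10)
```

```
Gene-level burden scan: 100 genes, Bonferroni p < 0.0005 (0 filtered by carriers)
     gene n_carriers  beta    se        p p_bonf   q_bh sig_bonf sig_fdr
 gene0007        132 -2.39 0.632 0.000153 0.0153 0.0153     TRUE    TRUE
 gene0001        138 -1.77 0.612 0.003747 0.3747 0.1621    FALSE   FALSE
 gene0022        234 -1.33 0.473 0.004862 0.4862 0.1621    FALSE   FALSE
 ...
```

The injected gene tops the scan: 132 of 20,000 samples carry a qualifying
PTV, their estimated deficit is −2.39 kg per allele (SE 0.63, consistent
with the injected −1.5), and it alone passes the Bonferroni threshold
0.05/100 = 5 × 10⁻⁴. Null genes scatter around β = 0 with uniform
p-values.

## Documentation

`vignettes/grip-burden-methods.Rmd` describes the statistical model, the
generator's assumptions and defaults, numerical choices (Firth iteration,
Box–Cox profiling, the Frisch–Waugh scan fast path, ridge LOCO offsets)
and known limitations.
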