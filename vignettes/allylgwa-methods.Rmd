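---
title: "Methods: trait algebra, heritability, and ridge-regression GWA for allyl feeding studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait algebra, heritability, and ridge-regression GWA for allyl feeding studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allylgwa)
```

## The experiment this package models

Allyl glucosinolate (sinigrin, 2-propenyl GSL) is a Brassicaceae defense
metabolite that, when fed exogenously through the roots, alters both the
biomass and the endogenous glucosinolate profile of *Arabidopsis thaliana*
seedlings. The design `allylgwa` analyses is a panel of inbred accessions
grown in replicate on control medium (`MS`) and on the same medium
supplemented with 50 uM allyl GSL (`MS+Allyl`), with per-seedling fresh
weight and 17 foliar glucosinolates (normalized to umol/g fresh weight)
measured on every plant. Two genetic features of such panels matter for the
analysis:

* accessions are fully inbred, so genotypes are homozygous and coded 0/1
  (never 0/1/2);
* roughly half of natural accessions carry a non-functional *AOP2* and make
  no alkenyl (allyl) GSL themselves; in those lines any measured allyl is
  exogenous uptake, which turns foliar allyl in the treated arm into a clean
  uptake phenotype.

The package implements the full analysis chain — derived-trait
construction, ANOVA/least-square means/broad-sense heritability, SNP-BLUP
ridge GWA with a heteroscedastic-effects (HEM) second stage and
permutation thresholds, gene-level candidate calling, condition-overlap
analysis, and expression-based prioritization — plus a synthetic-cohort
generator so every stage is testable without access to any real panel.

## Glucosinolate trait algebra

`compound_catalog()` fixes the 17 compounds (14 aliphatic, 3 indolic).
`build_trait_table()` adds 15 derived traits for a total of 32. The derived
memberships are reconstructed from the side-chain nomenclature (carbon
number; methylsulfinyl MS vs methylthio MT oxidation state; alkenyl,
hydroxylated, indolic classes):

* chain-length sums: 3C (3OHP, 3MSP, 3MTP, Allyl), 4C (4OHB, 4MSB, 4MTB,
  But-3-enyl, 2-OH-butenyl), 7C (7MSH, 7MTH), 8C (8MSO, 8MTO);
* short chain = 3C + 4C + 5MSP; long chain = 7C + 8C;
* chemistry sums: total MS, total MT, total alkyl (Allyl, But-3-enyl,
  2-OH-butenyl);
* class sums: total aliphatics = short + long; total indolics; total GSL =
  aliphatics + indolics;
* three ratios, all computed in the bounded form `a / (a + b)`
  (short vs. long, aliphatics vs. indolics, MS/MT). The one ratio whose
  formula is conventionally written out, the 4C oxidation ratio
  `4MSB / (4MSB + 4MTB)` (`oxidation_ratio()`), uses exactly this form,
  which is why the same convention is applied to every "X vs Y" trait.
  Both choices are overridable: `build_trait_table()` accepts any
  definition list of the same shape, so a supplementary-table definition
  can be dropped in verbatim.

Two conservation identities — total GSL = aliphatic + indolic, and
aliphatic = short + long — hold exactly by construction and are enforced in
the test suite to 1e-9 on random inputs.

Treatment responses are summarised by the relative difference
`(treated - control) / (0.5 (treated + control))`, which is antisymmetric
and bounded in [-2, 2] for non-negative traits: +2 means present only under
treatment, -2 only in the control. The 0/0 case is undefined and reported
as `NA` rather than 0, because "absent in both arms" carries no response
information.

## ANOVA, LS-means, and broad-sense heritability

`fit_anova()` fits the fixed-effects approximation
`trait ~ accession + treatment + accession:treatment + block` with
sequential (Type-I) sums of squares, in the declared term order
(`keep.order = TRUE`; the usual R reordering would silently move the
interaction after block). Treating block as a fixed additive term rather
than a random effect is deliberate: the replicate-level designs are
(nearly) balanced, where the two coincide, and block variance in such
experiments is minor; a full mixed-model REML for the phenotype ANOVA is
out of scope (the GWA variance components *are* REML-estimated, below).

`ls_means()` computes accession-by-treatment marginal means by averaging
model predictions over block levels; for balanced data this is the cell
mean, under unbalance it is the model-adjusted mean (checked against
`emmeans` in the tests). Cells that are entirely missing propagate `NA`.

`broad_sense_h2()` uses the expected-mean-square estimator

```
sigma_g^2 = max(0, (MS_accession - MS_error) / r_bar),   H^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)
```

with `r_bar` the harmonic mean number of observations per accession
(robust to a few lost seedlings) and `sigma_e^2` the residual mean square.
With treatment in the model the interaction term must be present so the
residual is pure error; `sigma_g^2` then measures the variance of
accession-level means across both arms (genetic main effects plus half the
accession-specific response). `H^2` is clamped to [0, 1].

`mutant_response_test()` reduces the validation-panel comparison to its
reported essence: a two-way genotype-by-treatment ANOVA of one mutant line
against the wild type, labelling the mutant `"b"` (response differs) iff
the interaction P <= 0.05, else `"a"`. Full multi-genotype compact-letter
assignment is intentionally out of scope.

## SNP-BLUP ridge regression and the HEM second stage

The GWA engine fits all SNPs jointly as random effects:
`y = 1 mu + Z u + e`, `u ~ N(0, sigma_u^2 I)`, `e ~ N(0, sigma_e^2 I)`,
with `y` the accession LS-means of a trait within one condition and `Z`
the centered genotype matrix. Columns are centered but *not*
variance-standardized, so effects remain in per-allele trait units.

Numerics: everything runs in the dual (n x n) representation. One
eigendecomposition of `K = Z Z'` per genotype matrix is reused for
(i) the REML profile over the single ratio `lambda = sigma_e^2 / sigma_u^2`
(a 1-D line search on `log lambda` over `log(mean diag eigenvalue) +/- 16`,
with the intercept handled by GLS and `sigma_u^2` profiled out), and
(ii) the BLUP effects `u_hat = Z' (K + lambda I)^{-1} (y - 1 mu_hat)`,
which for fixed `lambda` equal the primal ridge solution
`(Z'Z + lambda I)^{-1} Z' (y - mu_hat)` (verified to 1e-8 in the tests via
the push-through identity). Degenerate inputs (constant `y`) refuse to fit;
a `lambda` landing on the search boundary is recorded in the fit object.

The HEM second stage gives each SNP its own shrinkage. From the first
stage, per-SNP hat values `h_j = [(Z'Z + lambda I)^{-1} Z'Z]_{jj}`
(computed in the dual as `z_j'(K + lambda I)^{-1} z_j`) deflate the
apparent effects into per-SNP variances `w_j = u_hat_j^2 / (1 - h_j)`,
i.e. SNP-specific penalties `sigma_e^2 / w_j`; a single weighted re-solve
through `Z W Z' + sigma_e^2 I` yields the heteroscedastic effects
`u_hem`. One pass, no iteration: the first-stage effect decides each
SNP's penalty, and SNPs with a zero first-stage effect stay exactly zero.
Hat values numerically at or above 1 are clipped with a warning.

## Permutation significance thresholds

Degrees of freedom for jointly-shrunk random effects are ill-defined, so
significance is empirical: `permutation_threshold()` shuffles the
accession means against the genotype rows `B` times, re-runs the *entire*
pipeline — REML, BLUP, HEM — on each shuffle, pools `|u_hem|` across all
SNPs and permutations, and takes the `q`-quantile as `tau`. Re-estimating
the variance components inside every permutation is deliberate: the
threshold must reflect the null behaviour of the whole estimator, not of
the effects conditional on the observed `lambda`. A per-permutation-maximum
(family-wise) variant is available via `pool = "per_perm_max"`.

`q` defaults to 0.99 but is a first-class parameter (0.95 is a common
alternative convention for this threshold; both are supported and the
choice is reported in every output). Calls are `|u_hem| > tau`, and are
invariant under affine transformations of the phenotype and under SNP
relabelling (tested).

A property of this design worth knowing: under the null, the *per-dataset*
exceedance fraction is heavily right-skewed — most datasets have no SNP
above `tau`, a small minority (those whose REML lands at an interior
`lambda` while most permutations sit at the no-signal boundary) have many.
The SNP-level type-I rate is correct on average (about `1 - q`), but
averages over a small number of cohorts carry Monte-carlo error of the
same order as the rate itself; calibration statements should therefore be
made over many cohorts, or at the level of long-run averages.

## Gene-level candidates and prioritization

A SNP supports every annotated gene whose `[start, end]` span contains its
position (1-based inclusive; the gene body stands in for "coding region"
since plain gene annotations do not distinguish CDS from UTR/intron, and
SNPs in overlapping genes count toward each). A gene is a candidate iff it
has at least 2 significant SNPs — one significant SNP is too easily a
singleton artefact, while two independent hits in one gene body are strong
joint evidence. Candidate sets from the two conditions are partitioned
into control-unique / treatment-unique / shared; genes significant in
*both* conditions are interpreted as condition-independent and removed
before prioritization, and the remaining condition-unique candidates are
ranked by absolute transcript log2 fold-change response (direction-
agnostic, ties broken by gene id) with the top 13 retained by default.

## The synthetic cohort generator

`sim_config()` defaults encode the emulated design: 96 accessions, 5
replicates per treatment, 5 blocks, MAF floor 0.2, half the panel
AOP2-null, biomass heritability 0.88, uptake heritability 0.70, uptake
mean 0.34 umol/g fw. Specific choices:

* **Genotypes.** Minor-allele *counts* are drawn uniformly over the
  feasible set `{k : min(k, n-k)/n >= maf_min}` and carriers are a random
  subset, so the realized MAF floor holds exactly for every SNP. SNPs are
  independent (no linkage-disequilibrium model): downstream stages test
  the gene-calling logic, which is driven by placing several causal SNPs
  inside a gene, not by LD structure. The MAF spectrum is uniform above
  the floor rather than mutation-drift shaped — acceptable for common
  variants but one of the ways these cohorts are simpler than real panels.
* **Annotation.** Genes are SNP-bounded contiguous intervals (about 70% of
  SNPs genic), guaranteeing >= 2 SNPs per gene and non-overlap.
* **Biomass.** Mean 15 mg/plant and phenotypic SD 3.5 mg (realistic for
  15-day rosettes); additive model of accession genetic value (causal-SNP
  effects plus an unlinked polygenic term), treatment main effect (-7%),
  accession-by-treatment interaction carried by designated
  treatment-specific ("response") causal genes, small i.i.d. block effects
  (about 1% of the phenotypic SD, matching a nuisance term that experiments
  of this kind find non-significant), and Gaussian residuals. Component
  variances are rescaled so the realized accession-level variance fraction
  under the EMS estimator equals the target exactly: with response effects
  acting in one arm, their contribution to accession means is a quarter of
  their raw variance, so the budget is
  `v_main + v_response/4 + v_polygenic = h2 * Vp`. If the configured
  causal effects exceed the budget they are scaled down (with a message)
  rather than refused — only `target_h2 >= 1` is rejected outright.
  The default per-SNP effect is 0.25 phenotypic SD per allele; the
  "strong effect" regime used in the power experiments is 0.5.
* **Compounds.** Multiplicative lognormal model (base level x accession x
  treatment response x accession-response interaction x block x replicate
  noise), which keeps abundances non-negative and gives the expected
  ANOVA structure (aliphatics induced ~1.25x, indolics repressed ~0.8x
  under feeding). Allyl is special-cased: AOP2-null accessions have
  *exactly zero* endogenous allyl, and every treated seedling adds an
  uptake contribution.
* **Uptake.** Accession uptake means are lognormal with mean 0.34 umol/g
  fw and CV 0.45 (chosen so that a 44-accession panel spans roughly
  0.11-0.86 umol/g, matching the reported spread of such accumulation
  phenotypes), log-standardized per cohort; replicate noise is a mean-one
  lognormal multiplier whose variance is calibrated against the *realized*
  accession moments so that the between/(between+within) variance fraction
  equals the uptake heritability target in expectation.
* **Expression.** One log2 fold-change per gene, `N(0, 0.5^2)`, inflated
  by `1 + enrichment` for causal genes (enrichment 0 gives identical
  distributions).

Every generator stage draws from its own derived substream of the
configured seed, so stages are individually reproducible and never replay
each other's draws.

What these cohorts do **not** contain: population structure or kinship
(accessions are exchangeable — the analysis itself also applies no
structure correction, so tests exercise the estimator under its own
assumptions), LD, presence/absence variation in compounds other than
allyl, multi-trait genetic correlations, or maternal/plate effects.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to confounding present in real panels.

## Problem sizes used in the tests and acceptance runs

Chosen so the whole suite runs comfortably on one CPU while preserving the
design's shape: heritability-recovery cohorts use 96 (or 44 AOP2-null)
accessions with a 400-SNP / 50-gene panel (the H2 estimator depends on the
phenotype model, not the SNP count); null-calibration cohorts use the full
96 x 2000-SNP shape with B = 200 permutations and 20 seeds; power cohorts
use 96 x 3000 SNPs over 300 genes with 5 treatment-specific causal genes
at 0.5 SD/allele, B = 200, 10 seeds. The `analysis/` drivers run a single
96 x 3000 cohort end-to-end with B = 200; production-scale runs should
raise `B` to 1000.

## Known limitations

* The heteroscedastic pass is single-shot by design; iterating it would
  change the shrinkage profile and is not implemented.
* Fixed-effects block adjustment assumes near-balance; heavily unbalanced
  designs would warrant the mixed model this package deliberately omits.
* The permutation threshold inherits the per-dataset skew described above;
  with small `B` the pooled quantile is also discrete.
* Gene-body SNP assignment cannot distinguish regulatory from coding hits;
  with a CDS-resolved annotation the assignment table can simply be built
  from those features instead.
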