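---
title: "Genomic-feature mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-feature mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Genomic prediction regresses a quantitative trait on genome-wide markers at
once, predicting the genetic merit of unphenotyped individuals from a
relationship matrix estimated from those markers. For complex traits in
diversity panels — here the motivating setting is photosynthesis and growth
traits measured by high-throughput imaging in a panel of a few hundred fully
homozygous plant accessions — accuracy is limited by panel size and by
heritability. One proposed remedy is prior biology: if the genes relevant to
the trait are (partly) known, the markers inside those genes can be given
their own variance component, letting the model weight them differently from
the genomic background. `gfblup` implements that programme end to end:
marker QC, design-adjusted phenotypes, relationship matrices, the mixed
models, cross-validated evaluation, and a genome-wide scan over gene-set
features, plus a synthetic-data generator so every stage can be validated
against known truth.

## Models

All models operate on the adjusted phenotype vector $\tilde y$ (one value
per accession, see *Phenotype adjustment*) with an intercept as the only
fixed effect.

**GBLUP** (one genomic component):
$$\tilde y = \mu + g + \varepsilon,\qquad
  g \sim N(0, G\sigma_g^2),\quad \varepsilon \sim N(0, I\sigma_e^2).$$

**GFBLUP** (feature + remainder):
$$\tilde y = \mu + f + r + \varepsilon,\qquad
  f \sim N(0, G_f\sigma_f^2),\quad r \sim N(0, G_r\sigma_r^2),$$
where $G_f$ is built from the markers inside the feature's gene set and
$G_r$ from all remaining markers. The total genomic value is
$\hat g = \hat f + \hat r$.

**MultiBLUP** (adaptive regions): several region-specific kinships
$K_1,\dots,K_M$ plus a background; regions are chosen by tiling each
chromosome into 10-kb windows with 50% overlap, jointly testing each
window's markers against the phenotype (an OLS F-test of the centered
window markers vs. intercept-only), seeding regions where $p < 10^{-5}$,
and merging adjacent significant windows while the merged region stays
Bonferroni-significant at 0.05. If no window passes, the model falls back to
the single all-marker kinship, i.e. to GBLUP. The F-test is a deliberate,
documented choice: it is the simplest joint association test with an exact
small-sample null; tools in this space use related score tests, and the
region topology (seed-and-merge) matters more than the exact statistic.

**Relationship matrices.** Markers are centered and scaled per column,
$w_i = (z_i - 2p_i)/\sqrt{2p_i(1-p_i)}$ with $p_i$ the minor-allele
frequency of marker $i$ in the analyzed panel, and $G = WW'/m$. For a fully
homozygous panel (calls 0/2 only) the expected diagonal is 2 rather than
the outbred 1 — a useful sanity check on real data. Allele frequencies are
taken from the full panel (train and test together), matching the common
workflow of building one GRM before splitting; the leakage this causes is
negligible at these panel sizes and affects all compared models equally.
Feature and remainder GRMs are each scaled by their own marker count, which
makes the cross-product identity $k\,G_f + (m-k)\,G_r = m\,G_{\text{ALL}}$
exact — the test suite checks it to $10^{-8}$ relative tolerance.
Monomorphic markers are excluded at GRM construction (their scaling divides
by zero); a marker that QC removed simply contributes to no feature.

## REML estimation

Variance components are estimated by average-information REML written for
this package: the profile restricted likelihood of
$V = \sum_k \sigma_k^2 K_k + \sigma_e^2 I$ with the fixed effects projected
out, score vector from the projection matrix $P$, and updates from the
average-information matrix $\mathrm{AI}_{ij} = \tfrac12 y'PK_iPK_jPy$.
Numerical choices, all of which the solver's tests exercise:

* **Start:** the phenotypic variance split equally across all components
  plus the residual — a neutral start that avoids privileging any kinship.
* **First step:** one EM-REML update before switching to AI; EM is slow but
  guaranteed uphill, which stabilizes the first move when the start is far
  from the optimum.
* **Line search:** a proposed AI step that lowers the restricted
  log-likelihood is halved up to 10 times; if the AI direction fails
  entirely the solver retries the EM direction, and only gives up when no
  ascent is possible (declaring convergence if the attempted move was
  already below tolerance).
* **Boundaries:** negative proposals are floored at $10^{-8}\times$ the
  phenotypic variance; a component floored for three consecutive iterations
  is fixed at zero with a boundary flag and the remaining components are
  refit. This mirrors how practitioners read "variance could not be
  estimated" in small-panel REML.
* **Convergence:** largest absolute parameter change relative to the
  phenotypic variance below $10^{-5}$, within at most 100 iterations — the
  scale-free reading of the conventional tolerance.

The solver is validated against an independent grid-search oracle on
$n = 8$ instances (profiling the scale parameter analytically along a grid
over the variance ratio) and by Monte-Carlo parameter recovery
($|E[\hat h^2] - 0.5| < 0.05$ at $n = 500$ over 200 replicates).

**Prediction.** Test-set genomic values are predicted conditional on the
training phenotypes: per component,
$\hat g_k(\text{test}) = \sigma_k^2 K_k[\text{test},\text{train}]
V_{\text{train}}^{-1}(y - X\hat\beta)$. For a single kinship this is
algebraically identical to ridge-regression BLUP on marker effects with
$\lambda = m\sigma_e^2/\sigma_g^2$; the test suite checks the equivalence to
$10^{-8}$, which pins down both the scaling of $G$ and the handling of the
intercept.

## Phenotype adjustment

Replicated, spatially arranged phenotyping experiments carry design
variance: spatial row and column, the camera's image position, and the
sowing block. The adjusted phenotype is the genotype BLUE from a mixed model
with genotype fixed (cell-means coding, so values stay on the observed
scale) and each design factor as an independent random intercept, fit by
REML with `lme4::lmer` — the standard tool for exactly this model. Row and
column enter as categorical factors, not smooth trends, matching the
factor-list formulation. With balanced replicates and no design effects the
BLUE equals the replicate mean; with planted block effects it beats raw
means in mean-squared error, and both properties are tested. A design
factor observed at fewer than two levels is dropped with a warning; when
every accession has a single observation the genotype effect saturates the
data and the design factors are ignored with a message rather than
estimated from nothing. Variance components estimated at zero are reported
with a boundary flag, not silently dropped.

## Features from prior biology

Ontology annotations are up-propagated: a term's gene set is the union of
its direct annotations and those of all its descendants, traversing `is_a`
and `part_of` edges only (the relations annotation propagators use), with
evidence codes ignored. The propagation is a single topological sweep,
verified against a transitive-closure oracle, and a cycle raises an error
naming an offending term. Gene sets become genomic features positionally: a
marker belongs to a gene when its position lies inside the annotated
interval, boundaries included, strand ignored; a gene's multiple records
contribute the union of their intervals. Whether markers in UTRs or introns
count is controlled by the caller through the GFF record type used — the
package maps whatever intervals it is given. Features may map to zero
markers (small terms on sparsely genotyped regions); the scan skips them
with a report rather than failing.

## Evaluation

Accuracy is the Pearson correlation between observed adjusted phenotypes
and predicted total genomic values of the test fold, over k-fold
cross-validation repeated with fresh random partitions; the identical split
list is reused for every model compared, so model contrasts are paired.
Folds whose training fit puts the total heritability at a boundary (0 or 1)
are discarded and counted — predictions from such fits are constants and
their "accuracy" is meaningless. Models are compared on median accuracy;
significance by the two-sided Wilcoxon–Mann–Whitney test (exact when both
samples are small and tie-free, normal approximation with tie correction
otherwise), and the percent gain is defined on the medians.

The feature scan fits, per feature and timepoint, the full-data GFBLUP, the
boundary-mixture likelihood-ratio test against the all-marker GBLUP
($\mathrm{LR}$ clamped at zero; $p = \tfrac12 P(\chi^2_1 > \mathrm{LR})$,
$p = 1$ at $\mathrm{LR} = 0$), the cross-validated accuracies of both
models, and Benjamini–Hochberg q-values over the whole features ×
timepoints family. A record "passes filters" when $0.01 < h^2_f < 0.99$
(outside that range the feature variance is over-estimated or
undetermined), $p_{\mathrm{LRT}} < 0.05$, and the GFBLUP median accuracy
exceeds the GBLUP one with Wilcoxon $p < 0.05$; the unadjusted-p
("informative") and FDR-adjusted readings are exposed as separate flags.
The filtering is applied to the full-data fit, not per fold. The reported
component correlation is the Pearson correlation between the full-data
BLUPs $\hat f$ and $\hat r$ across accessions — one reasonable reading of a
quantity that could also be defined on the kinship matrices themselves; the
choice is deliberate and documented here.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
any particular genome:

* **Genotypes:** fully homozygous calls (0/2), minor-allele frequencies
  drawn uniformly from a configurable range (default includes rare
  alleles), positions with geometric gaps. LD comes from a block-copy
  model: within a block span (default 5 kb) each marker copies the previous
  marker's carrier vector and redraws each accession with probability 0.1.
  This gives tunable adjacent-marker correlation at $O(nm)$ cost;
  coalescent realism (allele-frequency/LD coupling, recombination maps) is
  deliberately out of scope, so tests passing here say nothing about, e.g.,
  population-structure confounding in real panels.
* **Features:** gene sets of configurable size drawn independently, so
  genes belong to several features, as with real ontology terms.
* **Traits:** causal effects $\sim N(0,1)$ scaled per marker by
  $1/\sqrt{2p(1-p)}$, the scaling under which the GRM matches the
  architecture and heritability is analytically controllable. The genetic
  value is rescaled so its sample variance is exactly
  $\sigma_g^2 = \frac{h^2}{1-h^2}\sigma_e^2$, and the within-feature
  component carries exactly the configured share of it. Replicates per
  accession are drawn uniformly from 1 up to the configured maximum
  (partially replicated designs are the norm in this kind of experiment);
  balanced designs are available for testing. Plants are randomized over a
  square grid; image positions group 12 consecutive grid slots, sowing
  blocks are equal quarters; each design factor contributes random
  intercepts with configurable SDs. Across timepoints the genetic values
  follow an AR(1) with independent genetic innovations — serial
  correlations above 0.9 are typical of measurements taken hours apart.
  Because residual noise is independent across timepoints, the
  *phenotype*-level serial correlation is attenuated below the configured
  value at moderate heritability; the configured parameter is the
  correlation of the underlying genetic values, and that is what the tests
  assert.
* Monomorphic markers are never chosen as causal (they carry no variance
  and the effect scaling would be undefined).

Everything is deterministic given the seed, and the package restores the
caller's RNG state.

## Problem sizes and known limitations

The validation experiments use panels of 160–500 accessions and 2000–4000
markers: large enough for REML to be well-behaved and planted features to be
recoverable, small enough that the whole suite runs on a single CPU in
minutes. Observations from those experiments worth knowing about:

* At very low heritability ($h^2 \approx 0.1$) the GBLUP baseline is
  frequently inestimable in 300–400-accession panels (training-fold
  heritability at a boundary), and relative accuracy gains — ratios with a
  near-zero denominator — are heavy-tailed. The negative association
  between heritability and the causal feature's percent gain emerges
  clearly with deeper cross-validation (more repeats) and mean aggregation;
  single shallow runs at $h^2 = 0.1$ can land anywhere.
* The null rejection rate of the boundary-mixture LRT is calibrated to
  $\approx 0.05$ in the realistic geometry (feature kinship vs. all-marker
  kinship); the $\tfrac12\delta_0 + \tfrac12\chi^2_1$ mixture is an
  asymptotic result and small panels show somewhat fewer exact-zero LR
  statistics than the limiting half.
* GFBLUP with the all-marker model as LRT null is a one-parameter
  enlargement along the constraint $\sigma_f^2/\sigma_r^2 = k/(m-k)$; tiny
  negative LR values from optimizer tolerance are clamped to zero.
* The models are strictly additive: dominance, epistasis and
  genotype-by-environment interaction are out of scope, as is imputation
  (markers with any missing call are removed, which is only sensible for
  dense homozygous panels with low missingness).
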