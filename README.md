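# gfblup — genomic-feature mixed models for genomic prediction

`gfblup` is an R package for genomic prediction in inbred diversity panels
where prior biology — Gene Ontology terms, co-expression clusters, curated
gene lists — defines *genomic features*: sets of markers that get their own
variance component. It is aimed at quantitative geneticists working with
replicated, high-throughput phenotyping of homozygous plant panels who want
to know whether a gene set actually helps predict a trait, and by how much.

## What it computes

With $\tilde y$ the design-adjusted phenotype (one BLUE per accession) and
$G = WW'/m$ the VanRaden relationship matrix from centered, scaled allele
counts $w_i = (z_i - 2p_i)/\sqrt{2p_i(1-p_i)}$:

* **GBLUP** — $\tilde y = \mu + g + \varepsilon$,
  $g \sim N(0, G\sigma_g^2)$: the all-marker baseline, with genomic
  heritability $h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$.
* **GFBLUP** — $\tilde y = \mu + f + r + \varepsilon$ with
  $f \sim N(0, G_f\sigma_f^2)$ built from the feature's markers and
  $r \sim N(0, G_r\sigma_r^2)$ from the rest;
  $h_f^2 = \sigma_f^2/(\sigma_f^2 + \sigma_r^2 + \sigma_e^2)$ measures the
  feature's share of phenotypic variance.
* **Adaptive MultiBLUP** — region-specific kinships found by scanning
  10-kb half-overlapping windows, seeding at $p < 10^{-5}$ and merging
  while Bonferroni-significant, falling back to GBLUP when nothing passes.

Variance components come from an average-information REML solver written
for this package (EM first step, AI updates with step-halving, boundary
handling, 100 iterations at tolerance $10^{-5}$). Test-set genomic values
are predicted conditional on training phenotypes; for one kinship this is
provably identical to ridge-regression BLUP on marker effects. Evaluation
uses repeated k-fold cross-validation with splits shared across models,
median-accuracy comparisons with Wilcoxon tests, boundary-mixture
likelihood-ratio tests ($\tfrac12\delta_0 + \tfrac12\chi^2_1$), and
Benjamini–Hochberg control over the feature × timepoint scan. A
synthetic-data generator produces homozygous genotypes with local LD, gene
models, overlapping feature sets, and replicate-level phenotypes with known
heritability, feature share, design effects and AR(1) timepoint structure.

## Worked example

Simulate a panel, plant 60% of the genetic variance of a $h^2 = 0.5$ trait
inside one feature, and ask whether GFBLUP on that feature beats GBLUP:

```r
library(gfblup)

cfg <- sim_config(n_accessions = 200, n_markers = 3000, n_chromosomes = 3,
                  n_genes = 300, n_features = 10,
                  feature_size_range = c(10, 40), seed = 42)
sim  <- simulate_genotypes(cfg)
geno <- qc_chain(sim$genotypes, maf = 0.01, window_bp = 50, r_threshold = 0.999)
geno
#> geno_matrix: 200 accessions x 2997 markers on 3 chromosome(s)
#>   missing calls: 0; MAF range: 0.01 - 0.5

feats  <- attach_markers(simulate_feature_sets(sim$genes, cfg), sim$genes, geno$map)
causal <- feats[[which.max(vapply(feats, function(f) f$n_markers, integer(1)))]]
causal
#> feature_set 'FT0008' (CUSTOM): 33 genes, 123 markers

tc <- trait_config(h2_target = 0.5, feature_id = causal$feature_id,
                   hf2_share = 0.6, n_causal = 50, n_replicates = 3,
                   vary_replicates = FALSE, seed = 7)
trait <- simulate_trait(geno, feats, tc)
blue  <- fit_design_model(trait$phenotypes)   # genotype BLUEs, design-adjusted
head(round(blue$blues, 3), 3)
#> acc0001 acc0002 acc0003
#>  12.480  11.050   7.642

G <- grm_from_genotypes(geno)
G
#> grm: 200 x 200 (subset 'ALL', 2997 markers), mean diag 2.000

y     <- blue$blues[rownames(geno$calls)]
fit_g <- reml_fit(y, list(g = G))
round(heritabilities(fit_g), 3)
#>    h2
#> 0.654

part  <- partition_grm(geno, causal$marker_indices, causal$feature_id)
fit_f <- reml_fit(y, list(f = part$G_f, r = part$G_r))
round(heritabilities(fit_f), 3)
#>    h2   hf2
#> 0.684 0.432

lrt <- likelihood_ratio_test(fit_f$restricted_loglik, fit_g$restricted_loglik,
                             tolerance = 0.05)
cat(sprintf("LR = %.2f, p = %.2g\n", lrt$LR, lrt$p))
#> LR = 56.20, p = 3.3e-14

sp   <- make_cv_splits(n_accessions(geno), k = 8, repeats = 10, seed = 1)
cv_g <- cross_validate(y, list(G), sp, model_id = "GBLUP")
cv_f <- cross_validate(y, list(part$G_f, part$G_r), sp, model_id = "GFBLUP")
cv_g
#> cv_result 'GBLUP': 80 accuracies (median 0.389), 0 discarded
cv_f
#> cv_result 'GFBLUP': 80 accuracies (median 0.683), 0 discarded
str(compare_accuracy(cv_f, cv_g))
#> List of 4
#>  $ median_a  : num 0.683
#>  $ median_b  : num 0.389
#>  $ pct_gain  : num 75.6
#>  $ p_wilcoxon: num 3.33e-15
```

Reading the numbers: the trait was built so the feature's markers carry
$0.6 \times 0.5 = 0.3$ of the phenotypic variance; the fitted $h_f^2 = 0.43$
(full-data REML overshoots somewhat at this panel size but ranks the causal
feature first among decoys — the scan tests quantify this), the
likelihood-ratio test firmly rejects $\sigma_f^2 = 0$, and cross-validated
accuracy rises from 0.389 to 0.683 (all 80 fold fits estimable, none
discarded). `feature_scan()` runs this whole contrast for a list of features
across timepoints and applies the $h_f^2$/LRT/Wilcoxon filters and FDR.

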