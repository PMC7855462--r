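#' Genomic heritabilities from a variance fit
#'
#' For a one-kinship (GBLUP) fit, h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2).
#' For a two-kinship (GFBLUP) fit with feature first, hf2 = sigma_f^2 /
#' (sigma_f^2 + sigma_r^2 + sigma_e^2) — the share of phenotypic variance
#' captured by the feature's markers — and h2 is the total genomic share.
#'
#' @param fit a `variance_fit`
#' @return named numeric with `h2` and, for multi-component fits, `hf2`
#' @export
heritabilities <- function(fit) {
  tot <- sum(fit$components) + fit$residual
  if (tot <= 0) stopf("undefined heritability: all variance components are zero")
  out <- c(h2 = sum(fit$components) / tot)
  if (length(fit$components) >= 2)
    out <- c(out, hf2 = unname(fit$components[1]) / tot)
  out
}

#' Likelihood-ratio test against a boundary null
#'
#' Tests a single variance component against zero. Because the null value
#' lies on the boundary of the parameter space, the LRT statistic is
#' asymptotically distributed as a 50:50 mixture of a point mass at 0 and a
#' chi-squared with 1 d.f.; the p-value is 1 when LR = 0 and
#' 0.5 * P(chi2_1 > LR) otherwise.
#'
#' @param loglik_full restricted log-likelihood of the full model
#' @param loglik_null restricted log-likelihood of the nested null model
#' @param tolerance slack allowed on the nesting inequality before erroring
#' @return list with `LR` (clamped at 0) and `p`
#' @export
likelihood_ratio_test <- function(loglik_full, loglik_null, tolerance = 1e-6) {
  lr <- 2 * (loglik_full - loglik_null)
  if (lr < -max(tolerance, 1e-8 * abs(loglik_null)) * 2)
    stopf("nesting violated: full-model log-likelihood %.6f < null %.6f",
          loglik_full, loglik_null)
  lr <- max(lr, 0)
  p <- if (lr == 0) 1 else 0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  list(LR = lr, p = p)
}

#' Benjamini-Hochberg adjustment over the whole scan family
#'
#' Step-up FDR over the complete features x timepoints family of p-values.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return numeric vector of q-values
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Genome-wide feature scan
#'
#' For every feature x timepoint combination, fits the two-component GFBLUP
#' (feature kinship + remainder kinship) on the full panel, tests it against
#' the all-marker GBLUP via the boundary-mixture LRT, cross-validates both
#' models on the shared splits, compares median accuracies with the
#' Wilcoxon-Mann-Whitney test, and adjusts the Wilcoxon p-values by
#' Benjamini-Hochberg over the whole scan. Features with no markers are
#' skipped with a report. Records pass the standard reporting filters when
#' 0.01 < hf2 < 0.99, p_LRT < 0.05 and the GFBLUP median accuracy exceeds
#' the GBLUP one with Wilcoxon p < 0.05.
#'
#' @param genotypes a QC'd [geno_matrix()]
#' @param features list of [feature_set()] with marker indices attached
#' @param blues accession x timepoint matrix of adjusted phenotypes (or a
#'   named vector for a single timepoint)
#' @param splits shared CV splits from [make_cv_splits()]
#' @param max_iter,tol REML controls
#' @return data.frame with one row per feature x timepoint: hf2, h2_gblup,
#'   LR, p_lrt, median_r_gfblup, median_r_gblup, pct_gain, p_wilcoxon,
#'   q_fdr, n_genes, n_markers, component_correlation, n_discarded,
#'   informative, passed_filters. The GBLUP baseline per timepoint and the
#'   correlation of pct_gain with h2_gblup are attached as attributes
#'   `baseline` and `gain_h2_correlation`.
#' @export
feature_scan <- function(genotypes, features, blues, splits,
                         max_iter = 100, tol = 1e-5) {
  if (is.vector(blues)) blues <- matrix(blues, ncol = 1,
                                        dimnames = list(names(blues), "t1"))
  acc <- rownames(genotypes$calls)
  if (!identical(rownames(blues), acc))
    blues <- blues[acc, , drop = FALSE]
  usable <- vapply(features, function(f)
    !is.null(f$marker_indices) && f$n_markers >= 1 &&
      f$n_markers < n_markers(genotypes), logical(1))
  if (!any(usable)) stopf("empty scan: no feature has a usable marker set")
  if (any(!usable))
    message(sprintf("skipping %d feature(s) with 0 markers (or all markers)",
                    sum(!usable)))
  features <- features[usable]

  G_all <- grm_from_genotypes(genotypes)
  tps <- colnames(blues)
  baseline <- list()
  for (tp in tps) {
    y <- blues[, tp]
    fit0 <- reml_fit(y, list(g = G_all), max_iter = max_iter, tol = tol)
    cv0 <- cross_validate(y, list(g = G_all), splits, model_id = "GBLUP",
                          max_iter = max_iter, tol = tol)
    baseline[[tp]] <- list(fit = fit0, cv = cv0,
                           h2 = unname(heritabilities(fit0)["h2"]))
  }

  rows <- list()
  for (f in features) {
    part <- partition_grm(genotypes, f$marker_indices, f$feature_id)
    for (tp in tps) {
      y <- blues[, tp]
      fitf <- reml_fit(y, list(f = part$G_f, r = part$G_r),
                       max_iter = max_iter, tol = tol)
      lrt <- likelihood_ratio_test(fitf$restricted_loglik,
                                   baseline[[tp]]$fit$restricted_loglik,
                                   tolerance = 1e-3)
      cvf <- cross_validate(y, list(f = part$G_f, r = part$G_r), splits,
                            model_id = f$feature_id,
                            max_iter = max_iter, tol = tol)
      cmp <- compare_accuracy(cvf, baseline[[tp]]$cv)
      h <- heritabilities(fitf)
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f$feature_id, timepoint = tp,
        hf2 = unname(h["hf2"]), h2_gblup = baseline[[tp]]$h2,
        LR = lrt$LR, p_lrt = lrt$p,
        median_r_gfblup = cmp$median_a, median_r_gblup = cmp$median_b,
        pct_gain = cmp$pct_gain, p_wilcoxon = cmp$p_wilcoxon,
        n_genes = f$n_genes, n_markers = f$n_markers,
        component_correlation = suppressWarnings(
          cor(fitf$blups[, 1], fitf$blups[, 2])),
        n_discarded = cvf$n_discarded,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q_fdr <- fdr_adjust(res$p_wilcoxon)
  res$informative <- res$p_lrt < 0.05 & res$p_wilcoxon < 0.05 &
    res$median_r_gfblup > res$median_r_gblup
  res$passed_filters <- res$informative & res$hf2 > 0.01 & res$hf2 < 0.99
  attr(res, "baseline") <- baseline
  ok <- is.finite(res$pct_gain)
  attr(res, "gain_h2_correlation") <-
    if (sum(ok) >= 3 && sd(res$h2_gblup[ok]) > 0 && sd(res$pct_gain[ok]) > 0)
      cor(res$h2_gblup[ok], res$pct_gain[ok]) else NA_real_
  res
}

#' Chi-square test for gene-set overlap
#'
#' 1-d.f. chi-square (no continuity correction) on the 2x2 table crossing
#' membership of the feature against membership of a reference list over a
#' gene universe — used to ask whether a feature contains more reference
#' genes than expected by chance.
#'
#' @param feature_genes,reference_genes character vectors, subsets of
#'   `universe`
#' @param universe character vector of all genes considered
#' @return list with `statistic`, `p` and the 2x2 `table`
#' @export
overlap_chisq <- function(feature_genes, reference_genes, universe) {
  if (length(universe) == 0) stopf("empty gene universe")
  feature_genes <- intersect(unique(feature_genes), universe)
  reference_genes <- intersect(unique(reference_genes), universe)
  in_f <- universe %in% feature_genes
  in_r <- universe %in% reference_genes
  tab <- table(factor(in_f, c(TRUE, FALSE)), factor(in_r, c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(abs(tab - expected) < 1e-12))
    return(list(statistic = 0, p = 1, table = tab))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}

#' Fisher enrichment of annotation terms in a gene set
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table of
#' term membership against feature membership over the universe, followed by
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param feature_genes character vector of genes in the feature
#' @param term_annotations named list: term id -> character vector of
#'   annotated genes (e.g. the output of [up_propagate()])
#' @param universe character vector of all genes
#' @param q_threshold threshold used for the `enriched` flag
#' @return data.frame term, n_term, n_overlap, odds_ratio, p, q, enriched
#' @export
fisher_enrichment <- function(feature_genes, term_annotations, universe,
                              q_threshold = 0.05) {
  feature_genes <- intersect(unique(feature_genes), universe)
  if (length(feature_genes) == 0) stopf("empty feature: nothing to test")
  rows <- lapply(names(term_annotations), function(tm) {
    tg <- intersect(unique(term_annotations[[tm]]), universe)
    a <- length(intersect(tg, feature_genes))
    b <- length(feature_genes) - a
    c_ <- length(tg) - a
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(term = tm, n_term = length(tg), n_overlap = a,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- fdr_adjust(res$p)
  res$enriched <- res$q < q_threshold
  res[order(res$p), , drop = FALSE]
}
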