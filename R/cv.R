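#' Repeated k-fold cross-validation splits
#'
#' Within each repeat the n accessions are randomly partitioned into k folds
#' whose sizes differ by at most one; every fold in turn is the test set.
#' The split list is deterministic given the seed and is meant to be reused
#' unchanged for every model being compared, so all models see exactly the
#' same train/test accessions.
#'
#' @param n number of accessions
#' @param k folds per repeat
#' @param repeats number of repeats
#' @param seed integer seed
#' @return list of length `k * repeats`; each element has `train`, `test`
#'   (integer index vectors), `fold` and `repeat_`
#' @export
make_cv_splits <- function(n, k = 8, repeats = 10, seed = 1L) {
  if (k > n) stopf("k (%d) exceeds n (%d)", k, n)
  if (k < 2) stopf("need at least 2 folds")
  with_seed(seed, {
    out <- list()
    for (r in seq_len(repeats)) {
      # assign fold labels cyclically to a random permutation of accessions
      perm <- sample.int(n)
      fold_of <- integer(n)
      fold_of[perm] <- rep(seq_len(k), length.out = n)
      for (f in seq_len(k)) {
        test <- which(fold_of == f)
        out[[length(out) + 1L]] <- list(train = which(fold_of != f),
                                        test = test, fold = f, repeat_ = r)
      }
    }
    out
  })
}

#' Cross-validated prediction accuracy
#'
#' For every split, refits REML on the training accessions only, predicts
#' the test set's total genomic values conditional on the training
#' phenotypes, and records the Pearson correlation between observed and
#' predicted values. Folds whose training fit puts the total genomic
#' heritability at a boundary (0 or 1), making it inestimable, are discarded
#' and counted, mirroring standard practice for small-panel REML.
#'
#' @param y named numeric adjusted phenotypes for the whole panel
#' @param kinships list of full-panel `grm` objects (or matrices)
#' @param splits split list from [make_cv_splits()]
#' @param model_id label stored in the result
#' @param discard_boundary apply the boundary-discard rule (default). Set to
#'   `FALSE` to keep every fold's accuracy, e.g. for null-calibration
#'   diagnostics where the rule would discard nearly everything.
#' @param max_iter,tol REML controls (see [reml_fit()])
#' @return a `cv_result`: `model_id`, `fold_accuracies` (numeric),
#'   `n_discarded`, `splits_seed` attribute-free bookkeeping fields
#' @export
cross_validate <- function(y, kinships, splits, model_id = "model",
                           discard_boundary = TRUE,
                           max_iter = 100, tol = 1e-5) {
  K <- lapply(kinships, function(k) if (inherits(k, "grm")) k$values else k)
  y <- stats::setNames(as.numeric(y), names(y))
  acc <- vector("numeric", 0)
  disc <- 0L
  for (sp in splits) {
    tr <- sp$train; te <- sp$test
    Ktr <- lapply(K, function(k) k[tr, tr, drop = FALSE])
    fit <- reml_fit(y[tr], Ktr, max_iter = max_iter, tol = tol)
    h2 <- sum(fit$components) / (sum(fit$components) + fit$residual)
    if (discard_boundary && (!is.finite(h2) || h2 < 1e-4 || h2 > 1 - 1e-4)) {
      disc <- disc + 1L
      next
    }
    pred <- predict_genomic_values(fit, K, y[tr], tr, te)
    # constant predictions (all variance at a boundary, kept only when
    # discard_boundary = FALSE) have no defined correlation
    acc <- c(acc, suppressWarnings(cor(y[te], pred$total)))
  }
  if (length(acc) == 0) stopf("all %d folds discarded: no accuracies", disc)
  structure(list(model_id = model_id, fold_accuracies = acc,
                 n_discarded = disc, n_splits = length(splits)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result '%s': %d accuracies (median %.3f), %d discarded\n",
              x$model_id, length(x$fold_accuracies),
              median(x$fold_accuracies), x$n_discarded))
  invisible(x)
}

#' Compare two cross-validated models
#'
#' Median accuracies, the percent gain of model a over model b, and a
#' two-sided Wilcoxon-Mann-Whitney test on the two accuracy samples (exact
#' when both samples have at most 12 values and no ties; normal
#' approximation with tie correction otherwise). Both results must come from
#' identical splits for the comparison to be fair.
#'
#' @param cv_a,cv_b `cv_result` objects (a is the candidate, b the baseline)
#' @return list with `median_a`, `median_b`, `pct_gain` (percent,
#'   100 * (median_a - median_b) / median_b; NA when median_b <= 0) and
#'   `p_wilcoxon`
#' @export
compare_accuracy <- function(cv_a, cv_b) {
  a <- cv_a$fold_accuracies
  b <- cv_b$fold_accuracies
  if (length(a) < 2 || length(b) < 2)
    stopf("need at least 2 accuracies per model (have %d and %d)",
          length(a), length(b))
  med_a <- median(a)
  med_b <- median(b)
  exact <- length(a) <= 12 && length(b) <= 12 && !any(duplicated(c(a, b)))
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
  list(median_a = med_a, median_b = med_b,
       pct_gain = if (med_b > 0) 100 * (med_a - med_b) / med_b else NA_real_,
       p_wilcoxon = p)
}
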