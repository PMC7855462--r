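#' Design-adjusted phenotypes (per-accession BLUEs)
#'
#' Fits the replicated design model for one timepoint with genotype as a
#' fixed effect and the experimental design factors — spatial row `x`,
#' column `y`, camera `image_position` and `sowing_block` — as independent
#' random intercepts, by REML via [lme4::lmer()]. The BLUE of each accession
#' is its estimated genotype fixed effect on the observed scale (cell-means
#' coding, so with no design corrections the BLUE is the replicate mean). A
#' random factor with fewer than two observed levels is dropped with a
#' warning; if no random factor survives, an ordinary least-squares fit is
#' used. Variance components estimated at (or clamped to) zero are reported
#' with a boundary flag rather than dropped.
#'
#' @param tbl phenotype data.frame with columns accession, replicate,
#'   timepoint, x, y, image_position, sowing_block, value
#' @param timepoint which timepoint to analyze (a level of `tbl$timepoint`);
#'   default: the only timepoint present
#' @return list with `blues` (named numeric, one per accession), `timepoint`,
#'   `varcomp` (data.frame factor/variance/boundary incl. residual),
#'   `dropped_factors`, `excluded_accessions` (accessions with zero
#'   observations at the timepoint)
#' @export
fit_design_model <- function(tbl, timepoint = NULL) {
  need <- c("accession", "value")
  if (!all(need %in% names(tbl)))
    stopf("phenotype table needs columns %s", paste(need, collapse = ", "))
  if (is.null(timepoint)) {
    tps <- unique(tbl$timepoint)
    if (length(tps) > 1)
      stopf("several timepoints present; pick one of: %s",
            paste(head(tps, 5), collapse = ", "))
    timepoint <- if (length(tps)) tps else NA
  }
  dat <- if ("timepoint" %in% names(tbl))
    tbl[tbl$timepoint == timepoint, , drop = FALSE] else tbl
  if (!all(is.finite(dat$value))) stopf("non-finite phenotype values")
  all_acc <- unique(tbl$accession)
  excluded <- setdiff(all_acc, unique(dat$accession))
  if (length(excluded))
    message(sprintf("%d accession(s) have no observations at timepoint %s and are excluded",
                    length(excluded), timepoint))
  if (length(unique(dat$accession)) < 2)
    stopf("need at least 2 accessions with data")
  dat$accession <- factor(dat$accession)

  rand <- c("x", "y", "image_position", "sowing_block")
  rand <- rand[rand %in% names(dat)]
  keep <- vapply(rand, function(f) length(unique(dat[[f]])) >= 2, logical(1))
  dropped <- rand[!keep]
  if (length(dropped))
    warnf("random factor(s) with < 2 levels dropped: %s",
          paste(dropped, collapse = ", "))
  rand <- rand[keep]
  for (f in rand) dat[[f]] <- factor(dat[[f]])
  if (length(rand) && nrow(dat) <= nlevels(dat$accession)) {
    # one observation per accession: the genotype fixed effect saturates the
    # data, so design variances are not separable; fall back to identity
    message("single observation per accession: design factors cannot be estimated and are ignored")
    rand <- character(0)
  }

  if (length(rand) == 0) {
    fit <- lm(value ~ 0 + accession, data = dat)
    blues <- coef(fit)
    varcomp <- data.frame(factor = "residual",
                          variance = sum(resid(fit)^2) / max(1, fit$df.residual),
                          boundary = FALSE)
  } else {
    fml <- as.formula(paste("value ~ 0 + accession +",
                            paste(sprintf("(1 | %s)", rand), collapse = " + ")))
    fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE,
                                       control = lme4::lmerControl(
                                         check.nobs.vs.nlev = "ignore",
                                         check.nobs.vs.nRE = "ignore",
                                         calc.derivs = FALSE)))
    blues <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- data.frame(factor = ifelse(vc$grp == "Residual", "residual", vc$grp),
                          variance = vc$vcov,
                          boundary = vc$vcov < 1e-10)
  }
  names(blues) <- sub("^accession", "", names(blues))
  list(blues = blues, timepoint = timepoint, varcomp = varcomp,
       dropped_factors = dropped, excluded_accessions = excluded)
}

#' BLUEs for every timepoint
#'
#' Runs [fit_design_model()] per timepoint and assembles an accession x
#' timepoint matrix (NA where an accession is missing at a timepoint).
#'
#' @inheritParams fit_design_model
#' @return numeric matrix, accessions x timepoints
#' @export
blue_matrix <- function(tbl) {
  tps <- unique(tbl$timepoint)
  acc <- unique(tbl$accession)
  out <- matrix(NA_real_, length(acc), length(tps),
                dimnames = list(acc, tps))
  for (tp in tps) {
    b <- fit_design_model(tbl, tp)$blues
    out[names(b), tp] <- b
  }
  out
}

#' Phenotypic variation summaries
#'
#' Per-timepoint coefficient of variation of the accession BLUEs
#' (CV = 100 * SD / mean) and the Pearson correlation matrix between
#' timepoint BLUE vectors (complete accessions only).
#'
#' @inheritParams fit_design_model
#' @return list with `cv` (named numeric, percent) and `correlation`
#'   (timepoint x timepoint matrix)
#' @export
summarize_variation <- function(tbl) {
  B <- blue_matrix(tbl)
  mu <- colMeans(B, na.rm = TRUE)
  if (any(abs(mu) < .Machine$double.eps))
    stopf("CV undefined: zero mean BLUE at timepoint %s",
          colnames(B)[which(abs(mu) < .Machine$double.eps)[1]])
  cv <- 100 * apply(B, 2, sd, na.rm = TRUE) / mu
  list(cv = cv,
       correlation = suppressWarnings(cor(B, use = "pairwise.complete.obs")))
}
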