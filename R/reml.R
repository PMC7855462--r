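#' Average-information REML for multi-kinship mixed models
#'
#' Fits y = X b + sum_k g_k + e with g_k ~ N(0, sigma_k^2 K_k) and
#' e ~ N(0, sigma_e^2 I) by restricted maximum likelihood. One kinship gives
#' GBLUP, two (feature + remainder) give GFBLUP, and several region kinships
#' give MultiBLUP. The first update is an EM-REML step (slow but safe), later
#' updates use the average-information matrix with step-halving whenever a
#' proposed step would decrease the restricted log-likelihood. Variance
#' proposals are floored at `1e-8 * var(y)`; a component stuck at the floor
#' for three consecutive iterations is fixed at zero (boundary flag) and the
#' remaining components are refit. Convergence is declared when the largest
#' parameter change, relative to the phenotypic variance, falls below `tol`.
#'
#' @param y named numeric vector of adjusted phenotypes, aligned with the
#'   kinships' accession order
#' @param kinships list of `grm` objects (or bare matrices) sharing accession
#'   order
#' @param X fixed-effects design matrix (default: intercept only)
#' @param max_iter maximum REML iterations
#' @param tol convergence tolerance on variance-ratio changes
#' @return a `variance_fit`: `components` (named variances, one per
#'   kinship), `residual`, `restricted_loglik`, `converged`, `n_iterations`,
#'   `boundary` (logical per component incl. residual), `beta` (fixed
#'   effects), `blups` (accessions x components matrix of fitted random
#'   effects), `fitted_mean`.
#' @export
reml_fit <- function(y, kinships, X = NULL, max_iter = 100, tol = 1e-5) {
  K <- lapply(kinships, function(k) if (inherits(k, "grm")) k$values else k)
  y <- stats::setNames(as.numeric(y), names(y))   # tolerate 1-d arrays
  n <- length(y)
  if (n < 2) stopf("need at least 2 observations")
  for (k in K) {
    if (!is.matrix(k) || nrow(k) != n || ncol(k) != n)
      stopf("every kinship must be %d x %d to match y", n, n)
    if (!is.null(rownames(k)) && !is.null(names(y)) &&
        !identical(rownames(k), names(y)))
      stopf("kinship accession order does not match y")
  }
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(names(y), "mu"))
  if (qr(X)$rank < ncol(X)) stopf("fixed-effects matrix is rank-deficient")
  nc <- length(K)
  if (n < nc + 1 + ncol(X))
    stopf("too few observations (%d) for %d variance parameters + %d fixed effects",
          n, nc + 1, ncol(X))
  vp <- var(y)
  if (vp <= 0) stopf("phenotype has zero variance")
  floor_v <- 1e-8 * vp

  theta <- rep(vp / (nc + 1), nc + 1)   # equal split across components
  fixed0 <- rep(FALSE, nc + 1)          # components pinned at exactly 0
  at_floor_run <- rep(0L, nc + 1)

  eval_theta <- function(theta) {
    V <- diag(theta[nc + 1], n)
    for (k in seq_len(nc)) if (theta[k] > 0) V <- V + theta[k] * K[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch))
      stopf("covariance matrix V is numerically singular (condition problem); variances: %s",
            paste(signif(theta, 4), collapse = ", "))
    Vinv <- chol2inv(ch)
    ViX <- Vinv %*% X
    XtViX <- crossprod(X, ViX)
    chx <- chol(XtViX)
    P <- Vinv - ViX %*% chol2inv(chx) %*% t(ViX)
    Py <- as.numeric(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll, Vinv = Vinv, XtViX = XtViX, ViX = ViX)
  }

  st <- eval_theta(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    free <- which(!fixed0)
    # score and AI over free components (K_{nc+1} = I)
    KPy <- lapply(seq_len(nc + 1), function(k)
      if (k <= nc) as.numeric(K[[k]] %*% st$Py) else st$Py)
    score <- vapply(free, function(k) {
      trPK <- if (k <= nc) sum(st$P * K[[k]]) else sum(diag(st$P))
      -0.5 * (trPK - sum(st$Py * KPy[[k]]))
    }, numeric(1))
    if (iter == 1L) {
      # EM-REML step: robust far from the optimum
      prop <- vapply(free, function(k) {
        trPK <- if (k <= nc) sum(st$P * K[[k]]) else sum(diag(st$P))
        theta[k] + theta[k]^2 * (sum(st$Py * KPy[[k]]) - trPK) / n
      }, numeric(1))
      delta <- prop - theta[free]
    } else {
      AI <- matrix(0, length(free), length(free))
      PKPy <- lapply(free, function(k) as.numeric(st$P %*% KPy[[k]]))
      for (a in seq_along(free)) for (b in seq_len(a)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(KPy[[free[a]]] * PKPy[[b]])
      }
      delta <- tryCatch(solve(AI, score), error = function(e) score * 0)
      if (all(delta == 0)) delta <- score * (vp / n)   # gradient fallback
    }
    try_step <- function(delta) {
      for (h in 0:10) {
        cand <- theta
        cand[free] <- pmax(theta[free] + delta / 2^h, floor_v)
        st_cand <- tryCatch(eval_theta(cand), error = function(e) NULL)
        if (!is.null(st_cand) && st_cand$ll >= st$ll - 1e-10)
          return(list(cand = cand, st = st_cand))
      }
      NULL
    }
    step <- try_step(delta)
    if (is.null(step) && iter > 1L) {
      # AI direction failed even after 10 halvings (typical at a variance
      # boundary); retry with the always-ascending EM direction
      em <- vapply(free, function(k) {
        trPK <- if (k <= nc) sum(st$P * K[[k]]) else sum(diag(st$P))
        theta[k] + theta[k]^2 * (sum(st$Py * KPy[[k]]) - trPK) / n
      }, numeric(1))
      step <- try_step(em - theta[free])
    }
    if (is.null(step)) {
      # no ascent possible: at a stationary point if the attempted move was
      # already below tolerance, otherwise give up
      attempted <- max(abs(pmax(theta[free] + delta, floor_v) - theta[free])) / vp
      converged <- attempted < tol
      break
    }
    cand <- step$cand
    st_cand <- step$st
    change <- max(abs(cand - theta)) / vp
    theta <- cand
    st <- st_cand
    # boundary bookkeeping: fix a persistently floored component at 0
    at_floor <- !fixed0 & theta <= floor_v * (1 + 1e-12)
    at_floor_run <- ifelse(at_floor, at_floor_run + 1L, 0L)
    newly_fixed <- which(at_floor_run >= 3L & !fixed0)
    if (length(newly_fixed)) {
      fixed0[newly_fixed] <- TRUE
      theta[newly_fixed] <- 0
      if (fixed0[nc + 1]) theta[nc + 1] <- floor_v  # keep V nonsingular
      st <- eval_theta(theta)
      next   # refit remainder before judging convergence
    }
    if (change < tol) {
      converged <- TRUE
      break
    }
  }

  beta <- solve(st$XtViX, crossprod(X, st$Vinv %*% y))
  blups <- vapply(seq_len(nc), function(k)
    theta[k] * as.numeric(K[[k]] %*% st$Py), numeric(n))
  blups <- matrix(blups, n, nc,
                  dimnames = list(names(y),
                                  names(K) %||% paste0("k", seq_len(nc))))
  comp <- theta[seq_len(nc)]
  names(comp) <- colnames(blups)
  structure(list(components = comp,
                 residual = theta[nc + 1],
                 restricted_loglik = st$ll,
                 converged = converged,
                 n_iterations = iter,
                 boundary = c(theta[seq_len(nc)] <= floor_v,
                              theta[nc + 1] <= floor_v),
                 beta = as.numeric(beta),
                 blups = blups,
                 fitted_mean = as.numeric(X %*% beta)),
            class = "variance_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.variance_fit <- function(x, ...) {
  cat("variance_fit:",
      paste(sprintf("%s=%.4g", names(x$components), x$components),
            collapse = ", "),
      sprintf("residual=%.4g; logLik=%.3f; %s in %d iter\n",
              x$residual, x$restricted_loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Predict genomic values of test accessions
#'
#' Conditional prediction of the test set given training phenotypes: for each
#' component k, g_k(test) = sigma_k^2 K_k[test, train] V_train^-1
#' (y_train - X beta), with V_train assembled from the fitted variances over
#' the training block. The total genomic value is the sum over components.
#'
#' @param fit a `variance_fit` obtained on the training subset
#' @param kinships list of full-panel `grm` objects (or matrices), same
#'   order as in the fit
#' @param y_train named numeric vector of training phenotypes
#' @param train_idx,test_idx integer indices into the panel; must not overlap
#' @param X full-panel fixed-effects matrix (default intercept)
#' @return list with `accession_ids`, `total` (named numeric) and
#'   `per_component` (test x component matrix)
#' @export
predict_genomic_values <- function(fit, kinships, y_train, train_idx, test_idx,
                                   X = NULL) {
  K <- lapply(kinships, function(k) if (inherits(k, "grm")) k$values else k)
  y_train <- stats::setNames(as.numeric(y_train), names(y_train))
  if (length(intersect(train_idx, test_idx)))
    stopf("train and test sets overlap (%d shared accessions)",
          length(intersect(train_idx, test_idx)))
  n_all <- nrow(K[[1]])
  if (is.null(X)) X <- matrix(1, n_all, 1)
  nc <- length(K)
  ntr <- length(train_idx)
  V <- diag(fit$residual, ntr)
  for (k in seq_len(nc))
    if (fit$components[k] > 0)
      V <- V + fit$components[k] * K[[k]][train_idx, train_idx]
  Vinv <- chol2inv(chol(V))
  Xtr <- X[train_idx, , drop = FALSE]
  beta <- solve(crossprod(Xtr, Vinv %*% Xtr), crossprod(Xtr, Vinv %*% y_train))
  alpha <- Vinv %*% (y_train - Xtr %*% beta)
  per <- vapply(seq_len(nc), function(k)
    fit$components[k] * as.numeric(K[[k]][test_idx, train_idx, drop = FALSE] %*% alpha),
    numeric(length(test_idx)))
  per <- matrix(per, length(test_idx), nc)
  ids <- rownames(K[[1]])[test_idx] %||% as.character(test_idx)
  dimnames(per) <- list(ids, names(fit$components))
  total <- rowSums(per)
  names(total) <- ids
  list(accession_ids = ids, total = total, per_component = per)
}
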