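test_that("REML solution matches a brute-force grid search at n = 8", {
  K <- random_kinship(8, m = 12, seed = 2)
  n_checked <- 0
  for (seed in c(6, 9, 11, 12)) {   # instances with an interior optimum
    y <- draw_y(K, 0.6, 0.4, seed)
    fit <- reml_fit(y, list(K))
    # oracle: profile likelihood over h2 grid (step 1e-3 on the ratio);
    # for fixed structure V0 = h K + (1-h) I the scale profiles out as
    # tau = y'P0y / (n - 1)
    grid <- seq(0.001, 0.999, by = 0.001)
    ll <- vapply(grid, function(h) {
      n <- length(y)
      V0 <- h * K + (1 - h) * diag(n)
      X <- matrix(1, n, 1)
      Vi <- solve(V0)
      XtViX <- crossprod(X, Vi %*% X)
      P0 <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
      tau <- drop(t(y) %*% P0 %*% y) / (n - 1)
      -0.5 * (determinant(V0)$modulus[1] + n * log(tau) +
                log(XtViX[1, 1] / tau) + (n - 1))
    }, numeric(1))
    h_grid <- grid[which.max(ll)]
    h_fit <- fit$components[1] / (fit$components[1] + fit$residual)
    if (h_grid > 0.002 && h_grid < 0.998) {
      n_checked <- n_checked + 1
      expect_lt(abs(h_fit - h_grid), 2e-3)
      # the fitted restricted log-likelihood can't be beaten by the grid
      expect_gte(fit$restricted_loglik, max(ll) - 1e-6)
    }
  }
  expect_gte(n_checked, 3)
})

test_that("pure-noise phenotypes drive the genetic variance to the boundary", {
  K <- random_kinship(80, seed = 6)
  y <- withr::with_seed(9, structure(rnorm(80), names = rownames(K)))
  fit <- reml_fit(y, list(K))
  h2 <- fit$components[1] / (fit$components[1] + fit$residual)
  expect_lt(h2, 0.05)
  expect_true(fit$boundary[1] || h2 < 0.05)
})

test_that("restricted log-likelihood at the optimum matches the direct formula", {
  K <- random_kinship(40, seed = 12)
  y <- draw_y(K, 0.5, 0.5, seed = 13)
  fit <- reml_fit(y, list(K))
  expect_equal(fit$restricted_loglik,
               reml_loglik_direct(y, K, fit$components[1], fit$residual),
               tolerance = 1e-6)
})

test_that("REML recovers simulated variance parameters on average", {
  # lighter companion to the acceptance-scale run: n = 200, 40 replicates
  K <- random_kinship(200, m = 500, seed = 20)
  h2_hat <- vapply(1:40, function(i) {
    y <- draw_y(K, 0.5, 0.5, seed = 100 + i)
    fit <- reml_fit(y, list(K))
    unname(fit$components[1] / (fit$components[1] + fit$residual))
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.08)
})

test_that("fit is invariant to simultaneous permutation of accessions", {
  K <- random_kinship(50, seed = 30)
  y <- draw_y(K, 0.7, 0.3, seed = 31)
  fit1 <- reml_fit(y, list(K))
  perm <- withr::with_seed(32, sample(50))
  fit2 <- reml_fit(y[perm], list(K[perm, perm]))
  expect_equal(fit1$components, fit2$components, tolerance = 1e-6)
  expect_equal(fit1$restricted_loglik, fit2$restricted_loglik,
               tolerance = 1e-6)
})

test_that("GFBLUP collapses to GBLUP when the feature variance is zero", {
  pan <- small_panel()
  part <- partition_grm(pan$g, pan$feats[[1]]$marker_indices)
  y <- draw_y(part$G_r$values, 0.5, 0.5, seed = 41)
  fit_r <- reml_fit(y, list(r = part$G_r))
  # predictions from a two-component model with sigma_f^2 pinned at 0 equal
  # the one-component predictions on the remainder kinship
  fit0 <- fit_r
  fit0$components <- c(f = 0, r = unname(fit_r$components[1]))
  tr <- 1:120; te <- 121:160
  p2 <- predict_genomic_values(fit0, list(part$G_f, part$G_r), y[tr], tr, te)
  p1 <- predict_genomic_values(fit_r, list(part$G_r), y[tr], tr, te)
  expect_equal(p2$total, p1$total, tolerance = 1e-10)
  expect_equal(unname(p2$per_component[, 1]), rep(0, length(te)))
})

test_that("conditional prediction equals ridge-regression marker effects", {
  pan <- small_panel()
  g <- pan$g
  W <- center_scale(g)
  m <- ncol(W)
  G <- compute_grm(W)
  y <- draw_y(G$values, 0.6, 0.4, seed = 55)
  tr <- 1:120; te <- 121:160
  s2g <- 0.6; s2e <- 0.4
  fit <- structure(list(components = c(g = s2g), residual = s2e,
                        beta = mean(y[tr])), class = "variance_fit")
  pred <- predict_genomic_values(fit, list(G), y[tr], tr, te)
  # RR-BLUP oracle: a_hat = W_tr' (W_tr W_tr' + lambda I)^-1 (y - mu_hat),
  # lambda = m * s2e / s2g, mu_hat the GLS intercept
  Wtr <- W[tr, , drop = FALSE]
  Vtr <- s2g * G$values[tr, tr] + s2e * diag(length(tr))
  Vi <- solve(Vtr)
  mu <- drop(crossprod(rep(1, length(tr)), Vi %*% y[tr]) /
               crossprod(rep(1, length(tr)), Vi %*% rep(1, length(tr))))
  lambda <- m * s2e / s2g
  a_hat <- crossprod(Wtr, solve(tcrossprod(Wtr) + lambda * diag(length(tr)),
                                y[tr] - mu))
  pred_rr <- drop(W[te, , drop = FALSE] %*% a_hat)
  expect_lt(max(abs(unname(pred$total) - pred_rr)), 1e-8)
})

test_that("duplicated genotype rows get the training accession's BLUP", {
  K0 <- random_kinship(40, seed = 60)
  # make accession 40 an exact genetic copy of accession 1
  K <- K0
  K[40, ] <- K[1, ]; K[, 40] <- K[, 1]; K[40, 40] <- K[1, 1]
  y <- draw_y(K0, 0.6, 0.4, seed = 61)[1:39]
  fit <- reml_fit(y, lapply(list(K), function(k) k[1:39, 1:39]))
  pred <- predict_genomic_values(fit, list(K), y, 1:39, 40)
  blup1 <- fit$blups[1, 1]
  expect_equal(unname(pred$total), unname(blup1), tolerance = 1e-8)
  expect_error(predict_genomic_values(fit, list(K), y, 1:39, c(5, 40)),
               "overlap")
})

test_that("near-zero residual interpolates the training phenotypes", {
  K <- random_kinship(60, seed = 70)
  K <- K + diag(1e-6, 60)   # full rank so interpolation is well defined
  y <- draw_y(K, 1, 1e-8, seed = 71)   # essentially noise-free
  fit <- reml_fit(y, list(K))
  gfit <- fit$blups[, 1]
  expect_lt(max(abs(gfit - (y - fit$fitted_mean))), 1e-3)
  expect_lt(fit$residual / fit$components[1], 1e-3)
})

test_that("two-component fits recover a planted feature share", {
  pan <- small_panel()
  f <- pan$feats[[which.max(vapply(pan$feats, function(x) x$n_markers,
                                   integer(1)))]]
  part <- partition_grm(pan$g, f$marker_indices)
  hf2_hat <- vapply(1:25, function(i) {
    tc <- trait_config(h2_target = 0.6, feature_id = f$feature_id,
                       hf2_share = 0.6, n_causal = 40, n_replicates = 1,
                       vary_replicates = FALSE,
                       design_effect_sds = c(x = 0, y = 0,
                                             image_position = 0,
                                             sowing_block = 0),
                       seed = 500 + i)
    tr <- simulate_trait(pan$g, pan$feats, tc)
    y <- tapply(tr$phenotypes$value, tr$phenotypes$accession, mean)
    y <- y[rownames(pan$g$calls)]
    fit <- reml_fit(y, list(f = part$G_f, r = part$G_r))
    unname(heritabilities(fit)["hf2"])
  }, numeric(1))
  # planted: hf2 = h2 * share = 0.36
  expect_lt(abs(mean(hf2_hat) - 0.36), 0.12)
  expect_gt(mean(hf2_hat), 0.15)
})
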