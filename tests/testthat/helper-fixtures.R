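# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Tiny hand-built genotype matrix with known MAFs.
tiny_geno <- function() {
  calls <- matrix(c(0, 2, 2, 0,
                    2, 2, 0, 0,
                    0, 0, 0, 2), nrow = 4, ncol = 3,
                  dimnames = list(paste0("a", 1:4), paste0("m", 1:3)))
  map <- data.frame(marker_id = paste0("m", 1:3), chrom = "chr1",
                    pos = c(100, 220, 500))
  geno_matrix(calls, map)
}

# Small QC'd panel + mapped features shared across tests.
small_panel <- function() {
  cached("small_panel", function() {
    cfg <- sim_config(n_accessions = 160, n_markers = 3000, n_chromosomes = 3,
                      n_genes = 300, n_features = 8,
                      feature_size_range = c(10, 40), seed = 101)
    sim <- simulate_genotypes(cfg)
    g <- qc_chain(sim$genotypes)
    feats <- attach_markers(simulate_feature_sets(sim$genes, cfg),
                            sim$genes, g$map)
    list(cfg = cfg, genes = sim$genes, g = g, feats = feats,
         G = grm_from_genotypes(g))
  })
}

# Larger panel for planted-feature experiments: 400 accessions, ~4k markers,
# 21 overlapping gene-set features.
panel400 <- function() {
  cached("panel400", function() {
    cfg <- sim_config(n_accessions = 400, n_markers = 4000, n_chromosomes = 5,
                      n_genes = 500, n_features = 21,
                      feature_size_range = c(15, 50),
                      maf_range = c(0.05, 0.5), seed = 2024)
    sim <- simulate_genotypes(cfg)
    g <- qc_chain(sim$genotypes)
    feats <- attach_markers(simulate_feature_sets(sim$genes, cfg),
                            sim$genes, g$map)
    nm <- vapply(feats, function(f) f$n_markers, integer(1))
    causal_idx <- which.min(abs(nm - stats::median(nm)))
    list(cfg = cfg, g = g, feats = feats, G = grm_from_genotypes(g),
         causal_idx = causal_idx,
         parts = lapply(feats, function(f)
           partition_grm(g, f$marker_indices, f$feature_id)))
  })
}

# Accession-mean phenotype vector aligned to the panel.
trait_blues <- function(g, feats, tc) {
  tr <- simulate_trait(g, feats, tc)
  y <- tapply(tr$phenotypes$value, tr$phenotypes$accession, mean)
  stats::setNames(as.numeric(y), names(y))[rownames(g$calls)]
}

# Rebuild a geno_matrix from a column subset (tests only use exported API).
subset_markers_for_test <- function(g, idx) {
  geno_matrix(g$calls[, idx, drop = FALSE], g$map[idx, , drop = FALSE])
}

# Random PSD kinship of dimension n (not marker-derived; for solver tests).
random_kinship <- function(n, m = 4 * n, seed = 1) {
  withr::with_seed(seed, {
    W <- scale(matrix(rnorm(n * m), n, m))
    K <- tcrossprod(W) / m
    dimnames(K) <- list(paste0("a", seq_len(n)), paste0("a", seq_len(n)))
    K
  })
}

# Draw y ~ N(0, s2g * K + s2e * I), named by K's accessions.
draw_y <- function(K, s2g, s2e, seed) {
  withr::with_seed(seed, {
    n <- nrow(K)
    V <- s2g * K + s2e * diag(n)
    y <- drop(rnorm(n) %*% chol(V))
    names(y) <- rownames(K)
    y
  })
}

# Independent restricted log-likelihood evaluator (direct formula, no reuse
# of the solver's internals): -0.5 [log|V| + log|X'V^-1 X| + y'Py].
reml_loglik_direct <- function(y, K, s2g, s2e) {
  n <- length(y)
  V <- s2g * K + s2e * diag(n)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
  -0.5 * (determinant(V)$modulus[1] + log(XtViX[1, 1]) +
            drop(t(y) %*% P %*% y))
}
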