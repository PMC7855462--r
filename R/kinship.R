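new_grm <- function(values, n_markers_used, marker_subset_id = "ALL") {
  structure(list(values = values,
                 n_markers_used = as.integer(n_markers_used),
                 marker_subset_id = marker_subset_id),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d (subset '%s', %d markers), mean diag %.3f\n",
              nrow(x$values), ncol(x$values), x$marker_subset_id,
              x$n_markers_used, mean(diag(x$values))))
  invisible(x)
}

#' Center and scale a genotype matrix for GRM construction
#'
#' Each marker column z_i is transformed to w_i = (z_i - 2 p_i) /
#' sqrt(2 p_i (1 - p_i)), where p_i is the minor-allele frequency computed
#' from the supplied panel. Columns of the result have mean exactly zero.
#' Monomorphic markers make the scaling divide by zero and must be excluded
#' beforehand; an informative error names the first offender.
#'
#' @param g a [geno_matrix()] without missing calls
#' @return numeric matrix W (accessions x markers)
#' @export
center_scale <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$calls)) stopf("remove missing calls before centering/scaling")
  p <- colMeans(g$calls) / 2        # frequency of the counted (minor) allele
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stopf("monomorphic marker '%s' cannot be scaled (division by zero); drop it first",
          colnames(g$calls)[which(mono)[1]])
  W <- sweep(g$calls, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  W
}

#' Compute a genomic relationship matrix
#'
#' G = W W' / m from the centered, scaled genotype matrix W over m markers
#' (VanRaden's first method). For a fully inbred panel the expected diagonal
#' is 2.
#'
#' @param W centered/scaled marker matrix from [center_scale()]
#' @param subset_id label recording which marker subset built this GRM
#' @return a `grm` object: symmetric accession x accession matrix plus the
#'   marker count used.
#' @export
compute_grm <- function(W, subset_id = "ALL") {
  m <- ncol(W)
  if (is.null(m) || m == 0) stopf("empty marker subset: no markers to build a GRM from")
  G <- tcrossprod(W) / m
  G <- (G + t(G)) / 2   # enforce exact symmetry against rounding
  new_grm(G, m, subset_id)
}

#' Build feature and remainder GRMs
#'
#' Splits the markers into a feature set and its complement; each GRM is
#' scaled by its own marker count, so the cross-product additivity
#' `k G_f + (m - k) G_r = m G_ALL` holds exactly.
#'
#' @param g a [geno_matrix()] without missing or monomorphic markers
#' @param feature_markers integer indices (columns of `g$calls`) of the
#'   feature's markers; must be a nonempty strict subset.
#' @param subset_id label for the feature GRM
#' @return list with elements `G_f` and `G_r` (both `grm` objects)
#' @export
partition_grm <- function(g, feature_markers, subset_id = "feature") {
  stopifnot(inherits(g, "geno_matrix"))
  m <- n_markers(g)
  feature_markers <- sort(unique(as.integer(feature_markers)))
  if (length(feature_markers) == 0)
    stopf("degenerate partition: feature has no markers")
  if (any(feature_markers < 1 | feature_markers > m))
    stopf("feature marker indices out of range 1..%d", m)
  if (length(feature_markers) == m)
    stopf("degenerate partition: feature covers all markers (remainder empty)")
  W <- center_scale(g)
  list(G_f = compute_grm(W[, feature_markers, drop = FALSE], subset_id),
       G_r = compute_grm(W[, -feature_markers, drop = FALSE],
                         paste0(subset_id, "_remainder")))
}

#' Full-panel GRM from a genotype matrix
#'
#' Convenience wrapper: drops monomorphic markers (with a message), centers,
#' scales and builds G from everything that remains.
#'
#' @param g a [geno_matrix()] without missing calls
#' @return a `grm` object
#' @export
grm_from_genotypes <- function(g) {
  mono <- g$maf <= 0
  if (any(mono)) {
    message(sprintf("excluding %d monomorphic marker(s) from GRM construction",
                    sum(mono)))
    g <- subset_markers(g, !mono)
  }
  compute_grm(center_scale(g), "ALL")
}
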