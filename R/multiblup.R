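#' Adaptive region selection for MultiBLUP
#'
#' Tiles each chromosome into windows of `window_bp` base pairs stepping
#' `window_bp * (1 - overlap)` (default: adjacent 10-kb windows overlapping
#' by half). The markers of each window are jointly tested against the
#' phenotype with an F-test of the ordinary least-squares regression of y on
#' the window's centered allele counts versus intercept only. Windows with
#' p < `p_enter` seed regions; overlapping or adjacent significant windows
#' are merged while the merged region's Bonferroni-adjusted p (times the
#' number of windows tested) stays below `p_merge_bonferroni`. When no
#' window reaches significance, the single all-marker group is returned, so
#' the model falls back to GBLUP.
#'
#' @param g a [geno_matrix()] without missing calls
#' @param y named numeric phenotype aligned to `g`'s accessions
#' @param window_bp window size in base pairs
#' @param overlap fractional overlap between adjacent windows, in [0, 1)
#' @param p_enter per-window significance threshold for seeding a region
#' @param p_merge_bonferroni Bonferroni-adjusted threshold a merged region
#'   must satisfy
#' @return list with `groups` (list of integer marker-index vectors; the
#'   last one named `background` holds the complement, unless the fallback
#'   single `ALL` group is returned), `fallback` (logical) and `windows`
#'   (data.frame of all tested windows with their p-values)
#' @export
multiblup_select_regions <- function(g, y, window_bp = 10000, overlap = 0.5,
                                     p_enter = 1e-5,
                                     p_merge_bonferroni = 0.05) {
  stopifnot(inherits(g, "geno_matrix"))
  if (window_bp <= 0) stopf("'window_bp' must be positive")
  if (overlap < 0 || overlap >= 1) stopf("'overlap' must lie in [0, 1)")
  if (anyNA(g$calls)) stopf("remove missing calls before region selection")
  y <- align_to(y, rownames(g$calls))
  step <- max(1, round(window_bp * (1 - overlap)))

  win <- do.call(rbind, lapply(unique(g$map$chrom), function(ch) {
    len <- max(g$map$pos[g$map$chrom == ch])
    starts <- seq(1L, max(1L, len - step), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp - 1L, len),
               stringsAsFactors = FALSE)
  }))
  win$p <- vapply(seq_len(nrow(win)), function(i) {
    idx <- which(g$map$chrom == win$chrom[i] &
                   g$map$pos >= win$start[i] & g$map$pos <= win$end[i])
    window_ftest(g$calls[, idx, drop = FALSE], y)
  }, numeric(1))
  n_win <- nrow(win)

  sig <- which(win$p < p_enter)
  if (length(sig) == 0) {
    return(list(groups = list(ALL = seq_len(n_markers(g))),
                fallback = TRUE, windows = win))
  }
  # merge overlapping/adjacent significant windows into regions, keeping a
  # merge only while the merged region stays Bonferroni-significant
  regions <- list()
  cur <- win[sig[1], c("chrom", "start", "end")]
  if (length(sig) > 1) for (i in sig[-1]) {
    adjacent <- win$chrom[i] == cur$chrom && win$start[i] <= cur$end + 1L
    if (adjacent) {
      cand <- cur
      cand$end <- max(cur$end, win$end[i])
      idx <- which(g$map$chrom == cand$chrom &
                     g$map$pos >= cand$start & g$map$pos <= cand$end)
      p_merged <- window_ftest(g$calls[, idx, drop = FALSE], y)
      if (min(p_merged * n_win, 1) < p_merge_bonferroni) {
        cur <- cand
        next
      }
    }
    regions[[length(regions) + 1]] <- cur
    cur <- win[i, c("chrom", "start", "end")]
  }
  regions[[length(regions) + 1]] <- cur

  groups <- lapply(regions, function(r)
    which(g$map$chrom == r$chrom & g$map$pos >= r$start & g$map$pos <= r$end))
  names(groups) <- vapply(regions, function(r)
    sprintf("%s:%d-%d", r$chrom, r$start, r$end), character(1))
  background <- setdiff(seq_len(n_markers(g)), unlist(groups))
  if (length(background)) groups$background <- background
  list(groups = groups, fallback = FALSE, windows = win)
}

# Joint F-test of y on the window's centered marker columns vs intercept-only.
# Collinear columns are absorbed by the QR; zero informative columns => p = 1.
window_ftest <- function(calls, y) {
  if (ncol(calls) == 0) return(1)
  Z <- scale(calls, center = TRUE, scale = FALSE)
  qr_z <- qr(Z)
  r <- qr_z$rank
  n <- length(y)
  if (r == 0 || n - r - 1 <= 0) return(1)
  Q <- qr.Q(qr_z)[, seq_len(r), drop = FALSE]
  yc <- y - mean(y)
  ssr <- sum(as.numeric(crossprod(Q, yc))^2)
  sse <- sum(yc^2) - ssr
  if (sse <= 0) return(0)
  fstat <- (ssr / r) / (sse / (n - r - 1))
  pf(fstat, r, n - r - 1, lower.tail = FALSE)
}
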