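#' Genotype matrix container
#'
#' Holds an accession x marker table of minor-allele counts together with the
#' marker map (chromosome, 1-based physical position) and cached per-marker
#' minor-allele frequencies. Calls are 0, 1 or 2 copies of the minor allele
#' (fully homozygous panels only ever contain 0 and 2) with `NA` for missing.
#'
#' @param calls numeric matrix, accessions in rows, markers in columns, with
#'   dimnames giving accession ids and marker ids; entries in {0, 1, 2, NA}.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos` (1-based),
#'   one row per column of `calls`, in the same order.
#' @return An object of class `geno_matrix` with elements `calls`, `map` and
#'   `maf` (per-marker minor-allele frequency computed from non-missing
#'   calls).
#' @examples
#' calls <- matrix(c(0, 2, 2, 0), 2, 2,
#'                 dimnames = list(c("acc1", "acc2"), c("m1", "m2")))
#' map <- data.frame(marker_id = c("m1", "m2"), chrom = "chr1", pos = c(10, 60))
#' g <- geno_matrix(calls, map)
#' g$maf
#' @export
geno_matrix <- function(calls, map) {
  if (!is.matrix(calls)) stopf("'calls' must be a matrix")
  storage.mode(calls) <- "double"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stopf("genotype calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("acc", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("mk", seq_len(ncol(calls)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stopf("'map' needs columns marker_id, chrom, pos")
  if (nrow(map) != ncol(calls))
    stopf("map has %d rows but calls has %d markers", nrow(map), ncol(calls))
  map <- map[need]
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (!identical(map$marker_id, colnames(calls)))
    stopf("map marker_id order must match colnames(calls)")
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    rownames(map) <- NULL
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (anyDuplicated(p))
      stopf("duplicated position on chromosome %s", ch)
  }
  structure(
    list(calls = calls, map = map, maf = compute_maf(calls)),
    class = "geno_matrix"
  )
}

# Minor-allele frequency per marker from non-missing diploid allele counts.
compute_maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- NA_real_
  maf
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d accessions x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  nmiss <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d; MAF range: %s\n", nmiss,
              if (all(is.na(x$maf))) "NA" else
                paste(signif(range(x$maf, na.rm = TRUE), 3), collapse = " - ")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of accessions / markers
#' @param g a [geno_matrix()]
#' @return integer count.
#' @export
n_accessions <- function(g) nrow(g$calls)

#' @rdname n_accessions
#' @export
n_markers <- function(g) ncol(g$calls)

# Subset markers by column index, keeping map and MAF cache consistent.
subset_markers <- function(g, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L)
    stopf("marker subset is empty: every marker was removed")
  out <- g
  out$calls <- g$calls[, idx, drop = FALSE]
  out$map <- g$map[idx, , drop = FALSE]
  rownames(out$map) <- NULL
  out$maf <- g$maf[idx]
  out
}

# Subset accessions by row index or id.
subset_accessions <- function(g, idx) {
  out <- g
  out$calls <- g$calls[idx, , drop = FALSE]
  out$maf <- compute_maf(out$calls)
  out
}
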