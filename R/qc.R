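#' Load genotypes from PLINK text, VCF or TSV
#'
#' Only biallelic sites are kept. VCF records with more than one ALT allele
#' are dropped and counted (the count is attached as attribute
#' `n_multiallelic_dropped` and reported via a message). The minor allele is
#' determined per marker from the loaded sample, so calls are minor-allele
#' counts regardless of how the source file encodes alleles.
#'
#' @param path file path (for `plink-text`, the prefix of `.ped`/`.map`).
#' @param format one of `"plink-text"`, `"vcf"`, `"tsv"`.
#' @return a [geno_matrix()]
#' @export
load_genotypes <- function(path, format = c("tsv", "plink-text", "vcf")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stopf("unknown genotype format '%s'",
                                               format[1]))
  switch(format,
         "tsv" = load_genotypes_tsv(path),
         "plink-text" = load_genotypes_plink(path),
         "vcf" = load_genotypes_vcf(path))
}

load_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = c("NA", ""))
  ids <- as.character(dt[[1]])
  calls <- as.matrix(dt[, -1])
  if (length(calls) && !all(is.na(calls) | calls %in% c(0, 1, 2))) {
    bad <- colnames(calls)[which(apply(calls, 2, function(x)
      any(!is.na(x) & !x %in% c(0, 1, 2))))[1]]
    stopf("non-biallelic allele count at marker '%s' in TSV", bad)
  }
  rownames(calls) <- ids
  map_path <- paste0(path, ".map")
  map <- if (file.exists(map_path)) {
    as.data.frame(data.table::fread(map_path, sep = "\t"))
  } else {
    data.frame(marker_id = colnames(calls), chrom = "chr1",
               pos = seq_len(ncol(calls)), stringsAsFactors = FALSE)
  }
  geno_matrix(orient_minor(calls), map)
}

load_genotypes_plink <- function(prefix) {
  map <- as.data.frame(data.table::fread(paste0(prefix, ".map"),
                                         header = FALSE, sep = "\t"))
  names(map) <- c("chrom", "marker_id", "cm", "pos")[seq_len(ncol(map))]
  ped <- as.data.frame(data.table::fread(paste0(prefix, ".ped"),
                                         header = FALSE, sep = " ",
                                         colClasses = "character"))
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stopf(".ped has %d allele columns but .map lists %d markers",
          ncol(ped) - 6, m)
  ids <- as.character(ped[[2]])
  calls <- matrix(NA_real_, nrow(ped), m, dimnames = list(ids, map$marker_id))
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    if (length(alleles) > 2)
      stopf("non-biallelic marker '%s' in .ped (alleles: %s)",
            map$marker_id[j], paste(alleles, collapse = ","))
    if (length(alleles) == 0) next
    # count the rarer allele (ties broken lexicographically) so the coding
    # is reproducible whatever the row order of the .ped
    cnt <- vapply(alleles, function(a) sum(a1 == a) + sum(a2 == a), numeric(1))
    ref <- alleles[order(cnt, alleles)][[1]]
    x <- (a1 == ref) + (a2 == ref)
    x[a1 == "0" | a2 == "0"] <- NA
    calls[, j] <- x
  }
  geno_matrix(orient_minor(calls),
              data.frame(marker_id = map$marker_id, chrom = as.character(map$chrom),
                         pos = map$pos, stringsAsFactors = FALSE))
}

load_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  n_drop <- sum(multi)
  if (n_drop > 0) {
    message(sprintf("dropped %d multi-allelic VCF record(s)", n_drop))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", s), "/", fixed = FALSE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  calls <- t(apply(gt, 1, count_alt))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt))
  calls <- t(calls)  # accessions x markers
  dimnames(calls) <- list(colnames(gt), rownames(gt))
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker_id = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  blank <- is.na(map$marker_id) | map$marker_id == "."
  map$marker_id[blank] <- paste0(map$chrom[blank], "_", map$pos[blank])
  colnames(calls) <- map$marker_id
  g <- geno_matrix(orient_minor(calls), map)
  attr(g, "n_multiallelic_dropped") <- n_drop
  g
}

# Re-express calls as minor-allele counts: flip markers whose coded allele
# has frequency > 0.5 in the loaded sample.
orient_minor <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  calls[, flip] <- 2 - calls[, flip]
  calls
}

#' Remove markers with any missing call
#'
#' Markers (never accessions) carrying one or more missing calls are dropped.
#'
#' @param g a [geno_matrix()]
#' @return filtered [geno_matrix()]
#' @export
filter_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  keep <- colSums(is.na(g$calls)) == 0L
  if (!any(keep))
    stopf("empty panel: every marker has at least one missing call")
  if (all(keep)) return(g)
  subset_markers(g, keep)
}

#' Filter markers on minor-allele frequency
#'
#' Keeps markers with MAF >= `threshold`, preserving marker order. At
#' `threshold = 0` nothing is removed (monomorphic markers are excluded later,
#' at GRM construction, where their zero variance would break the scaling).
#'
#' @param g a [geno_matrix()] without missing calls
#' @param threshold MAF threshold in [0, 0.5]
#' @return filtered [geno_matrix()]
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "geno_matrix"))
  if (threshold < 0 || threshold > 0.5)
    stopf("MAF threshold must lie in [0, 0.5]")
  if (anyNA(g$calls)) stopf("remove missing calls before MAF filtering")
  if (threshold == 0) return(g)
  keep <- g$maf >= threshold
  if (!any(keep)) stopf("empty panel: no marker reaches MAF %.3g", threshold)
  if (all(keep)) return(g)
  subset_markers(g, keep)
}

#' Windowed LD pruning
#'
#' Greedy left-to-right scan within each chromosome: a marker is removed when
#' its allele counts correlate at `|r| >= r_threshold` with any previously
#' kept marker at most `window_bp` base pairs away. When a pair violates the
#' threshold, the later marker (larger position) is always the one removed.
#' Cross-chromosome pairs are never compared. Zero-variance markers never
#' trigger removal (their correlation is undefined).
#'
#' @param g a [geno_matrix()] without missing calls
#' @param window_bp window size in base pairs
#' @param r_threshold absolute Pearson correlation at or above which the
#'   later marker is pruned
#' @return pruned [geno_matrix()]
#' @export
ld_prune <- function(g, window_bp = 50, r_threshold = 0.999) {
  stopifnot(inherits(g, "geno_matrix"))
  if (window_bp <= 0) stopf("'window_bp' must be positive")
  if (anyNA(g$calls)) stopf("remove missing calls before LD pruning")
  keep <- rep(TRUE, n_markers(g))
  sds <- apply(g$calls, 2, sd)
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)   # already position-sorted
    kept <- integer(0)
    for (j in idx) {
      if (sds[j] == 0) { kept <- c(kept, j); next }
      near <- kept[g$map$pos[j] - g$map$pos[kept] <= window_bp & sds[kept] > 0]
      drop <- FALSE
      for (i in near) {
        if (abs(cor(g$calls[, i], g$calls[, j])) >= r_threshold) {
          drop <- TRUE
          break
        }
      }
      if (drop) keep[j] <- FALSE else kept <- c(kept, j)
    }
  }
  if (all(keep)) g else subset_markers(g, keep)
}

#' Standard QC chain
#'
#' Missing-call removal, then MAF filtering, then windowed LD pruning — the
#' order matters and is fixed.
#'
#' @inheritParams filter_maf
#' @inheritParams ld_prune
#' @param maf MAF threshold
#' @return filtered [geno_matrix()]
#' @export
qc_chain <- function(g, maf = 0.01, window_bp = 50, r_threshold = 0.999) {
  ld_prune(filter_maf(filter_missing(g), maf), window_bp, r_threshold)
}
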