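#' Write genotypes as a TSV of allele counts
#'
#' Header row of marker ids, first column `accession`, cells in {0, 1, 2, NA}.
#'
#' @param g a [geno_matrix()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(g, path) {
  dt <- data.table::data.table(accession = rownames(g$calls))
  dt <- cbind(dt, data.table::as.data.table(g$calls))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  map_path <- paste0(path, ".map")
  data.table::fwrite(g$map, map_path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write genotypes as PLINK text (.ped/.map)
#'
#' Allele counts are expressed as allele letters: minor allele `A`, major
#' allele `B`; missing calls as `0 0`. The .map file carries chromosome,
#' marker id, a zero genetic distance and the physical position.
#'
#' @param g a [geno_matrix()]
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  map <- data.frame(chrom = g$map$chrom, marker_id = g$map$marker_id,
                    cm = 0, pos = g$map$pos)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  allele1 <- ifelse(is.na(g$calls), "0", ifelse(g$calls >= 1, "A", "B"))
  allele2 <- ifelse(is.na(g$calls), "0", ifelse(g$calls == 2, "A", "B"))
  n <- nrow(g$calls)
  ped <- matrix("", n, 6 + 2 * ncol(g$calls))
  ped[, 1] <- rownames(g$calls)          # family id
  ped[, 2] <- rownames(g$calls)          # individual id
  ped[, 3] <- "0"; ped[, 4] <- "0"; ped[, 5] <- "0"; ped[, 6] <- "-9"
  ped[, 6 + 2 * seq_len(ncol(g$calls)) - 1] <- allele1
  ped[, 6 + 2 * seq_len(ncol(g$calls))] <- allele2
  data.table::fwrite(data.table::as.data.table(ped), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Write genotypes as a minimal VCF
#'
#' Biallelic sites with REF the major allele (`G`) and ALT the minor allele
#' (`T`), unphased GT genotypes; missing calls become `./.`.
#'
#' @param g a [geno_matrix()]
#' @param path output .vcf file
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gfblup-simulated",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(rownames(g$calls), collapse = "\t"))), con)
  gt <- matrix("./.", ncol(g$calls), nrow(g$calls))
  codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$calls))) {
    x <- g$calls[, j]
    gt[j, !is.na(x)] <- codes[x[!is.na(x)] + 1L]
  }
  body <- paste(g$map$chrom, g$map$pos, g$map$marker_id, "G", "T", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' One `gene` record per gene, 1-based inclusive coordinates, `ID=` attribute
#' carrying the gene id.
#'
#' @param genes data.frame with gene_id, chrom, orf_start, orf_end, strand.
#' @param path output .gff3 file
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             paste(genes$chrom, "gfblup", "gene", genes$orf_start,
                   genes$orf_end, ".", genes$strand, ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' GMT rows are tab-separated: set name, description, then member gene ids.
#'
#' @param sets list of [feature_set()] objects (for writing).
#' @param path file path.
#' @param source source label assigned to the read sets.
#' @return `write_gmt`: `path` invisibly; `read_gmt`: list of
#'   [feature_set()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$feature_id, s$source, s$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, source = "CUSTOM") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stopf("malformed GMT row: '%s'", substr(ln, 1, 40))
    src <- if (parts[2] %in% c("GO-BP", "GO-MF", "GO-CC", "COEX", "CUSTOM"))
      parts[2] else source
    feature_set(parts[1], gene_ids = parts[-(1:2)], source = src)
  })
}

#' Write replicate-level phenotypes as TSV
#'
#' Columns: accession, replicate, timepoint, x, y, image_position,
#' sowing_block, value.
#'
#' @param pheno phenotype data.frame from [simulate_trait()].
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(pheno, path) {
  data.table::fwrite(pheno, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read replicate-level phenotypes from TSV
#' @param path TSV written by [write_pheno_tsv()] (or matching its columns).
#' @return data.frame of phenotype records.
#' @export
read_pheno_tsv <- function(path) {
  ph <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("accession", "replicate", "timepoint", "value")
  if (!all(need %in% names(ph)))
    stopf("phenotype TSV must have columns %s", paste(need, collapse = ", "))
  ph
}

#' Write a genomic relationship matrix with sidecar metadata
#'
#' The matrix goes to a TSV with accession-id header; marker count and subset
#' id go to `<path>.meta` as JSON.
#'
#' @param grm a [grm] object from [compute_grm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  dt <- data.table::data.table(accession = rownames(grm$values))
  dt <- cbind(dt, data.table::as.data.table(grm$values))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(n_markers_used = grm$n_markers_used,
                            marker_subset_id = grm$marker_subset_id),
                       paste0(path, ".meta"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- dt$accession
  values <- as.matrix(dt[, -1])
  dimnames(values) <- list(ids, ids)
  meta_path <- paste0(path, ".meta")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(n_markers_used = NA_integer_, marker_subset_id = "ALL")
  new_grm(values, meta$n_markers_used, meta$marker_subset_id)
}
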