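#' Gene-set feature
#'
#' A named group of genes (an ontology term's up-propagated annotation set, a
#' co-expression cluster, or a curated list) together with the marker indices
#' derived from it (the genomic feature). Marker indices are attached later
#' with [attach_markers()] once a marker map is available; a feature may
#' legitimately map to zero markers.
#'
#' @param feature_id label
#' @param gene_ids character vector of member gene ids (deduplicated)
#' @param source one of GO-BP, GO-MF, GO-CC, COEX, CUSTOM
#' @param marker_indices optional integer marker indices
#' @return a `feature_set` object
#' @export
feature_set <- function(feature_id, gene_ids, source = "CUSTOM",
                        marker_indices = NULL) {
  source <- match.arg(source, c("GO-BP", "GO-MF", "GO-CC", "COEX", "CUSTOM"))
  gene_ids <- unique(as.character(gene_ids))
  structure(list(feature_id = as.character(feature_id),
                 source = source,
                 gene_ids = gene_ids,
                 marker_indices = if (is.null(marker_indices)) NULL
                 else sort(unique(as.integer(marker_indices))),
                 n_genes = length(gene_ids),
                 n_markers = if (is.null(marker_indices)) NA_integer_
                 else length(unique(marker_indices))),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set '%s' (%s): %d genes, %s markers\n",
              x$feature_id, x$source, x$n_genes,
              if (is.na(x$n_markers)) "unmapped" else x$n_markers))
  invisible(x)
}

#' Read an OBO ontology file
#'
#' Minimal reader for the OBO 1.2 flat format: `[Term]` stanzas with `id`,
#' `name`, `namespace`, `is_a` and `relationship: part_of` lines. Obsolete
#' terms are skipped. Only the `is_a` and `part_of` relations — the ones
#' annotation up-propagation traverses — are kept as child -> parent edges.
#'
#' @param path .obo file
#' @return list with `terms` (data.frame id, name, namespace) and `edges`
#'   (data.frame child, parent)
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  terms <- list(); edges <- list()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(lines)
    blk <- lines[(starts[k] + 1L):to]
    grab <- function(key) sub(paste0("^", key, ": *"), "",
                              grep(paste0("^", key, ":"), blk, value = TRUE))
    if (length(grab("is_obsolete")) && grab("is_obsolete")[1] == "true") next
    id <- grab("id")[1]
    if (is.na(id)) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id,
      name = if (length(grab("name"))) grab("name")[1] else NA_character_,
      namespace = if (length(grab("namespace"))) grab("namespace")[1] else NA_character_,
      stringsAsFactors = FALSE)
    parents <- sub(" *!.*$", "", grab("is_a"))
    rel <- grab("relationship")
    part <- sub(" *!.*$", "", sub("^part_of +", "", rel[grepl("^part_of ", rel)]))
    for (p in c(parents, part))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = p,
                                                stringsAsFactors = FALSE)
  }
  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(id = character(), name = character(), namespace = character())
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(child = character(), parent = character())
  known <- terms$id
  edges <- edges[edges$child %in% known & edges$parent %in% known, , drop = FALSE]
  rownames(edges) <- NULL
  list(terms = terms, edges = edges)
}

#' Read gene-term annotations from TSV
#'
#' Expects columns `gene`, `term` and optionally `evidence`; evidence codes
#' are read but ignored (all annotations count).
#'
#' @param path TSV file
#' @return data.frame with columns gene, term
#' @export
read_annotations <- function(path) {
  a <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("gene", "term") %in% names(a)))
    stopf("annotation TSV must have columns 'gene' and 'term'")
  unique(a[c("gene", "term")])
}

#' Up-propagate annotations along the ontology
#'
#' A term's full gene set is the union of its direct annotations and those of
#' all its descendants (terms reachable against the child -> parent edges).
#' The operation is idempotent and monotone: each term's set contains every
#' child's set.
#'
#' @param ontology list from [read_obo()] (or any list with `terms$id` and
#'   `edges$child`/`edges$parent`)
#' @param annotations data.frame gene/term of direct annotations
#' @return named list: term id -> character vector of gene ids
#' @export
up_propagate <- function(ontology, annotations) {
  ids <- ontology$terms$id
  edges <- ontology$edges
  # Kahn-style pass over child -> parent edges: process each term only after
  # all of its children, so unions bubble upward in one sweep; a stall means
  # the "ontology" has a cycle.
  idx <- seq_along(ids)
  names(idx) <- ids
  parent_of <- vector("list", length(ids))
  remaining <- integer(length(ids))     # unprocessed children per term
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ci <- idx[[edges$child[r]]]; pi <- idx[[edges$parent[r]]]
      parent_of[[ci]] <- c(parent_of[[ci]], pi)
      remaining[pi] <- remaining[pi] + 1L
    }
  }
  queue <- which(remaining == 0L)
  sets <- lapply(ids, function(tid)
    unique(annotations$gene[annotations$term == tid]))
  processed <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    processed <- processed + 1L
    for (p in parent_of[[t]]) {
      sets[[p]] <- union(sets[[p]], sets[[t]])
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (processed < length(ids)) {
    bad <- ids[remaining > 0][1]
    stopf("ontology contains a cycle involving term '%s'", bad)
  }
  names(sets) <- ids
  sets
}

#' Read gene models from GFF3
#'
#' Imports records of `feature_type` (default `gene`) and returns the
#' coordinate table used for marker mapping. GFF3 coordinates are 1-based
#' inclusive and kept as such.
#'
#' @param path GFF3 file
#' @param feature_type GFF3 type to keep
#' @return data.frame gene_id, chrom, orf_start, orf_end, strand
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             orf_start = GenomicRanges::start(gr),
             orf_end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Map genes to marker indices
#'
#' A marker belongs to a gene when the chromosome matches and the position
#' lies inside the annotated interval, boundaries included; strand is
#' ignored. Genes with several records (isoforms) contribute the union of
#' their intervals. Returns the union over all supplied genes as indices
#' into the marker map's row order.
#'
#' @param genes data.frame gene_id/chrom/orf_start/orf_end (subset of a gene
#'   model table)
#' @param map marker map data.frame (`marker_id`, `chrom`, `pos`), sorted by
#'   chrom then pos — the order of a [geno_matrix()]'s markers.
#' @return sorted integer vector of marker indices (possibly empty)
#' @export
map_genes_to_markers <- function(genes, map) {
  if (nrow(genes) == 0) return(integer(0))
  mk <- GenomicRanges::GRanges(map$chrom,
                               IRanges::IRanges(map$pos, map$pos))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$orf_start, genes$orf_end))
  # differing chromosome sets between genes and the marker map are expected
  # (a gene on an unrepresented chromosome just contributes nothing)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mk, gn, ignore.strand = TRUE))
  sort(unique(S4Vectors::queryHits(hits)))
}

#' Attach marker indices to feature sets
#'
#' Looks up each feature's genes in the gene-model table and maps them to
#' markers. Gene ids absent from the gene models stay in `gene_ids` but
#' contribute no markers; one warning reports how many ids were unknown.
#'
#' @param features list of [feature_set()]
#' @param genes full gene-model data.frame
#' @param map marker map (see [map_genes_to_markers()])
#' @return list of [feature_set()] with `marker_indices`/`n_markers` filled
#' @export
attach_markers <- function(features, genes, map) {
  unknown <- 0L
  out <- lapply(features, function(f) {
    hit <- genes[genes$gene_id %in% f$gene_ids, , drop = FALSE]
    unknown <<- unknown + (f$n_genes - length(unique(hit$gene_id)))
    feature_set(f$feature_id, f$gene_ids, f$source,
                marker_indices = map_genes_to_markers(hit, map))
  })
  if (unknown > 0)
    warnf("%d gene id(s) across features not present in the gene models; they contribute no markers",
          unknown)
  out
}

#' Load a curated gene list as a feature
#'
#' Accepts a plain list (one gene id per line) or a single GMT row.
#' Duplicates are removed; an empty file yields an empty feature with a
#' warning rather than an error.
#'
#' @param path text file of gene ids
#' @param feature_id label for the resulting set
#' @return a [feature_set()]
#' @export
load_custom_gene_list <- function(path, feature_id = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warnf("empty gene list '%s'", path)
    return(feature_set(feature_id, character(0)))
  }
  if (length(lines) == 1 && grepl("\t", lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)[[1]]
    return(feature_set(parts[1], parts[-(1:2)]))
  }
  feature_set(feature_id, lines)
}
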