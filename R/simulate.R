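#' Configuration for the synthetic genotype panel
#'
#' Describes a fully homozygous diversity panel: biallelic markers with a
#' controllable minor-allele-frequency spectrum, local LD blocks produced by a
#' block-copy model, and annotated gene ORFs laid out along the simulated
#' chromosomes. Defaults emulate a natural-accession association panel
#' (hundreds of inbred accessions, dense array markers, rare alleles present).
#'
#' @param n_accessions number of inbred accessions.
#' @param n_markers total number of biallelic markers across all chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param maf_range length-2 numeric in (0, 0.5]: sampling range for marker
#'   minor-allele frequencies.
#' @param ld_block_span base-pair span of a local LD block; markers within one
#'   span share an ancestral carrier pattern, giving elevated adjacent-marker
#'   correlation.
#' @param mutation_rate per-marker probability that an accession's carrier
#'   state is redrawn rather than copied from the previous marker in the same
#'   LD block; controls within-block correlation decay.
#' @param mean_marker_gap mean base-pair gap between adjacent markers.
#' @param n_genes number of annotated genes.
#' @param orf_length_range length-2 integer range of ORF lengths in base
#'   pairs.
#' @param n_features number of gene-set features to simulate.
#' @param feature_size_range length-2 integer range of feature sizes in genes.
#' @param seed integer seed; identical configurations with identical seeds
#'   give bit-identical output.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_accessions = 344,
                       n_markers = 20000,
                       n_chromosomes = 5,
                       maf_range = c(0.01, 0.5),
                       ld_block_span = 5000,
                       mutation_rate = 0.1,
                       mean_marker_gap = 500,
                       n_genes = 2000,
                       orf_length_range = c(500, 3000),
                       n_features = 50,
                       feature_size_range = c(1, min(200, n_genes)),
                       seed = 1L) {
  cfg <- list(n_accessions = n_accessions, n_markers = n_markers,
              n_chromosomes = n_chromosomes, maf_range = maf_range,
              ld_block_span = ld_block_span, mutation_rate = mutation_rate,
              mean_marker_gap = mean_marker_gap, n_genes = n_genes,
              orf_length_range = orf_length_range, n_features = n_features,
              feature_size_range = feature_size_range,
              seed = as.integer(seed))
  for (f in c("n_accessions", "n_markers", "n_chromosomes", "n_genes"))
    if (!is_count(cfg[[f]])) stopf("'%s' must be a positive integer", f)
  if (!is.numeric(cfg$n_features) || cfg$n_features < 0)
    stopf("'n_features' must be a non-negative integer")
  if (cfg$n_markers < cfg$n_chromosomes)
    stopf("invalid config: n_markers (%d) < n_chromosomes (%d)",
          cfg$n_markers, cfg$n_chromosomes)
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stopf("'maf_range' must be an increasing pair within (0, 0.5]")
  if (cfg$feature_size_range[2] > cfg$n_genes)
    stopf("invalid config: feature_size_range upper bound (%d) > n_genes (%d)",
          cfg$feature_size_range[2], cfg$n_genes)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stopf("'mutation_rate' must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate genotypes, marker map and gene models
#'
#' Generates a fully homozygous panel: every call is 0 or 2 copies of the
#' minor allele. Marker positions are strictly increasing within chromosome
#' (gaps ~ 1 + Geometric(1/mean_marker_gap)). LD is produced by a block-copy
#' model: within each `ld_block_span` window the carrier vector of a marker is
#' copied from the previous marker and each accession is independently redrawn
#' with probability `mutation_rate`, so adjacent markers in a block are
#' strongly correlated while blocks are independent.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [geno_matrix()]) and `genes` (data.frame
#'   `gene_id`, `chrom`, `orf_start`, `orf_end`, `strand`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_accessions
    m <- config$n_markers
    # markers split near-evenly across chromosomes
    per_chr <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1L)))
    acc_ids <- sprintf("acc%04d", seq_len(n))
    calls <- matrix(NA_real_, n, m)
    chrom <- character(m)
    pos <- integer(m)
    col0 <- 0L
    for (ci in seq_len(config$n_chromosomes)) {
      mc <- per_chr[ci]
      if (mc == 0L) next
      gaps <- 1L + stats::rgeom(mc, 1 / config$mean_marker_gap)
      p_chr <- cumsum(gaps)
      freq <- runif(mc, config$maf_range[1], config$maf_range[2])
      block <- (p_chr - 1L) %/% config$ld_block_span
      carrier_prev <- NULL
      for (j in seq_len(mc)) {
        if (j == 1L || block[j] != block[j - 1L]) {
          carrier <- rbinom(n, 1L, freq[j])
        } else {
          carrier <- carrier_prev
          mut <- runif(n) < config$mutation_rate
          if (any(mut)) carrier[mut] <- rbinom(sum(mut), 1L, freq[j])
        }
        carrier_prev <- carrier
        calls[, col0 + j] <- 2 * carrier
      }
      chrom[col0 + seq_len(mc)] <- sprintf("chr%d", ci)
      pos[col0 + seq_len(mc)] <- p_chr
      col0 <- col0 + mc
    }
    map <- data.frame(marker_id = sprintf("mk%06d", seq_len(m)),
                      chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    dimnames(calls) <- list(acc_ids, map$marker_id)
    genes <- simulate_gene_models(map, config)
    list(genotypes = geno_matrix(calls, map), genes = genes)
  })
}

# Place gene ORFs uniformly along the simulated chromosomes (non-degenerate
# 1-based inclusive intervals, clipped to the chromosome extent).
simulate_gene_models <- function(map, config) {
  chr_len <- tapply(map$pos, map$chrom, max)
  chrs <- names(chr_len)
  g_chr <- sample(chrs, config$n_genes, replace = TRUE,
                  prob = as.numeric(chr_len) / sum(chr_len))
  len <- sample(config$orf_length_range[1]:config$orf_length_range[2],
                config$n_genes, replace = TRUE)
  start <- vapply(seq_len(config$n_genes), function(i) {
    sample.int(max(1L, as.integer(chr_len[[g_chr[i]]]) - len[i] + 1L), 1L)
  }, integer(1))
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
    chrom = g_chr,
    orf_start = start,
    orf_end = start + len - 1L,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genes[order(genes$chrom, genes$orf_start), , drop = FALSE]
}

#' Simulate overlapping gene-set features
#'
#' Draws `n_features` gene sets with sizes uniform in `feature_size_range`.
#' Genes are sampled independently per feature, so a gene may belong to
#' several features, mirroring overlapping ontology terms and co-expression
#' clusters.
#'
#' @param genes gene-model data.frame from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return list of [feature_set()] objects (without marker indices; attach
#'   them with [map_genes_to_markers()] / [attach_markers()]).
#' @export
simulate_feature_sets <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$feature_size_range[2] > nrow(genes))
    stopf("invalid config: feature sizes up to %d exceed %d available genes",
          config$feature_size_range[2], nrow(genes))
  if (config$n_features == 0L) return(list())
  with_seed(config$seed + 1L, {
    sizes <- sample(config$feature_size_range[1]:config$feature_size_range[2],
                    config$n_features, replace = TRUE)
    lapply(seq_len(config$n_features), function(i) {
      feature_set(sprintf("FT%04d", i),
                  gene_ids = sample(genes$gene_id, sizes[i]),
                  source = "CUSTOM")
    })
  })
}

#' Configuration for a simulated trait
#'
#' Defines the genetic architecture and measurement design of one synthetic
#' trait: target genomic heritability, the share of genetic variance carried
#' by markers inside one named feature, replicate structure, random design
#' effects (spatial row/column, camera image position, sowing block) and an
#' AR(1) series of genetic values across timepoints.
#'
#' @param h2_target genomic heritability in [0, 1]: var(g) / (var(g) +
#'   residual variance at the adjusted-phenotype level).
#' @param feature_id id of the feature enriched for genetic variance, or
#'   `NULL` for a purely polygenic trait.
#' @param hf2_share fraction of genetic variance carried by causal markers
#'   inside `feature_id` (0 when `feature_id` is `NULL`).
#' @param n_causal number of causal markers.
#' @param n_replicates replicates per accession (1..4). With
#'   `vary_replicates = TRUE` each accession gets Uniform{1..n_replicates}
#'   replicates, reflecting partially replicated phenotyping designs.
#' @param vary_replicates logical, see `n_replicates`.
#' @param design_effect_sds named numeric: standard deviations of the random
#'   design effects `x`, `y`, `image_position`, `sowing_block` (trait units).
#' @param residual_sd residual standard deviation per observation (trait
#'   units).
#' @param n_timepoints number of measurement timepoints.
#' @param serial_correlation AR(1) parameter in [0, 1) linking genetic values
#'   of adjacent timepoints (plant phenotypes measured hours apart are
#'   strongly serially correlated).
#' @param grand_mean trait grand mean (trait units).
#' @param seed integer seed.
#' @return A validated `trait_config` list.
#' @export
trait_config <- function(h2_target = 0.5,
                         feature_id = NULL,
                         hf2_share = 0,
                         n_causal = 200,
                         n_replicates = 4,
                         vary_replicates = TRUE,
                         design_effect_sds = c(x = 0.25, y = 0.25,
                                               image_position = 0.5,
                                               sowing_block = 0.5),
                         residual_sd = 1,
                         n_timepoints = 1,
                         serial_correlation = 0.95,
                         grand_mean = 10,
                         seed = 1L) {
  if (!is.numeric(h2_target) || h2_target < 0 || h2_target > 1)
    stopf("'h2_target' must lie in [0, 1]")
  if (hf2_share < 0 || hf2_share > 1)
    stopf("'hf2_share' must lie in [0, 1]")
  if (is.null(feature_id) && hf2_share != 0)
    stopf("'hf2_share' must be 0 when no feature_id is given")
  if (!is_count(n_replicates) || n_replicates > 4)
    stopf("'n_replicates' must be an integer in 1..4")
  if (serial_correlation < 0 || serial_correlation >= 1)
    stopf("'serial_correlation' must lie in [0, 1)")
  if (residual_sd <= 0) stopf("'residual_sd' must be positive")
  structure(list(h2_target = h2_target, feature_id = feature_id,
                 hf2_share = hf2_share, n_causal = n_causal,
                 n_replicates = as.integer(n_replicates),
                 vary_replicates = isTRUE(vary_replicates),
                 design_effect_sds = design_effect_sds,
                 residual_sd = residual_sd,
                 n_timepoints = as.integer(n_timepoints),
                 serial_correlation = serial_correlation,
                 grand_mean = grand_mean, seed = as.integer(seed)),
            class = "trait_config")
}

#' Simulate a replicate-level phenotype with known genetic architecture
#'
#' Causal marker effects are drawn N(0, 1) and scaled per marker by
#' 1/sqrt(2 p (1-p)) so that rare and common causal alleles contribute equal
#' expected variance (the scaling under which the VanRaden relationship
#' matrix matches the architecture). Genetic values are then rescaled so the
#' sample variance of g equals `h2/(1-h2) * residual_sd^2` exactly, and the
#' within-feature component f is scaled to carry `hf2_share` of var(g).
#' Across timepoints, genetic values follow an AR(1) with parameter
#' `serial_correlation` (independent genetic innovations). Observations add
#' random intercepts for spatial row, column, camera image position and
#' sowing block, plus i.i.d. residual noise.
#'
#' @param genotypes a [geno_matrix()].
#' @param features list of [feature_set()] with marker indices attached (only
#'   needed when `trait$feature_id` is set).
#' @param trait a [trait_config()].
#' @return list with `effects` (data.frame of causal markers and their
#'   per-timepoint effects at timepoint 1), `genomic_values` (accessions x
#'   timepoints matrix of true genetic values), and `phenotypes` (data.frame
#'   with columns accession, replicate, timepoint, x, y, image_position,
#'   sowing_block, value).
#' @export
simulate_trait <- function(genotypes, features = list(), trait = trait_config()) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(trait, "trait_config"))
  n <- n_accessions(genotypes)
  m <- n_markers(genotypes)
  acc <- rownames(genotypes$calls)
  with_seed(trait$seed, {
    sigma_e2 <- trait$residual_sd^2
    sigma_g2 <- if (trait$h2_target >= 1) {
      sigma_e2 <- 0
      1
    } else trait$h2_target / (1 - trait$h2_target) * sigma_e2

    feat_idx <- integer(0)
    if (!is.null(trait$feature_id)) {
      ids <- vapply(features, function(f) f$feature_id, character(1))
      hit <- match(trait$feature_id, ids)
      if (is.na(hit)) stopf("feature '%s' not found", trait$feature_id)
      feat_idx <- features[[hit]]$marker_indices
      if (is.null(feat_idx))
        stopf("feature '%s' has no marker indices attached", trait$feature_id)
    }
    # monomorphic markers carry no variance and would break the 1/sqrt(2p(1-p))
    # effect scaling; they are never chosen as causal
    poly <- which(genotypes$maf > 0)
    feat_idx <- intersect(feat_idx, poly)
    n_in <- round(trait$n_causal * trait$hf2_share)
    if (n_in > length(feat_idx))
      stopf("feature '%s' has %d markers but %d causal markers are requested inside it",
            trait$feature_id, length(feat_idx), n_in)
    n_out <- trait$n_causal - n_in
    out_pool <- setdiff(poly, feat_idx)
    if (n_out > length(out_pool))
      stopf("not enough markers outside the feature for %d causal effects", n_out)
    caus_in <- if (n_in > 0) sort(sample(feat_idx, n_in)) else integer(0)
    caus_out <- if (n_out > 0) sort(sample(out_pool, n_out)) else integer(0)

    genetic_component <- function(idx) {
      # centered genotypes x per-marker-scaled effects; zero vector if empty
      if (length(idx) == 0L || sigma_g2 == 0) return(list(g = numeric(n), a = numeric(length(idx))))
      p <- genotypes$maf[idx]
      a <- rnorm(length(idx)) / sqrt(2 * p * (1 - p))
      Z <- sweep(genotypes$calls[, idx, drop = FALSE], 2, 2 * p)
      list(g = as.numeric(Z %*% a), a = a)
    }
    scale_to_var <- function(v, target) {
      s <- stats::var(v)
      if (s < .Machine$double.eps) return(list(v = v, k = 0))
      k <- sqrt(target / s)
      list(v = v * k, k = k)
    }

    draw_g <- function() {
      cin <- genetic_component(caus_in)
      cout <- genetic_component(caus_out)
      if (sigma_g2 == 0) return(list(g = numeric(n), a_in = cin$a * 0, a_out = cout$a * 0))
      sin2 <- sigma_g2 * trait$hf2_share
      sout2 <- sigma_g2 * (1 - trait$hf2_share)
      fin <- if (length(caus_in)) scale_to_var(cin$g, sin2) else list(v = numeric(n), k = 0)
      fout <- if (length(caus_out)) scale_to_var(cout$g, sout2) else list(v = numeric(n), k = 0)
      list(g = fin$v + fout$v, a_in = cin$a * fin$k, a_out = cout$a * fout$k)
    }

    first <- draw_g()
    G <- matrix(0, n, trait$n_timepoints,
                dimnames = list(acc, paste0("t", seq_len(trait$n_timepoints))))
    G[, 1] <- first$g
    rho <- trait$serial_correlation
    if (trait$n_timepoints > 1) {
      for (t in 2:trait$n_timepoints) {
        innov <- draw_g()$g
        G[, t] <- rho * G[, t - 1] + sqrt(1 - rho^2) * innov
      }
    }

    reps <- if (trait$vary_replicates && trait$n_replicates > 1)
      sample.int(trait$n_replicates, n, replace = TRUE)
    else rep(trait$n_replicates, n)
    plant_acc <- rep(seq_len(n), reps)
    n_plants <- length(plant_acc)
    # grid layout: slots filled row-major, images of 12 plants per camera
    # stop, sowing blocks as equal quarters of the table; plants are
    # randomized over slots so design factors are not confounded with
    # accessions (as in a randomized phenotyping layout)
    slot <- sample.int(n_plants)
    ncol_grid <- ceiling(sqrt(n_plants))
    plant_x <- ((slot - 1L) %/% ncol_grid) + 1L
    plant_y <- ((slot - 1L) %% ncol_grid) + 1L
    image_pos <- ((slot - 1L) %/% 12L) + 1L
    n_blocks <- 4L
    block <- ((slot - 1L) %/% ceiling(n_plants / n_blocks)) + 1L

    level_effect <- function(levels, sd_name) {
      sd <- trait$design_effect_sds[[sd_name]]
      if (is.null(sd) || is.na(sd)) sd <- 0
      eff <- rnorm(length(unique(levels)), 0, sd)
      eff[match(levels, unique(levels))]
    }
    ex <- level_effect(plant_x, "x")
    ey <- level_effect(plant_y, "y")
    ei <- level_effect(image_pos, "image_position")
    eb <- level_effect(block, "sowing_block")

    ph <- do.call(rbind, lapply(seq_len(trait$n_timepoints), function(t) {
      eps <- rnorm(n_plants, 0, trait$residual_sd)
      data.frame(accession = acc[plant_acc],
                 replicate = unlist(lapply(reps, seq_len)),
                 timepoint = paste0("t", t),
                 x = plant_x, y = plant_y,
                 image_position = paste0("img", image_pos),
                 sowing_block = paste0("blk", block),
                 value = trait$grand_mean + G[plant_acc, t] +
                   ex + ey + ei + eb + eps,
                 stringsAsFactors = FALSE)
    }))
    rownames(ph) <- NULL

    effects <- data.frame(
      marker_id = colnames(genotypes$calls)[c(caus_in, caus_out)],
      marker_index = c(caus_in, caus_out),
      in_feature = rep(c(TRUE, FALSE), c(length(caus_in), length(caus_out))),
      effect = c(first$a_in, first$a_out),
      stringsAsFactors = FALSE)
    list(effects = effects, genomic_values = G, phenotypes = ph)
  })
}
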