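test_that("TSV genotypes load with brute-force-correct MAFs", {
  d <- withr::local_tempdir()
  path <- file.path(d, "g.tsv")
  writeLines(c("accession\tm1\tm2\tm3",
               "a1\t0\t2\t1",
               "a2\t2\t2\t0"), path)
  g <- load_genotypes(path, "tsv")
  expect_equal(dim(g$calls), c(2L, 3L))
  # brute-force: m1 counts 2/4 -> 0.5; m2 counts 4/4 -> flipped, maf 0;
  # m3 counts 1/4 -> 0.25
  expect_equal(unname(g$maf), c(0.5, 0, 0.25))
  expect_error(load_genotypes(path, "parquet"), "unknown")

  bad <- file.path(d, "bad.tsv")
  writeLines(c("accession\tm1", "a1\t3"), bad)
  expect_error(load_genotypes(bad, "tsv"), "m1")
})

test_that("genotypes round-trip through every writer/loader pair", {
  cfg <- sim_config(n_accessions = 30, n_markers = 80, n_chromosomes = 2,
                    n_genes = 10, maf_range = c(0.1, 0.45), seed = 13)
  g <- simulate_genotypes(cfg)$genotypes
  d <- withr::local_tempdir()

  write_geno_tsv(g, file.path(d, "g.tsv"))
  g_tsv <- load_genotypes(file.path(d, "g.tsv"), "tsv")
  expect_equal(g_tsv$calls, g$calls)
  expect_equal(g_tsv$map, g$map)

  write_plink(g, file.path(d, "g"))
  g_ped <- load_genotypes(file.path(d, "g"), "plink-text")
  expect_equal(g_ped$calls, g$calls)
  expect_equal(g_ped$map$pos, g$map$pos)

  write_vcf(g, file.path(d, "g.vcf"))
  g_vcf <- load_genotypes(file.path(d, "g.vcf"), "vcf")
  expect_equal(g_vcf$calls, g$calls)
})

test_that("multi-allelic VCF records are dropped and counted", {
  d <- withr::local_tempdir()
  path <- file.path(d, "m.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta1\ta2",
               "chr1\t100\ts1\tG\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
               "chr1\t200\ts2\tG\tT,C\t.\tPASS\t.\tGT\t0/0\t1/2",
               "chr1\t300\ts3\tG\tT\t.\tPASS\t.\tGT\t1/1\t0/0"), path)
  expect_message(g <- load_genotypes(path, "vcf"), "1 multi-allelic")
  expect_equal(n_markers(g), 2L)
  expect_equal(attr(g, "n_multiallelic_dropped"), 1L)
})

test_that("missing-call filter removes exactly the affected markers", {
  calls <- matrix(c(0, 2, 2, NA, 0, 0), 2, 3,
                  dimnames = list(c("a1", "a2"), c("m1", "m2", "m3")))
  g <- geno_matrix(calls, data.frame(marker_id = c("m1", "m2", "m3"),
                                     chrom = "chr1", pos = 1:3 * 10))
  gf <- filter_missing(g)
  expect_equal(colnames(gf$calls), c("m1", "m3"))

  clean <- tiny_geno()
  expect_identical(filter_missing(clean), clean)

  # 5x5 random missingness: survivors equal a brute-force column scan
  set.seed(42)
  cc <- matrix(sample(c(0, 2), 25, replace = TRUE), 5, 5,
               dimnames = list(paste0("a", 1:5), paste0("m", 1:5)))
  cc[sample(25, 6)] <- NA
  gm <- geno_matrix(cc, data.frame(marker_id = paste0("m", 1:5),
                                   chrom = "chr1", pos = 1:5 * 100))
  keep_bf <- vapply(seq_len(5), function(j) !anyNA(cc[, j]), logical(1))
  if (any(keep_bf)) {
    expect_equal(colnames(filter_missing(gm)$calls), paste0("m", which(keep_bf)))
  }
  all_na <- geno_matrix(matrix(NA_real_, 2, 1,
                               dimnames = list(c("a1", "a2"), "m1")),
                        data.frame(marker_id = "m1", chrom = "c", pos = 1))
  expect_error(filter_missing(all_na), "empty panel")
})

test_that("MAF filter applies the threshold inclusively and keeps order", {
  # 100 inbred accessions, one marker with a single minor allele copy pair:
  # 1 accession carrying 2 minor alleles -> MAF = 0.01; and one rarer still
  set.seed(7)
  n <- 100
  calls <- cbind(m1 = c(2, rep(0, n - 1)),                  # maf 0.01
                 m2 = sample(c(0, 2), n, TRUE),             # common
                 m3 = c(2, 2, rep(0, n - 2)),               # maf 0.02
                 m4 = sample(c(0, 2), n, TRUE),
                 m5 = rep(c(0, 2), n / 2))                  # maf 0.5
  rownames(calls) <- paste0("a", 1:n)
  g <- geno_matrix(calls, data.frame(marker_id = paste0("m", 1:5),
                                     chrom = "chr1", pos = 1:5 * 100))
  half <- geno_matrix(calls[, "m5", drop = FALSE],
                      data.frame(marker_id = "m5", chrom = "chr1", pos = 1))
  expect_identical(filter_maf(half, 0.01), half)

  # marker below 0.01 threshold? m1 has maf exactly 0.01 -> kept (>=)
  gf <- filter_maf(g, 0.01)
  expect_true("m1" %in% colnames(gf$calls))
  gf2 <- filter_maf(g, 0.015)
  expect_false("m1" %in% colnames(gf2$calls))
  expect_equal(colnames(gf2$calls), setdiff(paste0("m", 1:5), "m1"))

  expect_identical(filter_maf(g, 0), g)      # monomorphic would be retained
  expect_error(filter_maf(g, 0.7), "threshold")
  # idempotence
  expect_identical(filter_maf(gf2, 0.015), gf2)
})

test_that("LD pruning matches a brute-force greedy left-to-right scan", {
  single <- tiny_geno()
  expect_equal(n_markers(ld_prune(single, window_bp = 50)), 3L)

  # two identical columns 10 bp apart: the later one goes
  calls <- matrix(c(0, 2, 0, 2,
                    0, 2, 0, 2), 4, 2,
                  dimnames = list(paste0("a", 1:4), c("m1", "m2")))
  g2 <- geno_matrix(calls, data.frame(marker_id = c("m1", "m2"),
                                      chrom = "chr1", pos = c(100, 110)))
  pruned <- ld_prune(g2, window_bp = 50, r_threshold = 0.999)
  expect_equal(colnames(pruned$calls), "m1")

  # 20-marker toy panel vs an independent greedy oracle
  set.seed(31)
  n <- 40; m <- 20
  cc <- matrix(sample(c(0, 2), n * m, TRUE, prob = c(0.6, 0.4)), n, m)
  # inject some near-duplicates at close positions
  cc[, 5] <- cc[, 4]
  cc[, 12] <- cc[, 11]; cc[1, 12] <- 2 - cc[1, 12]
  dimnames(cc) <- list(paste0("a", 1:n), sprintf("m%02d", 1:m))
  pos <- cumsum(sample(5:30, m, TRUE))
  gg <- geno_matrix(cc, data.frame(marker_id = sprintf("m%02d", 1:m),
                                   chrom = "chr1", pos = pos))
  win <- 50; thr <- 0.9
  kept_oracle <- integer(0)
  for (j in seq_len(m)) {
    near <- kept_oracle[gg$map$pos[j] - gg$map$pos[kept_oracle] <= win]
    viol <- FALSE
    for (i in near) {
      r <- suppressWarnings(cor(gg$calls[, i], gg$calls[, j]))
      if (!is.na(r) && abs(r) >= thr) viol <- TRUE
    }
    if (!viol) kept_oracle <- c(kept_oracle, j)
  }
  pr <- ld_prune(gg, window_bp = win, r_threshold = thr)
  expect_equal(colnames(pr$calls), gg$map$marker_id[kept_oracle])
  # idempotence and metadata carry-through
  expect_identical(ld_prune(pr, window_bp = win, r_threshold = thr), pr)
  expect_true(all(pr$map$marker_id %in% gg$map$marker_id))
  expect_equal(pr$map$pos,
               gg$map$pos[match(pr$map$marker_id, gg$map$marker_id)])
  expect_error(ld_prune(gg, window_bp = 0), "window_bp")
})
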