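make_dag <- function(edges, annots) {
  ids <- unique(c(edges$child, edges$parent, annots$term))
  list(terms = data.frame(id = ids, name = ids, namespace = "bp"),
       edges = edges)
}

test_that("up-propagation unions a term with all its descendants", {
  dag <- make_dag(data.frame(child = "leaf", parent = "root"),
                  annots <- data.frame(gene = c("a", "b", "c"),
                                       term = c("leaf", "leaf", "root")))
  sets <- up_propagate(dag, annots)
  expect_setequal(sets$root, c("a", "b", "c"))
  expect_setequal(sets$leaf, c("a", "b"))

  # term with nothing annotated below it
  dag2 <- make_dag(data.frame(child = "t2", parent = "t1"),
                   an2 <- data.frame(gene = character(), term = character()))
  expect_length(up_propagate(dag2, an2)$t1, 0)

  # idempotence: re-propagating the propagated sets changes nothing
  flat <- do.call(rbind, lapply(names(sets), function(t)
    if (length(sets[[t]])) data.frame(gene = sets[[t]], term = t) else NULL))
  expect_equal(lapply(up_propagate(dag, flat), sort), lapply(sets, sort))
})

test_that("up-propagation equals transitive closure on random DAGs", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      nt <- 10
      ids <- paste0("T", 1:nt)
      # random DAG: edges only from higher index (child) to lower (parent)
      edges <- do.call(rbind, lapply(2:nt, function(i) {
        np <- sample(0:2, 1)
        if (np == 0) return(NULL)
        data.frame(child = ids[i], parent = sample(ids[1:(i - 1)], np))
      }))
      annots <- data.frame(gene = paste0("g", sample(30, 20, TRUE)),
                           term = sample(ids, 20, TRUE))
      dag <- list(terms = data.frame(id = ids, name = ids, namespace = "bp"),
                  edges = unique(edges))
      sets <- up_propagate(dag, annots)
      # oracle: reachability by repeated edge relaxation
      reach <- lapply(ids, function(t) t)
      names(reach) <- ids
      repeat {
        changed <- FALSE
        for (r in seq_len(nrow(dag$edges))) {
          p <- dag$edges$parent[r]; c_ <- dag$edges$child[r]
          new <- union(reach[[p]], reach[[c_]])
          if (length(new) > length(reach[[p]])) {
            reach[[p]] <- new
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (t in ids) {
        expected <- unique(annots$gene[annots$term %in% reach[[t]]])
        expect_setequal(sets[[t]], expected)
        # monotone: parent's set contains every child's set
        for (ch in dag$edges$child[dag$edges$parent == t])
          expect_true(all(sets[[ch]] %in% sets[[t]]))
      }
    })
  }
})

test_that("cycles are detected and named", {
  dag <- list(terms = data.frame(id = c("A", "B"), name = c("A", "B"),
                                 namespace = "bp"),
              edges = data.frame(child = c("A", "B"), parent = c("B", "A")))
  expect_error(up_propagate(dag, data.frame(gene = "g", term = "A")), "cycle")
})

test_that("OBO reader keeps is_a/part_of edges and skips obsolete terms", {
  d <- withr::local_tempdir()
  obo <- file.path(d, "mini.obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:0000002", "name: child",
               "namespace: biological_process",
               "is_a: GO:0000001 ! root", "",
               "[Term]", "id: GO:0000003", "name: part",
               "relationship: part_of GO:0000002 ! child", "",
               "[Term]", "id: GO:0000004", "name: gone",
               "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), obo)
  ont <- read_obo(obo)
  expect_setequal(ont$terms$id, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(nrow(ont$edges), 2)
  expect_true(all(c("GO:0000002", "GO:0000003") %in% ont$edges$child))
})

test_that("marker mapping is boundary-inclusive and matches a double loop", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "chr9"),
                      orf_start = c(100, 400, 50),
                      orf_end = c(200, 450, 60),
                      strand = "+")
  map <- data.frame(marker_id = sprintf("m%02d", 1:10),
                    chrom = rep(c("chr1", "chr2"), each = 5),
                    pos = c(100, 150, 200, 201, 399, 10, 20, 30, 40, 50))
  idx <- map_genes_to_markers(genes, map)
  # oracle: exhaustive double loop
  oracle <- sort(unique(unlist(lapply(seq_len(nrow(genes)), function(i)
    which(map$chrom == genes$chrom[i] &
            map$pos >= genes$orf_start[i] &
            map$pos <= genes$orf_end[i])))))
  expect_equal(idx, oracle)
  expect_true(1L %in% idx)    # pos == orf_start included
  expect_true(3L %in% idx)    # pos == orf_end included
  expect_false(4L %in% idx)   # one past the end excluded
  # gene on a chromosome with no markers contributes nothing
  expect_equal(map_genes_to_markers(genes[genes$gene_id == "gC", ], map),
               integer(0))
  # union commutes with mapping
  a <- genes[1, ]; b <- genes[2, ]
  expect_equal(map_genes_to_markers(rbind(a, b), map),
               sort(union(map_genes_to_markers(a, map),
                          map_genes_to_markers(b, map))))
})

test_that("GFF3 gene models round-trip and drive feature mapping", {
  pan <- small_panel()
  d <- withr::local_tempdir()
  gff <- file.path(d, "genes.gff3")
  write_gff3(pan$genes, gff)
  back <- read_gene_models(gff)
  ord <- order(back$gene_id)
  ord0 <- order(pan$genes$gene_id)
  expect_equal(back$gene_id[ord], pan$genes$gene_id[ord0])
  expect_equal(back$orf_start[ord], pan$genes$orf_start[ord0])
  expect_equal(back$orf_end[ord], pan$genes$orf_end[ord0])

  f <- pan$feats[[2]]
  idx_again <- map_genes_to_markers(
    back[back$gene_id %in% f$gene_ids, ], pan$g$map)
  expect_equal(idx_again, f$marker_indices)
})

test_that("custom gene lists deduplicate and tolerate unknown ids", {
  d <- withr::local_tempdir()
  lst <- file.path(d, "genes.txt")
  writeLines(c("gene1", "gene2", "gene1"), lst)
  f <- load_custom_gene_list(lst, "myset")
  expect_equal(f$n_genes, 2)

  empty <- file.path(d, "empty.txt")
  writeLines(character(0), empty)
  expect_warning(fe <- load_custom_gene_list(empty), "empty")
  expect_equal(fe$n_genes, 0)

  gmt <- file.path(d, "sets.gmt")
  write_gmt(list(feature_set("S1", c("g1", "g2"), "GO-BP"),
                 feature_set("S2", c("g3"), "COEX")), gmt)
  sets <- read_gmt(gmt)
  expect_length(sets, 2)
  expect_equal(vapply(sets, function(s) s$feature_id, character(1)),
               c("S1", "S2"))
  expect_equal(sets[[1]]$source, "GO-BP")

  pan <- small_panel()
  stranger <- feature_set("ghost", c("nope1", "nope2"))
  expect_warning(att <- attach_markers(list(stranger), pan$genes, pan$g$map),
                 "not present")
  expect_equal(att[[1]]$n_markers, 0L)
  expect_equal(att[[1]]$n_genes, 2L)
})
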