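test_that("probeset filtering removes unmapped and ambiguous probes and collapses by brightest probe", {
  x <- matrix(c(1, 1, 5, 5, 2, 2, 9, 9, 3, 3), 5, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3", "p4", "p5"), c("s1", "s2")))
  mapping <- data.frame(
    probeset = c("p1", "p2", "p3", "p3", "p4"),
    gene = c("GA", "GA", "GB", "GC", ""))
  # p3 maps to two genes (removed), p4 empty gene (removed), p5 unlisted
  # (removed); p1/p2 both map to GA and p2 has the higher mean
  out <- filter_probesets(x, mapping)
  expect_identical(rownames(out), "GA")
  expect_equal(unname(out["GA", ]), c(5, 5), ignore_attr = TRUE)
  expect_error(filter_probesets(x, data.frame(probeset = "p9", gene = "G")),
               "no probesets survive")
})

test_that("signature derivation keeps target-specific genes and drops shared-basal decoys", {
  des <- population_design(n_genes = 300, n_masc_up = 30, n_basal_shared = 30,
                           n_luminal_up = 30, seed = 2)
  sim <- simulate_populations(des)
  sig <- derive_signature(sim$matrix, sim$samples$population)
  truth <- sim$truth
  masc <- truth$gene_id[truth$class == "masc_up"]
  decoys <- truth$gene_id[truth$class == "basal_shared"]
  expect_gt(length(intersect(signature_genes(sig), masc)) / length(masc), 0.8)
  expect_length(intersect(signature_genes(sig), decoys), 0)
  expect_length(intersect(signature_genes(sig),
                          truth$gene_id[truth$class == "luminal_up"]), 0)
  # the per-comparison evidence table covers every retained gene
  expect_setequal(unique(sig$stats$gene), signature_genes(sig))
  expect_length(sig$sam, 3)
})

test_that("a design with no effects yields an empty signature with a warning", {
  des <- population_design(n_genes = 150, n_masc_up = 15, n_basal_shared = 15,
                           n_luminal_up = 15, effect = 0, seed = 6)
  sim <- simulate_populations(des)
  w <- capture_warnings(
    sig <- derive_signature(sim$matrix, sim$samples$population))
  expect_true(any(grepl("empty signature", w)))
  expect_length(sig, 0)
})

test_that("top-signature refinement applies strict fold-change and FDR gates in both comparisons", {
  sig <- suppressWarnings(gene_signature(c("g1", "g2", "g3")))
  sam_a <- data.frame(gene = c("g1", "g2", "g3"),
                      fold_change = c(3.0, 2.5, 4.0),
                      fdr_local = c(0.01, 0.01, 0.01))
  sam_b <- data.frame(gene = c("g1", "g2", "g3"),
                      fold_change = c(2.6, 9.0, 2.7),
                      fdr_local = c(0.04, 0.01, 0.10))
  top <- refine_top_signature(sig, sam_a, sam_b)
  # g2 fails the strict > 2.5 gate in comparison a; g3 fails FDR in b
  expect_identical(signature_genes(top), "g1")
})

test_that("correlation clustering groups samples by population and rejects constant profiles", {
  des <- population_design(n_genes = 200, n_masc_up = 40, n_basal_shared = 40,
                           n_luminal_up = 40, seed = 13)
  sim <- simulate_populations(des)
  hc <- hierarchical_cluster(sim$matrix)
  # cutting into 2 clusters separates basal (MaSC+MYO) from luminal:
  # the planted classes make basal and luminal profiles anti-correlated
  cl <- cutree(hc$hclust, k = 2)
  pop <- sim$samples$population[match(names(cl), sim$samples$sample_id)]
  basal <- pop %in% c("MaSC", "MYO")
  expect_length(unique(cl[basal]), 1)
  expect_length(unique(cl[!basal]), 1)
  expect_false(unique(cl[basal]) == unique(cl[!basal]))

  bad <- sim$matrix
  bad[, 1] <- 5
  expect_error(hierarchical_cluster(bad), "constant")
})

test_that("gene_signature enforces uniqueness and reports its size", {
  expect_error(gene_signature(c("a", "a")), "unique")
  expect_warning(empty <- gene_signature(character(0)), "empty")
  expect_length(empty, 0)
  sig <- gene_signature(c("a", "b"))
  expect_length(sig, 2)
  expect_identical(signature_genes(c("x", "y")), c("x", "y"))
})
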