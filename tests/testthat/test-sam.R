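test_that("the two-class d-statistic equals the pooled-SE relative difference", {
  set.seed(42)
  x <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  res <- sam_two_class(x, factor(rep(c("a", "b"), each = 3),
                                 levels = c("a", "b")))
  for (g in 1:8) {
    a <- x[g, 1:3]; b <- x[g, 4:6]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / 3 + 1 / 3) * ss / 4)
    expect_equal(res$table$d[g], (mean(b) - mean(a)) / (s + res$s0))
    expect_equal(res$table$s[g], s)
    expect_equal(res$table$fold_change[g], 2^(mean(b) - mean(a)))
  }
})

test_that("3v3 designs are enumerated exhaustively and larger ones are sampled", {
  set.seed(1)
  x <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  res <- sam_two_class(x, rep(c("a", "b"), each = 3))
  expect_true(res$exhaustive)
  expect_identical(res$n_perm, 20L)

  big <- matrix(rnorm(5 * 22), 5, 22,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:22)))
  res_big <- sam_two_class(big, rep(c("a", "b"), each = 11), n_perm = 50)
  expect_false(res_big$exhaustive)
  expect_identical(res_big$n_perm, 50L)
})

test_that("the multiclass statistic reduces to |d| for two groups", {
  set.seed(7)
  x <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:8)))
  groups <- rep(c("a", "b"), each = 4)
  two <- sam_two_class(x, groups)
  multi <- sam_multiclass(x, groups)
  expect_equal(multi$table$d, abs(two$table$d))
})

test_that("planted differential genes earn extreme d and low q; error rates stay bounded", {
  des <- population_design(n_genes = 200, n_masc_up = 20, n_basal_shared = 0,
                           n_luminal_up = 0, effect = 2, seed = 8)
  sim <- simulate_populations(des)
  keep <- sim$samples$population %in% c("MYO", "MaSC")
  res <- sam_two_class(sim$matrix[, keep],
                       factor(sim$samples$population[keep],
                              levels = c("MYO", "MaSC")))
  planted <- sim$truth$gene_id[sim$truth$class == "masc_up"]
  tab <- res$table
  expect_true(all(tab$q_global >= 0 & tab$q_global <= 1))
  expect_true(all(tab$fdr_local >= 0 & tab$fdr_local <= 1))
  expect_true(all(tab$d[tab$gene %in% planted] > 0))
  hits <- tab$gene[tab$fdr_local < 0.05]
  expect_gt(length(intersect(hits, planted)), 15)
  expect_lt(length(setdiff(hits, planted)), 10)
})

test_that("SAM input validation rejects malformed designs", {
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(sam_two_class(x, c("a", "a", "a", "b")), ">= 2 samples")
  expect_error(sam_two_class(x, c("a", "b", "c", "a")), "two levels")
  expect_error(sam_two_class(x, c("a", "a", "b")), "number of samples")
  bad <- x; rownames(bad) <- rep("g1", 5)
  expect_error(sam_two_class(bad, rep(c("a", "b"), each = 2)))
})

test_that("tidy and glance expose the SAM table and run summary", {
  set.seed(3)
  x <- matrix(rnorm(6 * 6), 6, 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  res <- sam_two_class(x, rep(c("a", "b"), each = 3))
  expect_identical(tidy(res), res$table)
  gl <- glance(res)
  expect_identical(gl$n_genes, 6L)
  expect_true(gl$exhaustive)
})
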