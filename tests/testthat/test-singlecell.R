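noise_free_panel <- function(n_cells = 6) {
  simulate_single_cells(single_cell_design(n_cells = n_cells, sd_ct = 0,
                                           dropout = 0, spike_sd = 0,
                                           seed = 1))
}

test_that("spike linearity recovers the dilution line and efficiency exactly when noise-free", {
  lin <- spike_linearity(noise_free_panel())
  expect_equal(lin$slope, -log2(10))
  expect_equal(lin$intercept, 38)
  expect_equal(lin$r, -1)
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$efficiency, 10^(log10(2)) - 1)  # = 1 at 100% efficiency
  expect_equal(lin$efficiency, 1)
})

test_that("delta-delta-Ct relative expression follows 2^(-ddCt) by hand", {
  ct <- matrix(c(20, 25,
                 22, 24), 2, 2, byrow = TRUE,
               dimnames = list(c("cellA", "cellB"), c("target", "ref")))
  panel <- single_cell_panel(ct)
  out <- ddct_quantify(panel, reference = "ref", comparator = "cellB")
  rel <- out$rel_expr
  # dCt(target): A = -5, B = -2; ddCt vs cellB: A = -3, B = 0
  a <- rel[rel$cell_id == "cellA" & rel$gene == "target", ]
  expect_equal(a$dct, -5)
  expect_equal(a$ddct, -3)
  expect_equal(a$rel_expr, 8)
  b <- rel[rel$cell_id == "cellB" & rel$gene == "target", ]
  expect_equal(b$rel_expr, 1)
  # mean comparator centres each gene's dCt on its across-cell mean
  out2 <- ddct_quantify(panel, reference = "ref")
  expect_equal(mean(out2$rel_expr$ddct[out2$rel_expr$gene == "target"]), 0)
  expect_error(ddct_quantify(panel, reference = "nope"), "not in the panel")
})

test_that("reciprocal Ct maps undetected wells to zero by convention", {
  ct <- matrix(c(20, NA, 25, 40), 2, 2,
               dimnames = list(c("c1", "c2"), c("g1", "g2")))
  inv <- inverse_ct(single_cell_panel(ct))
  expect_equal(inv["c1", "g1"], 1 / 20)
  expect_equal(inv["c2", "g1"], 0)
  inv_na <- inverse_ct(single_cell_panel(ct), undetected = "missing")
  expect_true(is.na(inv_na["c2", "g1"]))
})

test_that("per-gene CV uses the population standard deviation", {
  inv <- matrix(c(2, 4, 6,
                  0, 0, 0), 3, 2,
                dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  cv <- cv_per_gene(inv)
  expect_equal(cv$mean[1], 4)
  expect_equal(cv$sd[1], sqrt(mean((c(2, 4, 6) - 4)^2)))
  expect_equal(cv$cv[1], cv$sd[1] / 4)
  expect_true(is.na(cv$cv[2]))
  expect_false(cv$defined[2])
})

test_that("cell-cell correlations flag constant profiles and adjust p-values", {
  set.seed(12)
  inv <- matrix(runif(4 * 8, 1 / 40, 1 / 15), 4, 8,
                dimnames = list(paste0("c", 1:4), paste0("g", 1:8)))
  inv["c4", ] <- 0.03
  expect_message(cc <- cell_correlation_matrix(inv), "constant")
  expect_identical(cc$constant_cells, "c4")
  expect_identical(dim(cc$r), c(4L, 4L))
  expect_identical(nrow(cc$pairs), 6L)
  expect_equal(cc$pairs$p_adjusted,
               p.adjust(cc$pairs$p_value, method = "BH"))
  r_hand <- cor(inv["c1", ], inv["c2", ])
  expect_equal(cc$pairs$r[cc$pairs$cell_a == "c1" & cc$pairs$cell_b == "c2"],
               r_hand)
})

test_that("co-expression contingency counts detection patterns with one-decimal percentages", {
  ct <- matrix(NA_real_, 10, 2, dimnames = list(paste0("c", 1:10),
                                                c("Krt15", "Vim")))
  ct[1:6, "Krt15"] <- 25          # 6 cells A+ of which 4 also B+
  ct[3:8, "Vim"] <- 28            # B+: cells 3..8
  panel <- single_cell_panel(ct)
  out <- coexpression_contingency(panel, "Krt15", "Vim")
  expect_identical(out$count[out$category == "double_positive"], 4L)
  expect_identical(out$count[out$category == "a_only"], 2L)
  expect_identical(out$count[out$category == "b_only"], 2L)
  expect_identical(out$count[out$category == "double_negative"], 2L)
  expect_equal(out$percent, c(20, 20, 20, 40))
  expect_identical(attr(out, "n_cells"), 10L)
  # a Ct ceiling reclassifies weak amplifications as undetected
  ct2 <- ct; ct2[1, "Krt15"] <- 39
  out2 <- coexpression_contingency(single_cell_panel(ct2), "Krt15", "Vim",
                                   max_ct = 35)
  expect_identical(out2$count[out2$category == "a_only"], 1L)
})
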