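test_that("population simulation plants the designed structure exactly when noise-free", {
  des <- population_design(n_genes = 40, n_masc_up = 5, n_basal_shared = 5,
                           n_luminal_up = 5, effect = 2, noise_sd = 0,
                           seed = 11)
  sim <- simulate_populations(des)
  expect_identical(dim(sim$matrix), c(40L, 16L))
  expect_identical(as.vector(table(sim$truth$class)[c("masc_up", "basal_shared",
                                                      "luminal_up", "null")]),
                   c(5L, 5L, 5L, 25L))
  pop <- sim$samples$population
  for (g in sim$truth$gene_id[sim$truth$class == "masc_up"]) {
    expect_equal(mean(sim$matrix[g, pop == "MaSC"]) -
                   mean(sim$matrix[g, pop == "MYO"]), 2)
    expect_equal(sd(sim$matrix[g, pop == "MaSC"]), 0)
  }
  for (g in sim$truth$gene_id[sim$truth$class == "basal_shared"]) {
    expect_equal(mean(sim$matrix[g, pop == "MaSC"]),
                 mean(sim$matrix[g, pop == "MYO"]))
    expect_equal(mean(sim$matrix[g, pop == "MaSC"]) -
                   mean(sim$matrix[g, pop == "LumERpos"]), 2)
  }
  for (g in sim$truth$gene_id[sim$truth$class == "null"]) {
    expect_equal(var(sim$matrix[g, ]), 0)
  }
})

test_that("population simulation is reproducible by seed and validates its design", {
  small <- function(seed)
    population_design(n_genes = 50, n_masc_up = 5, n_basal_shared = 5,
                      n_luminal_up = 5, seed = seed)
  a <- simulate_populations(small(3))
  b <- simulate_populations(small(3))
  c <- simulate_populations(small(4))
  expect_identical(a$matrix, b$matrix)
  expect_false(identical(a$matrix, c$matrix))
  expect_error(population_design(replicates = c(MaSC = 1, MYO = 3,
                                                LumERneg = 3, LumERpos = 3)),
               ">= 2 replicates")
  expect_error(population_design(n_genes = 100, n_masc_up = 200),
               "exceed")
  expect_error(population_design(effect = -1), "effect")
})

test_that("cohort survival times follow the designed proportional-hazards model", {
  des <- cohort_design(n_tumours = 4000, beta = log(3), censoring_rate = 0,
                       seed = 21)
  co <- simulate_cohort(des)
  expect_true(all(co$surv$event == 1))
  # with exponential baseline, log(T) = -log(h0) - beta*A + Gumbel noise:
  # regressing log time on activation recovers -beta
  fit <- lm(log(co$survival$time) ~ co$activation$activation)
  expect_equal(unname(coef(fit)[2]), -log(3), tolerance = 0.05)
  # beta = 0 decouples survival from activation
  co0 <- simulate_cohort(cohort_design(n_tumours = 4000, beta = 0,
                                       censoring_rate = 0, seed = 21))
  expect_lt(abs(cor(log(co0$survival$time), co0$activation$activation)), 0.05)
})

test_that("cohort expression loads signature genes on the latent activation only", {
  des <- cohort_design(n_tumours = 800, noise_sd = 0.3, seed = 5)
  co <- simulate_cohort(des)
  expect_identical(nrow(co$matrix), length(des$signature) + des$n_background)
  a <- co$activation$activation
  r_sig <- cor(co$matrix["sig001", ], a)
  r_bg <- cor(co$matrix["bg00001", ], a)
  expect_gt(r_sig, 0.9)
  expect_lt(abs(r_bg), 0.12)
})

test_that("single-cell panels respect dropout, Ct bounds and the spike line", {
  des <- single_cell_design(n_cells = 2000, dropout = 0.25, spike_sd = 0,
                            seed = 9)
  panel <- simulate_single_cells(des)
  expect_identical(dim(panel$ct), c(2000L, 12L))
  vals <- panel$ct[!is.na(panel$ct)]
  expect_true(all(vals >= 10 & vals <= 40))
  expect_equal(mean(is.na(panel$ct)), 0.25, tolerance = 0.02)
  ideal <- des$spike_intercept - des$slope * log10(des$spike_copies)
  expect_equal(unname(colMeans(panel$spike_ct)), unname(ideal))
})
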