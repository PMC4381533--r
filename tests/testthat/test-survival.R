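toy_cohort <- function(n = 80, beta = 1, seed = 17) {
  set.seed(seed)
  a <- rnorm(n)
  time <- rexp(n, 0.05 * exp(beta * a))
  cens <- rexp(n, 0.02)
  tibble::tibble(sample_id = paste0("p", seq_len(n)),
                 time = pmin(time, cens),
                 event = as.integer(time <= cens),
                 group = factor(ifelse(a > 0, "high", "low"),
                                levels = c("low", "high")))
}

test_that("Kaplan-Meier estimates match the manual product-limit worksheet", {
  tab <- tibble::tibble(
    sample_id = paste0("p", 1:8),
    time = c(3, 5, 5, 7, 9, 11, 14, 14),
    event = c(1, 1, 0, 1, 0, 1, 1, 0),
    group = "all")
  km <- km_estimate(tab)
  oracle <- oracle_km(tab$time, tab$event)
  got <- km$curves[km$curves$n_event > 0, c("time", "survival")]
  expect_equal(got$time, oracle$time)
  expect_equal(got$survival, oracle$survival)
})

test_that("the log-rank statistic matches the risk-set-table oracle", {
  tab <- toy_cohort()
  lr <- logrank_test(tab)
  expect_equal(lr$statistic, oracle_logrank(tab$time, tab$event, tab$group))
  expect_equal(lr$p_value, pchisq(lr$statistic, 1, lower.tail = FALSE))
  expect_error(logrank_test(dplyr::mutate(tab, group = "one")), "two groups")
})

test_that("the Cox coefficient maximises the Breslow partial likelihood", {
  tab <- toy_cohort(n = 60, seed = 23)
  # force ties so the Breslow approximation is actually exercised
  tab$time <- round(tab$time)
  tab <- tab[tab$time > 0, ]
  fit <- cox_univariate(tab)
  beta_oracle <- oracle_cox_beta(tab$time, tab$event,
                                 as.integer(tab$group == "high"))
  expect_equal(fit$beta, beta_oracle, tolerance = 1e-5)
  expect_equal(fit$hr, exp(fit$beta))
  expect_equal(fit$ci,
               exp(fit$beta + c(-1, 1) * qnorm(0.975) * fit$se))
  expect_false(fit$monotone)
  td <- tidy(fit)
  expect_equal(td$hr, fit$hr)
})

test_that("a monotone likelihood is flagged and leaves the interval unbounded", {
  tab <- tibble::tibble(
    sample_id = paste0("p", 1:10),
    time = c(1:5, 10 + 1:5),
    event = c(rep(1, 5), rep(0, 5)),
    group = rep(c("high", "low"), each = 5))
  fit <- cox_univariate(tab)
  expect_true(fit$monotone)
  expect_identical(fit$ci, c(0, Inf))
})

test_that("survival tables are validated before fitting", {
  tab <- toy_cohort()
  expect_error(logrank_test(tab[, c("time", "group")]), "lacks column")
  expect_error(logrank_test(dplyr::mutate(tab, event = event * 2)),
               "event must be 0")
  expect_error(logrank_test(dplyr::mutate(tab, time = -time)), ">= 0")
  expect_error(logrank_test(dplyr::mutate(tab, event = 0L)),
               "at least one event")
})

test_that("the matched random-list null matches signature size and expression profile", {
  co <- simulate_cohort(cohort_design(n_tumours = 120, seed = 33))
  sig <- cohort_design(seed = 33)$signature
  null <- matched_random_signature_null(co$matrix, sig, co$survival,
                                        n_lists = 60, seed = 2)
  expect_length(null$stats, 60)
  expect_gt(null$empirical_p, 0)
  expect_lte(null$empirical_p, 1)
  expect_equal(null$empirical_p,
               (1 + sum(null$stats >= null$observed)) / 61)
  # the signature is prognostic here, so the observed statistic should sit in
  # the upper tail of the matched null
  expect_lt(null$empirical_p, 0.2)
  # reproducibility by seed
  null2 <- matched_random_signature_null(co$matrix, sig, co$survival,
                                         n_lists = 60, seed = 2)
  expect_identical(null$stats, null2$stats)
  expect_error(
    matched_random_signature_null(co$matrix[1:100, ], sig, co$survival,
                                  n_lists = 5),
    "universe")
})
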