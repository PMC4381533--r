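check_survival_table <- function(table, need_group = TRUE) {
  table <- tibble::as_tibble(table)
  req <- c("time", "event", if (need_group) "group")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop_mascsig("survival table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(table$time < 0)) stop_mascsig("times must be >= 0")
  if (!all(table$event %in% c(0, 1)))
    stop_mascsig("event must be 0 (censored) or 1 (event)")
  if (sum(table$event) < 1) stop_mascsig("need at least one event")
  table
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of survival per group (or overall when the table
#' has no `group` column).
#'
#' @param table data frame with columns `time` (months), `event` (1 = event,
#'   0 = censored) and optionally `group`.
#' @return a `km_fit`: list with `curves` (tibble: group, time, n_risk,
#'   n_event, n_censor, survival) and `survfit` (the underlying fit).
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_tumours = 60, seed = 5))
#' km <- km_estimate(cbind(cohort$survival, group = "all"))
#' head(km$curves)
#' @export
km_estimate <- function(table) {
  has_group <- "group" %in% names(table)
  table <- check_survival_table(table, need_group = FALSE)
  if (!has_group) table$group <- "all"
  if (any(table(table$group) == 0)) stop_mascsig("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = table)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(table$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                           n_event = sm$n.event, n_censor = sm$n.censor,
                           survival = sm$surv)
  structure(list(curves = curves, survfit = fit), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$survfit)
  invisible(x)
}

#' @rdname km_estimate
#' @param x a `km_fit`.
#' @param ... unused.
#' @export
tidy.km_fit <- function(x, ...) x$curves

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom, two-sided p-value.
#'
#' @inheritParams km_estimate
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(table) {
  table <- check_survival_table(table)
  if (length(unique(table$group)) != 2)
    stop_mascsig("log-rank test needs exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  tibble::tibble(statistic = sd$chisq, df = 1,
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit for a binary group
#'
#' Partial-likelihood fit with Breslow tie handling; hazard ratio is for
#' the second group level against the first, with a Wald 95% confidence
#' interval. A monotone likelihood (e.g. all events in one group) is
#' flagged and leaves the interval unbounded.
#'
#' @inheritParams km_estimate
#' @return a `cox_fit`: list with `beta`, `hr`, `ci` (length 2), `se`,
#'   `p_value`, `monotone` flag and the underlying `coxph` fit.
#' @export
cox_univariate <- function(table) {
  table <- check_survival_table(table)
  table$group <- factor(table$group)
  if (nlevels(table$group) != 2)
    stop_mascsig("cox_univariate expects a binary group")
  events_by_group <- tapply(table$event, table$group, sum)
  monotone <- any(events_by_group == 0)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ group, data = table,
                    ties = "breslow"))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  monotone <- monotone || !is.finite(beta) || se > 1e3
  ci <- exp(beta + c(-1, 1) * qnorm(0.975) * se)
  if (monotone) ci <- c(0, Inf)
  structure(list(beta = beta, hr = exp(beta), ci = ci, se = se,
                 p_value = 2 * stats::pnorm(abs(beta / se),
                                            lower.tail = FALSE),
                 monotone = monotone, coxph = fit,
                 levels = levels(table$group)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (%s vs %s, Breslow ties): HR = %.3f; CI (%.3f to %.3f); P = %.3g\n",
              x$levels[2], x$levels[1], x$hr, x$ci[1], x$ci[2], x$p_value))
  if (x$monotone) cat("  WARNING: monotone likelihood, CI unbounded\n")
  invisible(x)
}

#' @rdname cox_univariate
#' @param x a `cox_fit`.
#' @param ... unused.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = paste(x$levels[2], "vs", x$levels[1]),
                 estimate = x$beta, std.error = x$se,
                 hr = x$hr, conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p_value)
}

#' @rdname cox_univariate
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(hr = x$hr, conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p_value, monotone = x$monotone)
}

# fast internal path shared by the null and the observed statistic:
# averaged score on a pre-centred matrix -> dichotomise -> log-rank chi-square
score_dichotomise_logrank <- function(mc, genes, surv, method) {
  score <- colMeans(mc[genes, , drop = FALSE])
  groups <- dichotomise(score, method = method)
  tab <- surv
  tab$group <- groups$group[match(tab$sample_id, groups$sample_id)]
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = tab)
  sd$chisq
}

#' Expression-matched random gene list null distribution
#'
#' Assesses whether a signature's survival stratification could arise by
#' chance: genes are binned into deciles (by default) of mean expression and
#' each of `n_lists` random lists draws, for every signature gene, a
#' non-signature gene from the same bin — so the random lists match the
#' signature in size and expression distribution. For every list the full
#' pipeline (median-centred averaged score, dichotomisation, two-group
#' log-rank) is rerun; the empirical p-value is
#' `(1 + #[null >= observed]) / (n_lists + 1)`, so it is never zero. The
#' log-rank chi-square (monotone in the p-value) is the comparison
#' statistic.
#'
#' @param x log2 expression matrix for the cohort.
#' @param signature a `gene_signature` or character vector.
#' @param surv data frame with `sample_id`, `time`, `event`.
#' @param n_lists number of random lists (default 1000).
#' @param method dichotomisation: `"top_tertile"` or `"median"`.
#' @param n_bins number of expression bins for matching (default 10).
#' @param seed integer seed.
#' @return a `matched_null`: list with `observed` (chi-square for the
#'   signature), `stats` (chi-squares of the random lists), `empirical_p`,
#'   `n_lists`, `n_bins`, `seed`.
#' @export
matched_random_signature_null <- function(x, signature, surv,
                                          n_lists = 1000,
                                          method = c("top_tertile", "median"),
                                          n_bins = 10, seed = 1L) {
  assert_matrix(x, "x")
  method <- match.arg(method)
  surv <- check_survival_table(tibble::as_tibble(surv), need_group = FALSE)
  if (!all(colnames(x) %in% surv$sample_id))
    stop_mascsig("every sample in the matrix needs a survival record")
  genes <- intersect(signature_genes(signature), rownames(x))
  if (length(genes) == 0) stop_mascsig("signature absent from matrix")
  universe <- rownames(x)
  if (length(universe) < 5 * length(genes))
    stop_mascsig("gene universe must be at least 5x the signature size")

  mc <- median_centre(x)
  observed <- score_dichotomise_logrank(mc, genes, surv, method)

  mean_expr <- rowMeans(x)
  breaks <- unique(quantile(mean_expr, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- as.integer(cut(mean_expr, breaks = breaks, include.lowest = TRUE))
  names(bin) <- universe
  pool_by_bin <- split(setdiff(universe, genes),
                       bin[setdiff(universe, genes)])
  sig_bin_counts <- table(bin[genes])

  # per-bin sampling pools, widened to neighbouring bins when short
  widened <- FALSE
  pools <- lapply(names(sig_bin_counts), function(b) {
    need <- sig_bin_counts[[b]]
    pool <- pool_by_bin[[b]] %||% character(0)
    radius <- 1L
    while (length(pool) < need) {
      widened <<- TRUE
      nb <- as.character(as.integer(b) + c(-radius, radius))
      pool <- unique(c(pool, unlist(pool_by_bin[intersect(nb, names(pool_by_bin))])))
      radius <- radius + 1L
      if (radius > length(pool_by_bin)) break
    }
    pool
  })
  if (widened)
    message("some expression bins were short of genes; widened to ",
            "neighbouring bins")
  names(pools) <- names(sig_bin_counts)

  set.seed(seed)
  stats <- vapply(seq_len(n_lists), function(i) {
    lst <- unlist(lapply(names(sig_bin_counts), function(b)
      sample(pools[[b]], sig_bin_counts[[b]])))
    score_dichotomise_logrank(mc, lst, surv, method)
  }, numeric(1))
  empirical_p <- (1 + sum(stats >= observed)) / (n_lists + 1)
  structure(list(observed = observed, stats = stats,
                 empirical_p = empirical_p, n_lists = n_lists,
                 n_bins = n_bins, method = method, seed = seed),
            class = "matched_null")
}

#' @export
print.matched_null <- function(x, ...) {
  cat("Expression-matched random-list null:", x$n_lists, "lists,",
      x$n_bins, "expression bins\n")
  cat(sprintf("  observed log-rank chi-square = %.3f; empirical P = %.4g\n",
              x$observed, x$empirical_p))
  invisible(x)
}

#' @rdname matched_random_signature_null
#' @param x a `matched_null`.
#' @param ... unused.
#' @export
glance.matched_null <- function(x, ...) {
  tibble::tibble(observed = x$observed, empirical_p = x$empirical_p,
                 n_lists = x$n_lists, n_bins = x$n_bins)
}
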