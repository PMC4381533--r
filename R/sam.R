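# Significance analysis of microarrays: moderated d-statistic with fudge
# factor s0, permutation-based global q-values and a local FDR estimated by
# comparing permuted and observed d-densities in a sliding value window.

# Tusher-style s0 tuning: evaluate s0 over a percentile grid of the gene-wise
# standard errors and keep the value minimising the coefficient of variation
# of the d-statistic's spread across s-quantile windows.
tune_s0 <- function(r, s, grid = seq(0, 100, by = 5)) {
  if (all(s == 0)) return(if (any(r != 0)) 1e-8 else 0)
  qs <- quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  bins <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cvs <- vapply(grid, function(pct) {
    s0 <- quantile(s, pct / 100, names = FALSE)
    d <- r / (s + s0)
    mads <- tapply(d, bins, function(v) median(abs(v - median(v))) * 1.4826)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  quantile(s, grid[which.min(cvs)] / 100, names = FALSE)
}

# all ways to assign labels with group sizes n_k to n = sum(n_k) columns;
# returns a list of integer label vectors, or NULL if more than `cap` exist
enumerate_assignments <- function(sizes, cap = 10000) {
  n <- sum(sizes)
  total <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (total > cap) return(NULL)
  build <- function(slots, sizes) {
    if (length(sizes) == 1) return(list(list(slots)))
    out <- list()
    for (p in combn(slots, sizes[1], simplify = FALSE)) {
      for (rest in build(setdiff(slots, p), sizes[-1])) {
        out[[length(out) + 1L]] <- c(list(p), rest)
      }
    }
    out
  }
  lapply(build(seq_len(n), sizes), function(parts) {
    lab <- integer(n)
    for (k in seq_along(parts)) lab[parts[[k]]] <- k
    lab
  })
}

# d-statistic pieces for a k-group labelling; reduces exactly to the
# two-sample pooled-SE form when k = 2
sam_stat <- function(x, labels, two_class = TRUE) {
  ks <- sort(unique(labels))
  nk <- vapply(ks, function(k) sum(labels == k), numeric(1))
  n <- length(labels)
  means <- vapply(ks, function(k) rowMeans(x[, labels == k, drop = FALSE]),
                  numeric(nrow(x)))
  ssw <- rowSums(vapply(seq_along(ks), function(j) {
    xi <- x[, labels == ks[j], drop = FALSE]
    rowSums((xi - means[, j])^2)
  }, numeric(nrow(x))))
  cinv <- sum(1 / nk)
  s <- sqrt(cinv * ssw / (n - length(ks)))
  if (two_class) {
    r <- means[, 2] - means[, 1]
  } else {
    grand <- rowMeans(x)
    ssb <- rowSums(sweep((means - grand)^2, 2, nk, `*`))
    r <- sqrt(cinv * ssb)
  }
  list(r = r, s = s, means = means)
}

# global q-values: expected false-positive count at each gene's threshold
# (mean over permutations) over the observed count, clamped and monotonised
# from most to least significant
sam_q_global <- function(stat_obs, stat_perm_pooled, n_perm) {
  g <- length(stat_obs)
  ord <- order(stat_obs, decreasing = TRUE)
  sorted_perm <- sort(stat_perm_pooled)
  # V(t) = #{perm stats >= t} / n_perm ; R(t) = #{obs >= t}
  v <- (length(sorted_perm) -
          findInterval(stat_obs, sorted_perm, left.open = TRUE)) / n_perm
  r <- vapply(stat_obs, function(t) sum(stat_obs >= t), numeric(1))
  fdr <- pmin(v / pmax(r, 1), 1)
  q <- fdr
  q[ord] <- rev(cummin(rev(fdr[ord])))
  q
}

# local FDR: ratio of the permutation-null to the observed density of d in a
# sliding window centred on each gene's d value. The window half-width is a
# fraction of the observed d range, and the null density is scaled by the
# estimated null proportion pi0 (share of observed d values inside the
# interquartile range of the permuted values, as in SAM).
sam_fdr_local <- function(stat_obs, stat_perm_pooled, n_perm,
                          window_frac = 0.025) {
  g <- length(stat_obs)
  rng <- range(stat_obs)
  h <- diff(rng) * window_frac
  if (h == 0) return(rep(1, g))
  sorted_perm <- sort(stat_perm_pooled)
  qs <- quantile(sorted_perm, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(stat_obs >= qs[1] & stat_obs <= qs[2]) / (0.5 * g))
  sorted_obs <- sort(stat_obs)
  lo <- stat_obs - h
  hi <- stat_obs + h
  n_obs <- findInterval(hi, sorted_obs) -
    findInterval(lo, sorted_obs, left.open = TRUE)
  n_null <- findInterval(hi, sorted_perm) -
    findInterval(lo, sorted_perm, left.open = TRUE)
  pmin(1, pi0 * (n_null / n_perm) / pmax(n_obs, 1))
}

sam_permutations <- function(n, sizes, n_perm, seed, cap = 10000) {
  all_assign <- enumerate_assignments(sizes, cap = cap)
  if (!is.null(all_assign)) {
    return(list(labels = all_assign, exhaustive = TRUE,
                n_perm = length(all_assign)))
  }
  set.seed(seed)
  base <- rep(seq_along(sizes), sizes)
  labels <- lapply(seq_len(n_perm), function(i) sample(base))
  list(labels = labels, exhaustive = FALSE, n_perm = as.integer(n_perm))
}

sam_run <- function(x, labels, sizes, n_perm, seed, window_frac, two_class) {
  obs <- sam_stat(x, labels, two_class)
  s0 <- tune_s0(obs$r, obs$s)
  d <- obs$r / (obs$s + s0)
  perms <- sam_permutations(ncol(x), sizes, n_perm, seed)
  d_perm <- vapply(perms$labels, function(lab) {
    st <- sam_stat(x, lab, two_class)
    st$r / (st$s + s0)
  }, numeric(nrow(x)))
  crit <- if (two_class) abs(d) else d
  crit_perm <- if (two_class) abs(d_perm) else d_perm
  q <- sam_q_global(crit, as.numeric(crit_perm), perms$n_perm)
  fdr <- sam_fdr_local(d, as.numeric(d_perm), perms$n_perm, window_frac = window_frac)
  list(d = unname(d), s = unname(obs$s), s0 = s0, q = unname(q),
       fdr = unname(fdr), means = unname(obs$means),
       n_perm = perms$n_perm, exhaustive = perms$exhaustive)
}

new_sam_result <- function(table, s0, n_perm, exhaustive, comparison, seed) {
  structure(list(table = table, s0 = s0, n_perm = n_perm,
                 exhaustive = exhaustive, comparison = comparison,
                 seed = seed),
            class = "sam_result")
}

#' Two-class unpaired SAM
#'
#' Computes the moderated relative-difference statistic
#' `d = (mean2 - mean1) / (s + s0)` per gene, where `s` is the two-sample
#' pooled standard-error term and `s0` is the fudge factor chosen on a
#' percentile grid of `s` to minimise the coefficient of variation of `d`
#' across `s`-quantile windows. Significance is assessed against the
#' permutation null obtained by relabelling columns: when the number of
#' distinct relabellings is at most 10,000 they are enumerated exhaustively,
#' otherwise `n_perm` random relabellings are drawn. Reported per gene:
#' the global q-value (expected false positives over observed positives at
#' the gene's |d| threshold, monotonised) and the local FDR (ratio of the
#' permutation-null to observed density of `d` in a sliding window centred
#' on the gene's `d`, scaled by the estimated null proportion).
#'
#' @param x log2 expression matrix, genes x samples.
#' @param groups two-level factor or character vector over columns; `d > 0`
#'   means higher in the second level.
#' @param n_perm number of random permutations when exhaustive enumeration
#'   is not feasible.
#' @param seed integer seed for permutation sampling.
#' @param window_frac half-width of the local-FDR window as a fraction of
#'   the observed range of `d` (default 0.025).
#' @return a `sam_result`; its `table` is a tibble with columns `gene`, `d`,
#'   `s`, `fold_change` (linear scale, second over first level), `q_global`,
#'   `fdr_local`, `direction`.
#' @examples
#' sim <- simulate_populations(population_design(n_genes = 100, seed = 1))
#' keep <- sim$samples$population %in% c("MYO", "MaSC")
#' res <- sam_two_class(sim$matrix[, keep],
#'                      factor(sim$samples$population[keep],
#'                             levels = c("MYO", "MaSC")))
#' head(tidy(res))
#' @export
sam_two_class <- function(x, groups, n_perm = 1000, seed = 1L, window_frac = 0.025) {
  assert_matrix(x, "x")
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2)
    stop_mascsig("groups must have exactly two levels")
  if (length(groups) != ncol(x))
    stop_mascsig("groups must match the number of samples")
  sizes <- as.numeric(table(groups))
  if (any(sizes < 2)) stop_mascsig("each group needs >= 2 samples")
  if (n_perm < 1) stop_mascsig("n_perm must be >= 1")
  labels <- as.integer(groups)
  fit <- sam_run(x, labels, sizes, n_perm, seed, window_frac, two_class = TRUE)
  tab <- tibble::tibble(
    gene = rownames(x),
    d = fit$d, s = fit$s,
    fold_change = 2^(fit$means[, 2] - fit$means[, 1]),
    q_global = fit$q, fdr_local = fit$fdr,
    direction = sign(fit$d))
  new_sam_result(tab, fit$s0, fit$n_perm, fit$exhaustive,
                 comparison = paste(levels(groups)[2], "vs",
                                    levels(groups)[1]),
                 seed = seed)
}

#' Multiclass SAM
#'
#' ANOVA-like extension of the two-class statistic: the numerator is
#' `sqrt(sum(1/n_k) * sum_k n_k * (mean_k - grand)^2)` and the denominator
#' `s + s0` uses the pooled within-group standard error; for two groups the
#' statistic equals |d| of [sam_two_class()] exactly. Fold change is the
#' maximum pairwise group ratio.
#'
#' @inheritParams sam_two_class
#' @param groups factor with `k >= 3` levels (2 is accepted and reduces to
#'   the two-class statistic's magnitude).
#' @return a `sam_result`, `direction` fixed at 1.
#' @export
sam_multiclass <- function(x, groups, n_perm = 1000, seed = 1L, window_frac = 0.025) {
  assert_matrix(x, "x")
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) < 2)
    stop_mascsig("groups must have at least two levels")
  if (length(groups) != ncol(x))
    stop_mascsig("groups must match the number of samples")
  sizes <- as.numeric(table(groups))
  if (any(sizes < 2)) stop_mascsig("each group needs >= 2 samples")
  if (n_perm < 1) stop_mascsig("n_perm must be >= 1")
  labels <- as.integer(groups)
  fit <- sam_run(x, labels, sizes, n_perm, seed, window_frac, two_class = FALSE)
  fc <- 2^(apply(fit$means, 1, max) - apply(fit$means, 1, min))
  tab <- tibble::tibble(
    gene = rownames(x),
    d = fit$d, s = fit$s, fold_change = fc,
    q_global = fit$q, fdr_local = fit$fdr,
    direction = rep(1, nrow(x)))
  new_sam_result(tab, fit$s0, fit$n_perm, fit$exhaustive,
                 comparison = paste("multiclass:",
                                    paste(levels(groups), collapse = "/")),
                 seed = seed)
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM result (", x$comparison, ")\n", sep = "")
  cat("  s0 =", signif(x$s0, 4), "|", x$n_perm,
      if (x$exhaustive) "exhaustive" else "sampled", "permutations\n")
  cat("  genes with local FDR < 0.05:",
      sum(x$table$fdr_local < 0.05), "of", nrow(x$table), "\n")
  invisible(x)
}

#' @rdname sam_two_class
#' @param x a `sam_result`.
#' @param ... unused.
#' @export
tidy.sam_result <- function(x, ...) x$table

#' @rdname sam_two_class
#' @export
glance.sam_result <- function(x, ...) {
  tibble::tibble(s0 = x$s0, n_perm = x$n_perm, exhaustive = x$exhaustive,
                 n_genes = nrow(x$table),
                 n_fdr_local_05 = sum(x$table$fdr_local < 0.05),
                 comparison = x$comparison)
}
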