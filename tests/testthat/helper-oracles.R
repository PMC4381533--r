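# Independent oracles used by the test suite. Every oracle is a deliberately
# naive reimplementation (explicit loops, exhaustive enumeration, grid/optimise
# search) so it shares no code path with the package functions it checks.

# Two-class SAM by brute force: enumerate every way to choose the group-2
# columns, recompute d with the plain pooled-SE formula, and derive global
# q-values with literal loops. `s0` is taken as given so the oracle checks the
# permutation and FDR machinery, not the fudge-factor tuning.
oracle_sam_two_class <- function(x, group2_cols, s0) {
  n <- ncol(x)
  d_for <- function(cols2) {
    cols1 <- setdiff(seq_len(n), cols2)
    n1 <- length(cols1); n2 <- length(cols2)
    vapply(seq_len(nrow(x)), function(g) {
      a <- x[g, cols1]; b <- x[g, cols2]
      ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
      (mean(b) - mean(a)) / (s + s0)
    }, numeric(1))
  }
  d_obs <- d_for(group2_cols)
  perms <- utils::combn(n, length(group2_cols), simplify = FALSE)
  d_perm <- vapply(perms, d_for, numeric(nrow(x)))

  crit <- abs(d_obs)
  crit_perm <- abs(as.numeric(d_perm))
  n_perm <- length(perms)
  fdr <- vapply(crit, function(t) {
    v <- sum(crit_perm >= t) / n_perm
    r <- sum(crit >= t)
    min(1, v / max(r, 1))
  }, numeric(1))
  q <- vapply(seq_along(crit), function(g)
    min(fdr[crit <= crit[g]]), numeric(1))
  list(d = d_obs, q = q, n_perm = n_perm)
}

# Kaplan-Meier product-limit worksheet: S(t) = prod over event times <= t of
# (1 - d_i / n_i), with n_i the number at risk just before t_i.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Two-group log-rank chi-square from the per-event-time risk-set table.
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    e1 <- n1 * d / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1))
  }
  o_minus_e^2 / v
}

# Breslow partial likelihood maximised by one-dimensional search: the oracle
# for the univariate Cox coefficient of a binary covariate.
oracle_cox_beta <- function(time, event, covariate) {
  loglik <- function(b) {
    ts <- sort(unique(time[event == 1]))
    ll <- 0
    for (t in ts) {
      ev <- time == t & event == 1
      risk <- time >= t
      ll <- ll + b * sum(covariate[ev]) -
        sum(ev) * log(sum(exp(b * covariate[risk])))
    }
    ll
  }
  optimize(loglik, c(-20, 20), maximum = TRUE, tol = 1e-9)$maximum
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hypergeom <- function(k, n_a, n_b, n_u) {
  js <- k:min(n_a, n_b)
  sum(exp(lchoose(n_a, js) + lchoose(n_u - n_a, n_b - js) - lchoose(n_u, n_b)))
}
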