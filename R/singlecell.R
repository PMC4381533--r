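#' Construct a single-cell qPCR panel
#'
#' @param ct cells x genes matrix of cycle thresholds; `NA` marks an
#'   undetected (never-amplified) well.
#' @param spike_ct optional cells x spikes matrix of spike-transcript Cts.
#' @param spikes tibble with `transcript` and `copies` (input molecules),
#'   matching `spike_ct` columns.
#' @return a `single_cell_panel`.
#' @export
single_cell_panel <- function(ct, spike_ct = NULL, spikes = NULL) {
  if (!is.matrix(ct)) ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop_mascsig("ct matrix needs cell rownames and gene colnames")
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop_mascsig("cell and gene identifiers must be unique")
  vals <- ct[!is.na(ct)]
  if (length(vals) && any(vals <= 0 | vals >= 45))
    stop_mascsig("numeric Ct values must lie in (0, 45)")
  if (!is.null(spikes)) {
    spikes <- tibble::as_tibble(spikes)
    if (any(spikes$copies <= 0)) stop_mascsig("spike copies must be > 0")
    if (!is.null(spike_ct) && ncol(spike_ct) != nrow(spikes))
      stop_mascsig("spike_ct columns must match the spikes table")
  }
  structure(list(ct = ct, spike_ct = spike_ct, spikes = spikes),
            class = "single_cell_panel")
}

#' Spike-in amplification linearity
#'
#' Least-squares fit of spike Ct against log10 input copies, pooled over
#' cells. At 100% PCR efficiency the slope is `-log2(10) = -3.3219` cycles
#' per tenfold dilution; efficiency is reported as `10^(-1/slope) - 1`.
#'
#' @param panel a `single_cell_panel` with >= 3 spike levels.
#' @return tibble with `slope`, `intercept`, `r` (Pearson correlation of Ct
#'   with log10 copies), `r_squared`, `efficiency`.
#' @export
spike_linearity <- function(panel) {
  stopifnot(inherits(panel, "single_cell_panel"))
  if (is.null(panel$spikes) || nrow(panel$spikes) < 3)
    stop_mascsig("need >= 3 spike levels")
  log_copies <- rep(log10(panel$spikes$copies), each = nrow(panel$spike_ct))
  ct <- as.numeric(panel$spike_ct)
  ok <- !is.na(ct)
  if (sum(ok) < 3) stop_mascsig("fewer than 3 detected spike measurements")
  fit <- lm(ct[ok] ~ log_copies[ok])
  slope <- unname(coef(fit)[2])
  tibble::tibble(slope = slope, intercept = unname(coef(fit)[1]),
                 r = cor(ct[ok], log_copies[ok]),
                 r_squared = cor(ct[ok], log_copies[ok])^2,
                 efficiency = 10^(-1 / slope) - 1)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' For each cell and gene, `dCt = Ct_gene - Ct_reference` within the cell;
#' `ddCt` subtracts the comparator's `dCt` (the across-cell mean by default,
#' or a named cell); relative expression is `2^(-ddCt)`. Cells in which the
#' reference is undetected yield missing values and are counted.
#'
#' @param panel a `single_cell_panel`.
#' @param reference name of a panel gene or spike transcript used as the
#'   within-cell reference.
#' @param comparator `"mean"` (per-gene mean dCt across detected cells) or a
#'   cell identifier.
#' @return list with `rel_expr` (tibble: cell_id, gene, dct, ddct,
#'   rel_expr) and `n_reference_missing`.
#' @export
ddct_quantify <- function(panel, reference, comparator = "mean") {
  stopifnot(inherits(panel, "single_cell_panel"))
  ct <- panel$ct
  if (reference %in% colnames(ct)) {
    ref_ct <- ct[, reference]
  } else if (!is.null(panel$spikes) && reference %in% panel$spikes$transcript) {
    ref_ct <- panel$spike_ct[, match(reference, panel$spikes$transcript)]
  } else stop_mascsig("reference '", reference, "' not in the panel")
  n_missing <- sum(is.na(ref_ct))
  dct <- ct - ref_ct
  if (identical(comparator, "mean")) {
    base <- colMeans(dct, na.rm = TRUE)
  } else {
    if (!comparator %in% rownames(ct))
      stop_mascsig("comparator cell '", comparator, "' not in the panel")
    base <- dct[comparator, ]
  }
  ddct <- sweep(dct, 2, base)
  long <- tibble::tibble(
    cell_id = rep(rownames(ct), ncol(ct)),
    gene = rep(colnames(ct), each = nrow(ct)),
    dct = as.numeric(dct), ddct = as.numeric(ddct),
    rel_expr = 2^(-as.numeric(ddct)))
  list(rel_expr = long, n_reference_missing = n_missing)
}

#' Reciprocal-Ct expression matrix
#'
#' `1/Ct` is a monotone proxy for expression level; undetected wells map to
#' 0 by the package's convention (non-amplification read as absence), or to
#' `NA` with `undetected = "missing"`.
#'
#' @param panel a `single_cell_panel` or a cells x genes Ct matrix with `NA`
#'   for undetected.
#' @param undetected `"zero"` (default) or `"missing"`.
#' @return cells x genes matrix of 1/Ct values.
#' @export
inverse_ct <- function(panel, undetected = c("zero", "missing")) {
  undetected <- match.arg(undetected)
  ct <- if (inherits(panel, "single_cell_panel")) panel$ct else panel
  inv <- 1 / ct
  if (undetected == "zero") inv[is.na(inv)] <- 0
  inv
}

#' Per-gene coefficient of variation across cells
#'
#' CV = population SD (n denominator) over mean, per gene, on the 1/Ct
#' scale. Genes with zero mean are flagged undefined.
#'
#' @param inv cells x genes 1/Ct matrix (>= 2 cells), e.g. from
#'   [inverse_ct()].
#' @return tibble with `gene`, `mean`, `sd`, `cv`, `defined`.
#' @export
cv_per_gene <- function(inv) {
  if (nrow(inv) < 2) stop_mascsig("need >= 2 cells")
  m <- unname(colMeans(inv))
  pop_sd <- unname(sqrt(colMeans(sweep(inv, 2, m)^2)))
  tibble::tibble(gene = colnames(inv), mean = m, sd = pop_sd,
                 cv = ifelse(m == 0, NA_real_, pop_sd / m),
                 defined = m != 0)
}

#' Cell-to-cell correlation of expression profiles
#'
#' Pearson correlation between every pair of cells over the gene panel, with
#' a two-sided test per pair and Benjamini-Hochberg adjustment. Cells with a
#' constant profile have undefined correlations and are flagged.
#'
#' @param inv cells x genes 1/Ct matrix (>= 3 genes).
#' @return list with `r` (cells x cells matrix), `pairs` (tibble: cell_a,
#'   cell_b, r, p_value, p_adjusted) and `constant_cells`.
#' @export
cell_correlation_matrix <- function(inv) {
  if (ncol(inv) < 3) stop_mascsig("need >= 3 genes")
  constant <- rownames(inv)[apply(inv, 1, sd) == 0]
  r <- suppressWarnings(cor(t(inv)))
  n <- ncol(inv)
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rv) >= 1] <- 0
  pairs <- tibble::tibble(cell_a = rownames(inv)[idx[, 1]],
                          cell_b = rownames(inv)[idx[, 2]],
                          r = rv, p_value = p,
                          p_adjusted = p.adjust(p, method = "BH"))
  if (length(constant))
    message("constant profile, correlations undefined for cell(s): ",
            paste(constant, collapse = ", "))
  list(r = r, pairs = pairs, constant_cells = constant)
}

#' Two-gene co-expression contingency
#'
#' Classifies each cell as double negative, A only, B only or double
#' positive by the detection rule `1/Ct > 0` (any amplification), or a Ct
#' ceiling when `max_ct` is given. Percentages are reported to one decimal
#' place.
#'
#' @param panel a `single_cell_panel` or cells x genes 1/Ct matrix.
#' @param gene_a,gene_b panel gene names.
#' @param max_ct optional Ct ceiling: with a panel input, wells with
#'   `Ct >= max_ct` also count as undetected.
#' @return a `coexpression_contingency`: tibble with `category`, `count`,
#'   `percent`; attribute `n_cells`.
#' @export
coexpression_contingency <- function(panel, gene_a, gene_b, max_ct = NULL) {
  if (inherits(panel, "single_cell_panel")) {
    ct <- panel$ct
    if (!is.null(max_ct)) ct[!is.na(ct) & ct >= max_ct] <- NA
    inv <- inverse_ct(single_cell_panel(ct))
  } else {
    inv <- panel
  }
  for (g in c(gene_a, gene_b))
    if (!g %in% colnames(inv)) stop_mascsig("gene '", g, "' not in the panel")
  a <- inv[, gene_a] > 0
  b <- inv[, gene_b] > 0
  counts <- c(double_negative = sum(!a & !b),
              a_only = sum(a & !b),
              b_only = sum(!a & b),
              double_positive = sum(a & b))
  out <- tibble::tibble(category = names(counts), count = unname(counts),
                        percent = round(100 * unname(counts) / nrow(inv), 1))
  attr(out, "n_cells") <- nrow(inv)
  attr(out, "genes") <- c(gene_a, gene_b)
  class(out) <- c("coexpression_contingency", class(out))
  out
}
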