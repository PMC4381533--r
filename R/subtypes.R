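#' Synthetic centroid set
#'
#' Random orthogonal-ish centroid profiles for testing nearest-centroid
#' classification; real centroid tables (e.g. PAM50 or TNBC subtype
#' centroids) are supplied by the user as inputs.
#'
#' @param n_genes number of genes.
#' @param subtypes character vector of subtype names.
#' @param seed integer seed.
#' @return matrix genes x subtypes with gene rownames.
#' @export
synthetic_centroids <- function(n_genes = 100,
                                subtypes = c("BL1", "BL2", "M", "LAR"),
                                seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * length(subtypes)), n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), subtypes))
  m
}

#' Nearest-centroid subtype classification
#'
#' Correlates each sample's expression profile (over the genes shared with
#' the centroid table) with every subtype centroid and assigns the
#' highest-correlation subtype. Ties are broken by subtype name order with a
#' message; assignments whose best correlation falls below `r_min` are
#' flagged low-confidence.
#'
#' @param x expression matrix, genes x samples.
#' @param centroids matrix genes x subtypes (>= 2 subtypes, no constant
#'   centroid); >= 10 genes must be shared with `x`.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param r_min confidence floor on the winning correlation (default 0.1).
#' @return tibble with `sample_id`, `subtype`, `confident`, plus one
#'   `r_<subtype>` column per centroid.
#' @examples
#' cen <- synthetic_centroids(n_genes = 60, seed = 1)
#' x <- cen[, sample(4, 20, replace = TRUE)] + rnorm(60 * 20, sd = 0.3)
#' colnames(x) <- paste0("s", 1:20)
#' head(classify_by_centroid(x, cen))
#' @export
classify_by_centroid <- function(x, centroids, method = c("pearson", "spearman"),
                                 r_min = 0.1) {
  assert_matrix(x, "x")
  method <- match.arg(method)
  if (ncol(centroids) < 2) stop_mascsig("need >= 2 subtype centroids")
  if (any(apply(centroids, 2, sd) == 0))
    stop_mascsig("constant centroid: ",
                 paste(colnames(centroids)[apply(centroids, 2, sd) == 0],
                       collapse = ", "))
  shared <- intersect(rownames(x), rownames(centroids))
  if (length(shared) == 0) stop_mascsig("no genes shared with the centroids")
  if (length(shared) < 10)
    stop_mascsig("only ", length(shared),
                 " genes shared with the centroids; >= 10 required")
  r <- cor(x[shared, , drop = FALSE], centroids[shared, , drop = FALSE],
           method = method)
  best <- apply(r, 1, function(v) {
    w <- which(v == max(v))
    if (length(w) > 1) message("correlation tie; broke by subtype name order")
    colnames(r)[min(w)]
  })
  out <- tibble::tibble(sample_id = colnames(x), subtype = unname(best),
                        confident = unname(apply(r, 1, max) >= r_min))
  rcols <- tibble::as_tibble(r, .name_repair = ~ paste0("r_", colnames(r)))
  dplyr::bind_cols(out, rcols)
}

#' Score distribution and high-score enrichment by subtype
#'
#' Summarises activation scores per subtype (median and quartiles) and tests
#' each subtype for enrichment of "high"-score tumours (top tertile by
#' default) with a hypergeometric test, Benjamini-Hochberg corrected across
#' subtypes. Subtypes with fewer than 3 tumours are summarised but excluded
#' from testing.
#'
#' @param scores an `activation_scores` or named numeric vector.
#' @param subtypes subtype label per sample (named by sample, or in the
#'   order of the scores).
#' @param dichotomy how the "high" group is defined; see [dichotomise()].
#' @return tibble with one row per subtype: `subtype`, `n`, `median`, `q1`,
#'   `q3`, `n_high`, `expected_high`, `p_value`, `p_adjusted` (`NA` for
#'   subtypes too small to test, or when only one subtype exists).
#' @export
score_by_subtype <- function(scores, subtypes,
                             dichotomy = c("top_tertile", "median")) {
  dichotomy <- match.arg(dichotomy)
  s <- if (inherits(scores, "activation_scores")) scores$scores else scores
  if (!is.null(names(subtypes)) && !is.null(names(s)))
    subtypes <- subtypes[names(s)]
  if (length(subtypes) != length(s))
    stop_mascsig("subtype labels must cover every scored sample")
  subtypes <- as.character(subtypes)
  summ <- tibble::tibble(subtype = subtypes, score = unname(s)) |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(.data$score),
                     q1 = quantile(.data$score, 0.25, names = FALSE),
                     q3 = quantile(.data$score, 0.75, names = FALSE),
                     .groups = "drop")
  if (length(unique(subtypes)) < 2) {
    summ$n_high <- NA_integer_; summ$expected_high <- NA_real_
    summ$p_value <- NA_real_; summ$p_adjusted <- NA_real_
    return(summ)
  }
  groups <- dichotomise(s, method = dichotomy)
  high <- groups$group == "high"
  n_total <- length(s)
  n_high_total <- sum(high)
  per <- tibble::tibble(subtype = subtypes, high = high) |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n = dplyr::n(), n_high = sum(.data$high),
                     .groups = "drop") |>
    dplyr::mutate(
      expected_high = .data$n * n_high_total / n_total,
      p_value = ifelse(
        .data$n >= 3,
        phyper(.data$n_high - 1, n_high_total, n_total - n_high_total,
               .data$n, lower.tail = FALSE),
        NA_real_))
  small <- per$subtype[per$n < 3]
  if (length(small))
    message("subtype(s) with < 3 tumours summarised but not tested: ",
            paste(small, collapse = ", "))
  per$p_adjusted <- NA_real_
  testable <- !is.na(per$p_value)
  per$p_adjusted[testable] <- p.adjust(per$p_value[testable], method = "BH")
  dplyr::left_join(summ, per[, c("subtype", "n_high", "expected_high",
                                 "p_value", "p_adjusted")],
                   by = "subtype")
}
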