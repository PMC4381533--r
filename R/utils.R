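# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats median quantile sd cor cor.test p.adjust phyper rnorm
#'   runif rexp rbinom rchisq setNames complete.cases coef pchisq cophenetic
#'   hclust as.dist ks.test qnorm lm
#' @importFrom utils head combn
NULL

stop_mascsig <- function(...) stop(..., call. = FALSE)

assert_matrix <- function(x, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_mascsig(name, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_mascsig(name, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop_mascsig(name, " has duplicate gene identifiers: ",
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_mascsig(name, " has duplicate sample identifiers: ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x)))
    stop_mascsig(name, " contains non-finite values")
  invisible(x)
}

# nearest-rank upper percentile cutoff: smallest value v such that at least
# ceiling(p * n) of the sorted values are <= v
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p * length(s)))]
}
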