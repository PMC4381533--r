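#' Hypergeometric gene-list overlap
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between two gene lists drawn from an explicit universe. The
#' universe must be supplied: the significance of any overlap depends
#' entirely on it, so there is no default.
#'
#' @param list_a,list_b character vectors of gene identifiers, each a subset
#'   of `universe`.
#' @param universe character vector of all genes that could have appeared in
#'   either list.
#' @return a `gene_overlap`: tibble with `n_a`, `n_b`, `n_universe`,
#'   `n_overlap`, `expected_overlap`, `p_value`
#'   (P(X >= observed overlap)).
#' @examples
#' hypergeom_overlap(letters[1:4], letters[3:8], letters)
#' @export
hypergeom_overlap <- function(list_a, list_b, universe) {
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  universe <- unique(as.character(universe))
  off <- setdiff(c(list_a, list_b), universe)
  if (length(off))
    stop_mascsig("gene(s) outside the universe: ",
                 paste(sort(off), collapse = ", "))
  k <- length(intersect(list_a, list_b))
  n_u <- length(universe)
  p <- phyper(k - 1, length(list_a), n_u - length(list_a), length(list_b),
              lower.tail = FALSE)
  out <- tibble::tibble(n_a = length(list_a), n_b = length(list_b),
                        n_universe = n_u, n_overlap = k,
                        expected_overlap = length(list_a) * length(list_b) / n_u,
                        p_value = p)
  class(out) <- c("gene_overlap", class(out))
  out
}

#' Venn region counts for two or three gene sets
#'
#' @param lists named list of 2 or 3 character vectors.
#' @return tibble with `region` (e.g. `"A_only"`, `"A_B"`, `"A_B_C"`) and
#'   `count`; counts over all regions sum to the size of the union.
#' @export
venn_counts <- function(lists) {
  if (!is.list(lists) || length(lists) < 2 || length(lists) > 3)
    stop_mascsig("venn_counts takes 2 or 3 gene sets")
  lists <- lapply(lists, function(x) unique(as.character(x)))
  nm <- names(lists) %||% LETTERS[seq_along(lists)]
  if (is.null(names(lists)) || any(!nzchar(nm)))
    nm <- LETTERS[seq_along(lists)]
  u <- unique(unlist(lists))
  member <- vapply(lists, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(nm[row], collapse = "_"))
  regions <- unlist(lapply(seq_along(lists), function(k)
    combn(nm, k, paste, collapse = "_")))
  counts <- table(factor(pattern, levels = regions))
  suffix <- ifelse(grepl("_", regions), "", "_only")
  tibble::tibble(region = paste0(regions, suffix),
                 count = as.integer(counts))
}
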