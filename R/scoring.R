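#' Translate signature identifiers through a mapping table
#'
#' Converts signature genes from one identifier space to another (e.g. mouse
#' symbols to human Ensembl genes) through a user-supplied two-column table.
#' One-to-many mappings expand the signature; genes without a mapping are
#' dropped and counted in the provenance note.
#'
#' @param signature a `gene_signature` or character vector.
#' @param mapping data frame whose first two columns are source and target
#'   identifiers.
#' @return the mapped `gene_signature`; its `n_dropped` element records how
#'   many source genes had no mapping.
#' @export
map_signature_ids <- function(signature, mapping) {
  genes <- signature_genes(signature)
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("source", "target")
  mapping <- mapping[!is.na(mapping$target) & nzchar(mapping$target), ]
  hit <- mapping[mapping$source %in% genes, ]
  dropped <- sum(!genes %in% hit$source)
  out <- unique(hit$target[order(match(hit$source, genes))])
  if (length(out) == 0) stop_mascsig("no signature gene could be mapped")
  sig <- gene_signature(out, provenance = sprintf(
    "mapped from %d genes (%d unmapped, dropped)", length(genes), dropped))
  sig$n_dropped <- dropped
  sig
}

#' Median-centre a matrix by gene
#'
#' Subtracts each gene's median across samples, so relative expression is
#' comparable between genes with different baseline abundance.
#'
#' @param x expression matrix, genes x samples.
#' @return the centred matrix (every row median 0).
#' @export
median_centre <- function(x) {
  assert_matrix(x, "x")
  sweep(x, 1, apply(x, 1, median))
}

new_activation_scores <- function(scores, method, retained, dropped, params) {
  structure(list(scores = scores, method = method, retained = retained,
                 n_dropped = dropped, params = params),
            class = "activation_scores")
}

#' Signature activation by averaged relative expression
#'
#' The whole-signature score: median-centre the cohort matrix and average the
#' relative expression of the signature genes within each sample. Genes in
#' the signature but absent from the matrix are dropped with a warning.
#'
#' @param x log2 expression matrix, genes x samples.
#' @param signature a `gene_signature` or character vector of up-genes.
#' @return an `activation_scores` object; `tidy()` gives a tibble
#'   (sample_id, score).
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_tumours = 50, seed = 2))
#' sc <- average_score(cohort$matrix, cohort_design(seed = 2)$signature)
#' head(tidy(sc))
#' @export
average_score <- function(x, signature) {
  assert_matrix(x, "x")
  genes <- signature_genes(signature)
  present <- intersect(genes, rownames(x))
  if (length(present) == 0)
    stop_mascsig("no signature gene is present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature gene(s) absent from the matrix, dropped")
  mc <- median_centre(x)
  scores <- colMeans(mc[present, , drop = FALSE])
  new_activation_scores(scores, "average", present,
                        length(genes) - length(present),
                        list())
}

#' Signature activation by relevance-network score
#'
#' A denoising score in the spirit of relevance-network pathway-activity
#' methods: build the correlation graph over the signature genes in the
#' cohort, keep edges that are positively correlated above `r_min` and
#' significant at `alpha` (Bonferroni-corrected over candidate edges, since
#' all signature genes are up-genes a consistent gene must correlate
#' positively with the rest), retain the largest connected component, drop
#' genes anti-correlated with the component's mean profile, and score each
#' sample as the mean z-scored expression of the retained genes. If fewer
#' than 3 genes survive, the method falls back to [average_score()] with a
#' warning.
#'
#' @param x log2 expression matrix (>= 10 samples).
#' @param signature a `gene_signature` (>= 3 genes present required).
#' @param r_min correlation threshold for an edge (default 0.3).
#' @param alpha significance level for the correlation test, Bonferroni
#'   corrected over the candidate edges (default 0.05).
#' @return list with `scores` (an `activation_scores`) and `network` (a
#'   `relevance_network`: `nodes`, `edges` tibble with gene_a, gene_b, r,
#'   p_value, and `retained`).
#' @export
relevance_network_score <- function(x, signature, r_min = 0.3, alpha = 0.05) {
  assert_matrix(x, "x")
  if (ncol(x) < 10) stop_mascsig("need >= 10 samples")
  genes <- signature_genes(signature)
  present <- intersect(genes, rownames(x))
  if (length(present) < 3)
    stop_mascsig("fewer than 3 signature genes present in the matrix")
  sub <- x[present, , drop = FALSE]
  cm <- cor(t(sub))
  n <- ncol(x)
  p <- length(present)
  n_edges <- p * (p - 1) / 2
  # two-sided test of r = 0 via the t transform
  tstat <- cm * sqrt((n - 2) / pmax(1 - cm^2, 1e-12))
  pval <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  thr <- alpha / n_edges
  adj <- cm > r_min & pval < thr
  diag(adj) <- FALSE
  ut <- upper.tri(cm)
  idx <- which(ut & adj, arr.ind = TRUE)
  edges <- tibble::tibble(gene_a = present[idx[, 1]],
                          gene_b = present[idx[, 2]],
                          r = cm[cbind(idx[, 1], idx[, 2])],
                          p_value = pval[cbind(idx[, 1], idx[, 2])])
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = present)
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  retained <- present[comp$membership == main]
  if (length(retained) >= 3) {
    # denoise: drop genes anti-correlated with the component mean profile
    zc <- t(scale(t(sub[retained, , drop = FALSE])))
    repeat {
      centre <- colMeans(zc)
      r_to_centre <- as.numeric(cor(t(zc), centre))
      bad <- r_to_centre < 0
      if (!any(bad) || sum(!bad) < 3) break
      zc <- zc[!bad, , drop = FALSE]
    }
    retained <- rownames(zc)
  }
  network <- structure(list(nodes = present, edges = edges,
                            retained = retained,
                            r_min = r_min, alpha = alpha),
                       class = "relevance_network")
  if (length(retained) < 3) {
    warning("retained component has fewer than 3 genes; ",
            "falling back to the averaged score")
    sc <- average_score(x, signature)
    return(list(scores = sc, network = network))
  }
  z <- t(scale(t(sub[retained, , drop = FALSE])))
  scores <- colMeans(z)
  sc <- new_activation_scores(scores, "relevance_network", retained,
                              length(genes) - length(present),
                              list(r_min = r_min, alpha = alpha))
  list(scores = sc, network = network)
}

#' @export
print.relevance_network <- function(x, ...) {
  cat("Relevance network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (r >", x$r_min, ", Bonferroni alpha", x$alpha, ")\n")
  cat("retained component:", length(x$retained), "genes\n")
  invisible(x)
}

#' @export
print.activation_scores <- function(x, ...) {
  cat("Activation scores (", x$method, ") for ", length(x$scores),
      " samples, ", length(x$retained), " genes used",
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " dropped)"),
      "\n", sep = "")
  print(summary(unname(x$scores)))
  invisible(x)
}

#' @rdname average_score
#' @param x an `activation_scores` object.
#' @param ... unused.
#' @export
tidy.activation_scores <- function(x, ...) {
  tibble::tibble(sample_id = names(x$scores), score = unname(x$scores))
}

#' Split samples into high/low activation groups
#'
#' `top_tertile`: "high" is every sample whose score is at least the
#' 66.67th-percentile cutoff (nearest rank), so ties at the cutoff join the
#' high group. `median`: "high" is a score strictly above the median, ties
#' go low.
#'
#' @param scores an `activation_scores`, or a named numeric vector.
#' @param method `"top_tertile"` or `"median"`.
#' @return tibble (sample_id, score, group) with `group` a factor
#'   low < high.
#' @export
dichotomise <- function(scores, method = c("top_tertile", "median")) {
  method <- match.arg(method)
  s <- if (inherits(scores, "activation_scores")) scores$scores else scores
  if (is.null(names(s))) names(s) <- paste0("s", seq_along(s))
  if (length(unique(s)) < 2)
    stop_mascsig("all scores identical; no split possible")
  if (method == "top_tertile") {
    if (length(s) < 3) stop_mascsig("top_tertile needs >= 3 samples")
    cutoff <- nearest_rank(s, 0.6667)
    high <- s >= cutoff
  } else {
    if (length(s) < 2) stop_mascsig("median split needs >= 2 samples")
    high <- s > median(s)
  }
  tibble::tibble(sample_id = names(s), score = unname(s),
                 group = factor(ifelse(high, "high", "low"),
                                levels = c("low", "high")))
}
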