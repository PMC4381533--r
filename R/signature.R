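#' Gene signatures
#'
#' A gene signature is an ordered set of gene identifiers, each with a
#' direction (+1 throughout this package: all signature genes are up-genes in
#' the population of interest), plus a provenance note.
#'
#' @param genes character vector of unique gene identifiers.
#' @param direction +1/-1 per gene (recycled).
#' @param provenance free-text note on how the signature was obtained.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(genes, direction = 1, provenance = "") {
  genes <- as.character(genes)
  if (length(genes) == 0) {
    warning("empty gene signature")
  }
  if (anyDuplicated(genes))
    stop_mascsig("signature gene identifiers must be unique")
  structure(list(genes = genes,
                 direction = rep_len(direction, length(genes)),
                 provenance = provenance),
            class = "gene_signature")
}

#' @rdname gene_signature
#' @param x a `gene_signature` or plain character vector.
#' @export
signature_genes <- function(x) {
  if (inherits(x, "gene_signature")) x$genes else as.character(x)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", length(x$genes), "genes")
  if (nzchar(x$provenance)) cat(" (", x$provenance, ")", sep = "")
  cat("\n")
  if (length(x$genes)) cat(" ", paste(head(x$genes, 8), collapse = ", "),
                           if (length(x$genes) > 8) "...", "\n")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

#' Collapse probesets to genes
#'
#' Removes probesets mapping to no gene or to more than one gene, relabels
#' the survivors by gene symbol and, where several probesets map to the same
#' gene, keeps the probeset with the highest mean expression.
#'
#' @param x expression matrix with probeset rownames.
#' @param mapping data frame whose first two columns are probeset identifier
#'   and gene identifier; a probeset absent from the table, or present with
#'   an empty/NA gene, counts as unmapped; a probeset listed with several
#'   distinct genes is multi-mapped. Both are removed.
#' @return the filtered matrix, rows named by gene.
#' @export
filter_probesets <- function(x, mapping) {
  assert_matrix(x, "x")
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("probeset", "gene")
  mapping <- mapping[!is.na(mapping$gene) & nzchar(mapping$gene), ]
  mapping <- unique(mapping)
  genes_per_probe <- table(mapping$probeset)
  unique_map <- mapping[mapping$probeset %in%
                          names(genes_per_probe)[genes_per_probe == 1], ]
  keep <- rownames(x) %in% unique_map$probeset
  if (!any(keep))
    stop_mascsig("no probesets survive filtering: every row is unmapped ",
                 "or maps to multiple genes")
  x <- x[keep, , drop = FALSE]
  gene <- unique_map$gene[match(rownames(x), unique_map$probeset)]
  # collapse duplicates per gene: highest mean expression wins
  means <- rowMeans(x)
  ord <- order(gene, -means)
  x <- x[ord, , drop = FALSE]
  gene <- gene[ord]
  x <- x[!duplicated(gene), , drop = FALSE]
  rownames(x) <- gene[!duplicated(gene)]
  x[order(rownames(x)), , drop = FALSE]
}

#' Derive an up-gene signature from multiple two-class comparisons
#'
#' Runs a two-class SAM of the target population against each reference
#' population and keeps the genes significantly upregulated in the target in
#' every comparison: direction up, local FDR below `fdr_max` and linear fold
#' change at least `fc_min` (the defaults reproduce the FDR < 5% /
#' 1.5-fold derivation gates). Basal-shared genes — elevated in the target
#' and one reference alike — fail the comparison against that reference and
#' are thereby excluded, which is the point of intersecting all comparisons.
#'
#' @param x log2 expression matrix over all populations.
#' @param groups population label per column.
#' @param target population whose up-genes define the signature.
#' @param references character vector of populations to compare against
#'   (default: all non-target populations).
#' @param fdr_max local-FDR gate (default 0.05).
#' @param fc_min linear fold-change gate (default 1.5).
#' @inheritParams sam_two_class
#' @return a `gene_signature` with a `stats` element: one row per retained
#'   gene and comparison (gene, comparison, d, fold_change, q_global,
#'   fdr_local), and a `sam` element with the full `sam_result` per
#'   comparison.
#' @examples
#' sim <- simulate_populations(population_design(n_genes = 300, seed = 3))
#' sig <- derive_signature(sim$matrix, sim$samples$population)
#' length(sig)
#' @export
derive_signature <- function(x, groups, target = "MaSC",
                             references = setdiff(unique(groups), target),
                             fdr_max = 0.05, fc_min = 1.5,
                             n_perm = 1000, seed = 1L, window_frac = 0.025) {
  assert_matrix(x, "x")
  groups <- as.character(groups)
  if (!target %in% groups) stop_mascsig("target population not in groups")
  sams <- lapply(references, function(ref) {
    keep <- groups %in% c(target, ref)
    sam_two_class(x[, keep, drop = FALSE],
                  factor(groups[keep], levels = c(ref, target)),
                  n_perm = n_perm, seed = seed, window_frac = window_frac)
  })
  names(sams) <- references
  hits <- lapply(sams, function(s) {
    t <- s$table
    t$gene[t$direction > 0 & t$fdr_local < fdr_max & t$fold_change >= fc_min]
  })
  genes <- sort(Reduce(intersect, hits))
  if (length(genes) == 0)
    warning("no genes pass every comparison; returning an empty signature")
  stats <- purrr::map_dfr(names(sams), function(ref) {
    t <- sams[[ref]]$table
    dplyr::mutate(t[t$gene %in% genes, ], comparison = sams[[ref]]$comparison,
                  .before = 1)
  })
  sig <- gene_signature(genes,
                        provenance = sprintf(
                          "up in %s vs {%s}; local FDR < %g, FC >= %g",
                          target, paste(references, collapse = ", "),
                          fdr_max, fc_min))
  sig$stats <- stats
  sig$sam <- sams
  sig
}

#' Refine a signature to its most strongly enriched genes
#'
#' Keeps the signature genes whose fold change exceeds `fc_min` and whose
#' local FDR is below `fdr_max` in *both* supplied comparisons — typically
#' target vs myoepithelial and target vs the pooled luminal populations
#' (the 2.5-fold "top signature" refinement).
#'
#' @param signature a `gene_signature`.
#' @param sam_a,sam_b `sam_result` objects (or data frames with columns
#'   `gene`, `fold_change`, `fdr_local`) for the two comparisons.
#' @param fc_min linear fold-change floor (default 2.5; strict inequality).
#' @param fdr_max local-FDR gate (default 0.05).
#' @return the refined `gene_signature`.
#' @export
refine_top_signature <- function(signature, sam_a, sam_b,
                                 fc_min = 2.5, fdr_max = 0.05) {
  genes <- signature_genes(signature)
  pass <- function(s) {
    t <- if (inherits(s, "sam_result")) s$table else tibble::as_tibble(s)
    stopifnot(all(c("gene", "fold_change", "fdr_local") %in% names(t)))
    t$gene[t$fold_change > fc_min & t$fdr_local < fdr_max]
  }
  keep <- intersect(genes, intersect(pass(sam_a), pass(sam_b)))
  gene_signature(genes[genes %in% keep],
                 provenance = sprintf("top signature: FC > %g, FDR < %g in both comparisons",
                                      fc_min, fdr_max))
}

#' Hierarchical clustering of samples by correlation
#'
#' Average-linkage agglomeration on the distance `1 - Pearson r` between
#' sample expression profiles.
#'
#' @param x expression matrix, genes x samples (>= 2 samples).
#' @return a list of class `expr_hclust` with `hclust` (the tree), `order`
#'   (leaf sample identifiers) and `cophenetic` (dist object).
#' @export
hierarchical_cluster <- function(x) {
  assert_matrix(x, "x")
  if (ncol(x) < 2) stop_mascsig("need >= 2 samples to cluster")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop_mascsig("constant expression profile (correlation undefined) in ",
                 "sample(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(x))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, order = colnames(x)[hc$order],
                 cophenetic = cophenetic(hc)),
            class = "expr_hclust")
}

#' @export
print.expr_hclust <- function(x, ...) {
  cat("Average-linkage clustering (1 - Pearson) of",
      length(x$order), "samples\n")
  cat("leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}
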