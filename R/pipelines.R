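pipeline_provenance <- function(seed, params) {
  c(list(package = "mascsig",
         version = as.character(utils::packageVersion("mascsig")),
         seed = seed),
    params)
}

#' Signature-derivation pipeline
#'
#' Runs the full derivation chain: optional probeset filtering, a two-class
#' SAM of the target population against every reference, intersection of the
#' significant up-genes (local FDR and fold-change gates), and the
#' fold-change refinement against the contrast population and the pooled
#' remaining populations. When `out_dir` is given, the signatures and
#' per-comparison SAM tables are written with provenance headers.
#'
#' @param x log2 expression matrix (or a path to one).
#' @param groups population label per sample.
#' @param mapping optional probeset-to-gene table for [filter_probesets()].
#' @param target population defining the signature (default `"MaSC"`).
#' @param contrast the single population used (with the pooled remainder) in
#'   the top-signature refinement (default `"MYO"`).
#' @param fdr_max,fc_min derivation gates (defaults 0.05 and 1.5).
#' @param fc_top refinement fold-change floor (default 2.5).
#' @inheritParams sam_two_class
#' @param out_dir optional output directory.
#' @return list with `signature`, `top_signature`, `sam` (per-comparison
#'   results), `sam_combined` (target vs contrast and vs pooled remainder)
#'   and per-stage `counts`.
#' @export
pipeline_derive <- function(x, groups, mapping = NULL,
                            target = "MaSC", contrast = "MYO",
                            fdr_max = 0.05, fc_min = 1.5, fc_top = 2.5,
                            n_perm = 1000, seed = 1L, window_frac = 0.025,
                            out_dir = NULL) {
  if (is.character(x) && length(x) == 1) x <- read_expression_matrix(x)
  assert_matrix(x, "x")
  groups <- as.character(groups)
  counts <- list(genes_in = nrow(x), samples = ncol(x))
  if (!is.null(mapping)) {
    x <- filter_probesets(x, mapping)
    counts$genes_after_probeset_filter <- nrow(x)
  }
  refs <- setdiff(unique(groups), target)
  sig <- derive_signature(x, groups, target = target, references = refs,
                          fdr_max = fdr_max, fc_min = fc_min,
                          n_perm = n_perm, seed = seed, window_frac = window_frac)
  counts$signature <- length(sig)

  sam_a <- sig$sam[[contrast]]
  keep_b <- groups != contrast
  sam_b <- sam_two_class(
    x[, keep_b, drop = FALSE],
    factor(ifelse(groups[keep_b] == target, target, "pooled_rest"),
           levels = c("pooled_rest", target)),
    n_perm = n_perm, seed = seed, window_frac = window_frac)
  top <- refine_top_signature(sig, sam_a, sam_b, fc_min = fc_top,
                              fdr_max = fdr_max)
  counts$top_signature <- length(top)
  message("pipeline_derive: ", counts$genes_in, " genes in, ",
          counts$signature, " in signature, ", counts$top_signature,
          " in top signature")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- pipeline_provenance(seed, list(fdr_max = fdr_max,
                                           fc_min = fc_min, fc_top = fc_top,
                                           n_perm = n_perm, target = target))
    write_signature(sig, file.path(out_dir, "signature.txt"),
                    provenance = prov)
    write_signature(top, file.path(out_dir, "top_signature.txt"),
                    provenance = prov)
    for (ref in names(sig$sam))
      utils::write.table(sig$sam[[ref]]$table,
                         file.path(out_dir, paste0("sam_", ref, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(signature = sig, top_signature = top, sam = sig$sam,
       sam_combined = list(contrast = sam_a, pooled_rest = sam_b),
       counts = counts)
}

#' Prognosis pipeline
#'
#' Scores signature activation in a tumour cohort, dichotomises, and runs
#' the Kaplan-Meier / log-rank / Cox stratification plus (optionally) the
#' expression-matched random-gene-list null.
#'
#' @param x cohort log2 expression matrix (or a path).
#' @param signature a `gene_signature`, character vector, or path to a
#'   signature file.
#' @param surv survival table (`sample_id`, `time`, `event`) or a path.
#' @param mapping optional identifier mapping applied to the signature
#'   first (see [map_signature_ids()]).
#' @param scoring `"average"` or `"relevance_network"`.
#' @param dichotomy `"top_tertile"` or `"median"`.
#' @param n_lists random lists for the matched null; 0 skips it.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return list with `scores`, `groups`, `km`, `logrank`, `cox`, `null`
#'   (or `NULL`) and `network` (relevance-network scoring only).
#' @export
pipeline_prognose <- function(x, signature, surv, mapping = NULL,
                              scoring = c("average", "relevance_network"),
                              dichotomy = c("top_tertile", "median"),
                              n_lists = 1000, seed = 1L, out_dir = NULL) {
  scoring <- match.arg(scoring)
  dichotomy <- match.arg(dichotomy)
  if (is.character(x) && length(x) == 1) x <- read_expression_matrix(x)
  if (is.character(signature) && length(signature) == 1 &&
      file.exists(signature)) signature <- read_signature(signature)
  if (is.character(surv) && length(surv) == 1) surv <- read_survival_table(surv)
  surv <- tibble::as_tibble(surv)
  if (!is.null(mapping)) signature <- map_signature_ids(signature, mapping)

  network <- NULL
  if (scoring == "average") {
    scores <- average_score(x, signature)
  } else {
    rn <- relevance_network_score(x, signature)
    scores <- rn$scores
    network <- rn$network
  }
  groups <- dichotomise(scores, method = dichotomy)
  tab <- dplyr::inner_join(surv, groups, by = "sample_id")
  message("pipeline_prognose: ", nrow(tab), " samples scored (",
          sum(tab$group == "high"), " high)")
  km <- km_estimate(tab)
  lr <- logrank_test(tab)
  cox <- cox_univariate(tab)
  null <- if (n_lists > 0)
    matched_random_signature_null(x, signature, surv, n_lists = n_lists,
                                  method = dichotomy, seed = seed)
  else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- pipeline_provenance(seed, list(scoring = scoring,
                                           dichotomy = dichotomy,
                                           n_lists = n_lists))
    utils::write.csv(groups, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(km$curves, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(provenance_header(prov),
                 sprintf("logrank_chisq=%.6g", lr$statistic),
                 sprintf("logrank_p=%.6g", lr$p_value),
                 sprintf("cox_hr=%.6g", cox$hr),
                 sprintf("cox_ci=%.6g,%.6g", cox$ci[1], cox$ci[2]),
                 if (!is.null(null))
                   sprintf("matched_null_p=%.6g", null$empirical_p)),
               file.path(out_dir, "stratification.txt"))
  }
  list(scores = scores, groups = groups, km = km, logrank = lr, cox = cox,
       null = null, network = network)
}
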