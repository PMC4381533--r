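#' Design for a purified-population microarray experiment
#'
#' Describes a synthetic genes x samples log2 expression experiment over the
#' four mammary epithelial populations (MaSC, MYO, luminal ER-, luminal ER+)
#' with planted gene classes. The default replicate counts (7, 3, 3, 3)
#' reflect the sorted-population design this generator emulates: seven
#' independent stem-cell isolations against three of each differentiated
#' population. Planted classes:
#' \describe{
#'   \item{masc_up}{elevated in MaSC only — the recoverable signature.}
#'   \item{basal_shared}{elevated in both MaSC and MYO — decoys that a
#'     correct intersection procedure must exclude.}
#'   \item{luminal_up}{elevated in both luminal populations.}
#'   \item{null}{no planted effect.}
#' }
#'
#' @param n_genes total number of genes.
#' @param replicates named integer vector of per-population array counts,
#'   names `MaSC`, `MYO`, `LumERneg`, `LumERpos`; each must be >= 2.
#' @param n_masc_up,n_basal_shared,n_luminal_up counts of planted genes per
#'   class; the remainder are null.
#' @param effect log2 fold-change added to the elevated populations for every
#'   planted gene (default 2, i.e. 4-fold).
#' @param noise_sd scale of the per-gene replicate standard deviation on the
#'   log2 scale. Per-gene variances are drawn from a scaled inverse
#'   chi-square with `var_df` degrees of freedom so genes differ in
#'   dispersion, as real arrays do. `noise_sd = 0` gives noise-free data.
#' @param var_df degrees of freedom of the variance heterogeneity model.
#' @param seed integer seed.
#' @return an object of class `population_design`.
#' @seealso [simulate_populations()]
#' @export
population_design <- function(n_genes = 1000,
                              replicates = c(MaSC = 7, MYO = 3,
                                             LumERneg = 3, LumERpos = 3),
                              n_masc_up = 100,
                              n_basal_shared = 100,
                              n_luminal_up = 100,
                              effect = 2,
                              noise_sd = 0.35,
                              var_df = 20,
                              seed = 1L) {
  pops <- c("MaSC", "MYO", "LumERneg", "LumERpos")
  if (!all(pops %in% names(replicates)))
    stop_mascsig("replicates must be named ", paste(pops, collapse = ", "))
  replicates <- replicates[pops]
  if (any(replicates < 2))
    stop_mascsig("each population needs >= 2 replicates")
  planted <- n_masc_up + n_basal_shared + n_luminal_up
  if (planted > n_genes)
    stop_mascsig("planted class counts (", planted,
                 ") exceed n_genes (", n_genes, ")")
  if (effect < 0) stop_mascsig("effect must be >= 0")
  if (noise_sd < 0) stop_mascsig("noise_sd must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes), replicates = replicates,
         n_masc_up = as.integer(n_masc_up),
         n_basal_shared = as.integer(n_basal_shared),
         n_luminal_up = as.integer(n_luminal_up),
         effect = effect, noise_sd = noise_sd, var_df = var_df,
         seed = as.integer(seed)),
    class = "population_design")
}

# per-gene SDs under the scaled inverse chi-square heterogeneity model
draw_gene_sd <- function(n, scale, df) {
  if (scale == 0) return(rep(0, n))
  sqrt(scale^2 * df / rchisq(n, df = df))
}

#' Simulate a purified-population expression experiment
#'
#' Generates a log2 expression matrix with the planted structure described by
#' the design, plus the population label of every sample and a truth table
#' recording each gene's planted class. Planted effects are additive on the
#' log2 scale, so a `masc_up` gene's expected MaSC-minus-other difference
#' equals `design$effect` exactly.
#'
#' @param design a [population_design()].
#' @return a list with elements `matrix` (genes x samples, log2),
#'   `samples` (tibble: sample_id, population) and `truth`
#'   (tibble: gene_id, class).
#' @examples
#' sim <- simulate_populations(population_design(n_genes = 200, seed = 42))
#' table(sim$truth$class)
#' @export
simulate_populations <- function(design) {
  stopifnot(inherits(design, "population_design"))
  set.seed(design$seed)
  reps <- design$replicates
  population <- rep(names(reps), reps)
  sample_id <- paste0(population, "_", unlist(lapply(reps, seq_len)))
  n <- design$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  class <- rep("null", n)
  idx <- 0L
  for (cl in c("masc_up", "basal_shared", "luminal_up")) {
    k <- design[[paste0("n_", cl)]]
    if (k > 0) class[idx + seq_len(k)] <- cl
    idx <- idx + k
  }
  baseline <- runif(n, 4, 10)
  sds <- draw_gene_sd(n, design$noise_sd, design$var_df)
  mu <- matrix(baseline, n, length(population))
  up <- list(masc_up = "MaSC",
             basal_shared = c("MaSC", "MYO"),
             luminal_up = c("LumERneg", "LumERpos"))
  for (cl in names(up)) {
    g <- class == cl
    s <- population %in% up[[cl]]
    mu[g, s] <- mu[g, s] + design$effect
  }
  mat <- mu + matrix(rnorm(n * length(population)), n) * sds
  dimnames(mat) <- list(gene_id, sample_id)
  list(matrix = mat,
       samples = tibble::tibble(sample_id = sample_id, population = population),
       truth = tibble::tibble(gene_id = gene_id, class = class))
}

#' Design for a synthetic tumour cohort with a latent signature activation
#'
#' Each tumour carries a latent activation `A ~ N(0, 1)`. Signature genes
#' load on `A` (expression = baseline + loading * A + noise); background
#' genes are independent noise with matched baselines, giving the
#' expression-matched gene universe the random-list null requires. Event
#' times follow a proportional-hazards model with hazard
#' `h0 * exp(beta * A)` and independent exponential censoring.
#'
#' @param n_tumours cohort size (>= 20).
#' @param signature character vector of signature gene identifiers (all
#'   up-genes), or a [gene_signature()].
#' @param beta log-hazard per unit activation.
#' @param baseline_hazard exponential baseline event rate per month (> 0).
#' @param weibull_shape shape of an optional Weibull baseline; 1 (default)
#'   is the exponential.
#' @param censoring_rate rate of the independent exponential censoring
#'   process; 0 means no censoring.
#' @param loading per-gene coefficient on the latent activation (recycled
#'   across signature genes).
#' @param noise_sd residual SD of expression around the latent structure.
#' @param n_background number of non-signature genes (default ten per
#'   signature gene).
#' @param seed integer seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_tumours = 500,
                          signature = paste0("sig", sprintf("%03d", 1:50)),
                          beta = log(2),
                          baseline_hazard = 0.02,
                          weibull_shape = 1,
                          censoring_rate = 0.01,
                          loading = 1,
                          noise_sd = 0.5,
                          n_background = 10 * length(signature_genes(signature)),
                          seed = 1L) {
  sig <- signature_genes(signature)
  if (n_tumours < 20) stop_mascsig("n_tumours must be >= 20")
  if (baseline_hazard <= 0) stop_mascsig("baseline_hazard must be > 0")
  if (weibull_shape <= 0) stop_mascsig("weibull_shape must be > 0")
  if (censoring_rate < 0) stop_mascsig("censoring_rate must be >= 0")
  loading <- rep_len(loading, length(sig))
  if (!all(is.finite(loading))) stop_mascsig("loadings must be finite")
  structure(
    list(n_tumours = as.integer(n_tumours), signature = sig, beta = beta,
         baseline_hazard = baseline_hazard, weibull_shape = weibull_shape,
         censoring_rate = censoring_rate, loading = loading,
         noise_sd = noise_sd, n_background = as.integer(n_background),
         seed = as.integer(seed)),
    class = "cohort_design")
}

#' Simulate a tumour cohort with survival linked to signature activation
#'
#' @param design a [cohort_design()].
#' @return a list with `matrix` (genes x tumours, log2; signature genes plus
#'   background genes), `survival` (tibble: sample_id, time, event) and
#'   `activation` (tibble: sample_id, activation — the latent truth).
#' @examples
#' cohort <- simulate_cohort(cohort_design(n_tumours = 100, seed = 7))
#' head(cohort$survival)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n <- design$n_tumours
  sig <- design$signature
  sample_id <- sprintf("T%04d", seq_len(n))
  activation <- rnorm(n)

  bg_id <- sprintf("bg%05d", seq_len(design$n_background))
  n_genes <- length(sig) + design$n_background
  baseline <- runif(n_genes, 4, 10)
  expr <- matrix(rnorm(n_genes * n, sd = design$noise_sd), n_genes, n)
  expr[seq_along(sig), ] <- expr[seq_along(sig), ] +
    design$loading %o% activation
  expr <- expr + baseline
  dimnames(expr) <- list(c(sig, bg_id), sample_id)

  rate <- design$baseline_hazard * exp(design$beta * activation)
  # inverse-transform Weibull with PH hazard h(t) = h0 * k * t^(k-1) * exp(bA)
  u <- runif(n)
  event_time <- (-log(u) / rate)^(1 / design$weibull_shape)
  cens_time <- if (design$censoring_rate > 0)
    rexp(n, design$censoring_rate) else rep(Inf, n)
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)

  list(matrix = expr,
       survival = tibble::tibble(sample_id = sample_id, time = time,
                                 event = event),
       activation = tibble::tibble(sample_id = sample_id,
                                   activation = activation))
}

#' Design for a synthetic single-cell RT-qPCR panel
#'
#' Emulates a plate of single cells assayed by qPCR for a gene panel, with
#' per-gene mean cycle threshold (Ct), replicate SD and detection dropout,
#' plus exogenous spike transcripts of known copy number in every cell. The
#' default spike copies (8400, 900, 90) are the serial tenfold dilution used
#' to verify amplification linearity; at 100% PCR efficiency the Ct-per-decade
#' slope is log2(10) = 3.3219 cycles.
#'
#' @param n_cells number of cells.
#' @param genes character vector of panel gene names.
#' @param mean_ct,sd_ct per-gene mean and SD of detected Ct values
#'   (recycled).
#' @param dropout per-gene probability a cell fails to detect the gene
#'   (recycled; in \[0, 1\]).
#' @param spike_copies named numeric vector of molecule counts per spike
#'   transcript.
#' @param spike_intercept Ct of a single molecule.
#' @param slope cycles per tenfold dilution (default 100% efficiency).
#' @param spike_sd replicate SD of spike Cts.
#' @param seed integer seed.
#' @return an object of class `single_cell_design`.
#' @export
single_cell_design <- function(n_cells = 32,
                               genes = paste0("gene", sprintf("%02d", 1:12)),
                               mean_ct = 25,
                               sd_ct = 2,
                               dropout = 0.1,
                               spike_copies = c(LTP4 = 8400, LTP6 = 900,
                                                TIM = 90),
                               spike_intercept = 38,
                               slope = log2(10),
                               spike_sd = 0.2,
                               seed = 1L) {
  mean_ct <- rep_len(mean_ct, length(genes))
  sd_ct <- rep_len(sd_ct, length(genes))
  dropout <- rep_len(dropout, length(genes))
  if (any(dropout < 0 | dropout > 1))
    stop_mascsig("dropout probabilities must lie in [0, 1]")
  if (any(spike_copies <= 0)) stop_mascsig("spike copies must be > 0")
  if (any(mean_ct < 10 | mean_ct > 40))
    stop_mascsig("mean Ct values must lie in [10, 40]")
  structure(
    list(n_cells = as.integer(n_cells), genes = genes,
         mean_ct = mean_ct, sd_ct = sd_ct, dropout = dropout,
         spike_copies = spike_copies, spike_intercept = spike_intercept,
         slope = slope, spike_sd = spike_sd, seed = as.integer(seed)),
    class = "single_cell_design")
}

#' Simulate a single-cell qPCR panel
#'
#' Detected Cts are Gaussian around the per-gene mean, clamped to \[10, 40\];
#' dropouts are recorded as undetected (`NA` internally, serialised as
#' `"ND"`). Spike Cts follow the calibration line
#' `Ct = intercept - slope * log10(copies)` plus noise.
#'
#' @param design a [single_cell_design()].
#' @return a `single_cell_panel`: list with `ct` (cells x genes matrix, `NA`
#'   = undetected), `spike_ct` (cells x spikes matrix) and `spikes`
#'   (tibble: transcript, copies).
#' @export
simulate_single_cells <- function(design) {
  stopifnot(inherits(design, "single_cell_design"))
  set.seed(design$seed)
  n <- design$n_cells
  g <- length(design$genes)
  cells <- sprintf("cell%02d", seq_len(n))
  ct <- matrix(rnorm(n * g), n, g, byrow = FALSE)
  ct <- sweep(ct, 2, design$sd_ct, `*`)
  ct <- sweep(ct, 2, design$mean_ct, `+`)
  ct <- pmin(pmax(ct, 10), 40)
  drop <- matrix(runif(n * g), n, g) <
    matrix(design$dropout, n, g, byrow = TRUE)
  ct[drop] <- NA_real_
  dimnames(ct) <- list(cells, design$genes)

  sp <- design$spike_copies
  ideal <- design$spike_intercept - design$slope * log10(sp)
  spike_ct <- matrix(rep(ideal, each = n), n, length(sp)) +
    matrix(rnorm(n * length(sp), sd = design$spike_sd), n)
  dimnames(spike_ct) <- list(cells, names(sp))

  structure(
    list(ct = ct, spike_ct = spike_ct,
         spikes = tibble::tibble(transcript = names(sp),
                                 copies = unname(sp)),
         seed = design$seed),
    class = "single_cell_panel")
}

#' @export
print.single_cell_panel <- function(x, ...) {
  cat("Single-cell qPCR panel: ", nrow(x$ct), " cells x ", ncol(x$ct),
      " genes; spikes: ",
      paste0(x$spikes$transcript, " (", x$spikes$copies, " copies)",
             collapse = ", "), "\n", sep = "")
  cat(sum(is.na(x$ct)), "undetected wells\n")
  invisible(x)
}
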