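test_that("the derivation pipeline chains filtering, SAM and refinement and writes artefacts", {
  des <- population_design(n_genes = 250, n_masc_up = 25, n_basal_shared = 25,
                           n_luminal_up = 25, seed = 14)
  sim <- simulate_populations(des)
  out_dir <- withr::local_tempdir()
  res <- suppressMessages(
    pipeline_derive(sim$matrix, sim$samples$population, out_dir = out_dir))
  expect_s3_class(res$signature, "gene_signature")
  expect_lte(length(res$top_signature), length(res$signature))
  expect_identical(res$counts$genes_in, 250L)
  expect_true(file.exists(file.path(out_dir, "signature.txt")))
  expect_true(file.exists(file.path(out_dir, "top_signature.txt")))
  expect_true(file.exists(file.path(out_dir, "sam_MYO.tsv")))
  written <- read_signature(file.path(out_dir, "signature.txt"))
  expect_identical(signature_genes(written), signature_genes(res$signature))
  # provenance header is machine-parseable key=value
  hdr <- readLines(file.path(out_dir, "signature.txt"))
  expect_match(hdr[1], "^# package=mascsig$")
  expect_true(any(grepl("^# seed=1$", hdr)))
})

test_that("the prognosis pipeline stratifies a cohort end to end", {
  des <- cohort_design(n_tumours = 150, seed = 27)
  co <- simulate_cohort(des)
  out_dir <- withr::local_tempdir()
  res <- suppressMessages(
    pipeline_prognose(co$matrix, des$signature, co$survival,
                      n_lists = 40, seed = 5, out_dir = out_dir))
  expect_s3_class(res$scores, "activation_scores")
  expect_identical(levels(res$groups$group), c("low", "high"))
  expect_s3_class(res$km, "km_fit")
  expect_true(res$logrank$p_value >= 0 && res$logrank$p_value <= 1)
  expect_s3_class(res$cox, "cox_fit")
  expect_s3_class(res$null, "matched_null")
  strat <- readLines(file.path(out_dir, "stratification.txt"))
  expect_true(any(grepl("^cox_hr=", strat)))
  expect_true(any(grepl("^matched_null_p=", strat)))
  expect_true(file.exists(file.path(out_dir, "scores.csv")))
  # a planted cohort at the default effect should stratify clearly
  expect_gt(res$cox$hr, 1)
})

test_that("the prognosis pipeline accepts file paths and identifier mappings", {
  des <- cohort_design(n_tumours = 100, seed = 8)
  co <- simulate_cohort(des)
  dir <- withr::local_tempdir()
  mat_path <- file.path(dir, "expr.tsv")
  surv_path <- file.path(dir, "surv.csv")
  sig_path <- file.path(dir, "sig.txt")
  write_expression_matrix(co$matrix, mat_path)
  write_survival_table(co$survival, surv_path)
  # the signature arrives in a foreign identifier space and is mapped back
  write_signature(paste0("m_", des$signature), sig_path)
  mapping <- data.frame(src = paste0("m_", des$signature),
                        dst = des$signature)
  res <- suppressMessages(
    pipeline_prognose(mat_path, sig_path, surv_path, mapping = mapping,
                      n_lists = 0, seed = 1))
  expect_null(res$null)
  direct <- suppressMessages(
    pipeline_prognose(co$matrix, des$signature, co$survival,
                      n_lists = 0, seed = 1))
  expect_equal(res$scores$scores, direct$scores$scores)
})
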