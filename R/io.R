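# File dialects: UTF-8, LF, '.' decimal. '#'-prefixed header lines carry
# machine-parseable key=value provenance and are skipped on read.

provenance_header <- function(provenance) {
  if (is.null(provenance) || !length(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", unname(unlist(provenance)))
}

read_table_checked <- function(path, sep, what) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  offset <- which(!is_comment)[1]
  body <- lines[!is_comment]
  if (length(body) < 2)
    stop_mascsig(what, " file ", path, " has no data rows")
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  attr(df, "first_data_line") <- offset
  df
}

#' Read and write expression matrices
#'
#' TSV dialect: optional `#`-prefixed provenance lines, then a header row of
#' sample identifiers; the first column (named `gene`) holds gene
#' identifiers. Values are log2 expression. Duplicate identifiers and
#' non-numeric cells are reported with line numbers.
#'
#' @param path file path.
#' @return [read_expression_matrix()]: a genes x samples numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- read_table_checked(path, sep = "\t", what = "expression matrix")
  offset <- attr(df, "first_data_line")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    i <- which(duplicated(ids))[1]
    stop_mascsig("duplicate gene identifier '", ids[i], "' at line ",
                 offset + i)
  }
  if (anyDuplicated(names(df)[-1]))
    stop_mascsig("duplicate sample identifier '",
                 names(df)[-1][duplicated(names(df)[-1])][1],
                 "' in header (line ", offset, ")")
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop_mascsig("non-numeric cell '", vals[[j]][i], "' in column '",
                   names(vals)[j], "' at line ", offset + i)
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  assert_matrix(m, "matrix")
}

#' @rdname read_expression_matrix
#' @param x genes x samples numeric matrix.
#' @param provenance named list/vector written as `# key=value` lines.
#' @export
write_expression_matrix <- function(x, path, provenance = NULL) {
  assert_matrix(x, "x")
  lines <- c(provenance_header(provenance),
             paste(c("gene", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i],
                       format(x[i, ], digits = 15, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write survival tables
#'
#' CSV with columns `sample_id`, `time`, `event` and optionally `subtype`
#' and/or `group`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_survival_table <- function(path) {
  df <- read_table_checked(path, sep = ",", what = "survival table")
  offset <- attr(df, "first_data_line")
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_mascsig("survival table lacks column(s): ",
                 paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    i <- which(duplicated(df$sample_id))[1]
    stop_mascsig("duplicate sample_id '", df$sample_id[i], "' at line ",
                 offset + i)
  }
  attr(df, "first_data_line") <- NULL
  tibble::as_tibble(df)
}

#' @rdname read_survival_table
#' @param table data frame with the survival columns.
#' @inheritParams write_expression_matrix
#' @export
write_survival_table <- function(table, path, provenance = NULL) {
  hdr <- provenance_header(provenance)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gene signatures
#'
#' Plain format: one gene identifier per line (with optional `#` provenance
#' lines). GMT format: tab-separated `name`, `description`, then genes — one
#' signature per line.
#'
#' @param path file path.
#' @param format `"plain"` or `"gmt"`.
#' @return a `gene_signature` (the first record, for GMT files with one
#'   line) .
#' @export
read_signature <- function(path, format = c("plain", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (format == "plain") return(gene_signature(lines))
  fields <- strsplit(lines[1], "\t")[[1]]
  gene_signature(fields[-(1:2)], provenance = fields[2])
}

#' @rdname read_signature
#' @param signature a `gene_signature` or character vector.
#' @param name signature name used in GMT output.
#' @inheritParams write_expression_matrix
#' @export
write_signature <- function(signature, path, format = c("plain", "gmt"),
                            name = "signature", provenance = NULL) {
  format <- match.arg(format)
  genes <- signature_genes(signature)
  if (format == "plain") {
    writeLines(c(provenance_header(provenance), genes), path)
  } else {
    desc <- if (inherits(signature, "gene_signature") &&
                nzchar(signature$provenance)) signature$provenance else "na"
    writeLines(paste(c(name, desc, genes), collapse = "\t"), path)
  }
  invisible(path)
}

#' Read a centroid table
#'
#' TSV: first column `gene`, one column per subtype.
#'
#' @param path file path.
#' @return genes x subtypes numeric matrix.
#' @export
read_centroids <- function(path) read_expression_matrix(path)

#' Read and write single-cell Ct panels
#'
#' TSV with cells as rows and genes as columns; spike transcripts appear as
#' extra columns named `spike:<transcript>:<copies>` (spikes are measured in
#' every cell's reaction, so they live alongside the genes). Undetected
#' wells are serialised as `ND`.
#'
#' @param path file path.
#' @return a `single_cell_panel`.
#' @export
read_ct_panel <- function(path) {
  df <- read_table_checked(path, sep = "\t", what = "Ct panel")
  cells <- as.character(df[[1]])
  if (anyDuplicated(cells))
    stop_mascsig("duplicate cell identifier: ",
                 cells[duplicated(cells)][1])
  cols <- names(df)[-1]
  is_spike <- startsWith(cols, "spike:")
  parse_col <- function(v) {
    v[v == "ND"] <- NA
    as.numeric(v)
  }
  vals <- vapply(df[, -1, drop = FALSE], parse_col, numeric(nrow(df)))
  if (nrow(df) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, cols))
  rownames(vals) <- cells
  ct <- vals[, !is_spike, drop = FALSE]
  spike_ct <- NULL; spikes <- NULL
  if (any(is_spike)) {
    parts <- strsplit(sub("^spike:", "", cols[is_spike]), ":")
    spikes <- tibble::tibble(
      transcript = vapply(parts, `[`, character(1), 1),
      copies = as.numeric(vapply(parts, `[`, character(1), 2)))
    spike_ct <- vals[, is_spike, drop = FALSE]
    colnames(spike_ct) <- spikes$transcript
  }
  single_cell_panel(ct, spike_ct = spike_ct, spikes = spikes)
}

#' @rdname read_ct_panel
#' @param panel a `single_cell_panel`.
#' @inheritParams write_expression_matrix
#' @export
write_ct_panel <- function(panel, path, provenance = NULL) {
  stopifnot(inherits(panel, "single_cell_panel"))
  m <- panel$ct
  header <- colnames(m)
  if (!is.null(panel$spikes)) {
    header <- c(header, paste0("spike:", panel$spikes$transcript, ":",
                               panel$spikes$copies))
    m <- cbind(m, panel$spike_ct)
  }
  fmt <- function(v) {
    out <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    out[is.na(v)] <- "ND"
    out
  }
  lines <- c(provenance_header(provenance),
             paste(c("cell", header), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
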