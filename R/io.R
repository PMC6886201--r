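## TSV/CSV readers and writers for count and covariate tables.
## Canonical dialect: tab-separated, UTF-8, '#' comment lines; commas are
## accepted by sniffing the header line.

sniff_sep <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) jde_stop_validation(paste0("empty table: ", path))
  header <- lines[[1L]]
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

read_table_checked <- function(path) {
  if (!file.exists(path)) jde_stop_validation(paste0("file not found: ", path))
  sep <- sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = ""),
    error = function(e) jde_stop_validation(
      paste0("malformed table ", path, ": ", conditionMessage(e))))
  df
}

#' Read a genes-by-samples count table
#'
#' Expects a TSV (or CSV) with a header row of sample identifiers and the
#' first column holding gene identifiers. Validates that identifiers are
#' unique and all counts are non-negative numbers.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path) {
  df <- read_table_checked(path)
  if (ncol(df) < 2L) jde_stop_validation("count table needs id column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    jde_stop_validation(paste0("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) jde_stop_validation("non-numeric count cells")
  bad <- which(mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    jde_stop_validation(sprintf("negative count at row %s, column %s",
                                ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  if (anyDuplicated(colnames(mat)))
    jde_stop_validation("duplicate sample ids in header")
  rownames(mat) <- ids
  mat
}

#' Read a samples-by-covariates table aligned to a count matrix
#'
#' First column must hold sample identifiers matching the count table's
#' header (order-insensitive); rows are reordered to \code{sample_ids}.
#' Missing or extra samples are errors.
#'
#' @param path file path.
#' @param sample_ids character vector giving the required sample order;
#'   \code{NULL} keeps file order.
#' @return numeric matrix, samples in rows.
#' @export
read_covariates <- function(path, sample_ids = NULL) {
  df <- read_table_checked(path)
  if (ncol(df) < 2L) jde_stop_validation("covariate table needs id column plus covariates")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) jde_stop_validation("duplicate sample ids in covariate table")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) jde_stop_validation("non-numeric covariate cells")
  rownames(mat) <- ids
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, ids)
    extra <- setdiff(ids, sample_ids)
    if (length(missing))
      jde_stop_validation(paste0("covariates missing for samples: ",
                                 paste(missing, collapse = ", ")))
    if (length(extra))
      jde_stop_validation(paste0("covariates for unknown samples: ",
                                 paste(extra, collapse = ", ")))
    mat <- mat[sample_ids, , drop = FALSE]
  }
  mat
}

# short content hash for output provenance headers (31-bit multiplicative)
settings_hash <- function(s) {
  bytes <- utf8ToInt(paste(names(s), unlist(s), sep = "=", collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

output_header <- function(settings) {
  ver <- as.character(utils::packageVersion("jointDE"))
  sprintf("# jointDE %s settings=%s", ver, settings_hash(settings))
}

write_tsv_with_header <- function(df, path, settings) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(settings), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a count matrix as TSV
#'
#' Genes in rows, header row of sample ids, first column \code{gene_id};
#' one leading comment line records the tool version and a settings hash.
#'
#' @param counts numeric matrix with dimnames.
#' @param path output path.
#' @param settings named list recorded in the header hash.
#' @export
write_counts <- function(counts, path, settings = list()) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv_with_header(df, path, settings)
  invisible(path)
}

#' Write a covariate matrix as TSV (samples in rows)
#' @inheritParams write_counts
#' @param covariates numeric matrix with sample rownames.
#' @export
write_covariates <- function(covariates, path, settings = list()) {
  df <- data.frame(sample_id = rownames(covariates), covariates,
                   check.names = FALSE)
  write_tsv_with_header(df, path, settings)
  invisible(path)
}
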