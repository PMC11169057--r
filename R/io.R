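#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs (any
#' column name). Cells must be non-negative numbers.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read counts file '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df[, -1])[!vapply(df[, -1], is.numeric, logical(1))]
    abort(sprintf("non-numeric count columns in '%s': %s",
                  path, paste(bad, collapse = ", ")))
  }
  rownames(m) <- gene_ids
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  m
}

#' Read a sample sheet (sample, condition, replicate) from TSV
#' @param path Path to a tab-separated file with at least columns
#'   `sample` and `condition`.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read sample sheet '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(sample = "c", condition = "c"))
  missing <- setdiff(c("sample", "condition"), names(df))
  if (length(missing)) {
    abort(sprintf("sample sheet '%s' lacks column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a gene-length table (gene_id, length_bp) from TSV
#' @param path Path to a tab-separated two-column file.
#' @return Named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read gene-lengths file '%s'", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) < 2) abort(sprintf("gene-lengths file '%s' needs two columns", path))
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a regulator (TF) ID list
#'
#' Accepts either one gene ID per line or an iTAK-style TSV whose first
#' column is the gene ID (remaining columns ignored).
#'
#' @param path Path to the list file.
#' @return Character vector of unique TF gene IDs.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read TF list '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unique(vapply(strsplit(lines, "\t"), `[[`, character(1), 1))
}
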