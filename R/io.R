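# TSV readers/writers for the gene-by-sample matrix convention: genes as
# rows, first column `gene_id`, one column per sample. gzip-transparent via
# readr.

#' Read and write expression matrices as TSV
#'
#' @param path File path (`.tsv`, gzip-transparent).
#' @param scale Scale of the stored values; recorded on the returned
#'   [expr_matrix()], never guessed from the data.
#' @return `read_expression_tsv()` returns an [expr_matrix()];
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = "rpk") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") abort("The first column must be `gene_id`.")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$gene_id
  expr_matrix(m, scale)
}

#' @rdname read_expression_tsv
#' @param m Numeric gene-by-sample matrix.
#' @export
write_expression_tsv <- function(m, path) {
  v <- unclass(as.matrix(m))
  df <- tibble::as_tibble(v, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects at least `sample_id` and `disease` columns; `batch` and numeric
#' covariates are optional.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_metadata_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("sample_id", "disease", "batch"), names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  missing <- setdiff(c("sample_id", "disease"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("Metadata is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  df
}

#' Serialise a simulated dataset to three TSV files
#'
#' Writes `<prefix>_matrix.tsv` (genes x samples), `<prefix>_metadata.tsv`
#' (`sample_id`, `disease`, `batch`) and `<prefix>_truth.tsv` (`gene_id`,
#' `is_signal`, `d_mu`, `d_theta`, `d_pi`, `direction`).
#'
#' @param ds A `zi_dataset`.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "zi_dataset"))
  paths <- paste0(prefix, c("_matrix.tsv", "_metadata.tsv", "_truth.tsv"))
  write_expression_tsv(ds$matrix, paths[1])
  readr::write_tsv(ds$metadata, paths[2], progress = FALSE)
  readr::write_tsv(ds$truth, paths[3], progress = FALSE)
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `zi_dataset`.
#' @export
read_dataset <- function(prefix) {
  m <- read_expression_tsv(paste0(prefix, "_matrix.tsv"))
  metadata <- read_metadata_tsv(paste0(prefix, "_metadata.tsv"))
  truth <- readr::read_tsv(paste0(prefix, "_truth.tsv"), show_col_types = FALSE,
                           progress = FALSE)
  structure(list(matrix = unclass(m), metadata = metadata, truth = truth,
                 spec = NULL),
            class = "zi_dataset")
}
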