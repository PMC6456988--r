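#' Validate an expression matrix / sample sheet pair
#'
#' Checks the structural contract shared by every downstream analysis:
#' a numeric genes x samples matrix of log2(abundance + 1) values with
#' unique, non-empty gene and sample identifiers, and a sample sheet
#' assigning every column to an organ with at least two replicates per
#' organ.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs). Values are assumed to be
#'   on log2(x + 1) scale already; no transformation is applied here.
#' @param sheet data.frame with columns `sample_id`, `organ`, `replicate`.
#' @return invisibly `TRUE`; otherwise stops with a named condition class
#'   (`sigrevert_duplicate_gene`, `sigrevert_duplicate_sample`,
#'   `sigrevert_nonnumeric`, `sigrevert_sample_mismatch`,
#'   `sigrevert_too_few_replicates`, `sigrevert_nonfinite`).
#' @export
validate_expression <- function(expr, sheet) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop_sig("sigrevert_nonnumeric", "expression values must form a numeric matrix")
  }
  genes <- rownames(expr)
  samples <- colnames(expr)
  if (is.null(genes) || anyNA(genes) || any(genes == "")) {
    stop_sig("sigrevert_duplicate_gene", "gene IDs missing or empty")
  }
  if (anyDuplicated(genes)) {
    stop_sig("sigrevert_duplicate_gene",
             sprintf("duplicate gene ID(s): %s",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (is.null(samples) || anyDuplicated(samples)) {
    stop_sig("sigrevert_duplicate_sample", "sample IDs missing or duplicated")
  }
  if (ncol(expr) < 2) {
    stop_sig("sigrevert_sample_mismatch", "need at least 2 samples")
  }
  if (!all(is.finite(expr))) {
    stop_sig("sigrevert_nonfinite", "non-finite expression values present")
  }
  req <- c("sample_id", "organ", "replicate")
  if (!all(req %in% names(sheet))) {
    stop_sig("sigrevert_sample_mismatch",
             sprintf("sample sheet must have columns %s", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_sig("sigrevert_duplicate_sample", "duplicate sample_id in sample sheet")
  }
  if (!setequal(samples, sheet$sample_id)) {
    stop_sig("sigrevert_sample_mismatch",
             sprintf("samples differ between matrix and sheet (matrix-only: %s; sheet-only: %s)",
                     paste(setdiff(samples, sheet$sample_id), collapse = ",") ,
                     paste(setdiff(sheet$sample_id, samples), collapse = ",")))
  }
  if (any(!is.finite(sheet$replicate)) || any(sheet$replicate < 1)) {
    stop_sig("sigrevert_sample_mismatch", "replicate must be a positive integer")
  }
  tab <- table(sheet$organ)
  if (any(tab < 2)) {
    stop_sig("sigrevert_too_few_replicates",
             sprintf("organ(s) with fewer than 2 replicates: %s",
                     paste(names(tab)[tab < 2], collapse = ", ")))
  }
  invisible(TRUE)
}

stop_sig <- function(class, msg) {
  stop(structure(class = c(class, "sigrevert_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with the gene symbol in the first
#' column and one column per sample; the sheet is tab-separated with
#' columns `sample_id`, `organ`, `replicate`. Values are used as-is
#' (the contract is log2(x + 1) scale).
#'
#' @param matrix_path,sheet_path paths to the two TSV files.
#' @return list with elements `expr` (numeric matrix) and `sheet`
#'   (data.frame), validated by [validate_expression()].
#' @export
read_expression <- function(matrix_path, sheet_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop_sig("sigrevert_sample_mismatch", "matrix needs >= 2 sample columns")
  genes <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    stop_sig("sigrevert_nonnumeric",
             sprintf("non-numeric expression column(s): %s",
                     paste(names(vals)[nonnum], collapse = ", ")))
  }
  expr <- as.matrix(vals)
  rownames(expr) <- genes
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  validate_expression(expr, sheet)
  # keep sheet rows in matrix column order for downstream convenience
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  list(expr = expr, sheet = sheet)
}

#' Write an expression matrix and sample sheet to TSV
#'
#' Inverse of [read_expression()]; round-trips exactly (values are
#' written with full precision).
#'
#' @param expr,sheet as returned by [read_expression()].
#' @param matrix_path,sheet_path output paths.
#' @export
write_expression <- function(expr, sheet, matrix_path, sheet_path) {
  validate_expression(expr, sheet)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, sheet_path))
}

organ_samples <- function(sheet, organ) sheet$sample_id[sheet$organ == organ]
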