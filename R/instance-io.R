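#' Construct a drug-perturbation instance database
#'
#' An instance is one perturbation experiment (compound at a dose in a
#' cell line) represented as a complete rank vector over the probe
#' universe: rank 1 = most upregulated probe. The rank matrix is probes
#' x instances and every column must be a permutation of 1..n.
#'
#' @param ranks integer matrix, probes x instances; rownames = probe IDs,
#'   colnames = instance IDs.
#' @param meta data.frame with columns `instance_id`, `compound`,
#'   `cell_line`, `dose_text` (dose kept verbatim as text).
#' @return object of class `instance_db` with elements `probe_ids`,
#'   `ranks`, `meta`.
#' @export
instance_db <- function(ranks, meta) {
  if (!is.matrix(ranks)) stop_sig("sigrevert_rank_matrix", "ranks must be a matrix")
  n <- nrow(ranks)
  if (is.null(rownames(ranks)) || anyDuplicated(rownames(ranks))) {
    stop_sig("sigrevert_rank_matrix", "probe IDs missing or duplicated")
  }
  if (is.null(colnames(ranks)) || anyDuplicated(colnames(ranks))) {
    stop_sig("sigrevert_rank_matrix", "instance IDs missing or duplicated")
  }
  for (j in seq_len(ncol(ranks))) {
    col <- ranks[, j]
    if (anyNA(col) || length(col) != n || !identical(sort(as.integer(col)), seq_len(n))) {
      stop_sig("sigrevert_not_permutation",
               sprintf("column '%s' is not a permutation of 1..%d", colnames(ranks)[j], n))
    }
  }
  req <- c("instance_id", "compound", "cell_line", "dose_text")
  if (!all(req %in% names(meta))) {
    stop_sig("sigrevert_instance_meta",
             sprintf("metadata must have columns %s", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(meta$instance_id)) {
    stop_sig("sigrevert_instance_meta", "duplicate instance_id in metadata")
  }
  missing <- setdiff(colnames(ranks), meta$instance_id)
  if (length(missing)) {
    stop_sig("sigrevert_instance_meta",
             sprintf("instance(s) in rank matrix missing from metadata: %s",
                     paste(missing, collapse = ", ")))
  }
  if (any(!nzchar(meta$compound)) || anyNA(meta$compound)) {
    stop_sig("sigrevert_instance_meta", "every instance needs a non-empty compound label")
  }
  meta <- meta[match(colnames(ranks), meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  storage.mode(ranks) <- "integer"
  structure(list(probe_ids = rownames(ranks), ranks = ranks, meta = meta),
            class = "instance_db")
}

#' @export
print.instance_db <- function(x, ...) {
  cat(sprintf("instance_db: %d probes x %d instances (%d compounds)\n",
              length(x$probe_ids), ncol(x$ranks), length(unique(x$meta$compound))))
  invisible(x)
}

#' Read an instance database from rank-matrix and metadata TSVs
#'
#' Rank matrix: tab-separated, first column probe ID, one integer column
#' per instance. Metadata: `instance_id`, `compound`, `cell_line`,
#' `dose_text` (dose preserved verbatim as text).
#'
#' @param rank_matrix_path,metadata_path input TSV paths.
#' @return an [instance_db()].
#' @export
read_instance_db <- function(rank_matrix_path, metadata_path) {
  raw <- utils::read.delim(rank_matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  probes <- as.character(raw[[1]])
  ranks <- as.matrix(raw[, -1, drop = FALSE])
  rownames(ranks) <- probes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  instance_db(ranks, meta)
}

#' Write an instance database to rank-matrix and metadata TSVs
#' @param db an [instance_db()].
#' @param rank_matrix_path,metadata_path output TSV paths.
#' @export
write_instance_db <- function(db, rank_matrix_path, metadata_path) {
  stopifnot(inherits(db, "instance_db"))
  df <- data.frame(probe_id = db$probe_ids, db$ranks, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, rank_matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(db$meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(rank_matrix_path, metadata_path))
}
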