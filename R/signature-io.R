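#' Construct a gene signature
#'
#' An ordered pair of up- and down-regulated gene lists together with a
#' provenance record of how each derivation step contributed (candidate
#' counts, centroid markers, validated markers, cluster expansion,
#' appended down genes).
#'
#' @param up,down character vectors of gene symbols; order is meaningful
#'   and preserved on disk. Must be disjoint and non-empty together.
#' @param provenance arbitrary named list documenting the derivation
#'   (see [derive_signature()] for the fields the workflow fills in).
#' @param name signature name used in GMT output.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(up, down, provenance = list(), name = "signature") {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop_sig("sigrevert_signature", "duplicate genes within a direction")
  }
  if (length(intersect(up, down))) {
    stop_sig("sigrevert_signature_overlap",
             sprintf("up/down overlap: %s", paste(intersect(up, down), collapse = ", ")))
  }
  structure(list(up = up, down = down, provenance = provenance, name = name),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up + %d down = %d genes\n",
              x$name, length(x$up), length(x$down), length(x$up) + length(x$down)))
  if (length(x$provenance)) {
    counts <- x$provenance$counts
    if (!is.null(counts)) {
      cat("  derivation: ",
          paste(sprintf("%s=%s", names(counts), unlist(counts)), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a signature as GMT plus two GRP files
#'
#' The GMT file holds two sets, `<name>_up` and `<name>_down`; the GRP
#' files hold one gene symbol per line, preserving list order. A JSON
#' provenance sidecar is written next to the GMT when provenance is
#' non-empty.
#'
#' @param sig a [gene_signature()].
#' @param path_gmt,path_grp_up,path_grp_down output paths.
#' @export
write_signature <- function(sig, path_gmt, path_grp_up, path_grp_down) {
  stopifnot(inherits(sig, "gene_signature"))
  if (!length(sig$up) || !length(sig$down)) {
    stop_sig("sigrevert_signature", "cannot write an empty up or down set")
  }
  lines <- c(
    paste(c(paste0(sig$name, "_up"), "up-regulated", sig$up), collapse = "\t"),
    paste(c(paste0(sig$name, "_down"), "down-regulated", sig$down), collapse = "\t"))
  writeLines(lines, path_gmt)
  writeLines(sig$up, path_grp_up)
  writeLines(sig$down, path_grp_down)
  if (length(sig$provenance)) {
    jsonlite::write_json(sig$provenance, paste0(path_gmt, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path_gmt)
}

#' Read a signature back from its GMT file
#'
#' Inverts [write_signature()]: expects exactly two sets named
#' `<name>_up` and `<name>_down`. Order within each set is preserved.
#'
#' @param path_gmt GMT path written by [write_signature()].
#' @return a [gene_signature()] (provenance restored from the JSON
#'   sidecar if present).
#' @export
read_signature <- function(path_gmt) {
  lines <- readLines(path_gmt)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 2) stop_sig("sigrevert_signature", "GMT must hold exactly two sets")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1), 1)
  up_i <- grep("_up$", nm); down_i <- grep("_down$", nm)
  if (length(up_i) != 1 || length(down_i) != 1) {
    stop_sig("sigrevert_signature", "GMT sets must be named <name>_up and <name>_down")
  }
  name <- sub("_up$", "", nm[up_i])
  prov_path <- paste0(path_gmt, ".provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  gene_signature(up = fields[[up_i]][-(1:2)], down = fields[[down_i]][-(1:2)],
                 provenance = prov, name = name)
}
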