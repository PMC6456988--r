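#' Construct a probe map
#'
#' A probe map links gene symbols to microarray probe IDs (one gene may
#' map to several probes, a probe may carry several symbols) and records
#' the full probe universe of the platform.
#'
#' @param map named list, gene symbol -> character vector of probe IDs.
#' @param universe character vector of all platform probe IDs.
#' @return object of class `probe_map`.
#' @export
probe_map <- function(map, universe) {
  stopifnot(is.list(map), is.character(universe))
  if (anyDuplicated(universe)) stop_sig("sigrevert_duplicate_probe", "duplicate probe in universe")
  probes <- unique(unlist(map, use.names = FALSE))
  if (length(probes) && !all(probes %in% universe)) {
    stop_sig("sigrevert_probe_universe", "mapped probe not in universe")
  }
  structure(list(map = map, universe = universe), class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("probe_map: %d mapped genes, %d probes in universe\n",
              length(x$map), length(x$universe)))
  invisible(x)
}

#' Read a GPL96-style probe annotation table
#'
#' Expects a tab-separated table with columns `ID` (probe) and
#' `Gene Symbol`; the symbol field may hold several symbols separated by
#' `" /// "` and may be empty. Every probe enters the universe; a probe
#' with k symbols is listed under each of the k genes.
#'
#' @param path annotation TSV path.
#' @return a [probe_map()].
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("ID", "Gene Symbol") %in% names(tab))) {
    stop_sig("sigrevert_annotation_columns",
             "annotation table must have columns 'ID' and 'Gene Symbol'")
  }
  if (anyDuplicated(tab$ID)) {
    stop_sig("sigrevert_duplicate_probe", "duplicate probe ID in annotation")
  }
  map <- list()
  for (i in seq_len(nrow(tab))) {
    syms <- strsplit(tab[["Gene Symbol"]][i], " /// ", fixed = TRUE)[[1]]
    syms <- syms[nzchar(syms)]
    for (s in syms) map[[s]] <- c(map[[s]], tab$ID[i])
  }
  probe_map(map, tab$ID)
}

#' Write a probe map as a GPL96-style annotation table
#' @param pm a [probe_map()].
#' @param path output TSV path.
#' @export
write_probe_annotation <- function(pm, path) {
  stopifnot(inherits(pm, "probe_map"))
  # invert gene -> probes into probe -> " /// "-joined symbols
  sym <- stats::setNames(rep("", length(pm$universe)), pm$universe)
  for (g in names(pm$map)) {
    for (p in pm$map[[g]]) {
      sym[p] <- if (nzchar(sym[p])) paste(sym[p], g, sep = " /// ") else g
    }
  }
  out <- data.frame(ID = pm$universe, `Gene Symbol` = unname(sym),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
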