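#' Run the full pipeline: simulate, derive, map probes, score compounds
#'
#' End-to-end driver over the package's stages with one config and one
#' master seed: (optionally) simulate the multi-organ expression panel,
#' probe annotation and perturbation database; derive the signature;
#' map it to probe tag sets; rank compounds by inverse connectivity.
#' Every artifact is written to `outdir` in the package's TSV/GMT/GRP
#' dialects together with a JSON provenance sidecar (config, seeds,
#' stage counts), so two runs with the same config and seed produce an
#' identical artifact tree.
#'
#' @param config a [workflow_config()] or the path to a YAML config
#'   file.
#' @param outdir artifact directory (created if missing).
#' @param expr,sheet an existing expression panel; when `NULL` (the
#'   default) the planted synthetic panel is simulated from `design`.
#' @param design a [planted_design()] used when simulating.
#' @param probe_annotation a [probe_map()]; simulated over the gene
#'   universe when `NULL` (full coverage).
#' @param db an [instance_db()]; when `NULL` a synthetic database of
#'   one strength-1 inverter, one strength-1 mimic and 18 null
#'   compounds (2 instances each) over the annotation's probe universe
#'   is simulated.
#' @return invisible list with `signature`, `tags`, `compounds` (the
#'   ranked table), `paths` (written artifacts).
#' @export
run_pipeline <- function(config = workflow_config(), outdir = tempfile("sigrevert_"),
                         expr = NULL, sheet = NULL, design = planted_design(),
                         probe_annotation = NULL, db = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_line <- function(...) message(sprintf(...))

  if (is.null(expr)) {
    sim <- simulate_multiorgan_expression(design, seed = seed)
    expr <- sim$expr; sheet <- sim$sheet
    jsonlite::write_json(sim$truth, file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    log_line("simulate: %d genes x %d samples", nrow(expr), ncol(expr))
  }
  write_expression(expr, sheet, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "samples.tsv"))

  sig <- derive_signature(expr, sheet, config)
  write_signature(sig, file.path(outdir, "signature.gmt"),
                  file.path(outdir, "signature_up.grp"),
                  file.path(outdir, "signature_down.grp"))
  log_line("derive: %d up + %d down genes", length(sig$up), length(sig$down))

  if (is.null(probe_annotation)) {
    probe_annotation <- simulate_probe_annotation(rownames(expr), seed = seed + 10L)
  }
  write_probe_annotation(probe_annotation, file.path(outdir, "probe_annotation.tsv"))
  tags <- map_signature_to_probes(sig, probe_annotation)
  log_line("map-probes: %d up tags, %d down tags", length(tags$up), length(tags$down))

  if (is.null(db)) {
    compounds <- c(list(planted_compound("planted_inverter", "inverter", 1),
                        planted_compound("planted_mimic", "mimic", 1)),
                   lapply(seq_len(18), function(i)
                     planted_compound(sprintf("null_%02d", i), "null")))
    db <- simulate_instance_db(probe_annotation$universe, tags, compounds,
                               instances_per_compound = 2, seed = seed + 11L)
  }
  write_instance_db(db, file.path(outdir, "rank_matrix.tsv"),
                    file.path(outdir, "instance_meta.tsv"))

  comp <- rank_compounds(db, tags, n_null = config$n_null, seed = seed + 12L)
  utils::write.table(comp, file.path(outdir, "compound_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(comp, "instance_scores"),
                     file.path(outdir, "instance_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(top_compounds(comp, config$top_k),
                     file.path(outdir, "top_compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("cmap-score: %d compounds ranked; best mean score %.3f (%s)",
           nrow(comp), comp$mean_score[1], comp$compound[1])

  prov <- list(config = unclass(config),
               signature = sig$provenance,
               mapping = tags$report,
               n_instances = ncol(db$ranks),
               n_compounds = length(unique(db$meta$compound)))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(signature = sig, tags = tags, compounds = comp,
                 outdir = outdir,
                 paths = list.files(outdir, full.names = TRUE)))
}
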