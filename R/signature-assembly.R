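#' Derive an organ-tropic signature by the five-step workflow
#'
#' Executes, in order: (1) per-organ moderated-t differential expression and
#' the union candidate set; (2) nearest-shrunken-centroid selection of
#' target-organ markers among the candidate up-genes; (3) validation of
#' the markers by the conjunction of three independent permutation
#' analyses — pooled rank product (pfp_up below cutoff), per-organ
#' meta rank product (pfp_up below cutoff), and SAM (q below cutoff with
#' positive d); (4) expansion of the validated markers to the minimal
#' hierarchical cluster containing them, within the candidate up-genes;
#' (5) appending the most downregulated genes of the pooled rank
#' product as the down set. Step counts, thresholds and seeds are
#' recorded in the signature provenance.
#'
#' Stage seeds are derived deterministically from `config$seed` so the
#' whole derivation is reproducible bit for bit.
#'
#' @param expr,sheet expression matrix and sample sheet.
#' @param config a [workflow_config()].
#' @return a [gene_signature()]; the up set is ordered markers-first
#'   (by decreasing shrunken difference) then cluster additions
#'   alphabetically, the down set by rank-product strength. Fails with
#'   an explicit "no signature" error naming the first empty step.
#' @export
derive_signature <- function(expr, sheet, config = workflow_config()) {
  validate_config(config)
  validate_expression(expr, sheet)
  target <- config$target_organ
  if (!target %in% sheet$organ) {
    stop_sig("sigrevert_config", sprintf("target organ '%s' absent from sample sheet", target))
  }
  others <- setdiff(unique(sheet$organ), target)
  seed <- config$seed

  # (1) candidate set
  comparisons <- lapply(others, function(o) pairwise_de(expr, sheet, target, o))
  cand <- build_candidate_set(comparisons, config$de_fdr, config$de_min_abs_log2fc)
  if (!length(cand$up)) {
    stop_sig("sigrevert_no_signature", "no signature: step 1 produced no upregulated candidates")
  }

  # (2) shrunken-centroid markers among candidate up-genes
  fit <- fit_shrunken_centroids(expr[cand$up, , drop = FALSE], sheet,
                                cv_folds = config$pam_cv_folds,
                                target_organ = target, seed = seed + 1L)
  markers <- target_markers(fit, target)
  if (!length(markers)) {
    stop_sig("sigrevert_no_signature", "no signature: step 2 selected no centroid markers")
  }

  # (3) triple validation
  rp_pooled <- rank_product(expr, sheet, target, mode = "pooled",
                            n_perm = config$n_permutations, seed = seed + 2L)
  rp_meta <- rank_product(expr, sheet, target, mode = "meta",
                          n_perm = config$n_permutations, seed = seed + 3L)
  sam <- sam_test(expr, sheet, target, n_perm = config$n_permutations,
                  seed = seed + 4L)
  pass_pooled <- rp_pooled$gene[rp_pooled$pfp_up < config$pfp_cutoff]
  pass_meta <- rp_meta$gene[rp_meta$pfp_up < config$pfp_cutoff]
  pass_sam <- sam$gene[sam$q < config$sam_q_cutoff & sam$d > 0]
  validated <- markers[markers %in% pass_pooled &
                       markers %in% pass_meta &
                       markers %in% pass_sam]
  if (!length(validated)) {
    stop_sig("sigrevert_no_signature", "no signature: step 3 validated no markers")
  }

  # (4) cluster expansion within candidate up-genes
  tree <- hierarchical_cluster(expr[cand$up, , drop = FALSE],
                               metric = config$cluster_metric,
                               linkage = config$cluster_linkage)
  validated_in_tree <- intersect(validated, tree$genes)
  if (!length(validated_in_tree)) {
    stop_sig("sigrevert_no_signature", "no signature: validated markers lost to zero variance")
  }
  # expansion by flat clusters at a fixed co-clustering ceiling: on
  # trees whose module leaves chain, the literal minimal containing
  # subtree of a marker subset systematically drops late-joining module
  # members, and a data-driven gap cut fragments the module when the
  # candidate set holds nothing but the module itself. Cutting at the
  # fixed ceiling expand_h_max (average correlation 1 - h) recovers the
  # co-clustering module in both regimes.
  up_cluster <- minimal_containing_cluster(tree, validated_in_tree,
                                           cut_height = config$expand_h_max)
  additions <- sort(setdiff(up_cluster, validated_in_tree))
  up <- c(validated_in_tree, additions)   # markers first, additions alphabetical

  # (5) append most downregulated genes (pooled rank product ordering)
  down <- top_downregulated(rp_pooled, min(config$n_down_append, nrow(expr)))
  overlap <- intersect(up, down)
  down <- setdiff(down, overlap)
  down_in_candidates <- sum(down %in% cand$down)

  prov <- list(
    counts = list(
      candidates_up = length(cand$up), candidates_down = length(cand$down),
      markers = length(markers), validated = length(validated),
      cluster_members = length(up_cluster), cluster_additions = length(additions),
      down_appended = length(down), up = length(up), down = length(down),
      total = length(up) + length(down)),
    markers = markers, validated = validated,
    removed_from_down = overlap,
    down_in_candidate_down = down_in_candidates,
    pam = list(delta_star = fit$delta_star,
               cv_error = min(fit$cv_error)),
    thresholds = config[c("de_fdr", "de_min_abs_log2fc", "pfp_cutoff",
                          "sam_q_cutoff", "n_down_append")],
    target_organ = target,
    seed = seed,
    stage_seeds = list(pam = seed + 1L, rp_pooled = seed + 2L,
                       rp_meta = seed + 3L, sam = seed + 4L))
  gene_signature(up = up, down = down, provenance = prov,
                 name = paste0(target, "_signature"))
}

#' Map a gene signature to probe tag sets
#'
#' Each signature gene contributes every probe it maps to; unmapped
#' genes are reported. A probe mapped to both an up- and a down-gene
#' would violate tag-set disjointness and is dropped from both sides
#' (recorded in the report).
#'
#' @param sig a [gene_signature()].
#' @param pm a [probe_map()].
#' @return list of class `tag_sets`: `up`, `down` (probe ID vectors) and
#'   `report` (mapped gene counts, probe counts, unmapped symbols,
#'   ambiguous probes).
#' @export
map_signature_to_probes <- function(sig, pm) {
  stopifnot(inherits(sig, "gene_signature"), inherits(pm, "probe_map"))
  if (!length(sig$up) && !length(sig$down)) {
    stop_sig("sigrevert_signature", "empty signature")
  }
  probes_of <- function(genes) {
    hit <- genes[genes %in% names(pm$map)]
    list(mapped_genes = hit,
         probes = unique(unlist(pm$map[hit], use.names = FALSE)),
         unmapped = setdiff(genes, hit))
  }
  u <- probes_of(sig$up); d <- probes_of(sig$down)
  ambiguous <- intersect(u$probes, d$probes)
  up <- setdiff(u$probes, ambiguous)
  down <- setdiff(d$probes, ambiguous)
  if (!length(up) && !length(down)) {
    stop_sig("sigrevert_empty_tagsets", "no signature gene maps to any probe")
  }
  structure(list(
    up = up, down = down,
    report = list(
      up_genes = length(sig$up), up_mapped_genes = length(u$mapped_genes),
      up_probes = length(up), up_unmapped = u$unmapped,
      down_genes = length(sig$down), down_mapped_genes = length(d$mapped_genes),
      down_probes = length(down), down_unmapped = d$unmapped,
      ambiguous_probes = ambiguous)), class = "tag_sets")
}

#' @export
print.tag_sets <- function(x, ...) {
  r <- x$report
  cat(sprintf("tag_sets: up %d/%d genes mapped -> %d probes; down %d/%d genes mapped -> %d probes\n",
              r$up_mapped_genes, r$up_genes, r$up_probes,
              r$down_mapped_genes, r$down_genes, r$down_probes))
  invisible(x)
}
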