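#' Workflow configuration
#'
#' Collects every threshold and option of the five-step derivation and
#' the connectivity stage. Defaults follow the motivating analysis
#' profile: rank-product pfp cutoff 0.01, SAM q cutoff 0.05, 54 appended
#' down-genes, top-10 compound report.
#'
#' @param target_organ organ label treated as the signature target.
#' @param de_fdr BH-adjusted p cutoff for the per-organ differential
#'   expression step (default 0.05).
#' @param de_min_abs_log2fc minimum |log2 fold change| for a candidate
#'   (default 1, i.e. two-fold).
#' @param pfp_cutoff rank-product percentage-of-false-prediction cutoff
#'   (default 0.01).
#' @param sam_q_cutoff SAM q-value cutoff (default 0.05).
#' @param n_down_append number of most-downregulated genes appended as
#'   the signature down set (default 54).
#' @param pam_cv_folds cross-validation folds for the shrunken-centroid
#'   threshold choice; values >= number of samples mean leave-one-out
#'   (default 12, i.e. LOO on the 4x3 design).
#' @param n_permutations permutations for rank-product pfp and SAM q
#'   estimation (default 1000). The floor is 100, but the pfp of the
#'   top-ranked gene is estimated on a 1/n_permutations grid: at the
#'   floor a single null tie equals the 0.01 cutoff exactly and the
#'   monotone enforcement then erases every call, so the default keeps
#'   the grid two decades below the cutoff. At 1000 the SAM null is the
#'   exhaustive 220-assignment set on a 4x3 design.
#' @param cluster_metric,cluster_linkage dissimilarity and linkage of the
#'   cluster-expansion step (defaults: 1 - Pearson correlation, average
#'   linkage).
#' @param expand_h_max co-clustering ceiling of the expansion step: the
#'   dendrogram is cut at this height and the validated markers' flat
#'   cluster(s) become the up set. Under the correlation metric the
#'   default 0.2 reads as "genes joining the marker cluster at average
#'   correlation above 0.8 co-cluster with it" — between the planted
#'   module's internal merge scale and the incidental correlations of
#'   threshold-selected outsiders.
#' @param n_null resampled null subsets for the compound permutation p
#'   (default 10000).
#' @param top_k rows of the compound report (default 10).
#' @param seed integer master seed; every stochastic stage derives its
#'   own stream from it and records it.
#' @return object of class `workflow_config` (a validated named list).
#' @export
workflow_config <- function(target_organ = "brain",
                            de_fdr = 0.05,
                            de_min_abs_log2fc = 1,
                            pfp_cutoff = 0.01,
                            sam_q_cutoff = 0.05,
                            n_down_append = 54,
                            pam_cv_folds = 12,
                            n_permutations = 1000,
                            cluster_metric = "pearson",
                            cluster_linkage = "average",
                            expand_h_max = 0.2,
                            n_null = 10000,
                            top_k = 10,
                            seed = 1L) {
  cfg <- list(target_organ = target_organ, de_fdr = de_fdr,
              de_min_abs_log2fc = de_min_abs_log2fc, pfp_cutoff = pfp_cutoff,
              sam_q_cutoff = sam_q_cutoff, n_down_append = n_down_append,
              pam_cv_folds = pam_cv_folds, n_permutations = n_permutations,
              cluster_metric = cluster_metric, cluster_linkage = cluster_linkage,
              expand_h_max = expand_h_max,
              n_null = n_null, top_k = top_k, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "workflow_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$target_organ) || !nzchar(cfg$target_organ)) {
    stop_sig("sigrevert_config", "target_organ must be set")
  }
  for (k in c("de_fdr", "pfp_cutoff", "sam_q_cutoff")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop_sig("sigrevert_config", sprintf("%s must lie in (0, 1]", k))
    }
  }
  if (cfg$n_permutations < 100) {
    stop_sig("sigrevert_config", "n_permutations must be >= 100")
  }
  if (cfg$n_down_append < 0 || cfg$top_k < 1) {
    stop_sig("sigrevert_config", "n_down_append/top_k out of range")
  }
  invisible(TRUE)
}

#' Read a workflow configuration from a flat YAML file
#'
#' Unknown keys are rejected so typos fail before any compute.
#'
#' @param path YAML file with (a subset of) the [workflow_config()]
#'   argument names as top-level keys.
#' @return a `workflow_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(workflow_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop_sig("sigrevert_config",
             sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(workflow_config, vals)
}

#' @export
print.workflow_config <- function(x, ...) {
  cat("workflow_config:\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, x[[k]]))
  invisible(x)
}
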