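#' Per-gene moderated-t differential expression between two organs
#'
#' Compares the target organ against one other organ on log2-scale
#' values with limma's empirical-Bayes moderated t (per-gene linear
#' model, variances shrunk toward the common prior) and
#' Benjamini-Hochberg adjustment within the comparison. At three
#' replicates per organ an unmoderated t is unstable in both
#' directions — Welch's Satterthwaite df collapses toward 2, and a
#' single inflated within-group variance silently drops even 8-sigma
#' effects — so the moderated fit is the standard choice; it also
#' handles zero-variance genes without a special floor.
#'
#' @param expr,sheet expression matrix and sample sheet (see
#'   [validate_expression()]).
#' @param target_organ,other_organ organ labels; must differ and both be
#'   present with >= 2 replicates.
#' @return data.frame of class `de_comparison` with columns `gene`,
#'   `log2fc` (target minus other), `t`, `p`, `padj`, and attribute
#'   `other_organ`.
#' @export
pairwise_de <- function(expr, sheet, target_organ, other_organ) {
  validate_expression(expr, sheet)
  if (identical(target_organ, other_organ)) {
    stop_sig("sigrevert_de", "target and other organ must differ")
  }
  for (o in c(target_organ, other_organ)) {
    if (!o %in% sheet$organ) stop_sig("sigrevert_de", sprintf("unknown organ '%s'", o))
  }
  s1 <- organ_samples(sheet, target_organ)
  s2 <- organ_samples(sheet, other_organ)
  grp <- factor(rep(c("target", "other"), c(length(s1), length(s2))),
                levels = c("other", "target"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(expr[, c(s1, s2), drop = FALSE], design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none",
                        adjust.method = "BH")
  out <- data.frame(gene = rownames(expr), log2fc = tt$logFC, t = tt$t,
                    p = tt$P.Value, padj = tt$adj.P.Val,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "other_organ") <- other_organ
  attr(out, "target_organ") <- target_organ
  class(out) <- c("de_comparison", "data.frame")
  out
}

#' Union candidate set over all per-organ comparisons
#'
#' A gene enters the up (down) candidate list if, in at least one
#' comparison, its BH-adjusted p is at most `de_fdr` and its log2 fold
#' change is at least `de_min_abs_log2fc` in magnitude with the matching
#' sign. A gene may appear in both directions through different organs;
#' per-comparison membership is recorded.
#'
#' @param comparisons list of [pairwise_de()] results.
#' @param de_fdr,de_min_abs_log2fc thresholds (see [workflow_config()]).
#' @return list of class `candidate_set`: `up`, `down` (character),
#'   `membership` (data.frame gene/comparison/direction records).
#' @export
build_candidate_set <- function(comparisons, de_fdr = 0.05, de_min_abs_log2fc = 1) {
  if (!length(comparisons)) stop_sig("sigrevert_de", "need at least one comparison")
  rec <- list()
  for (cmp in comparisons) {
    o <- attr(cmp, "other_organ")
    hit_up <- cmp$padj <= de_fdr & cmp$log2fc >= de_min_abs_log2fc
    hit_down <- cmp$padj <= de_fdr & cmp$log2fc <= -de_min_abs_log2fc
    if (any(hit_up)) {
      rec[[length(rec) + 1]] <- data.frame(gene = cmp$gene[hit_up], comparison = o,
                                           direction = "up", stringsAsFactors = FALSE)
    }
    if (any(hit_down)) {
      rec[[length(rec) + 1]] <- data.frame(gene = cmp$gene[hit_down], comparison = o,
                                           direction = "down", stringsAsFactors = FALSE)
    }
  }
  membership <- if (length(rec)) do.call(rbind, rec) else
    data.frame(gene = character(0), comparison = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  structure(list(
    up = sort(unique(membership$gene[membership$direction == "up"])),
    down = sort(unique(membership$gene[membership$direction == "down"])),
    membership = membership), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  both <- length(intersect(x$up, x$down))
  cat(sprintf("candidate_set: %d up, %d down (%d in both), %d unique genes\n",
              length(x$up), length(x$down), both, length(union(x$up, x$down))))
  invisible(x)
}
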