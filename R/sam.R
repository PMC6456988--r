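#' Significance analysis of microarrays (two-class, permutation q-values)
#'
#' The target organ forms one class, all remaining samples the other.
#' The per-gene statistic is `d = (mean_target - mean_other) / (s + s0)`
#' with `s` the pooled two-sample standard error and the
#' exchangeability constant `s0` fixed at the median of the per-gene
#' `s` (a deterministic stand-in for the original coefficient-of-
#' variation tuner). The null distribution of `d` comes from relabeling
#' the class assignment: all `choose(n, n_target)` distinct assignments
#' when there are no more than `n_perm` of them, otherwise `n_perm`
#' sampled assignments.
#'
#' For each gene the q-value compares the median null count of
#' `|d*| >= |d(g)|` with the observed count at the same threshold
#' (pi0 fixed at 1, conservative), clamped to `[0, 1]` and made monotone
#' by a cumulative maximum along the decreasing-|d| ordering.
#'
#' @param expr,sheet expression matrix and sample sheet.
#' @param target_organ organ forming the first class.
#' @param n_perm permutation budget (>= 100).
#' @param seed integer seed.
#' @return data.frame of class `sam_result` with columns `gene`, `d`,
#'   `s`, `q`; attributes `s0`, `n_perm_used`, `exhaustive`, `seed`,
#'   `degenerate` (TRUE when fewer than 20 distinct assignments exist).
#' @export
sam_test <- function(expr, sheet, target_organ, n_perm = 100, seed = 1L) {
  validate_expression(expr, sheet)
  if (!target_organ %in% sheet$organ) {
    stop_sig("sigrevert_sam", sprintf("target organ '%s' absent", target_organ))
  }
  tcols <- which(sheet$organ == target_organ)
  n <- ncol(expr); n1 <- length(tcols); n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop_sig("sigrevert_sam", "need >= 2 samples per class")
  set.seed(as.integer(seed))
  genes <- rownames(expr)

  d_of <- function(idx1) {
    x1 <- expr[, idx1, drop = FALSE]
    x2 <- expr[, -idx1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- matrixStats::rowVars(x1) * (n1 - 1) + matrixStats::rowVars(x2) * (n2 - 1)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n - 2))
    list(num = m1 - m2, s = s)
  }
  obs <- d_of(tcols)
  s0 <- stats::median(obs$s)
  d <- obs$num / (obs$s + s0)

  n_assign <- choose(n, n1)
  degenerate <- n_assign < 20
  if (degenerate) {
    warning("fewer than 20 distinct label assignments; q-values are coarse")
  }
  if (n_assign <= n_perm) {
    assigns <- utils::combn(n, n1, simplify = FALSE)
  } else {
    assigns <- replicate(n_perm, sample(n, n1), simplify = FALSE)
  }
  null_abs <- lapply(assigns, function(idx1) {
    nd <- d_of(idx1)
    sort(abs(nd$num / (nd$s + s0)))
  })

  ng <- length(d)
  abs_d <- abs(d)
  ord <- order(-abs_d, genes)              # most significant first
  # counts of |d| >= threshold via sorted lookups (findInterval with
  # left.open counts strictly-smaller values)
  obs_cnt <- ng - findInterval(abs_d, sort(abs_d), left.open = TRUE)
  cnts <- vapply(null_abs,
                 function(s) ng - findInterval(abs_d, s, left.open = TRUE),
                 integer(ng))
  null_cnt <- matrixStats::rowMedians(matrix(cnts, nrow = ng))
  q <- pmin(1, pmax(0, null_cnt / obs_cnt))
  q[ord] <- cummax(q[ord])

  out <- data.frame(gene = genes, d = d, s = obs$s, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "s0") <- s0
  attr(out, "n_perm_used") <- length(assigns)
  attr(out, "exhaustive") <- n_assign <= n_perm
  attr(out, "seed") <- as.integer(seed)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("sam_result", "data.frame")
  out
}
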