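#' Kolmogorov-Smirnov enrichment of a tag set in a rank vector
#'
#' Build-2 style statistic: with the t tag positions sorted ascending as
#' `V(1..t)` inside a rank list of length n,
#' `a = max_j ( j/t - V(j)/n )` and `b = max_j ( V(j)/n - (j-1)/t )`;
#' the enrichment is `a` if `a > b`, else `-b`. Positive values mean the
#' tags sit near the top of the list (most upregulated).
#'
#' @param tag_positions strictly increasing integer ranks in `1..n`.
#' @param n length of the full rank list.
#' @return single numeric in `[-1, 1]`.
#' @export
ks_enrichment <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t < 1) stop_sig("sigrevert_ks", "empty tag set")
  if (t >= n) stop_sig("sigrevert_ks", "tag set must be smaller than the list")
  v <- as.numeric(tag_positions)
  if (any(v < 1) || any(v > n) || any(diff(v) <= 0)) {
    stop_sig("sigrevert_ks", "tag positions must be strictly increasing in 1..n")
  }
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Raw connectivity score of one instance against the query tag sets
#'
#' `ks_up` is the enrichment of the up tags, `ks_down` of the down tags;
#' the raw score is `s = ks_up - ks_down` when the two enrichments have
#' opposite signs and 0 otherwise (the null convention: an instance
#' moving both halves of the query in the same direction carries no
#' connectivity signal).
#'
#' @param ranks integer rank vector named by probe ID (a column of an
#'   [instance_db()] rank matrix), rank 1 = most upregulated.
#' @param tags a `tag_sets` object (or list with `up`/`down` probe IDs).
#' @return list with `ks_up`, `ks_down`, `s`.
#' @export
score_instance <- function(ranks, tags) {
  probes <- names(ranks)
  if (!all(c(tags$up, tags$down) %in% probes)) {
    stop_sig("sigrevert_tagset", "tag probes missing from the instance probe universe")
  }
  n <- length(ranks)
  ks_up <- ks_enrichment(sort(ranks[tags$up]), n)
  ks_down <- ks_enrichment(sort(ranks[tags$down]), n)
  s <- if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
  list(ks_up = ks_up, ks_down = ks_down, s = s)
}

#' Scale raw connectivity scores to [-1, 1]
#'
#' Positive raw scores are divided by the maximum positive score `p`,
#' negative ones by the magnitude of the minimum negative score `q`;
#' zeros stay zero. The strongest signature-reverting instance therefore
#' scores exactly -1 and the strongest mimic exactly +1.
#'
#' @param s numeric vector of raw scores across all instances.
#' @return numeric vector of scaled scores in `[-1, 1]`.
#' @export
scale_scores <- function(s) {
  if (!length(s)) stop_sig("sigrevert_ks", "no scores to scale")
  out <- numeric(length(s))
  pos <- s > 0; neg <- s < 0
  if (any(pos)) out[pos] <- s[pos] / max(s[pos])
  if (any(neg)) out[neg] <- -s[neg] / min(s[neg])
  out
}

#' Score every instance of a database against the query tag sets
#'
#' @param db an [instance_db()].
#' @param tags tag sets within the database probe universe.
#' @return data.frame with one row per instance: `instance_id`,
#'   `compound`, `cell_line`, `dose_text`, `ks_up`, `ks_down`, `s`
#'   (raw), `score` (scaled across the whole database).
#' @export
score_instances <- function(db, tags) {
  stopifnot(inherits(db, "instance_db"))
  raw <- vapply(seq_len(ncol(db$ranks)), function(j) {
    r <- db$ranks[, j]; names(r) <- db$probe_ids
    sc <- score_instance(r, tags)
    c(sc$ks_up, sc$ks_down, sc$s)
  }, numeric(3))
  out <- data.frame(db$meta[c("instance_id", "compound", "cell_line", "dose_text")],
                    ks_up = raw[1, ], ks_down = raw[2, ], s = raw[3, ],
                    stringsAsFactors = FALSE)
  out$score <- scale_scores(out$s)
  out
}

#' Rank compounds by mean scaled connectivity score
#'
#' Instances are scored and scaled across the whole database, grouped by
#' compound, and summarized by the mean scaled score (zero raw scores
#' included). The permutation p-value of a compound with k instances is
#' the fraction of `n_null` random k-subsets of all instance scores with
#' a mean at least as extreme (at or below the observed mean for
#' negative means, at or above for positive ones). Compounds are ranked
#' ascending by mean score, so rank 1 is the strongest candidate
#' signature inverter.
#'
#' @param db an [instance_db()].
#' @param tags query tag sets.
#' @param n_null resampled subsets for the permutation p (default
#'   10000).
#' @param seed integer seed for the resampling.
#' @return data.frame of class `compound_result`: `rank`, `compound`,
#'   `dose_text`, `n`, `mean_score`, `p`; attribute `instance_scores`
#'   holds the per-instance table.
#' @export
rank_compounds <- function(db, tags, n_null = 10000, seed = 1L) {
  inst <- score_instances(db, tags)
  set.seed(as.integer(seed))
  comps <- split(inst, inst$compound)
  all_scores <- inst$score
  res <- lapply(comps, function(g) {
    m <- mean(g$score)
    k <- nrow(g)
    null_means <- vapply(seq_len(n_null),
                         function(i) mean(all_scores[sample.int(length(all_scores), k)]),
                         numeric(1))
    p <- if (m < 0) mean(null_means <= m) else mean(null_means >= m)
    data.frame(compound = g$compound[1],
               dose_text = paste(unique(g$dose_text), collapse = "; "),
               n = k, mean_score = m, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mean_score, out$compound), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "instance_scores") <- inst
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("compound_result", "data.frame")
  out
}

#' Top rows of a compound ranking
#'
#' @param result a [rank_compounds()] table.
#' @param k rows to keep (default 10, the usual candidate short-list).
#' @return the first `k` rows.
#' @export
top_compounds <- function(result, k = 10) {
  stopifnot(inherits(result, "compound_result"))
  utils::head(result, k)
}
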