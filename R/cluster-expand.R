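#' Hierarchical clustering of gene profiles
#'
#' Rows are z-scored across samples, pairwise dissimilarity is
#' 1 - Pearson correlation (or Euclidean on the z-scores), and the tree
#' is built by agglomerative clustering (average linkage by default).
#' Genes with zero variance across samples cannot be z-scored and are
#' excluded with a warning.
#'
#' @param expr expression matrix restricted to the genes of interest
#'   (>= 2 genes after exclusions).
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @param linkage any method accepted by [stats::hclust()] (default
#'   `"average"`).
#' @return object of class `linkage_tree`: the `hclust` fit, `genes`
#'   (leaf labels), `excluded` (zero-variance genes).
#' @export
hierarchical_cluster <- function(expr, metric = c("pearson", "euclidean"),
                                 linkage = "average") {
  metric <- match.arg(metric)
  stopifnot(is.matrix(expr))
  sds <- matrixStats::rowSds(expr)
  excluded <- rownames(expr)[sds == 0]
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance gene(s) from clustering", length(excluded)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop_sig("sigrevert_cluster", "need >= 2 genes to cluster")
  z <- (expr - rowMeans(expr)) / matrixStats::rowSds(expr)
  dd <- if (metric == "pearson") stats::as.dist(1 - stats::cor(t(z))) else stats::dist(z)
  hc <- stats::hclust(dd, method = linkage)
  structure(list(hclust = hc, genes = hc$labels, excluded = excluded,
                 metric = metric, linkage = linkage),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree: %d leaves, %d merges (%s / %s linkage)\n",
              length(x$genes), nrow(x$hclust$merge), x$metric, x$linkage))
  invisible(x)
}

#' Leaf sets of every internal node of a linkage tree
#' @keywords internal
node_leaf_sets <- function(hc) {
  n_nodes <- nrow(hc$merge)
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    members <- integer(0)
    for (child in hc$merge[i, ]) {
      members <- c(members, if (child < 0) -child else sets[[child]])
    }
    sets[[i]] <- members
  }
  sets
}

#' Height of the dominant gap in a linkage tree
#'
#' Returns the midpoint of the largest gap between consecutive merge
#' heights — the natural place to cut a dendrogram whose leaves split
#' into a tight module plus unrelated genes. With fewer than two merges
#' (no gap to speak of) the height above the root is returned, so
#' cutting yields a single cluster.
#'
#' @param tree a [hierarchical_cluster()] result.
#' @return single numeric cut height.
#' @export
dominant_gap_height <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  h <- sort(tree$hclust$height)
  if (length(h) < 2) return(max(h) + 1)
  gaps <- diff(h)
  i <- which.max(gaps)
  (h[i] + h[i + 1]) / 2
}

#' Smallest cluster containing a set of seed genes
#'
#' Returns the leaf set of the lowest internal node whose subtree holds
#' every seed gene — the operational reading of "genes that clustered
#' together with" a validated gene list. A single seed returns just that
#' gene.
#'
#' @param tree a [hierarchical_cluster()] result.
#' @param seed_genes character vector of leaf genes.
#' @param cut_height optional alternative: instead of the minimal
#'   containing subtree, cut the tree at this height and return the
#'   union of the seed genes' clusters.
#' @return character vector of member genes (always a superset of the
#'   seeds).
#' @export
minimal_containing_cluster <- function(tree, seed_genes, cut_height = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  seed_genes <- unique(as.character(seed_genes))
  if (!length(seed_genes)) stop_sig("sigrevert_cluster", "empty seed set")
  missing <- setdiff(seed_genes, tree$genes)
  if (length(missing)) {
    stop_sig("sigrevert_cluster",
             sprintf("seed gene(s) not in tree: %s", paste(missing, collapse = ", ")))
  }
  hc <- tree$hclust
  if (!is.null(cut_height)) {
    cl <- stats::cutree(hc, h = cut_height)
    return(sort(names(cl)[cl %in% unique(cl[seed_genes])]))
  }
  if (length(seed_genes) == 1) return(seed_genes)
  seed_idx <- match(seed_genes, hc$labels)
  sets <- node_leaf_sets(hc)
  sizes <- lengths(sets)
  containing <- which(vapply(sets, function(s) all(seed_idx %in% s), logical(1)))
  best <- containing[which.min(sizes[containing])]
  sort(hc$labels[sets[[best]]])
}
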