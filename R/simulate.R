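#' Planted multi-organ experimental design
#'
#' Describes the synthetic world the generator emulates: a 4-organ x
#' 3-replicate metastasis panel with one target organ carrying a planted
#' up-regulated gene module and a planted down-regulated gene set, plus
#' a private nuisance module per non-target organ. Effects are additive
#' on the log2 scale; module members share an equicorrelated noise term.
#'
#' @param n_genes total genes simulated (default 1000).
#' @param organs organ labels; the first is the target (default brain,
#'   adrenal, ovary, bone).
#' @param replicates samples per organ (default 3).
#' @param up_size,up_effect,up_cor target-organ up module: size 54,
#'   effect 4.0 log2 units, within-module correlation 0.5.
#' @param down_size,down_effect target-organ down set: size 54, effect
#'   4.0 (applied with negative sign); members are mutually independent.
#' @param nuisance_size,nuisance_effect,nuisance_cor one up-module per
#'   non-target organ (size 20, effect 2.0, correlation 0.5) so the
#'   non-target organs are themselves distinguishable.
#' @param sigma per-gene Gaussian noise s.d. on log2 scale (default 0.5).
#' @param baseline_mean,baseline_sd per-gene baseline abundance drawn
#'   once per gene from N(baseline_mean, baseline_sd^2) (defaults 7, 2).
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_genes = 1000,
                           organs = c("brain", "adrenal", "ovary", "bone"),
                           replicates = 3,
                           up_size = 54, up_effect = 4, up_cor = 0.5,
                           down_size = 54, down_effect = 4,
                           nuisance_size = 20, nuisance_effect = 2,
                           nuisance_cor = 0.5,
                           sigma = 0.5,
                           baseline_mean = 7, baseline_sd = 2) {
  stopifnot(length(organs) >= 2, !anyDuplicated(organs), replicates >= 2,
            up_effect > 0, down_effect > 0, nuisance_effect >= 0, sigma > 0,
            up_cor >= 0, up_cor < 1, nuisance_cor >= 0, nuisance_cor < 1)
  planted_total <- up_size + down_size + nuisance_size * (length(organs) - 1)
  if (planted_total >= n_genes) {
    stop_sig("sigrevert_design", "planted sets must not exhaust the gene universe")
  }
  structure(list(n_genes = n_genes, organs = organs, target = organs[1],
                 replicates = replicates,
                 up_size = up_size, up_effect = up_effect, up_cor = up_cor,
                 down_size = down_size, down_effect = down_effect,
                 nuisance_size = nuisance_size, nuisance_effect = nuisance_effect,
                 nuisance_cor = nuisance_cor, sigma = sigma,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "planted_design")
}

#' Simulate a multi-organ expression matrix with planted structure
#'
#' Gene g in sample s takes value
#' `baseline_g + effect(g, organ(s)) + module(g, s) + noise`, where the
#' module term is `sigma * sqrt(rho) * u_{m,s}` shared by all members of
#' a planted module and the independent term is
#' `sigma * sqrt(1 - rho) * eps_{g,s}` (rho = 0 outside modules). The
#' same seed reproduces the matrix bit for bit.
#'
#' @param design a [planted_design()].
#' @param seed integer seed.
#' @return list with `expr` (matrix), `sheet` (sample sheet data.frame)
#'   and `truth` (planted memberships: `up`, `down`, and a per-organ
#'   `nuisance` list).
#' @export
simulate_multiorgan_expression <- function(design = planted_design(), seed = 1L) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(as.integer(seed))
  d <- design
  genes <- sprintf("G%04d", seq_len(d$n_genes))
  n_samp <- length(d$organs) * d$replicates
  sheet <- data.frame(
    sample_id = paste0(rep(d$organs, each = d$replicates), "_",
                       rep(seq_len(d$replicates), length(d$organs))),
    organ = rep(d$organs, each = d$replicates),
    replicate = rep(seq_len(d$replicates), length(d$organs)),
    stringsAsFactors = FALSE)

  idx <- seq_len(d$up_size)
  up_genes <- genes[idx]
  down_genes <- genes[d$up_size + seq_len(d$down_size)]
  nuis <- list()
  off <- d$up_size + d$down_size
  for (o in d$organs[-1]) {
    nuis[[o]] <- genes[off + seq_len(d$nuisance_size)]
    off <- off + d$nuisance_size
  }

  baseline <- stats::rnorm(d$n_genes, d$baseline_mean, d$baseline_sd)
  expr <- matrix(baseline, nrow = d$n_genes, ncol = n_samp,
                 dimnames = list(genes, sheet$sample_id))

  target_cols <- sheet$organ == d$target
  expr[up_genes, target_cols] <- expr[up_genes, target_cols] + d$up_effect
  expr[down_genes, target_cols] <- expr[down_genes, target_cols] - d$down_effect
  for (o in names(nuis)) {
    expr[nuis[[o]], sheet$organ == o] <- expr[nuis[[o]], sheet$organ == o] + d$nuisance_effect
  }

  # equicorrelated noise inside modules, independent elsewhere
  rho <- rep(0, d$n_genes); names(rho) <- genes
  rho[up_genes] <- d$up_cor
  module_of <- rep(NA_character_, d$n_genes); names(module_of) <- genes
  module_of[up_genes] <- "up"
  for (o in names(nuis)) {
    rho[nuis[[o]]] <- d$nuisance_cor
    module_of[nuis[[o]]] <- o
  }
  modules <- unique(module_of[!is.na(module_of)])
  shared <- matrix(stats::rnorm(length(modules) * n_samp), length(modules), n_samp,
                   dimnames = list(modules, NULL))
  eps <- matrix(stats::rnorm(d$n_genes * n_samp), d$n_genes, n_samp)
  noise <- d$sigma * sqrt(1 - rho) * eps
  in_mod <- !is.na(module_of)
  noise[in_mod, ] <- noise[in_mod, ] +
    d$sigma * sqrt(rho[in_mod]) * shared[module_of[in_mod], , drop = FALSE]
  expr <- expr + noise

  validate_expression(expr, sheet)
  list(expr = expr, sheet = sheet,
       truth = list(up = up_genes, down = down_genes, nuisance = nuis))
}

#' Planted compound for the synthetic instance database
#'
#' @param label compound name.
#' @param role `"null"` (uniform-random rank vectors), `"inverter"`
#'   (pushes query down-tags to the top and up-tags to the bottom) or
#'   `"mimic"` (the mirror image).
#' @param strength in (0, 1]: the probability that each tag probe is
#'   moved to its extreme block; at 1 the arrangement is exact.
#' @return object of class `planted_compound`.
#' @export
planted_compound <- function(label, role = c("null", "inverter", "mimic"),
                             strength = 1) {
  role <- match.arg(role)
  stopifnot(nzchar(label), strength > 0, strength <= 1)
  structure(list(label = label, role = role, strength = strength),
            class = "planted_compound")
}

#' Simulate a drug-perturbation instance database
#'
#' Null compounds receive uniform-random permutations of the probe
#' universe. An inverter of strength p moves each query down-tag probe
#' with probability p into the top block (ranks 1..k, random order
#' within the block) and each up-tag probe into the bottom block; a
#' mimic is the mirror image. At strength 1 the arrangement is exact, so
#' a strength-1 inverter attains the most negative possible raw
#' connectivity score for the query.
#'
#' @param probes probe universe: a character vector of probe IDs, or a
#'   single integer n (IDs are then generated as `p<i>_at`).
#' @param tagsets list with character elements `up` and `down`, subsets
#'   of the universe, disjoint.
#' @param compounds list of [planted_compound()] objects.
#' @param instances_per_compound instances simulated per compound.
#' @param seed integer seed.
#' @param cell_line,dose_text metadata filled verbatim into every
#'   instance.
#' @return an [instance_db()] whose `meta` carries extra ground-truth
#'   columns `role` and `strength`.
#' @export
simulate_instance_db <- function(probes, tagsets, compounds,
                                 instances_per_compound = 1, seed = 1L,
                                 cell_line = "SYN1", dose_text = "10uM") {
  if (is.numeric(probes) && length(probes) == 1) {
    probes <- sprintf("p%05d_at", seq_len(probes))
  }
  n <- length(probes)
  up <- tagsets$up; down <- tagsets$down
  if (!all(c(up, down) %in% probes)) {
    stop_sig("sigrevert_tagset", "tag sets must lie inside the probe universe")
  }
  if (length(up) + length(down) >= n) {
    stop_sig("sigrevert_tagset", "tag sets larger than the free probe universe")
  }
  stopifnot(instances_per_compound >= 1, length(compounds) >= 1)
  set.seed(as.integer(seed))

  cols <- list(); meta <- list(); k <- 0L
  for (cmp in compounds) {
    stopifnot(inherits(cmp, "planted_compound"))
    for (i in seq_len(instances_per_compound)) {
      k <- k + 1L
      top <- character(0); bottom <- character(0)
      if (cmp$role != "null") {
        # which tag probes get pulled to their extreme block
        pick <- function(tags) tags[stats::runif(length(tags)) <= cmp$strength]
        if (cmp$role == "inverter") { top <- pick(down); bottom <- pick(up) }
        else                        { top <- pick(up);   bottom <- pick(down) }
      }
      mid <- setdiff(probes, c(top, bottom))
      ordering <- c(sample(top), sample(mid), sample(bottom))
      ranks <- match(probes, ordering)
      cols[[k]] <- ranks
      meta[[k]] <- data.frame(instance_id = sprintf("inst_%04d", k),
                              compound = cmp$label, cell_line = cell_line,
                              dose_text = dose_text, role = cmp$role,
                              strength = cmp$strength, stringsAsFactors = FALSE)
    }
  }
  ranks <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  rownames(ranks) <- probes
  colnames(ranks) <- meta$instance_id
  instance_db(ranks, meta)
}

#' Simulate an incomplete probe annotation for a gene universe
#'
#' Emulates partial platform coverage: a fixed fraction of genes receive
#' at least one probe and, of those, a fraction receive two.
#'
#' @param gene_ids gene symbols to annotate.
#' @param mapped_fraction fraction of genes given >= 1 probe; the mapped
#'   count is `ceiling(mapped_fraction * length(gene_ids))`.
#' @param multiprobe_fraction fraction of mapped genes given a second
#'   probe (rounded).
#' @param seed integer seed.
#' @return a [probe_map()] whose universe is exactly the generated
#'   probes.
#' @export
simulate_probe_annotation <- function(gene_ids, mapped_fraction = 1,
                                      multiprobe_fraction = 0, seed = 1L) {
  stopifnot(mapped_fraction >= 0, mapped_fraction <= 1,
            multiprobe_fraction >= 0, multiprobe_fraction <= 1)
  set.seed(as.integer(seed))
  n_map <- ceiling(mapped_fraction * length(gene_ids))
  mapped <- sort(sample(gene_ids, n_map))
  n_multi <- round(multiprobe_fraction * n_map)
  multi <- if (n_multi) sort(sample(mapped, n_multi)) else character(0)
  map <- list(); universe <- character(0); p <- 0L
  for (g in mapped) {
    p <- p + 1L
    ids <- sprintf("%05d_at", p)
    if (g %in% multi) {
      p <- p + 1L
      ids <- c(ids, sprintf("%05d_s_at", p))
    }
    map[[g]] <- ids
    universe <- c(universe, ids)
  }
  probe_map(map, universe)
}
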