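# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written as plain loops / closed forms so they
# stay independent of the package's vectorized implementations.

# small genes x samples matrix with a standard 2-organ or 4-organ sheet
make_expr <- function(n_genes = 20, organs = c("brain", "adrenal"),
                      replicates = 3, mean = 5, sd = 1, seed = 42) {
  set.seed(seed)
  sheet <- data.frame(
    sample_id = paste0(rep(organs, each = replicates), "_", seq_len(replicates)),
    organ = rep(organs, each = replicates),
    replicate = rep(seq_len(replicates), length(organs)),
    stringsAsFactors = FALSE)
  expr <- matrix(rnorm(n_genes * nrow(sheet), mean, sd), n_genes,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)), sheet$sample_id))
  list(expr = expr, sheet = sheet)
}

# brute-force KS enrichment: scan the empirical-CDF difference at every
# threshold position of the full list
ks_oracle <- function(positions, n) {
  t <- length(positions)
  hit <- numeric(n); hit[positions] <- 1
  cnt <- cumsum(hit)                      # tags at or above each threshold
  i <- seq_len(n)
  a <- max(cnt / t - i / n)               # excess of tag CDF over uniform
  b <- max(i / n - c(0, cnt[-n]) / t)     # excess of uniform over tag CDF
  if (a > b) a else -b
}

# brute-force two-class rank product: plain loops over all target x
# other sample pairs
rp_oracle <- function(expr, sheet, target) {
  tcols <- which(sheet$organ == target)
  ocols <- which(sheet$organ != target)
  ng <- nrow(expr)
  logs_up <- numeric(ng); logs_down <- numeric(ng); np <- 0
  for (ti in tcols) {
    for (oi in ocols) {
      d <- expr[, ti] - expr[, oi]
      r_up <- rank(-d, ties.method = "average")
      r_down <- rank(d, ties.method = "average")
      logs_up <- logs_up + log(r_up)
      logs_down <- logs_down + log(r_down)
      np <- np + 1
    }
  }
  list(rp_up = unname(exp(logs_up / np)), rp_down = unname(exp(logs_down / np)))
}

# pooled-variance two-sample t (the unmoderated classic) as the
# independent DE cross-check
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  tt <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
}

# shrunken-centroid statistic computed directly from its definition
pam_d_oracle <- function(expr, organ, gene, class) {
  classes <- sort(unique(organ))
  x <- expr[gene, ]
  n <- length(x); nk <- sum(organ == class)
  xbar <- mean(x)
  xbark <- mean(x[organ == class])
  ss <- 0
  for (k in classes) ss <- ss + sum((x[organ == k] - mean(x[organ == k]))^2)
  s_gene <- function(g) {
    v <- expr[g, ]; tot <- 0
    for (k in classes) tot <- tot + sum((v[organ == k] - mean(v[organ == k]))^2)
    sqrt(tot / (n - length(classes)))
  }
  s_all <- vapply(rownames(expr), s_gene, numeric(1))
  s0 <- median(s_all)
  mk <- sqrt(1 / nk - 1 / n)
  unname((xbark - xbar) / (mk * (s_all[gene] + s0)))
}

# equicorrelated gene module on top of independent noise genes: the
# fixture behind the cluster-expansion checks
make_module_fixture <- function(n_module = 54, n_noise = 30, n_samples = 12,
                                rho = 0.9, seed = 7) {
  set.seed(seed)
  shared <- rnorm(n_samples)
  module <- t(sapply(seq_len(n_module), function(i)
    sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n_samples)))
  noise <- matrix(rnorm(n_noise * n_samples), n_noise)
  expr <- rbind(module, noise)
  rownames(expr) <- c(sprintf("M%03d", seq_len(n_module)),
                      sprintf("N%03d", seq_len(n_noise)))
  colnames(expr) <- sprintf("S%02d", seq_len(n_samples))
  list(expr = expr, module = rownames(expr)[seq_len(n_module)],
       noise = rownames(expr)[n_module + seq_len(n_noise)])
}

# connected component of the correlation-threshold graph containing a
# seed gene — the stated oracle for "clusters together"
cor_component_oracle <- function(expr, seed_gene, r0 = 0.5) {
  cc <- cor(t(expr))
  members <- seed_gene
  repeat {
    nb <- rownames(cc)[apply(cc[members, , drop = FALSE] >= r0, 2, any)]
    nb <- union(members, nb)
    if (setequal(nb, members)) break
    members <- nb
  }
  sort(members)
}

# tiny instance database with planted roles over an explicit universe
make_db <- function(n_probes = 60, n_up = 5, n_down = 5, seed = 3,
                    roles = c(rep("null", 9), "inverter"),
                    strength = 1, instances_per_compound = 1) {
  probes <- sprintf("p%03d_at", seq_len(n_probes))
  tags <- list(up = probes[seq_len(n_up)],
               down = probes[n_up + seq_len(n_down)])
  comps <- lapply(seq_along(roles), function(i)
    planted_compound(sprintf("cmp_%02d_%s", i, roles[i]), roles[i], strength))
  db <- simulate_instance_db(probes, tags, comps,
                             instances_per_compound = instances_per_compound,
                             seed = seed)
  list(db = db, tags = tags, probes = probes, roles = roles)
}
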