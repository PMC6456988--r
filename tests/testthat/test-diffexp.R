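test_that("pairwise_de recovers planted effects and rejects bad organs", {
  fx <- make_expr(n_genes = 200, organs = c("brain", "bone"), sd = 0.1, seed = 5)
  fx$expr[1:5, fx$sheet$organ == "brain"] <- fx$expr[1:5, fx$sheet$organ == "brain"] + 4
  de <- pairwise_de(fx$expr, fx$sheet, "brain", "bone")
  # planted genes: adjusted p below 0.05, positive sign, log2FC near 4
  expect_true(all(de$padj[1:5] < 0.05))
  expect_true(all(de$t[1:5] > 0))
  expect_equal(de$log2fc[1:5], rep(4, 5), tolerance = 0.15)
  # log2FC is exactly the group-mean difference
  g <- 17
  m <- mean(fx$expr[g, fx$sheet$organ == "brain"]) -
       mean(fx$expr[g, fx$sheet$organ == "bone"])
  expect_equal(de$log2fc[g], m, tolerance = 1e-12)
  expect_error(pairwise_de(fx$expr, fx$sheet, "brain", "brain"),
               class = "sigrevert_de")
  expect_error(pairwise_de(fx$expr, fx$sheet, "brain", "liver"),
               class = "sigrevert_de")
  # adjusted p never below raw p
  expect_true(all(de$padj >= de$p - 1e-15))
})

test_that("moderated DE agrees with an unmoderated pooled-t oracle on strong effects", {
  fx <- make_expr(n_genes = 300, organs = c("brain", "ovary"), sd = 0.5, seed = 9)
  planted <- 1:20
  fx$expr[planted, fx$sheet$organ == "brain"] <-
    fx$expr[planted, fx$sheet$organ == "brain"] + 4
  de <- pairwise_de(fx$expr, fx$sheet, "brain", "ovary")
  p_oracle <- vapply(seq_len(nrow(fx$expr)), function(g)
    pooled_t_oracle(fx$expr[g, fx$sheet$organ == "brain"],
                    fx$expr[g, fx$sheet$organ == "ovary"]), numeric(1))
  # both routes must call every planted gene and the two p-value sets
  # must be strongly concordant overall
  padj_oracle <- p.adjust(p_oracle, "BH")
  expect_true(all(de$padj[planted] < 0.05))
  expect_gt(cor(log10(de$p), log10(p_oracle), method = "spearman"), 0.9)
})

test_that("null data yields uniform raw p-values and near-zero BH calls", {
  counts <- integer(0); bh_calls <- integer(0)
  for (s in 1:5) {
    fx <- make_expr(n_genes = 1000, organs = c("brain", "adrenal"),
                    sd = 0.5, seed = 100 + s)
    de <- pairwise_de(fx$expr, fx$sheet, "brain", "adrenal")
    counts <- c(counts, sum(de$p <= 0.05))
    bh_calls <- c(bh_calls, sum(de$padj <= 0.05))
  }
  # binomial 99% bounds for 5 x 1000 uniform p-values at alpha = 0.05
  total <- sum(counts)
  expect_gte(total, qbinom(0.005, 5000, 0.05))
  expect_lte(total, qbinom(0.995, 5000, 0.05))
  expect_lte(sum(bh_calls), 5)
})

test_that("candidate set takes the union over organs with membership records", {
  fx <- make_expr(n_genes = 50, organs = c("brain", "adrenal", "ovary", "bone"),
                  sd = 0.1, seed = 21)
  brain <- fx$sheet$organ == "brain"
  adrenal <- fx$sheet$organ == "adrenal"
  bone <- fx$sheet$organ == "bone"
  # G001: up vs every organ; G002: up only vs ovary;
  # G003: up vs adrenal but down vs bone (enters both lists)
  fx$expr[1, brain] <- fx$expr[1, brain] + 4
  fx$expr[2, fx$sheet$organ == "ovary"] <- fx$expr[2, fx$sheet$organ == "ovary"] - 4
  fx$expr[3, adrenal] <- fx$expr[3, adrenal] - 4
  fx$expr[3, bone] <- fx$expr[3, bone] + 4
  cmps <- lapply(c("adrenal", "ovary", "bone"),
                 function(o) pairwise_de(fx$expr, fx$sheet, "brain", o))
  cand <- build_candidate_set(cmps, de_fdr = 0.05, de_min_abs_log2fc = 1)
  expect_true(all(c("G001", "G002", "G003") %in% cand$up))
  expect_true("G003" %in% cand$down)       # down vs bone, up vs adrenal
  m3 <- cand$membership[cand$membership$gene == "G003", ]
  expect_setequal(paste(m3$comparison, m3$direction),
                  c("adrenal up", "bone down"))
  # degenerate thresholds empty the set
  none <- build_candidate_set(cmps, de_fdr = 1e-12, de_min_abs_log2fc = Inf)
  expect_equal(length(none$up), 0)
  expect_equal(length(none$down), 0)
  expect_error(build_candidate_set(list()), class = "sigrevert_de")
})

test_that("adding a comparison never shrinks the candidate set", {
  fx <- make_expr(n_genes = 300, organs = c("brain", "adrenal", "ovary", "bone"),
                  sd = 0.5, seed = 31)
  fx$expr[1:20, fx$sheet$organ == "brain"] <- fx$expr[1:20, fx$sheet$organ == "brain"] + 3
  cmps <- lapply(c("adrenal", "ovary", "bone"),
                 function(o) pairwise_de(fx$expr, fx$sheet, "brain", o))
  prev_up <- character(0); prev_down <- character(0)
  for (k in 1:3) {
    cand <- build_candidate_set(cmps[1:k], 0.05, 1)
    expect_true(all(prev_up %in% cand$up))
    expect_true(all(prev_down %in% cand$down))
    prev_up <- cand$up; prev_down <- cand$down
  }
})
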