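test_that("rank product matches the brute-force pairwise oracle", {
  for (s in 1:3) {
    fx <- make_expr(n_genes = 40, organs = c("brain", "adrenal", "bone"),
                    replicates = 2, seed = 50 + s)
    rp <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 100, seed = s)
    oracle <- rp_oracle(fx$expr, fx$sheet, "brain")
    expect_equal(rp$rp_up, oracle$rp_up, tolerance = 1e-12)
    expect_equal(rp$rp_down, oracle$rp_down, tolerance = 1e-12)
    # meta mode shares the observed rank products
    rp_m <- rank_product(fx$expr, fx$sheet, "brain", "meta", n_perm = 100, seed = s)
    expect_equal(rp_m$rp_up, rp$rp_up, tolerance = 1e-12)
  }
})

test_that("a gene leading every pairwise list attains the minimum rank product", {
  fx <- make_expr(n_genes = 30, organs = c("brain", "adrenal"), sd = 0.3, seed = 4)
  fx$expr[1, fx$sheet$organ == "brain"] <- fx$expr[1, fx$sheet$organ == "brain"] + 50
  rp <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 100, seed = 1)
  expect_equal(rp$rp_up[1], 1)             # rank 1 in all 9 pairs
  expect_equal(rp$pos_up[1], 1)
  expect_equal(rp$rp_down[1], 30)          # mirrored: last in every list
})

test_that("rank product is invariant to monotone transformation of expression", {
  fx <- make_expr(n_genes = 25, organs = c("brain", "ovary"), seed = 12)
  rp1 <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 100, seed = 2)
  # strictly monotone map applied to all values preserves all pairwise
  # difference orderings gene-by-gene only if applied per sample pair;
  # a global affine map is the safe monotone case
  rp2 <- rank_product(fx$expr * 3 + 7, fx$sheet, "brain", "pooled",
                      n_perm = 100, seed = 2)
  expect_equal(rp1$rp_up, rp2$rp_up, tolerance = 1e-12)
  expect_equal(rp1$pfp_up, rp2$pfp_up, tolerance = 1e-12)
})

test_that("pfp is monotone along the rank ordering and reproducible", {
  fx <- make_expr(n_genes = 60, organs = c("brain", "adrenal", "ovary"), seed = 33)
  rp <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 120, seed = 5)
  ord <- order(rp$rp_up, rp$gene)
  expect_true(all(diff(rp$pfp_up[ord]) >= -1e-12))
  ord_d <- order(rp$rp_down, rp$gene)
  expect_true(all(diff(rp$pfp_down[ord_d]) >= -1e-12))
  expect_true(all(rp$rp_up >= 1) && all(rp$rp_down >= 1))
  expect_true(all(rp$pfp_up >= 0))
  rp2 <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 120, seed = 5)
  expect_identical(rp, rp2)
  expect_error(rank_product(fx$expr, fx$sheet, "brain", n_perm = 10),
               class = "sigrevert_rp")
  expect_error(rank_product(fx$expr, fx$sheet, "liver"), class = "sigrevert_rp")
})

test_that("exchangeable null data stays near the nominal pfp call rate", {
  calls <- 0L
  for (s in 1:4) {
    fx <- make_expr(n_genes = 50, organs = c("brain", "adrenal", "ovary", "bone"),
                    seed = 200 + s)
    rp <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 100, seed = s)
    calls <- calls + sum(rp$pfp_up < 0.01)
  }
  # 1% of 200 gene-tests plus generous binomial slack
  expect_lte(calls, qbinom(0.995, 200, 0.01) + 3)
})

test_that("top_downregulated returns k genes with stable lexicographic ties", {
  fx <- make_expr(n_genes = 30, organs = c("brain", "bone"), seed = 8)
  fx$expr[5:10, fx$sheet$organ == "brain"] <- fx$expr[5:10, fx$sheet$organ == "brain"] - 20
  rp <- rank_product(fx$expr, fx$sheet, "brain", "pooled", n_perm = 100, seed = 3)
  top <- top_downregulated(rp, 6)
  expect_setequal(top, sprintf("G%03d", 5:10))
  expect_equal(top_downregulated(rp, 0), character(0))
  expect_error(top_downregulated(rp, 31), class = "sigrevert_rp")
  # exact ties fall back to symbol order, stable across calls
  rp$rp_down[1:2] <- 0.5
  expect_equal(top_downregulated(rp, 2), sort(rp$gene[1:2]))
  rp_meta <- rank_product(fx$expr, fx$sheet, "brain", "meta", n_perm = 100, seed = 3)
  expect_error(top_downregulated(rp_meta, 3), class = "sigrevert_rp")
})

test_that("SAM separates a planted gene with an exhaustive permutation null", {
  fx <- make_expr(n_genes = 100, organs = c("brain", "adrenal", "ovary", "bone"),
                  sd = 0.1, seed = 77)
  fx$expr[1, fx$sheet$organ == "brain"] <- fx$expr[1, fx$sheet$organ == "brain"] + 4
  sam <- sam_test(fx$expr, fx$sheet, "brain", n_perm = 250, seed = 1)
  expect_true(attr(sam, "exhaustive"))     # all C(12,3) = 220 assignments
  expect_equal(attr(sam, "n_perm_used"), 220)
  expect_equal(which.max(abs(sam$d)), 1)
  expect_lt(sam$q[1], 0.05)
  expect_gt(sam$d[1], 0)
  # d sign equals the sign of the mean difference, every gene
  signs <- sign(rowMeans(fx$expr[, fx$sheet$organ == "brain"]) -
                rowMeans(fx$expr[, fx$sheet$organ != "brain"]))
  expect_true(all(sign(sam$d) == signs | sam$d == 0))
})

test_that("SAM gives d = 0, q = 1 for constant genes and monotone q", {
  fx <- make_expr(n_genes = 50, organs = c("brain", "bone"), seed = 14)
  fx$expr[7, ] <- 3.14                      # constant gene
  sam <- sam_test(fx$expr, fx$sheet, "brain", n_perm = 100, seed = 2)
  expect_equal(sam$d[7], 0)
  expect_equal(sam$q[7], 1)
  ord <- order(-abs(sam$d), sam$gene)
  expect_true(all(diff(sam$q[ord]) >= -1e-12))
  expect_true(all(sam$q >= 0 & sam$q <= 1))
  sam2 <- sam_test(fx$expr, fx$sheet, "brain", n_perm = 100, seed = 2)
  expect_identical(sam, sam2)
})

test_that("SAM null calls on exchangeable data stay near the nominal rate", {
  calls <- 0L
  for (s in 1:4) {
    fx <- make_expr(n_genes = 50, organs = c("brain", "adrenal", "ovary", "bone"),
                    seed = 300 + s)
    sam <- sam_test(fx$expr, fx$sheet, "brain", n_perm = 100, seed = s)
    calls <- calls + sum(sam$q < 0.05)
  }
  expect_lte(calls, qbinom(0.995, 200, 0.05) + 5)
})
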