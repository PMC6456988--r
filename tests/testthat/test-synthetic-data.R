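test_that("multi-organ simulator is deterministic and matches its design", {
  d <- planted_design()
  a <- simulate_multiorgan_expression(d, seed = 1)
  b <- simulate_multiorgan_expression(d, seed = 1)
  expect_identical(a$expr, b$expr)          # same seed, bit-identical
  expect_equal(dim(a$expr), c(1000, 12))    # 4 organs x 3 replicates
  expect_equal(sort(unique(a$sheet$organ)), sort(d$organs))
  # ground truth covers every planted entity and the sets are disjoint
  expect_equal(length(a$truth$up), 54)
  expect_equal(length(a$truth$down), 54)
  expect_equal(lengths(a$truth$nuisance), c(adrenal = 20, ovary = 20, bone = 20))
  all_planted <- c(a$truth$up, a$truth$down, unlist(a$truth$nuisance))
  expect_equal(anyDuplicated(all_planted), 0)
  c_ <- simulate_multiorgan_expression(d, seed = 2)
  expect_false(identical(a$expr, c_$expr))
})

test_that("planted effect sizes are recovered by direct group means", {
  sim <- simulate_multiorgan_expression(planted_design(), seed = 11)
  brain <- sim$sheet$sample_id[sim$sheet$organ == "brain"]
  rest <- setdiff(colnames(sim$expr), brain)
  # oracle: per planted gene, mean(target) - mean(others) ~ effect
  # within 3 standard errors of the group-mean difference
  for (g in sim$truth$up[1:10]) {
    diffs <- mean(sim$expr[g, brain]) - mean(sim$expr[g, rest])
    se <- sqrt(0.5^2 / 3 + 0.5^2 / 9)
    expect_lt(abs(diffs - 4), 3 * se)
  }
  for (g in sim$truth$down[1:10]) {
    diffs <- mean(sim$expr[g, brain]) - mean(sim$expr[g, rest])
    se <- sqrt(0.5^2 / 3 + 0.5^2 / 9)
    expect_lt(abs(diffs + 4), 3 * se)
  }
  # planted sets too large for the universe are rejected
  expect_error(planted_design(n_genes = 100), class = "sigrevert_design")
})

test_that("instance simulator plants exact inverters and valid permutations", {
  fx <- make_db(n_probes = 60, n_up = 5, n_down = 5,
                roles = c(rep("null", 18), "inverter", "mimic"),
                instances_per_compound = 2)
  db <- fx$db
  expect_equal(ncol(db$ranks), 40)          # 20 compounds x 2 instances
  # every column is a permutation (the constructor enforces it; check one)
  expect_setequal(db$ranks[, 1], 1:60)
  # strength-1 inverter: down tags occupy ranks 1..|down|, up tags the bottom
  inv_cols <- which(db$meta$role == "inverter")
  for (j in inv_cols) {
    r <- db$ranks[, j]; names(r) <- db$probe_ids
    expect_setequal(unname(r[fx$tags$down]), 1:5)
    expect_setequal(unname(r[fx$tags$up]), 56:60)
  }
  mim_cols <- which(db$meta$role == "mimic")
  for (j in mim_cols) {
    r <- db$ranks[, j]; names(r) <- db$probe_ids
    expect_setequal(unname(r[fx$tags$up]), 1:5)
    expect_setequal(unname(r[fx$tags$down]), 56:60)
  }
  # determinism and tag-set validation
  again <- make_db(n_probes = 60, n_up = 5, n_down = 5,
                   roles = c(rep("null", 18), "inverter", "mimic"),
                   instances_per_compound = 2)
  expect_identical(again$db$ranks, db$ranks)
  probes <- sprintf("p%03d_at", 1:10)
  expect_error(
    simulate_instance_db(probes, list(up = "zzz_at", down = probes[2]),
                         list(planted_compound("c", "null"))),
    class = "sigrevert_tagset")
})

test_that("probe annotation simulator hits requested coverage exactly", {
  genes <- sprintf("G%03d", 1:54)
  # full bijection
  pm <- simulate_probe_annotation(genes, mapped_fraction = 1,
                                  multiprobe_fraction = 0, seed = 1)
  expect_equal(length(pm$map), 54)
  expect_equal(length(pm$universe), 54)
  expect_true(all(lengths(pm$map) == 1))
  # partial-coverage shape: 37 of 54 genes carry at least one probe
  pm2 <- simulate_probe_annotation(genes, mapped_fraction = 37 / 54, seed = 2)
  expect_equal(length(pm2$map), 37)
  # reproducible under the same seed
  pm3 <- simulate_probe_annotation(genes, mapped_fraction = 37 / 54, seed = 2)
  expect_identical(pm3$map, pm2$map)
  # multiprobe fraction: 18 of 37 mapped genes get a second probe -> 55 probes
  pm4 <- simulate_probe_annotation(genes, mapped_fraction = 37 / 54,
                                   multiprobe_fraction = 18 / 37, seed = 3)
  expect_equal(length(pm4$map), 37)
  expect_equal(length(pm4$universe), 55)
})
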