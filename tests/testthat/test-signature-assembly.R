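# the full derivation is exercised once on the default planted panel
# and its outputs shared across assertions (permutations dominate cost)
sim_default <- simulate_multiorgan_expression(planted_design(), seed = 101)
sig_default <- derive_signature(sim_default$expr, sim_default$sheet,
                                workflow_config(seed = 101))

test_that("provenance chain of the five-step derivation is internally consistent", {
  pv <- sig_default$provenance
  expect_true(all(pv$validated %in% pv$markers))
  expect_true(all(pv$validated %in% sig_default$up))
  expect_lte(pv$counts$validated, pv$counts$markers)
  expect_lte(pv$counts$markers, pv$counts$candidates_up)
  expect_equal(pv$counts$up, pv$counts$validated + pv$counts$cluster_additions)
  expect_equal(pv$counts$total, length(sig_default$up) + length(sig_default$down))
  expect_equal(length(intersect(sig_default$up, sig_default$down)), 0)
  # thresholds and seeds are embedded
  expect_equal(pv$thresholds$pfp_cutoff, 0.01)
  expect_equal(pv$thresholds$sam_q_cutoff, 0.05)
  expect_equal(pv$seed, 101)
})

test_that("derivation is reproducible bit for bit under the same config", {
  sig2 <- derive_signature(sim_default$expr, sim_default$sheet,
                           workflow_config(seed = 101))
  expect_identical(sig2$up, sig_default$up)
  expect_identical(sig2$down, sig_default$down)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    write_signature(sig_default, file.path(d, "s.gmt"),
                    file.path(d, "up.grp"), file.path(d, "down.grp"))
  }
  expect_identical(readLines(file.path(d1, "s.gmt")),
                   readLines(file.path(d2, "s.gmt")))
})

test_that("signature ordering is markers-first then alphabetical additions", {
  pv <- sig_default$provenance
  nv <- length(pv$validated)
  expect_identical(sig_default$up[seq_len(nv)], pv$validated)
  additions <- sig_default$up[-seq_len(nv)]
  expect_identical(additions, sort(additions))
})

test_that("derivation without planted signal fails with a named no-signature error", {
  fx <- make_expr(n_genes = 300, organs = c("brain", "adrenal", "ovary", "bone"),
                  sd = 0.5, seed = 55)
  expect_error(derive_signature(fx$expr, fx$sheet, workflow_config(seed = 55)),
               class = "sigrevert_no_signature")
})

test_that("probe mapping handles partial coverage and multi-probe genes exactly", {
  # up: 37 of 54 genes mapped, 18 of them on two probes -> 55 probes;
  # down: 29 of 54 mapped, 11 doubled -> 40 probes
  up <- sprintf("UP%02d", 1:54); down <- sprintf("DN%02d", 1:54)
  sig <- gene_signature(up, down, name = "fixture")
  map <- list(); universe <- character(0); k <- 0
  add <- function(genes, n_mapped, n_double, prefix) {
    for (i in seq_len(n_mapped)) {
      k <<- k + 1; ids <- sprintf("%s%04d_at", prefix, k)
      if (i <= n_double) { k <<- k + 1; ids <- c(ids, sprintf("%s%04d_at", prefix, k)) }
      map[[genes[i]]] <<- ids
      universe <<- c(universe, ids)
    }
  }
  add(up, 37, 18, "U"); add(down, 29, 11, "D")
  pm <- probe_map(map, universe)
  tags <- map_signature_to_probes(sig, pm)
  expect_equal(tags$report$up_mapped_genes, 37)
  expect_equal(tags$report$up_probes, 55)
  expect_equal(tags$report$down_mapped_genes, 29)
  expect_equal(tags$report$down_probes, 40)
  expect_setequal(tags$report$up_unmapped, up[38:54])
  expect_equal(length(tags$up), 55)
  # disjointness is enforced when one probe serves both directions
  map2 <- map; map2[[down[1]]] <- c(map2[[down[1]]], map2[[up[1]]][1])
  tags2 <- map_signature_to_probes(sig, probe_map(map2, universe))
  expect_equal(tags2$report$ambiguous_probes, map[[up[1]]][1])
  expect_false(map[[up[1]]][1] %in% tags2$up)
  expect_false(map[[up[1]]][1] %in% tags2$down)
  # a signature with no mapped gene at all is an error
  pm_none <- probe_map(list(OTHER = "X1_at"), "X1_at")
  expect_error(map_signature_to_probes(sig, pm_none),
               class = "sigrevert_empty_tagsets")
})
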