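---
title: "Deriving an organ-tropic signature and ranking signature-reverting compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving an organ-tropic signature and ranking signature-reverting compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A tumor that metastasizes to several organs offers a natural contrast:
tumor cells recovered from the target organ (here called "brain"
throughout, after the motivating melanoma model) can be compared with
the same tumor's metastases in other organs to isolate an
organ-specific transcriptional program. Once that program is condensed
into an ordered list of up- and down-regulated genes — a *signature* —
it can be used as a query against a database of drug-perturbation
expression profiles: compounds whose perturbation profile *inverts* the
signature (pushes the signature's up-genes down and its down-genes up)
are candidate therapeutics for the organ-tropic disease.

`sigrevert` implements this discovery arm end to end: a five-step
signature derivation from a genes × samples expression matrix, mapping
of the signature to microarray probe *tag sets*, and
Kolmogorov–Smirnov (KS) connectivity scoring of rank-vector
perturbation instances with a ±1 scaling, the negative extreme meaning
complete signature reversal. Because the motivating experiment (4
organs × 3 replicates of sorted metastatic tumor cells) deposited no
raw data, the package carries a synthetic-data module that emulates
that design with planted ground truth, so every stage is testable
offline and the whole pipeline can be exercised with no download.

# The five-step derivation

Input: a matrix of log2(abundance + 1) values (the readers never
transform; this scale is the contract) and a sample sheet assigning
each sample to an organ, one organ designated the target.

1. **Candidate genes.** The target organ is compared with each other
   organ by limma's moderated t on the log2 values, BH-adjusted within
   each comparison. A gene is an up (down) candidate if, in *at least
   one* comparison, adjusted p ≤ `de_fdr` (default 0.05) and log2 fold
   change ≥ 1 (≤ −1). Union semantics mean a gene may be an up
   candidate through one organ and a down candidate through another;
   per-comparison membership is recorded. We use the moderated rather
   than an ordinary t because at three replicates an unmoderated
   statistic is unstable in both directions: Welch's Satterthwaite df
   collapses toward 2, and with a pooled t a single noisy target
   replicate inflates the shared group variance and silently drops
   even very large effects from all comparisons at once.
2. **Centroid markers.** Nearest-shrunken-centroid classification
   (the standard soft-thresholded construction, equal class priors) is
   fitted on the candidate up-genes over a 30-point shrinkage grid.
   The working threshold Δ\* is the *largest* grid value minimizing
   leave-one-out cross-validated error. Inside the workflow the error
   counts only target-versus-rest confusions: candidate up-genes carry
   no information separating the non-target organs from one another,
   so the overall multiclass error is noise among those organs and its
   minimizer is arbitrary, whereas the target-detection error has a
   clean plateau. Markers are the genes with a positive shrunken
   target-class difference at Δ\*.
3. **Triple validation.** A marker is *validated* if it passes all of:
   pooled rank product `pfp_up` < 0.01; meta rank product `pfp_up` <
   0.01; SAM q < 0.05 with d > 0. Conjunction (not majority) is used —
   the motivating workflow kept 8 of 10 markers through the same three
   analyses, which implies a strict filter; the rule is exposed in the
   config.
4. **Cluster expansion.** The candidate up-genes are z-scored per
   gene, clustered with average linkage under 1 − Pearson correlation,
   and the validated markers' flat cluster(s) at the co-clustering
   ceiling `expand_h_max` (default height 0.2, i.e. average
   correlation 0.8) become the up set. See "Numerical choices" for why
   the workflow cuts at a fixed ceiling rather than taking the minimal
   containing subtree (which `minimal_containing_cluster()` still
   offers as its default reading).
5. **Down appending.** The `n_down_append` (default 54) most
   downregulated genes by pooled rank product are appended as the down
   set, in rank-product order. Membership of these genes in the
   step-1 down-candidate list is recorded but not enforced; a gene
   appearing in both the up set and the down list is removed from the
   down side and recorded.

Every step writes its counts, thresholds and derived stage seeds into
the signature's provenance, and the whole derivation is reproducible
bit for bit from one master seed.

# The validation statistics

**Rank product.** For every (target replicate, other sample) pair,
genes are ranked by the pairwise log2 difference; a gene's rank
product is the geometric mean of its ranks over all pairs. The pooled
and meta readings share this observed pair set (target × all others),
so they differ only in their Monte-Carlo stream; both surfaces are
kept because the workflow consults both. The *percentage of false
prediction* (pfp) of the gene at position *i* of the observed ordering
is E(g)/i, with E(g) the pooled count of null rank products at or
below the observed value divided by the number of permutations, made
monotone by a cumulative maximum.

The null is the reference "random experiments" construction: gene
labels are permuted independently within each sample column and the
full pairwise rank products recomputed. Three alternatives fail in
instructive ways. Relabeling samples leaks planted signal whenever a
pseudo-target overlaps the true target, and a single contaminated null
value at position 1 erases every call through the cumulative maximum.
Drawing each pair's rank list independently at random ignores that
pair lists sharing a sample are rank-correlated (ρ ≈ 0.5) and is
anti-conservative. And permuting columns of the *raw* matrix
re-injects per-gene baseline variance that the observed pairwise
differences cancel, so rows are centered before the permutation.

**SAM.** d = (mean difference)/(s + s0) with s the pooled two-class
standard error and the exchangeability constant s0 fixed at the median
of the per-gene s — a deterministic stand-in for the original
coefficient-of-variation search, chosen because small test universes
make that tuner unstable. The null is all distinct class assignments
when there are at most `n_permutations` of them (220 on the 4 × 3
design at the default 1000), otherwise a sample. q compares the
*median* null count of |d\*| ≥ |d(g)| with the observed count at the
same threshold, with π0 fixed at 1 (conservative; π0 estimation is
unstable at small gene counts), clamped to [0, 1] and monotone-enforced
along decreasing |d|. The median, unlike the mean, is robust to the
partially-informative assignments that overlap the true labeling,
which is why SAM can keep sample relabeling while the rank product
cannot.

# Connectivity scoring

An *instance* is one perturbation experiment represented as a complete
rank vector over the probe universe, rank 1 = most upregulated. For a
query tag set with sorted positions V(1..t) in a list of length n, the
enrichment is `a` if `a > b` else `-b`, where
`a = max_j [ j/t − V(j)/n ]` and `b = max_j [ V(j)/n − (j−1)/t ]`.
Note the discrete statistic is not exactly mirror-symmetric (b uses
(j−1)/t where a uses j/t): positions (1, 2) in a list of 10 score
+0.8 while (9, 10) score −0.9.

The raw instance score is s = ks_up − ks_down when the two enrichments
have opposite signs and 0 otherwise; zero scores are *included* in
compound means (excluding them is undocumented behavior of the
original tool, so inclusion is the stated, conservative choice).
Scaling divides positive raw scores by the maximum positive and
negative ones by the magnitude of the minimum negative, so the
strongest inverter in a result set scores exactly −1 and the strongest
mimic exactly +1 — the sense in which "−1 means complete reversal".
Compounds are ranked by ascending mean scaled score; a permutation p
per compound comes from resampling same-size instance subsets
(default 10000), a tractable stand-in for full rank-matrix
permutation.

Gene symbols reach the probe space through a GPL96-style annotation
table (`ID`, `Gene Symbol`, with ` /// ` separating multiple symbols).
Every probe of every mapped gene enters the tag set; a probe mapped to
genes on both sides of the signature would break tag-set disjointness
and is dropped from both sides, recorded in the mapping report.

# The synthetic world

`planted_design()` emulates the motivating experiment: 1000 genes,
4 organs × 3 replicates, one target organ. Planted structure:

| parameter | default | why |
|---|---|---|
| target-up module | 54 genes, +4.0 log2 units | the workflow's emergent up-set size; effect and σ are the stated test world |
| target-down set | 54 genes, −4.0 | mirrors the appended down count |
| per-organ nuisance modules | 20 genes, +2.0 each | makes non-target organs distinguishable, as real organ programs would |
| noise | Gaussian, σ = 0.5 per gene | rank/centroid statistics downstream do not require heavier tails |
| within-module correlation | 0.5 | realistic co-regulation; after the shift the module's effective profile correlation is ≈ 0.95 |
| baseline | N(7, 2²) log2 units | typical log-expression spread |

Module members share an equicorrelated noise term (σ√ρ·u per sample);
the down set is independent by design. The instance simulator gives
null compounds uniform random permutations; an inverter of strength p
moves each query down-tag probe with probability p into the top block
and each up-tag probe into the bottom block (a mimic mirrors this), so
strength 1 attains the extreme arrangement exactly and strength is a
monotone dial for score-versus-strength properties.

What the generator does *not* emulate: count-level sequencing noise,
library-size effects, heavy-tailed dispersion, correlated probe
behavior within genes, or realistic perturbation signatures. A green
test therefore establishes that the pipeline's logic and statistics
behave as specified on data with the assumed additive log-scale
structure — not that the biological conclusions of any particular
dataset would replicate.

# Numerical choices

* **Cluster expansion cut.** "Clustered together with the validated
  genes" is operationalized in the workflow as the validated markers'
  flat cluster(s) when the dendrogram is cut at a fixed height
  (default 0.2 = average correlation 0.8). The literal minimal
  containing subtree systematically under-covers: average-linkage
  trees over near-equicorrelated module genes chain, so the minimal
  subtree over m seed leaves drops on the order of (M − m)/(m + 1) of
  an M-gene module's late-joining members, and a data-driven
  largest-gap cut fragments the module in the regime where the
  candidate set contains nothing but the module. The fixed ceiling
  sits between within-module merge heights (≲ 0.1) and the heights at
  which merely threshold-selected outsiders join (≳ 0.2).
  `minimal_containing_cluster()` keeps the minimal-subtree reading as
  its default for direct use, with `cut_height` as the option.
* **Permutation resolution.** pfp for the top-ranked gene is estimated
  on a 1/n_permutations grid; at 100 permutations a single null tie
  equals the 0.01 cutoff exactly and the monotone enforcement then
  erases every call. The default of 1000 keeps the grid two decades
  below the cutoff.
* **Ties.** Expression ties in rank lists take average ranks (the
  permutation invariant of instance databases makes ties impossible
  there); rank-product ties order lexicographically by gene symbol;
  exact nearest-centroid ties go to the alphabetically first class;
  compound-mean ties order lexicographically by compound.
* **Degenerate inputs.** Zero-variance genes: harmless in the
  moderated DE and in SAM (d = 0, q = 1); excluded with a warning from
  correlation clustering. Organs with fewer than two replicates are
  rejected at validation. An empty step of the derivation raises an
  explicit "no signature" error naming the step rather than returning
  a partial object.
* **Seeds.** Every stochastic stage derives its own stream from the
  master seed (recorded in provenance), so artifact trees are
  checksum-identical across reruns.

# Known limitations

* The derivation's emergent counts (candidates, markers, validated)
  fluctuate with the seed; only the final signature size is stabilized
  by the module structure. Occasionally a noise gene that genuinely
  mimics the target-up pattern survives validation or co-clusters with
  the module and the up set exceeds the planted size by one or two —
  that is honest behavior of the stated world, not corrected for.
* pfp and q are conservative by construction (π0 = 1, cumulative-max
  enforcement, signal-free null); on null data they call essentially
  nothing, which is the right failure direction for a discovery
  filter.
* The connectivity engine implements the build-2-style KS statistic
  and ±1 scaling only; moderated z-score (build-3 style) summaries and
  cell-line stratification are out of scope, as is querying any live
  service.
* The meta rank product coincides with the pooled one up to
  Monte-Carlo noise on a single-origin design (the pair sets are
  identical); the surface is kept because the workflow's validation
  consults both readings.

# A worked run

```{r, eval = FALSE}
library(sigrevert)

sim <- simulate_multiorgan_expression(planted_design(), seed = 1)
cfg <- workflow_config(seed = 1)
sig <- derive_signature(sim$expr, sim$sheet, cfg)
sig
#> gene_signature 'brain_signature': 54 up + 54 down = 108 genes
#>   derivation: candidates_up=66, candidates_down=118, markers=7,
#>   validated=7, cluster_members=54, cluster_additions=47,
#>   down_appended=54, up=54, down=54, total=108

pm <- simulate_probe_annotation(rownames(sim$expr), seed = 11)
tags <- map_signature_to_probes(sig, pm)
compounds <- c(list(planted_compound("planted_inverter", "inverter", 1)),
               lapply(1:9, function(i) planted_compound(sprintf("null_%02d", i), "null")))
db <- simulate_instance_db(pm$universe, tags, compounds, 2, seed = 12)
rank_compounds(db, tags, n_null = 1000, seed = 13)[1:3, ]
#>  rank         compound dose_text n  mean_score     p
#>     1 planted_inverter      10uM 2 -1.00000000 0.005
#>     2          null_04      10uM 2 -0.07802626 0.200
#>     3          null_03      10uM 2  0.00000000 0.732
```

The numbers shown are what the code printed for these exact calls (the
compound table's tail entries vary with the seed); `run_pipeline()`
wraps the same chain and writes every artifact plus a JSON provenance
sidecar to a directory.
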