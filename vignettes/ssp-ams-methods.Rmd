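---
title: "Methods: consensus SSP calling and AMS association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus SSP calling and AMS association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Plant small secreted proteins (SSPs) — complete ORFs of 50–250 amino acids
secreted either conventionally (via an N-terminal signal sequence, NSS) or
unconventionally (extracellular localization without an NSS) — act as
signalling molecules in plant–microbe interactions, including arbuscular
mycorrhizal symbiosis (AMS). sspAMS implements a comparative pipeline that
asks, across a panel of plant genomes with known AMS status:

1. Which proteins are SSPs? (consensus over imperfect per-tool predictions)
2. Which ortholog groups are associated with the AMS trait?
   (AMS-specific and AMS-preferential groups)
3. Which of those groups respond convergently to arbuscular mycorrhizal
   fungi (AMF) across species? (cross-species differential expression)
4. What else is co-expressed with the candidate SSPs? (thresholded Pearson
   networks)

Because the upstream predictors (signal-peptide, transmembrane and
localization tools) and public RNA-Seq runs are outside the package's scope,
a synthetic-data generator with planted ground truth stands in for them, so
the whole chain is testable end to end.

# The consensus caller

Each protein carries nine binary votes: three NSS tools, three transmembrane
(TM) tools, three extracellular-localization tools. With the default
`caller_thresholds()`:

* **Gate.** Complete ORF and length in the closed interval [50, 250] aa.
  Both bounds are inclusive: "50–250" is read as a closed range, and the
  boundary behaviour is pinned by tests at 49/50/250/251.
* **List 1 (conventional secretion).** At least 2 of 3 NSS votes and *no* TM
  vote — a single TM prediction by any tool vetoes the candidate, because
  membrane proteins frequently carry NSS-like N-termini.
* **List 2 (extracellular).** At least 2 of 3 localization votes. The TM veto
  is *not* applied to this branch by default; the branch structure of the
  published pipeline applies the veto only after signal-peptide prediction.
  `tm_applies_to_extra = TRUE` extends it for sensitivity analyses.
* **Categories.** `NSS_ONLY` (list 1 only), `EXTRA_ONLY` (list 2 only),
  `NSS_AND_EXTRA` (both), `NOT_SSP`. A protein is an SSP iff it is on either
  list; `partition_counts()` checks the identity
  `union = list1 + list2 − intersection` on every call table.

One tool (a Phobius-like predictor) legitimately appears in both the NSS and
TM tool sets; the caller treats the nine votes as independent columns and
applies no de-duplication, since no such rule is defined for the published
roster. The same simplification is made in the generator (see below).

The caller is validated against an independently coded truth-table oracle
over all 2^9 vote patterns crossed with gate outcomes, and is monotone:
adding a positive NSS vote can never remove a protein from the SSP set.

# Ortholog-group classification

Given an OrthoFinder-style membership table and per-species AMS status:

* **Source class.** Groups are classified by which species class contributes
  SSP members: `AMS_ONLY`, `NONAMS_ONLY`, `BOTH`, `NO_SSP`. These three
  SSP-containing classes partition the SSP-containing groups.
* **AMS-specific.** No member from any non-AMS species, members spanning at
  least `ceiling(0.30 × n_AMS)` AMS species, and at least one SSP. The
  ceiling is deliberate: "at least 30%" bounds an integer species count from
  below (12 of 39). Span is counted over all members by default because the
  operational description mentions *proteins* from ≥30% of AMS species; a
  `span_on = "ssp"` flag restricts the span to SSP members for the stricter
  reading.
* **AMS-preferential.** For `BOTH` groups only: per-species SSP counts, with
  zeros for species absent from the group, compared between AMS and non-AMS
  species by a one-sided Wilcoxon rank-sum test (AMS greater), flagged at
  p ≤ 0.05. Zeros are included because the alternative (present-species-only
  vectors) makes groups with a single non-AMS member untestable;
  `include_absent = FALSE` exposes that alternative. No multiplicity
  correction is applied by default (the published rule is raw p ≤ 0.05); a
  Benjamini–Hochberg option exists (`adjust = TRUE`).
* **Genome level.** Two-sided Wilcoxon tests on per-species SSP counts and
  SSP ratios (count ÷ annotated proteome size), overall and per lineage;
  one-sided tests are reserved for the directional preferentiality claim,
  two-sided for the undirected "difference" claims. Strata with fewer than
  two species on a side are skipped with an explicit note.

**Wilcoxon implementation.** `wilcoxon_rank_sum()` dispatches to the exact
null distribution when both samples have ≤ 10 observations and no ties, and
to the normal approximation with tie and continuity correction otherwise
(both via `stats::wilcox.test`). Tests compare the exact path against an
exhaustive enumeration of all rank assignments for every size pair up to
8 × 8, and the approximation path (forced with one sample of size 11)
against the same enumeration. A caution for very small samples: the
continuity-corrected normal approximation agrees with the exact p to within
0.02 in the decision-relevant region (exact p ≤ 0.2), but in the middle of
the null distribution the two-sided gap can reach ≈ 0.03 at sizes 4–8 and
≈ 0.09 at n = m = 2. The dispatcher therefore always prefers the exact path
where it is available.

# Differential expression and convergence

The package ships a deliberately simple DE engine rather than re-implementing
an empirical-Bayes count model: counts are scaled to the median library size,
a per-gene Welch t-test is run on `log2(normalized + 1)`, p-values are
BH-adjusted, and a gene is called `up`/`down` when `|log2fc| > 1`
(**strict**, so a fold change of exactly 2 is not called) and `padj ≤ 0.05`
(boundary inclusive — the operational threshold text uses ≤). The engine is a
substitute for the out-of-scope external DE tool; externally produced DE
tables are accepted by every downstream step, so the substitution is
isolated. Its operating characteristics are pinned by simulation: at planted
log2fc = 3, five replicates and dispersion 0.1, recall ≥ 0.9 at empirical
FDR ≤ 0.1. Genes with zero variance in both conditions get p = 1 when means
agree (all-zero genes included) and p ≈ 0 when they differ deterministically.

`detect_convergence()` maps DE SSPs into ortholog groups and reports a
(group, direction) pair when at least `min_species = 2` species each have at
least one DE SSP member with that direction. A group may appear in both
directions. The displayed per-(group, species) effect is the mean log2 fold
change of that group's DE SSP members — an aggregation choice, since heatmap
displays show one value per cell and no rule is stated. Contrasts are kept
separate per species; pooling multiple time points per species is left to the
caller of the function (an any-contrast union is a trivial post-processing
step on the DE table).

# Co-expression

`build_network()` computes Pearson correlations between seed genes (by
default the SSP genes of the atlas species, mirroring the use case of a few
hundred SSP seeds against a full-genome atlas) and all genes, retaining edges
with `|PCC| ≥ 0.95` and p ≤ 0.05 (two-sided t-based p on n − 2 degrees of
freedom). All-vs-all computation is behind a flag because its quadratic cost
is unnecessary for the seeded use case. Correlation p-values are raw by
default, matching the published threshold; a BH flag exists. The atlas is
taken as-given (an optional `log2(x + 1)` transform is provided), since the
pre-transformation of the original atlas is unstated.

Rank labels follow the published network figure: **rank1** SSPs belong to
groups that are both AMS-preferential and convergent-DE; **rank2** SSPs
belong to the union of AMS-specific, AMS-preferential and convergent-DE
groups minus rank1 (the "or" is read inclusively). rank1 and rank2 are
disjoint by construction and both are subsets of the SSP set.

# The synthetic world

`sim_config()` defaults describe the study design the pipeline targets,
reduced in proteome size only:

* **60 species, 65% AMS** (39 AMS / 21 non-AMS), lineages drawn 33:15:12
  among dicot/monocot/other — the composition of the emulated genome panel.
  The species count is kept at full scale because it is what makes the
  ≥30%-of-AMS-species rule discriminative: at 39 AMS species the threshold
  is 12, unreachable by chance for uniformly assigned background groups,
  while a strongly reduced panel would make small all-AMS background groups
  common and the planted/background separation would vanish.
* **600–800 proteins per species, 12% truly secreted** (half NSS, half
  unconventional), 10% membrane, 5% incomplete models. Real proteomes are
  ~30–60× larger with ~3% SSPs; the density here is raised so that the
  per-species true-SSP pool (~55 genes after the gate) supports the planted
  structures, which consume up to ~29 SSP genes per AMS species. Lengths are
  log-normal (median 140 aa, sdlog 0.7) truncated to [20, 600] so the 50–250
  gate is exercised on both sides (~7% below, ~20% above).
* **Tool error model:** sensitivity 0.90, specificity 0.95 per tool class,
  independent Bernoulli draws per tool. No per-tool agreement rates are
  published (only that tools disagree substantially), so these are
  stipulated, not calibrated. TM votes are drawn independently of NSS votes
  even for the shared Phobius-like tool — a simplification that ignores the
  real shared-tool correlation.
* **1500 ortholog groups** covering 92% of genes, matching the published
  group density (~0.5 members per species per group) and orthogroup coverage
  (91.6% of proteins). Planted: 3 AMS-specific groups (one true-SSP gene in
  each of ≥ 12 AMS species, no non-AMS member), 3 AMS-preferential groups
  (every AMS species contributes 1 + 5 true-SSP genes, every non-AMS species
  one — `preferential_effect = 5` is the strong-effect setting at which
  recovery is claimed), 3 + 3 convergent-DE groups per direction, plus the
  first 2 preferential groups marked convergently up-regulated, mirroring
  the observation that some AMS-preferential groups respond convergently to
  the fungus (and making rank1 attainable). Convergent-DE groups receive one
  non-SSP anchor member in each of two non-AMS species so they do not
  accidentally satisfy the AMS-specificity predicate.
* **Expression:** 4 AMS RNA-Seq species plus one non-AMS control contrast;
  negative-binomial counts (log-normal baseline means, dispersion 0.1), 5
  replicates per condition, planted |log2fc| = 3. Background DE genes (30
  per contrast, control included) are drawn from non-SSP genes: the control
  species therefore shows DEGs but no DE SSPs — the non-host expression
  pattern — and background DE cannot create false convergent groups.
* **Atlas:** 20 samples over the first AMS species; 2 planted modules of 5
  genes sharing a latent factor with expected pairwise PCC 0.995 ("near
  unit", so that all within-module sample correlations clear the 0.95
  threshold at n = 20 with overwhelming probability), each seeded on one
  true-SSP gene; background genes independent standard normal.
* **Determinism:** each stage seeds its own stream at `rng_seed + k` for a
  fixed small offset `k`, so identical configurations give byte-identical
  datasets and any stage can be reproduced in isolation.

What a green end-to-end test establishes: with these effect sizes the
pipeline recovers every planted structure with precision = recall = 1, and
its statistical components hold their nominal error rates. What it does not
establish: performance on real predictor output (label-level simulation, no
sequence realism, no inter-tool correlation), on real count data (no
outliers, batch effects or length biases), or at paper-scale multiplicity.

# Numerical and interface choices

* Boolean TSV columns are strictly `0`/`1`; readers never coerce silently.
* All writers emit deterministic column and row order, so artifact files are
  byte-reproducible.
* The run configuration is JSON (`read_run_config()`), not YAML: the package
  avoids a YAML dependency and jsonlite is already required for the
  ground-truth and report files.
* The command-line wrapper (`inst/scripts/ssp-ams`) is a thin layer over the
  exported functions; the functions are the contract and the only tested
  surface.
* `run_all()` re-checks the partition and group-class identities when
  assembling the run report, so an internally inconsistent report cannot be
  written.

# A small worked run

```{r, eval = FALSE}
library(sspAMS)

cfg <- run_config(out_dir = "ssp-ams-demo", rng_seed = 1)
report <- run_all(cfg)

report$ssp_partition$union      # non-redundant SSPs found
report$groups$n_ams_specific    # AMS-specific groups (3 planted)
report$recovery                 # precision/recall of all planted structures
```

# Known limitations

* The DE engine is a t-test on log counts; it is not a replacement for
  count-model DE methods on real data and is provided so the convergence
  layer has a self-contained upstream.
* Tool votes are simulated at the label level; the generator cannot expose
  weaknesses of real predictors (shared training data, length-dependent
  error, inter-tool correlation).
* The preferentiality test inherits the conservativeness of rank-sum tests
  on heavily tied sparse counts; with very sparse groups its power is low,
  which is also why background groups rarely trigger it.
* Functional annotation is imported, never computed: `annotate_functions()`
  only tallies an externally supplied gene-to-category table.
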