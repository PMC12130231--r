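---
title: "Methods: multi-omics functional profiling of SLC transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics functional profiling of SLC transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcfunmap)
```

`slcfunmap` analyses perturbation screens of the solute carrier (SLC)
superfamily: each analysis is one cell line with doxycycline-inducible
overexpression of one transporter, profiled by targeted metabolomics
(and, upstream, RNA-seq) in induced versus uninduced cultures. This
vignette documents the models the package implements, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## Normalization model

Targeted MRM peak areas carry large multiplicative nuisance factors:
instrument response drifts between runs, and individual injections vary.
Both are addressed by ratioing each metabolite's area against an
isotopically labeled internal standard (IS) spiked into every sample, since
a standard in the same injection experiences the same nuisance factors.

**IS assignment** (`assign_internal_standards`). Metabolites with a
structure-matched labeled standard use it directly. For the rest, the
package fits, per (metabolite, candidate IS, run), a weighted linear
regression of the expected calibration concentration on the
metabolite-to-IS area ratio, using the run's calibration dilution series.
A candidate qualifies in a run when its adjusted R²
(`1 − (1 − R²)(n − 1)/(n − 2)` for the simple regression) reaches the
`r2_threshold` (default 0.85); the reference is the candidate qualifying in
the largest fraction of eligible runs provided that fraction reaches
`run_fraction` (default 0.75), with ties keeping all tied candidates. When
no candidate reaches the fraction, the best available one is kept and
flagged `regression_fallback`. Runs with fewer than three usable
calibration points are excluded from that candidate's denominator.

Two open choices here were resolved as follows:

* *Regression direction.* The calibration regresses concentration on
  ratio. Analytical chemistry more often fits ratio on concentration; the
  direction only reorders which variable carries the error term, and R² is
  unchanged for the simple linear fit, so the choice is immaterial for the
  qualification rule. Concentration-on-ratio is kept as the package's
  definition.
* *Weights.* `inv_x2` (1/concentration²) is the default, the common MRM
  calibration weighting that equalizes relative error across a serial
  dilution; `inv_x` and unweighted fits are available.

**Normalization** (`normalize_peaks`). A cell's value is the mean over the
reference set of log2(metabolite area / IS area); log base 2 is used
throughout so that downstream effects read directly as log2 fold changes.
When some reference standards are undetected in a sample, the mean falls
back to the reduced set rather than dropping the injection; when none are
detected, or the metabolite area is zero, the cell is left missing.

**Run (batch) correction** (`batch_correct`). For each metabolite, every
run's values are centered and scaled so the run's median and interquartile
range match the metabolite's across-run targets. The targets are the
*median of the per-run medians* and the *median of the per-run IQRs*
rather than statistics of the pooled values: with per-run targets the
correction is exactly idempotent (a second application is the identity map,
since after one pass all runs share the same median and IQR), whereas
pooled-value targets would keep rescaling on repeated application. On runs
whose values are constant (IQR 0), only centering is applied. A metabolite
observed in a single run is untouched.

A consequence worth knowing: if an induction effect inflates a run's IQR —
which happens when a run contains only one or two analyses — the scaling
shrinks that run's values, attenuating the estimated effect. In realistic
screens a run holds many analyses and any single induction effect barely
moves the run IQR; the cohort-scale simulations in the tests therefore
place about twenty analyses per run, and the attenuation is negligible
there.

## Differential abundance

Per metabolite, induced and uninduced values are contrasted with an
ordinary linear model: intercept plus induction for wild-type
overexpression lines (`one_way`), plus a clone main effect for
knockout-overexpression lines with two independent clones
(`two_way_clone`). No induction-by-clone interaction is fitted; the clone
factor absorbs baseline offsets between clones. The induction term is
tested by F-test (on balanced two-group data this equals the squared
two-sample t statistic, a property the tests verify to 1e-12). The log2
fold change is reported as the difference of condition means, averaged over
clones — identical to the model coefficient under balance, and more robust
when cells are missing. P values are Benjamini–Hochberg-adjusted across the
metabolites of one analysis, and significance called at FDR 5 %.
Metabolites absent from an entire condition are emitted with missing
statistics and excluded from the BH family. Designs aim for four replicates
per condition (per clone); imbalance warns rather than errors, and with
balanced data the sequential and marginal sums of squares coincide, so no
sum-of-squares type decision arises.

## Ontology matching

Whether a measured metabolite "is" an annotated compound is decided on a
chemical-term graph with directional generalization edges (`is_a`, and
`has_role`, treated as chemical-to-role generalization) and symmetric
equivalence edges (conjugate acid/base, tautomer, enantiomer). Two terms
match when one is reachable from the other along a path whose directional
edges all point the same way — the query is then a strictly more specific
or strictly more generic term — with equivalence edges freely interleaved,
or when the two are connected by equivalence edges alone.

The single-direction rule is the substantive design decision: allowing the
direction to flip mid-path would let any two siblings match through their
common parent, collapsing the notion of "more generic or more specific"
into mere relatedness. Because the original analysis's path semantics are
not pinned down publicly, `match_policy(allow_direction_mixing = TRUE)`
exposes the permissive variant, and `max_depth` optionally caps path
length (unbounded by default). Matching is symmetric in the matched/not
verdict, with the direction label swapping sides.

The OBO reader consumes only `id`, `name`, `is_a` and `relationship:`
lines; everything else in OBO 1.2 is out of scope. A TSV edge-list dialect
(`source`, `relation`, `target`) covers programmatic use.

## Pathway mapping and permutation significance

Reactions carry educt and product term sets, protein annotations, and
pathway memberships under a single-rooted pathway DAG. A metabolite maps to
a reaction when it matches any educt or product; a gene maps via a
user-supplied gene-to-protein table. Reaction pathways are expanded to all
ancestors, so a pathway's feature set includes its descendants' — the
hierarchical reading of pathway membership. Per-pathway summaries
deduplicate features, and the mean pathway log2 fold change deliberately
applies no significance filter.

The hit frequency of a pathway is the number of analyses with at least one
significant feature mapping to it. Because hub pathways and promiscuous
features inflate raw frequencies, significance is assessed by permutation:
each iteration draws one random relabeling of the quantified feature
identities — a permutation of the rows of the feature-to-pathway map —
shared across all analyses and pathways, preserving the joint structure of
the significance calls and of the pathway map. The one-sided enrichment
p value uses the add-one convention, p = (#\{permuted ≥ observed\} + 1) /
(B + 1), so p is never zero and the test is exact-in-expectation. The
default B = 200,000 matches full-cohort use; tests and the vignette-scale
examples run far fewer. An exhaustive enumerator
(`exact_permutation_pvalues`) covers universes up to 8 features and anchors
the Monte-Carlo implementation in the tests.

## Pair categorization

Each significant (SLC, metabolite) pair receives exactly one category, by
precedence:

1. **annotated substrate** — the metabolite matches one of the SLC's
   annotated substrate terms;
2. **metabolic conversion** — some reaction links an annotated substrate to
   the metabolite: substrate matches an educt and metabolite a product, or
   symmetrically metabolite an educt and substrate a product. Terms
   occurring on both sides of the same reaction cannot anchor a match, and
   the ubiquitous substrate annotations hydron, hydroxide and water are
   ignored (both lists configurable);
3. **novel (non-orphan)** — the SLC has annotated substrates but neither
   rule fires;
4. **novel (orphan)** — the SLC has no annotated substrate.

The precedence order makes the categories a partition and is stable under
network growth: adding reactions can never demote an annotated-substrate
pair. The bidirectional conversion rule is the default because conversion
evidence is symmetric (the metabolite may be precursor or product of the
substrate); `bidirectional = FALSE` restricts to the substrate-to-product
direction. `compare_pair_categories` runs the Kruskal–Wallis comparison of
|log2 fold change| across categories.

## Profile clustering and enrichment

Profiles are restricted to features measured with finite log2 fold changes
in **every** analysis, then each item's profile is standard-normalized
(mean 0, sample SD 1, n−1 denominator) so clustering responds to profile
shape rather than overall response magnitude. Constant profiles cannot be
standardized and are dropped with a warning.

Clustering is Ward minimum-variance agglomeration on Euclidean distances.
Of the two Lance–Williams conventions in circulation, the package uses the
squared-distance variant (`hclust` method `ward.D2`). The dendrogram is cut
at every candidate count in the band implied by an average cluster size of
5–10 items (k from ⌈N/10⌉ to ⌊N/5⌋, clamped into [2, N−1] for small
cohorts), and the cut maximizing the mean silhouette width is selected,
ties resolved toward fewer clusters (the more conservative grouping). Items
are processed in sorted-id order, which makes the procedure invariant to
input order up to genuinely tied merge heights.

Cluster enrichment uses one-sided Fisher's exact tests of each functional
property (family, fold, localization, substrate class, ion coupling) in
each cluster, testing only properties with at least 3 annotated carriers in
the cohort, BH-adjusting within each property class separately, and calling
enrichment at FDR 20 % — a deliberately permissive threshold for what is a
hypothesis-ranking, not a confirmatory, step.

## Transcriptomic uniqueness

For each gene and analysis, two z-scores of the shrunken log2 fold change
are computed: across all genes within the analysis, and across all analyses
for the gene (requiring at least 3 analyses; zero spread yields z = 0,
since every deviation is zero). Reportable hits must be significant
(adjusted p < 0.05) and pass the minimum-signal rule — at least 50 reads in
both replicates of at least one condition, reflecting the two-replicate
transcriptomic design. The output is ordered by min(|z within|,
|z across|), descending; this combined ranking is a package convenience for
triage, not a claim about the original analysis, which displayed both
scores without a combined cutoff.

The package does not model read counts itself: negative-binomial testing
and fold-change shrinkage are upstream concerns, and their result tables
are this package's input.

## Cluster coherence

Two clusterings of the same items are compared through their contingency
distribution p_ij. With natural logarithms throughout,

* VI = H₁,₂ − MI, computed via the pairwise decomposition
  c_ij = p_ij · log(p_i p_j / p_ij²), with Σ c_ij = VI;
* a cluster's contribution is the sum of its pairwise terms against the
  other clustering, so contributions add up to the total exactly;
* NVI = VI / H₁,₂, where "shared entropy" is read as the joint entropy —
  the normalizer appearing in the VI formula itself — giving NVI ∈ [0, 1],
  0 for identical clusterings, 1 for independent ones, and defined as 0
  when the joint entropy is 0 (both clusterings trivial). NVI is invariant
  to the logarithm base, so nats-vs-bits conventions do not affect
  comparability.

Items present in only one clustering are dropped to the intersection, with
the dropped count reported — the alignment rule used when comparing
metabolomic (fewer analyses) against transcriptomic clusterings.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with the truth
needed to score recovery:

* `gen_ontology` — `is_a` forests with random equivalence partners and role
  terms, plus the exact match closure computed by an independent
  Floyd–Warshall transitive closure (the matcher's oracle).
* `gen_pathway_network` — a single-rooted pathway tree with reactions over
  ontology leaves; ~15 % of reactions share a species between educts and
  products so the anchor-exclusion rule is exercised.
* `gen_metabolomics_experiment` — peak areas as concentration × response ×
  run effect × lognormal injection noise, a ±doxycycline design with four
  replicates per condition (two clones under the two-way model), per-run
  six-point two-fold calibration dilutions, and an IS panel in which each
  metabolite shares a per-injection fluctuation with its true standard.
  That shared fluctuation is the discriminating structure: the true
  standard's calibration ratio is nearly noise-free while decoys inherit
  the full fluctuation (log2 SD 2.5 by default, at which decoys essentially
  never reach adjusted R² 0.85), emulating the empirical fact that a
  chemically matched standard tracks its analyte while an unmatched one
  does not. Planted log2 effects multiply induced concentrations;
  unplanted metabolites are exactly null.
* `gen_lfc_cohort` — cluster centroids separated by a requested Euclidean
  distance on top of a shared non-constant baseline profile, Gaussian
  noise, property labels agreeing with the true cluster with configurable
  fidelity, and negative-binomial replicate read counts for the uniqueness
  filter.
* `gen_pair_scenario` — a hand-structured ontology/reaction/annotation set
  whose significant pairs have categories known by construction, with
  substrate pairs planted at larger |log2 fold change| than conversion
  pairs.

All generators are deterministic given (seed, arguments), run on a local
RNG stream that never touches the session's `.Random.seed`, and return
`synth_truth` objects.

What passing on these data does **not** show: chromatographic reality
(peak integration, retention drift, detection limits are upstream and not
simulated); chemistry (the toy ontology has structure, not meaning);
transcript-count reality (counts are only rich enough to exercise the
≥ 50-reads rule); and correlated biology — real metabolites co-vary within
pathways, while planted effects here are independent across features.
Recovery rates on synthetic data are therefore upper bounds of a clean-data
regime, not performance claims about any real screen.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on a
single core in a few minutes while keeping estimates meaningful: 100 random
clustering pairs of up to 30 items for the information-theoretic checks; a
4-feature universe (4! = 24 relabelings) plus a 200-pathway, 30-analysis,
80-feature null at B = 2,000 for the permutation test; a 500-analysis,
20-metabolite, 25-run cohort under the two-way clone model for recovery and
false-positive measurement; and a 40-item, 6-cluster cohort for
clustering. Tolerances: information quantities are checked against brute
force at 1e-12; batch-correction idempotence and standardization
idempotence at 1e-9; 0·log(0) terms are defined as 0; BH adjustment
delegates to `stats::p.adjust`; Fisher p values delegate to
`stats::fisher.test` and are cross-checked against explicit hypergeometric
tail sums.

## Known limitations

* The batch correction's effect attenuation in sparse runs (above) is a
  property of median/IQR alignment itself; screens with one analysis per
  run should skip the correction or accept conservative effect sizes.
* `terms_match` path search is exact but unoptimized (per-pair BFS);
  all-pairs matching on ontologies beyond ~10³ terms will be slow.
* The clone model assumes no induction-by-clone interaction; a transporter
  whose effect differs strongly between clones will be averaged.
* Permutation p values are bounded below by 1/(B+1); pathways needing
  finer resolution need larger B.
* NVI comparisons are descriptive; no significance test for NVI differences
  is provided.
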