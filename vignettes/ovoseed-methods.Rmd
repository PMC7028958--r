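---
title: "ovoseed: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ovoseed: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoseed)
```

## The problem

In ovo microbiota-transplant experiments ask whether members of an adult
cecal community, applied topically to the egg surface, colonize the chick
gut after hatching. The observable is a time series of 16S ASV count tables:
a few pooled donor ("transplant", TRPL) samples, plus treated and control
chicks sampled at fixed ages (days posthatching, dph). `ovoseed` implements
the downstream inference: which ASVs engrafted, which community-level
differences follow, and how the two classifications relate.

The central classifier is deliberately simple and fully presence-based. For
each ASV we record its first appearance age in each arm (∞ if never) and
whether it occurs in the donor material, then call it

* **successfully transplanted** — in the transplant, and first seen in
  treated chicks strictly before control chicks (including treated-only);
* **possibly transplanted** — in the transplant, first seen in both arms at
  the same age;
* **environmental** — in the transplant but control-only/control-first, or
  not in the transplant at all.

ASVs seen only in the transplant are removed before classification (they
carry no information about the chicks) and reported as a separate dropped
set. "Strictly before" is read as strict inequality of first-appearance
ages with ∞ for never; the treated-only case therefore counts as successful.
That reading is a closure of the stated rules rather than something the
protocol spells out, so it is a documented choice.

Presence has an asymmetric sourcing rule that is easy to get wrong:
transplant presence is assessed on the **unfiltered** table, chick presence
on the **abundance-filtered** table used for the balance analysis. The API
makes both tables explicit arguments of `first_appearances()`.

## Filtering, rarefaction

`quartile_filter()` totals each ASV across all samples and excludes the
lowest quarter: the threshold is the first quartile of the totals under the
linear-interpolation convention (R's default `quantile(type = 7)`), and ASVs
whose total is ≥ the threshold are retained — the boundary is kept, matching
an "exclude totals *less than* t" rule. The originating pipeline's exact
interpolation rule is unknown and its thresholds are not re-derivable
without its raw reads, so the convention here is simply fixed and tested.

`rarefy()` subsamples each sample without replacement to exactly the target
depth in a single draw (no iteration averaging), dropping and warning about
samples below depth. The study depth is 5,000 reads. Determinism comes from
an explicit seed; the RNG state of the caller is never disturbed.

## Diversity

`shannon()` uses log base 2, the convention inherited from the QIIME
lineage; multiply by `log(2)` for nats. `unifrac()` computes, per branch b
with length `l_b`, the per-community descendant presence and proportion:
unweighted distance is unique branch length over covered branch length;
weighted is `Σ l_b |p_A(b) − p_B(b)|`, with the normalized variant dividing
by the attainable maximum `Σ l_b (p_A(b) + p_B(b))`. Published work rarely
says whether weighted UniFrac was normalized; the default here is
unnormalized, with the flag exposed. Both variants are validated against a
brute-force oracle that enumerates every branch by path tracing.

`anosim()` follows Clarke: rank all pairwise distances (average ranks on
ties), `R = (r̄_between − r̄_within)/(n(n−1)/4)`, permutation p-value
`(1 + #{R* ≥ R})/(1 + n_perm)` with 999 permutations by default and a
required seed. `pairwise_kruskal()` delegates each pair to the tie-corrected
`stats::kruskal.test` and applies Benjamini–Hochberg across all pairs;
groups with fewer than two values are flagged `NA`, not computed.
`donor_distance_test()` averages each chick's distance to all TRPL samples
and compares arms with a pooled two-sample t test (the unannotated
"Student's t test" convention; Welch available via `var_equal = FALSE`).
Equal constant groups return t = 0 rather than an error.

## Balances

The differential-abundance stage is the Gneiss-style ilr-balance workflow:

1. `build_balance_tree()`: proportions after a pseudocount, ASV–ASV
   dissimilarity `1 − cor(log p)` across samples, Ward linkage
   (`hclust(method = "ward.D2")`, the same algorithm as SciPy's `ward`).
   Internal nodes are balances labelled `y0, y1, …` in breadth-first order
   from the root. Which child is the numerator is fixed deterministically
   (the side whose smallest leaf id sorts first); the labels are positional,
   since the original study's indices cannot be reproduced without its data.
2. `ilr_transform()`: `y_b = √(rs/(r+s)) · ln(g(num)/g(den))` with geometric
   means over closed proportions. The pseudocount defaults to 1 (a common
   small-count choice; the source pipeline does not state its own); zero is
   permitted when the table has no zeros, which the closed-form tests use.
3. `regress_balances()`: one shared design (intercept, treatment coded
   control = 0 / treated = 1, age in dph numeric), OLS per balance. Overall
   fit is pooled, `R² = 1 − ΣSSE/ΣSST`; a covariate's variance fraction is
   the drop in pooled R² when it is removed (leave-one-covariate-out).
   Rank-deficient designs fail loudly, naming the collinear columns.
4. `classify_da()`: each balance significant for treatment at α assigns its
   numerator toward the arm with the higher fitted log ratio; conflicts are
   resolved by the shallowest significant balance; unclaimed ASVs are NDA.
   The original analysis also adjudicated some balances by eye from a
   heatmap. Those judgment calls are not inferable, so they enter only as an
   explicit overrides table (balance label, class; `/num` or `/den` suffix
   to address one side), which takes precedence over the automatic rule.

## Contingency analysis and qPCR

`chi_square_independence()` is the uncorrected Pearson statistic with
`e_ij = rowᵢ·colⱼ/N` and df = (r−1)(c−1); no Yates correction, which is what
reproduces the reference statistics on the 3×3 tables. Zero marginals are an
error, since expected cells would be undefined.

`relative_abundance()` averages detected CT replicates per (sample, target),
forms ΔCT against the reference-gene mean and reports 40 − ΔCT so that
larger means more abundant. Non-detection is a first-class flag: a target
with no detected replicate stays non-detected (no imputation at CT 40), and
a sample whose reference never amplified is excluded with a warning.
`group_compare()` refuses to fabricate a statistic when one arm never
amplified — the published t value for such a case is not reproducible
without an imputation convention the protocol does not state — and instead
returns a flagged degenerate result.

## The synthetic world

`simulate_study()` generates the stated design: `n_trpl = 3` donor samples;
treated and control chicks (`n_per_group = 7`) at 0/3/7/14 dph; 445 donor
ASVs of which a `spore_fraction` survive on the eggshell; sequencing depth
Poisson around `depth_mean = 82544` (the study's mean reads per sample,
safely above the 5,000 rarefaction depth). Mechanics:

* Donor and environmental ASVs draw log-normal base abundances
  (`sigma_log = 1.5`), the donor community being their closure — the
  standard steep rank-abundance shape; no empirical distribution is stated
  anywhere, so this is the package's choice.
* Engraftment is a deterministic schedule plus sampling noise: each
  surviving donor ASV gets a first-appearance timepoint in the treated arm
  (early-weighted), and appears in controls `engraftment_lead = 1`
  timepoints later (possibly never). Environmental ASVs share one schedule
  across arms. Non-surviving donor ASVs never appear in chicks. A
  mechanistic growth model would add realism but nothing the classifier or
  diversity stages can distinguish.
* Succession: expected composition at age t weights each present ASV's base
  abundance by a per-family multiplier (`default_succession()`):
  Enterobacteriaceae high at hatch and decaying, Lachnospiraceae rising
  first, Ruminococcaceae later — the qualitative trajectory reported for
  chick ceca. Counts are multinomial at the drawn depth.
* The phylogeny is a random coalescent topology over all ASVs (`ape::rcoal`);
  real trees come from alignments, which are out of scope here, so UniFrac
  results on synthetic data are exercised, not calibrated.
* `simulate_qpcr()` converts true family proportions (recorded pre-noise in
  the ground truth) into CTs under ideal efficiency,
  `CT_target = CT_ref − log2(p)` plus N(0, 0.1²) replicate noise, with
  crossings beyond cycle 40 reported non-detected.

Everything is a deterministic function of the scenario seed.

**What a green test establishes — and what it does not.** The generator
plants the engraftment structure the classifier is designed to detect, with
multinomial noise as the only corruption. Recovery ≥ 90% on this world shows
the chain is implemented correctly end to end (presence bookkeeping,
filtering interplay, rule order); it does not show the rules are robust to
real-data pathologies the generator omits: cross-contamination between
arms, index hopping, chimeras, compositional depth artifacts, or donor ASVs
arriving from the shared environment. The defaults were fixed before the
recovery criterion was evaluated and are not tuned to it.

## Numerical and degenerate-input conventions

* Quartile: `type = 7` interpolation; retention is threshold-inclusive.
* Ties in ANOSIM ranks: average ranks; permutation p is never exactly zero.
* t tests: pooled variance by default everywhere, two-sided; zero-variance
  equal groups give t = 0, p = 1.
* Balance child order and level-order labels are the deterministic
  conventions described above; rerunning on permuted input order changes
  neither calls nor classes.
* Empty tables, unknown sample ids, ASVs missing from the tree, zero
  marginals, rank-deficient designs, and constant log-proportion vectors
  all raise immediate, named errors.

## Known limitations

* The ASV-level results of the motivating study are not reproducible from
  its publication alone (that requires its deposited raw reads); the
  package reproduces the printed arithmetic surfaces — contingency
  statistics, expected frequencies, rate arithmetic — and validates the
  algorithms against oracles and planted truth instead.
* One printed expected-frequency cell (exact value 170.459, printed 171)
  cannot be reproduced by rounding; the corresponding acceptance test is
  left failing by design and documented in the README.
* UniFrac is O(samples² × edges) dense; adequate for hundreds of samples,
  not for atlas-scale tables.
* The balance-label namespace (`y0…`) is topology-dependent; overrides
  written for one filtered table do not transfer to another.
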