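---
title: "Methods: expression inheritance and heterosis in hybrid/parent trios"
author: "heterosisTrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression inheritance and heterosis in hybrid/parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`heterosisTrio` analyses bulk RNA-seq of hybrid/parent trios (an F1 and
its two inbred parents) across well-watered (WW), water-deficit (WD) and
re-watering (RW) conditions. This vignette documents the statistical model,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the places
where the design was genuinely open and a choice had to be made.

## The count model and the differential-expression test

Counts are modelled as negative binomial with mean `mu` and dispersion
`alpha`, `Var = mu + alpha * mu^2`. The test in `nb_test()` is a plain
Wald test on the log fold change between two design cells:

* library-size normalisation by median-of-ratios (`size_factors()`): each
  sample's factor is the median across genes of its ratio to the per-gene
  geometric-mean reference, restricted to genes observed in every sample,
  rescaled to geometric mean 1. If no gene is expressed everywhere the
  function falls back to total-count scaling with a warning.
* group means are estimated on normalised counts; the dispersion comes
  from a method-of-moments estimate `(s^2 - m)/m^2` pooled within groups.
  The default `shared_mom` averages the per-gene estimates across all
  genes of the contrast (negative estimates included, so the mean stays
  approximately unbiased) and floors the result at 1e-8. `per_gene_mom`
  floors each per-gene estimate instead, and `fixed` takes a caller value.
  No empirical-Bayes shrinkage is applied: the package's aim is a
  transparent, oracle-testable engine, and the downstream logic (calling
  rule, set algebra, classification) is the substance, not the GLM
  machinery.
* the Wald statistic uses the delta-method standard error
  `sqrt((1/m1 + alpha)/n1 + (1/m0 + alpha)/n0)` on the natural-log scale
  and a two-sided normal reference. Genes with all-zero counts on both
  sides get `p = 1` and `log2fc = 0`; when exactly one side is all-zero a
  pseudo-mean floor of 0.5 normalised counts enters the log so the fold
  change stays finite.

Calling (`call_de()`) applies the rule used throughout: a gene is `up`
iff `log2fc > log2(fc_threshold)` **and** `fdr < fdr_threshold`, `down`
symmetrically; defaults `fc_threshold = 2`, `fdr_threshold = 0.05` encode
|fold change| > 2 at FDR < 5%. The fold-change gate is applied to the
point estimate (not a shrunken or tested-against-boundary estimate) —
that is the plain reading of the rule, and a documented choice. BH
correction is per contrast (one family per test per trio x condition).

The null behaviour of this test is checked by simulation in the
acceptance suite: on a no-effect simulation at the design scale
(n = 3 per side, alpha = 0.05) the empirical type-I error at p < 0.05
must fall in [0.03, 0.07]. An independent cross-check against a standard
NB GLM implementation (DESeq2, unshrunken fold changes) is part of the
unit tests.

## Presence/absence (PAV) typing and the detection rule

The PAV taxonomy is exact-zero in definition (e.g. type I is "both
parents > 0, F1 = 0"), which is not directly observable under sampling
noise. `expressed_flag()` operationalises detection as: at least
`min_reps` replicates at or above `tau` (defaults `tau = 1` in FPKM or
normalised-count units, `min_reps = 2` of 3). `classify_pav()` then maps
the three flags to types I-V; the all-silent combination is not a PAV
type and is reported separately as `not_detected`. The five types
partition detected genes by construction, which the test suite asserts
exhaustively on the 8-row truth table.

## Inheritance modes

Type-V genes are classified from four tests per trio x condition, each
reduced to a tri-state (`higher`/`equal`/`lower`, where `equal` means
*not significantly different* under the same |FC| > 2, FDR < 5% rule):

| test | construction |
|---|---|
| F1 vs P1, F1 vs P2, P1 vs P2 | NB Wald on the two cells |
| F1 vs MPV | NB Wald of the hybrid against a mid-parent pseudo-group: per-replicate parent means `(P1_r + P2_r)/2` on normalised counts |

The rule table (`classify_mode()`): additive if F1 = MPV (evaluated
first); else overdominant if F1 above both parents; underdominant if
below both; high dominance if F1 equals the higher parent and the parents
differ; low dominance symmetrically; otherwise `other` (the taxonomy is
not logically exhaustive — partial dominance exists and is reported,
never dropped). The table is verified against an independently coded
scalar implementation over all 81 tri-state combinations.

Three open points were decided as follows:

* **Equality as non-significance.** The classification literature derives
  modes from DEG calls; reusing the single global calling rule keeps the
  pipeline coherent and gives "equal" a precise meaning. The consequence
  is a *deliberate conservatism*: with a 2-fold gate, a true
  high-dominance gene whose parents differ by 4-fold has an F1/MPV ratio
  of 1.6 and is therefore called additive. Dominance calls at this gate
  are only made when the parental split is large; sensitivity targets are
  accordingly set for additive, overdominant and underdominant classes
  (each must exceed 0.85 on simulation), not for the dominance classes.
* **Mid-parent pseudo-group** rather than a contrast of fitted GLM
  coefficients: simple, respects replicate variance, and directly
  testable against closed forms (identical hybrid and pseudo-group
  replicates give a log-ratio of exactly 0).
* **BH within each family** (per test type, per trio x condition), the
  per-contrast convention; a user wanting global correction can run the
  tests directly.

Type-III genes (hybrid-only expression) behave as overdominant and
`merged_overdominant()` unions them with the type-V overdominant class;
the two inputs are disjoint by construction so the union size is the
exact sum.

## Response sets and conserved-set algebra

Per genotype, drought-response genes (DRGs) are the WD-vs-WW calls and
re-watering response genes (RRGs) the RW-vs-WD calls, split by direction.
Conserved sets intersect matching directions across the two hybrids
(up with up, down with down) — the direction-stratified reading of
conserved-set bookkeeping; a plain ID intersection is available by
passing direction-agnostic unions to `conserved()`. The headline
overlaps are DODG = CDRG-up with common-overdominant(WD), DUDG =
CDRG-down with common-underdominant(WD), and RODG/RUDG analogously from
CRRGs under RW. `reset_accounting()` partitions each conserved drought
direction set into the re-watering-reversed part and the persistent
remainder.

Every derived set records its operation and parents; `rs_audit()`
re-derives each set from its provenance and requires bit-identical
membership. Gene identity is the bare `gene_id` string — both trios are
assumed mapped to one reference genome, so no ID translation is applied.

## Heterosis indices

`heterosis_indices()` computes `MP = (P1 + P2)/2`, `HP = max(P1, P2)`,
`MPH(%) = 100 (F1 - MP)/MP`, `HPH(%) = 100 (F1 - HP)/HP` from replicate
means. For all-positive means `MPH >= HPH` is a theorem (HP >= MP), and
both indices are invariant to rescaling all values — both are asserted
over random mean triples in the tests. Significance uses two-sided Welch
t-tests: hybrid replicates against per-replicate parent-pair means for
MP (default, requires equal parent replication) or against the pooled
parent values (`mp_test = "pooled"`), and against the higher parent's
replicates for HP. Welch rather than Student is the safe default under
unequal variances; legacy multiple-comparison procedures (Duncan) are
deliberately not provided — BH-adjusted pairwise tests cover the need
with known error control. Zero-variance degenerate groups return p = 1
when means coincide and NA otherwise (the t statistic is undefined).

## Enrichment

`enrich()` is one-sided hypergeometric over-representation:
`p = P[X >= k]`, `X ~ Hypergeom(N, K, n)`, BH across tested terms. The
universe defaults to the analysed (detected) gene set rather than the
whole annotation — the defensible background for RNA-seq-derived query
sets — and any other universe can be passed explicitly. The
implementation delegates the tail mass to `stats::phyper`; the test suite
verifies it against direct combinatorial enumeration on every instance
with N <= 60, and checks null calibration against the *exact attainable
level* of the discrete test rather than the nominal 0.05.

## The synthetic-data generator

`simulate_trios()` emulates the target design: two trios, WW/WD/RW,
three replicates — 54 libraries. Per gene:

* a WW baseline `b ~ Uniform(4, 12)` on the log2 expected-count scale.
  This is the detected-gene regime (roughly 16-4096 expected counts);
  genes below the detection rule are not the classifier's target, and a
  delta-method power analysis at the fixed design (n = 3, alpha = 0.05,
  effect 2 log2-fold) shows the Wald test is adequately powered across
  this range.
* an inheritance mode per trio (or one shared mode with
  `shared_modes = TRUE`), drawn from `mode_proportions`. Defaults —
  additive 0.40, high/low dominance 0.15 each, over/under-dominance 0.08
  each, PAV I-IV 0.03/0.04/0.03/0.04 — reflect the usual situation:
  additivity dominates, over/under-dominance is the minority, PAV is
  rare. Mode construction follows the rule table exactly (e.g. additive:
  hybrid mean = linear mid-parent of parents split by `effect_log2fc`;
  overdominant: both parents at baseline, hybrid `2^effect` above), so
  the generating means are assertable from the truth object without
  sampling.
* a condition response (`up_WD` 0.25, `down_WD` 0.25, null 0.50) shared
  across trios — a shared direction is what makes conserved-set recovery
  well defined. Responding genes scale all WD means by `2^effect`; with
  probability `reset_prob` (default 0.60) the RW mean reverts to the WW
  mean, otherwise it stays at the WD level. `response_coupling =
  "dominance"` instead ties the response to the dominance class
  (overdominant genes up, underdominant down), the construction used to
  benchmark DODG/DUDG recovery.
* counts are NB with dispersion `alpha = 0.05` (a typical bulk-RNA-seq
  magnitude for biological replicates) around `s_j * mu`, where the
  library factor `s_j` combines lognormal noise (`lib_size_cv = 0.1`)
  with scaling to a common expected depth (`lib_size_mean`, default
  1.5e6 reads for the default 2000 genes). Fixing expected depth is how
  sequencers behave and makes the data *compositional*: a globally
  asymmetric signal (e.g. every gene up in WD) is absorbed by
  normalisation, in the simulator exactly as in real data.

Randomness is organised as one counter-based substream per gene (two
substreams: parameters and counts), so results are reproducible and
independent of gene order.

What the generator does **not** emulate: gene-length and GC biases, batch
effects, correlated genes/pathway structure, per-gene dispersion trends,
read-level artefacts, or low-expression PAV (silent means are exact
zeros; thresholding behaviour near the detection boundary can be probed
by setting a small baseline range instead). Passing recovery tests
therefore demonstrates correctness of the inference chain under the
stated model, not robustness to every real-data pathology.

## Problem sizes and numerical choices

The test and acceptance runs use 2000 genes x 2 trios for recovery, 5000
genes for null calibration, 1000-term batches for enrichment calibration
and 10,000 mean triples for the heterosis invariants — sizes at which
Monte-Carlo error is far below the asserted margins while a full suite
run stays in the low minutes. Other numerical details: dispersion
estimates are floored at 1e-8; tri-state reduction uses the strict gates
described above; ties in BH are handled by `stats::p.adjust`; GTF
intervals are 1-based closed and exon unions are computed with
`GenomicRanges::reduce` (union-exon lengths; transcript-model lengths
are a coarser alternative the package does not implement).

## Known limitations

* Dominance calls (high/low) are conservative at a 2-fold gate, as
  discussed; lowering `fc_threshold` trades specificity for dominance
  sensitivity.
* Median-of-ratios normalisation assumes a non-DE majority between the
  cells being compared. Between hybrid and parent libraries of genes
  with large parental splits this can be ill-posed; the classifier works
  on a diverse mode mixture in practice, but extreme simulated designs
  (e.g. most genes with an 8-fold parental split) require supplying true
  library factors.
* The NB engine has no dispersion shrinkage, no GLM covariates, and no
  outlier handling; it is intended for clean replicated designs.
* Heterosis tests treat replicates as independent; field-design
  structure (blocks, years) is out of scope.
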