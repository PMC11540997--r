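---
title: "Shared ASVs between paired oral and gut microbiota: methods and design"
author: "oralgut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared ASVs between paired oral and gut microbiota: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralgut)
```

## The question the package answers

The oral cavity and the gut are connected ends of the same tract, yet their
bacterial communities are usually studied separately. When saliva and stool
are collected from the *same* person and profiled with 16S amplicon
sequencing, exact sequence variants (ASVs) can be compared across the two
habitats: an ASV detected in both the saliva and the stool of one participant
is direct evidence that the same organism occupies both ends of the tract,
and — because ASVs are exact sequences — this comparison needs no taxonomy.
`oralgut` implements that analysis for a paired two-age-group cohort:

1. **Habitat accounting.** Which ASVs are gut-exclusive, oral-exclusive, or
   detected in both environments (in anyone)?
2. **Within-individual co-detection.** Which of the both-environment ASVs are
   found in both habitats *of the same person*? This is the stronger, and the
   central, statistic: co-occurrence across different people can be explained
   by a shared external source, co-detection within a person much less so.
3. **Directionality.** For each co-detected ASV, is it more abundant in
   saliva or in stool? A predominance of oral-dominant ASVs is consistent
   with oral-to-gut translocation being the main route.
4. **Age persistence.** Are co-detected ASVs found in children only, adults
   only, or both — i.e. is shared colonisation transient or established in
   childhood and persistent?
5. **Supporting diversity statistics.** Shannon alpha diversity,
   zero-adjusted Bray-Curtis resemblance, ANOSIM permutation tests, PCO and
   NMDS ordination, and Welch's t-test post-hoc comparisons of genus
   profiles between strata (sex, age bin, BMI category).

## The transform chain and its state machine

Counts are normalised per sample to percentages (removing library-size
variation), then square-root transformed (damping the influence of dominant
taxa) before resemblance analysis:

counts → percent → sqrt_percent

`feature_table` objects carry their state, and each transform accepts only
its predecessor, so accidentally normalising or square-rooting twice is a
hard error rather than a silent corruption. Detection (presence/absence) is
always evaluated on the *count* scale: an ASV is present when its count is at
least `min_count` (default 1 — ASV tables arrive denoised, and no additional
abundance filter is applied by default; the threshold is exposed for
sensitivity analysis). Percent conversion preserves the presence pattern
exactly, so set-level results do not depend on where in the chain they are
computed.

All-zero samples are retained in the accounting (dropping them silently would
hide upstream failures) but excluded, with a warning, from diversity and
resemblance computations where they are undefined or degenerate.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_count` | 1 | detection threshold on counts |
| `tie_tol` | 1e-12 (percent points) | directionality tie guard |
| `dummy_value` | 1 (sqrt-percent scale) | zero-adjusted Bray-Curtis dummy |
| `n_permutations` | 4999 | ANOSIM permutations |
| `ci_level` | 0.95 | Welch CI level |

**Directionality** compares, for each co-detected ASV, its mean relative
abundance over *all* oral samples with its mean over *all* gut samples,
zeros included. The habitat-wide mean (rather than a mean over only the
samples where the ASV was detected) is the reading consistent with asking
"where is this organism most abundant?" at the population level; the
detected-only variant is available via `detected_only = TRUE` as a
sensitivity check. Ties — means equal to within `tie_tol` — get their own
class rather than being forced into one side; `tie_tol` defaults to a pure
floating-point guard (1e-12 percent points), so genuine ties are essentially
exact equalities.

**Zero-adjusted Bray-Curtis.** Bray-Curtis similarity is undefined for a
pair of empty samples and erratic for near-empty ones. Following standard
practice in community-ecology software, a constant pseudo-feature
(`dummy_value`, default 1 on the square-root-percent scale, i.e. 1% before
the square root) is appended to every sample before computing the
coefficient; two empty samples then score 100 (identical). Setting
`dummy_value = 0` recovers the classical coefficient.

**ANOSIM** uses Clarke's rank-based R with ties mid-ranked, and the
permutation p-value with the +1 convention, p = (1 + #{R\* ≥ R}) /
(1 + n~perm~), so p is never zero and never below 1/(n~perm~+1). When the
number of distinct label arrangements does not exceed `n_permutations` the
test switches to exhaustive enumeration and reports the exact p. A seed is
mandatory whenever permutations are sampled.

**PCO** converts similarities to dissimilarities d = (100 − s)/100 and
applies classical scaling (Gower double-centering of −d²/2). Negative
eigenvalues — the signature of a non-Euclidean resemblance, which
Bray-Curtis generally is — are counted and reported, not corrected:
corrections change the geometry and should be an explicit analyst choice.

**NMDS** minimises Kruskal stress-1 under monotone regression (vegan's
global-model engine). The first start is the metric PCO configuration —
usually already close to the optimum — and the remaining `n_restarts − 1`
starts (default 19) are random; the lowest-stress solution is kept. With a
fixed seed the result is deterministic.

**Welch's t-test** is used for all two-group post-hoc comparisons of
genus-level percent profiles, with Welch–Satterthwaite degrees of freedom
and the confidence interval obtained by inverting the Welch statistic. Raw
p-values are reported without multiplicity correction — these are
exploratory post-hoc profiles, and adjusted values are available behind
`p_adjust = "BH"` (with a prominent message when used). Genus aggregation
happens on the percent scale before testing. Genera absent from both groups
are dropped rather than reported as degenerate rows.

## The synthetic cohort generator

Real paired cohorts require sequencing; the generator provides a cohort with
*known* ground truth so every pipeline stage is testable. `default_cohort_spec()`
returns the documented default conditions: 39 children and 97 adults (one
saliva and one stool sample each), a gut pool of 2,350 and an oral pool of
1,350 habitat-exclusive ASVs (sized so expected detected totals land near
2.4k and 1.4k), 61 planted shared ASVs with an oral-dominant fraction of
38/61, an age-partition mixture of (15, 20, 26)/61, and 50,000 expected
reads per sample.

The community model, and why each choice was made:

- **Log-normal rank abundance** (σ = 1.5) for the habitat pools, giving the
  long right tail characteristic of 16S communities; a Dirichlet would be
  more convenient but produces unrealistically even tails, and the tail is
  exactly where depth-limited dropout — which the tests probe — happens.
- **Carriage**: each individual carries each habitat-pool ASV with
  probability 0.25 (a few hundred ASVs per sample) and each *eligible*
  shared ASV with probability 0.15. Eligibility encodes the planted age
  partition (child-only ASVs can only be carried by children, and so on), and
  a carriage repair step guarantees every shared ASV at least one carrier in
  each age group its label requires — without it a label would be
  unrecoverable by *any* method, which would make recovery tests
  meaningless rather than stringent.
- **Shared-ASV abundances are planted on the relative scale**: a carrier's
  home-habitat sample contains the ASV at a target relative abundance drawn
  log-uniformly from 0.05%–2%, and the other habitat at `transfer_factor`
  (default 0.2) times that target. Planting on the relative scale makes the
  dominance ratio exactly `transfer_factor` in every carrier regardless of
  how rich that person's background community is; planting raw weights
  instead would let per-sample normalisation flip the planted direction in
  small or uneven communities.
- **Sequencing noise**: per-sample log-normal abundance noise (σ = 0.6, mean
  1), library sizes negative-binomial around `read_depth` (dispersion 0.3),
  and multinomial read sampling. `read_depth = Inf` disables all three and
  emits the expected percent composition directly — the mode in which
  recovery of the planted truth is provably exact, used by the tests as the
  noiseless baseline.

What the generator does **not** emulate: ASVs detected in both environments
but never in the same individual (the generator's both-environment set
coincides with its within-individual set, so the distinction between those
two counts is exercised only by hand-built fixtures); compositional
correlations between taxa; strain-level variation; and any mechanistic model
of gastric survival — `transfer_factor` is a phenomenological knob. Passing
recovery tests therefore shows the *pipeline* is correct, not that real
cohorts will behave this way.

## Numerical conventions

- Percentages of the total ASV count are printed to 1 decimal; percentages
  of the shared subset and participant prevalence to the nearest integer;
  rounding is half-up (0.5 away from zero), matching how such figures are
  conventionally printed.
- Percent columns must sum to 100 within 1e-9; taxon aggregation conserves
  column sums exactly (verified to 1e-12 in tests).
- The Shannon index uses natural log by default (values of 4–5 nats for
  communities of hundreds of ASVs); `base = 2` is available.
- Permutation p-values are never 0; exact-mode p includes the observed
  labelling in the reference set.
- Degenerate inputs: all-zero samples are warned about and excluded from
  diversity/resemblance; a Welch test between two constant equal groups
  returns t = 0, p = 1; constant unequal groups are an error.

## Problem sizes used by the checks

The test-suite simulations use cohorts of 10–16 individuals with pools of
40–150 ASVs, sizes at which brute-force oracles (exhaustive double loops,
full permutation enumeration) are feasible; calibration checks use 500
ANOSIM null simulations at 999 permutations and 2,000 Welch null replicates.
The acceptance script runs the full default cohort (136 individuals, 272
samples, 3,761 ASVs, 50,000 reads/sample) end to end, with ANOSIM at 4,999
permutations, and separately recomputes the derived sharing figures from the
published raw counts. Recovery of the planted 61 shared ASVs is checked
across 10 seeds at full depth.

## Known limitations

- Directionality is abundance dominance, not evidence of transfer direction;
  strain-level identity and viability are out of scope.
- The 95-vs-61 style distinction (both-environment ASVs that are never
  co-detected within a person) is represented in the data model and the
  accounting but not planted by the generator.
- ANOSIM is single-factor; no PERMANOVA, SIMPER or UniFrac (no phylogeny is
  consumed).
- The generator's demographic margins (age, sex, BMI frequencies) are
  realistic but not calibrated to any particular cohort beyond the group
  sizes.

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(default_cohort_spec(), seed = 42)
bundle <- analyze_cohort(cohort$table, cohort$metadata, cohort$taxonomy,
                         config = run_config(seed = 42))
bundle$count_summary
cohort_report(bundle)
```
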