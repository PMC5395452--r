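---
title: "Methods: plant families as islands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant families as islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hostislands)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, the numerical choices, and what the synthetic-data generator does and
does not emulate.

## The data model

The unit of analysis is the plant family. A study consists of three
aligned objects, held together by `HostIslandExperiment`:

* a rooted, dated family-level phylogeny (branch lengths in Myr);
* a binary utilization matrix, families × groups, where a *group* is any
  consumer category — an insect guild, a pathogen class, a human use —
  and a 1 means at least one member of the group uses at least one member
  of the family;
* a per-family apparency table: species count, genus count, and
  distribution area (km²).

Working at the family level trades resolution for completeness: a
presence–absence list over ~420 angiosperm families is obtainable for
many consumer categories at a global scale, where species-level host
lists are not. The cost is that everything below the family node —
within-family host specificity, geography of the interaction — is
invisible to the analysis.

Reconciliation rules are deliberately asymmetric. Tree tips with no data
are pruned with a warning (supertrees routinely carry extra tips), but a
family in the utilization matrix with no apparency record or no tip is a
hard error: silently default-filling a typo would fabricate data. Groups
using fewer than 10 families (the `minHostFamilies` default) are dropped
with a warning, because both the logit fit and the signal statistic are
unstable at very low prevalence; the boundary is inclusive (exactly 10
hosts is kept).

Apparency defaults mirror how such tables are compiled: families listed
without accepted names get species and genus counts of 0.5, families
without a distribution map get 1,000 km². We also floor *reported* areas
at 1,000 km², so the post-load invariant (`area_km2 >= 1000`) is uniform;
the replacement counts are returned in a load report so nothing happens
silently.

## Utilization probability vs. apparency

Per group, presence is a binomial GLM with logit link,
`logit(UP) = a · PA + b`, with PA entering untransformed — the model is
defined on the apparency scale itself, and the log-apparency alternative
is deliberately not the default so the fitted thresholds stay
interpretable in species/genera/km² units.

The fit is by iteratively reweighted least squares with an explicit
contract:

* start at `a = 0`, `b = logit(mean(y))` with the mean clipped to
  `[1e-6, 1 − 1e-6]`;
* converged when the deviance (−2 log-likelihood) changes by less than
  1e-8; deviance is non-increasing across iterations (tested);
* variances from the inverse information at the optimum (observed and
  expected coincide for the canonical logit link);
* weights floored at 1e-10 to keep the weighted solve finite when fitted
  probabilities saturate.

Separation matters here because heavy-tailed apparency makes
quasi-separation easy: a fit is flagged `separated` when the standardized
slope `|a|·sd(PA)` exceeds 50 or the deviance collapses below 1e-6 with a
non-degenerate response. A separated fit refuses to produce G or derived
quantities — an effectively infinite MLE must not leak into the
cross-group regressions. The slope test is the Wald form `G = a²/VAR(a)`
against χ²(1), implemented exactly as that ratio (not as a likelihood
ratio).

The derived quantities are closed forms of the coefficients:
`PA_0.5 = −b/a`, `PA_0.95 = (ln 19 − b)/a`, `UP_0 = logistic(b)`. They
are only defined for converged, non-separated fits with `a ≠ 0`, and
`predictUp` round-trips them exactly (`UP(PA_0.5) = 0.5`,
`UP(PA_0.95) = 0.95`).

One calibration caveat, visible in the acceptance script's own numbers:
with log-normal apparency the largest family dominates the design, and
when a draw contains an extreme outlier the Wald test becomes
conservative (type-I error below nominal — it under-rejects, never
inflates). This is a property of Wald tests under extreme leverage, not
of the implementation; the likelihood-ratio test would be better
calibrated but is not the statistic this analysis is defined by.

## Phylogenetic signal for binary traits

The D statistic standardizes the observed sum of sister-clade
differences, `Σd`, between two simulated nulls:

```
D = (Σd_obs − mean Σd_Brownian) / (mean Σd_random − mean Σd_Brownian)
```

`Σd` sums, over internal nodes of a binary tree, the absolute difference
between the two child values, where tip values are the 0/1 trait and
internal values are Felsenstein-weighted averages: child branches are
lengthened by `b' = b + b_L' b_R' / (b_L' + b_R')` as estimates propagate
rootward, and a node takes the `1/b'`-weighted mean of its children.
Zero-length branches are replaced by ε = 1e-9 Myr *inside the weights
only* — distances are never altered — so a zero-length cherry takes the
plain average of its tips.

Choices worth making explicit:

* **Polytomies** are resolved by seeded random pairing with zero-length
  branches before computing Σd (sister pairs must exist; patristic
  distances are unchanged, which is tested). How the original analysis
  of family supertrees handled polytomies is generally unstated, so the
  resolution seed is recorded in the result.
* **The nulls use the identical estimator** as the observed trait: the
  random null shuffles the trait among tips; the Brownian null simulates
  Brownian motion (σ² = 1 — thresholding by rank is scale-invariant) and
  scores the top-k tips at the observed prevalence k. Because observed
  and null Σd share the estimator, the standardization is internally
  consistent whatever the estimator details; the contract we promise (and
  test) is the calibration — mean D ≈ 1 for shuffled traits, ≈ 0 for
  Brownian-threshold traits — not numerical equality with any legacy
  implementation, whose nodal-estimation conventions are not fully
  documented.
* **p-values** are one-sided empirical tails with the small-sample
  correction `(count + 1)/(nPerm + 1)`: `p_random` is the lower tail of
  the permutation Σd (clumping gives small sums), `p_Brownian` the upper
  tail of the Brownian Σd. The default `nPerm = 1000` balances Monte
  Carlo error (~0.016 SD on a tail probability near 0.5) against cost;
  shuffles, Brownian draws and polytomy resolution use independent
  sub-streams derived from the master seed, so complementing the trait
  reproduces the permutation null exactly.
* Both nulls are vectorized through one post-order pass over a
  tips × replicates matrix, which is what makes 1,000 replicates per null
  on a 420-tip tree take seconds.

Degenerate standardization (the two null means coinciding, e.g. on a
star tree) is an error, not an NA.

## Islands, mainland, and the cross-scale regressions

The utilizer ratio `UR(f)` is the row mean of the presence matrix; its
denominator is the number of groups *retained after filtering*, read from
the matrix, never a constant. Mainland families are the top
`ceiling(fraction · N)` by the chosen apparency measure (default fraction
0.10) *plus boundary ties* — tie inclusion is the only rule that makes
the boundary well defined on discrete counts. `PD_min(f)` is the minimum
cophenetic distance from f to the mainland set, self-distance included,
so mainland members get 0 (an `excludeSelf` flag provides the
alternative convention).

All association tests are ordinary least squares with the two-sided
t-test on the slope (df = n − 2); p-values are reported unadjusted, as no
multiple-testing correction is part of this analysis. A zero-variance
response returns a flagged degenerate result (slope 0, r² 0, p 1); a
zero-variance predictor is an error. In the cross-group regressions,
groups are screened to converged, non-separated fits with `a > 0`;
nonpositive `PA_0.5`/`PA_0.95` (possible when `b > 0`) and nonpositive D
exclude a group from the regressions that take logarithms. Every
exclusion is logged with a reason — the pipeline never drops a row
silently.

The randomized baseline draws presence Bernoulli(p), independent of
apparency, for p ∈ {0.1, 0.3, 0.5, 0.7, 0.9}, 1,000 replicates *per*
probability level (the per-level reading of "1,000 samples" is our
choice; `nReps` overrides it), and refits the model. Since presence is
independent of apparency, fitted slopes center on 0 and fitted `UP_0` on
p; real groups with a positive apparency effect sit below this baseline
at small apparency. Degenerate and separated replicates are recorded and
excluded from summaries.

## What the synthetic generator emulates — and what it does not

`simulateStudy` produces data with the statistical structure the analysis
assumes, at the scale it targets (420 families, 44 groups by default):

* a Yule tree at birth rate 0.05/Myr (crown depth ≈ ln(420)/0.05 ≈ 120
  Myr, the scale of the angiosperm family radiation), ultrametric,
  deterministic per seed;
* species counts from a rounded log-normal (meanlog log 50, sdlog 1.8):
  median ≈ 50 species per family with a heavy right tail reaching the
  ~2×10⁴ size of the largest real families; genus counts at a tenth of
  species counts; areas log-normal around 10⁷ km², floored at the 1,000
  km² default;
* three group mechanisms in even split: *logistic* presence
  (`P = logistic(0.0018 · PA − 2.15)`, a typical insect-herbivore fit),
  *clumped* presence (Brownian-threshold at prevalence 0.13), and
  *random* presence (iid Bernoulli(0.13)).

Real data differ in ways the generator deliberately does not copy:
apparency and phylogeny are generated independently (any
apparency–phylogeny correlation in nature is an empirical property, not
an assumption, so the generator must not build one in); real presence
vectors mix mechanisms within a single group; real supertrees have
polytomies and soft dates; and real apparency measures are mutually
correlated. Passing tests on synthetic data therefore demonstrate that
the estimators recover known structure under the model's own
assumptions — parameter recovery, null calibration, mechanism
separation — not that any particular empirical dataset satisfies those
assumptions.

## Problem sizes and reproducibility

The test suite exercises the statistical contracts at sizes chosen to
estimate each quantity to useful precision: grid-search oracle
equivalence on 20 eight-point datasets; parameter recovery over 200
replicates at n = 420; G-test type-I error over 1,000 null fits; D
calibration over 100 traits × 500 permutations per null on a 200-tip
tree; baseline recovery over 1,000 replicates per probability. The
acceptance script recomputes the headline quantities end-to-end at the
default study scale with `nPerm = 1000`.

Everything stochastic takes a seed, and every seeded routine restores the
caller's RNG state; derived sub-streams make per-group results
independent of group order. Two pipeline runs with the same inputs and
seed produce byte-identical output tables (tested).

## Known limitations

* The Wald G under-rejects under extreme-leverage apparency draws (see
  above); fits on the raw apparency scale can also quasi-separate when a
  single giant family carries all the signal — such groups are flagged
  and excluded rather than estimated.
* D values are exactly reproducible per seed but not guaranteed to match
  other implementations digit-for-digit, because nodal-estimation and
  polytomy conventions differ between implementations; the calibration
  contract is what is promised.
* PD_min to a top-decile mainland is a coarse isolation measure; it
  ignores how *many* mainland families are nearby.
* OLS on group-level summaries treats fitted quantities (`PA_0.5`, D) as
  known; estimation error in them is not propagated.
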