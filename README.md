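# hostislands

Plant families as islands: modeling which plants get used, by whom, and why.

Across herbivores, pathogens, pollinators and human uses alike, some plant
families are exploited by almost every kind of consumer while others are
ignored. `hostislands` implements an island-biogeography view of this
pattern at the plant-family level. Each family is an island; its
**apparency** — species count, genus count, or distribution area — is the
island's "area", and its phylogenetic distance to the most apparent
("mainland") families is the island's "distance". The package is written
for comparative ecologists and ethnobiologists working with family-level
presence–absence data and a dated phylogeny.

## The models

**Utilization vs. apparency.** For each utilization group (a consumer
category: leaf miners, sap suckers, medicinal use, ...), presence on each
family is modeled with a binomial GLM with logit link,

```
logit(UP) = a · PA + b
```

where UP is the utilization probability and PA the apparency. The slope is
tested with the Wald statistic `G = a² / VAR(a)` against χ²(1). From each
fit come `PA_0.5 = −b/a` and `PA_0.95 = (ln 19 − b)/a` (the apparency at
which UP reaches 0.5 and 0.95) and `UP_0 = logistic(b)` (the utilization
probability of the most unapparent families, PA → 0). A randomized
baseline — presence drawn Bernoulli(p) independently of apparency —
calibrates what these quantities look like with no apparency effect.

**Phylogenetic signal.** Each group's presence vector is a binary trait on
the family tree. Its clumping is measured with the Fritz–Purvis **D**
statistic: the sum of sister-clade differences of Felsenstein-weighted
nodal estimates, standardized between a permutation null (D = 1, no
signal) and a Brownian-threshold null (D = 0, clumping as under Brownian
evolution), with tail probabilities `p_random` and `p_Brownian`.

**Cross-scale regressions.** Per family, the utilizer ratio UR (fraction
of groups using it) is regressed on log₁₀(apparency) and on PD_min, the
minimum cophenetic distance (Myr) to the top-decile mainland families. Per
group, log₁₀(PA_0.5), log₁₀(PA_0.95), UP_0 and D are regressed on host
breadth HF (and UP_0 on log₁₀ D).

## Worked example

Everything runs on synthetic data with the structure the analysis assumes
(no downloads needed):

```r
library(hostislands)

study <- simulateStudy(nFamilies = 120, nGroups = 8, seed = 7)
hie <- HostIslandExperiment(study$utilization, study$apparency, study$tree)
hie
#> HostIslandExperiment: 120 plant families x 8 utilization groups
#>   host breadth (HF): 10-19 (median 16.5)
#>   tree: 120 tips, binary, depth 121.6 Myr

fit <- fitBinomialLogit(apparency(hie)$n_species,
                        utilization(hie)[, "logistic_01"])
fit
#> Binomial logit fit: logit(UP) = a * PA + b  (n = 120)
#>   a = 0.00118701 (var 4.39e-07)   b = -1.9584 (var 0.0905)
#>   deviance = 98.6743, 4 IRLS iteration(s)
```

This group was simulated with a true slope of 0.0018 and intercept −2.15;
the fit recovers them within one standard error. `gStatistic(fit)` gives
G = 3.21, p = 0.073 (at 120 families and prevalence 0.13 the slope test
has modest power), and `derivedQuantities(fit)` gives PA_0.5 ≈ 1650
species, PA_0.95 ≈ 4130, UP_0 ≈ 0.12: a family would need ~1,650 species
for even odds of being used, and families with no apparency at all are
still used with probability 0.12.

A phylogenetically clumped group is picked up by D:

```r
trait <- setNames(utilization(hie)[, "clumped_04"], rownames(hie))
phyloD(hostTree(hie), trait, nPerm = 1000, seed = 7)
#> Fritz-Purvis D for a binary trait on 120 tips (prevalence 0.133)
#>   sum(d) observed = 16.6762; null means: random 25.6571, Brownian 12.5663
#>   D = 0.3140   p_random = 0.000999   p_Brownian = 0.1129   (1000 permutations)
```

D = 0.31 sits near the Brownian end: host use is far more clumped than a
random trait (p_random ≈ 0.001) and compatible with Brownian clumping
(p_Brownian = 0.11).

The full pipeline — utilizer ratios, mainland selection, PD_min, per-group
fits and D, cross-group regressions — runs in one call and writes CSV
tables plus run metadata when given an output directory:

```r
res <- runPipeline(study = study, nPerm = 1000, seed = 7)
res$regressions
#>    regression     slope intercept     r2      p   n
#> 1 urApparency  0.018919     0.105 0.0100 0.2773 120
#> 2     urPdMin  0.000532     0.108 0.0202 0.1214 120
#> 3   logPa05Hf -0.312144     9.122 0.9732 0.0135   4
#> 4  logPa095Hf -0.315821     9.586 0.9678 0.0162   4
#> 5       up0Hf -0.002988     0.177 0.2883 0.4630   4
#> 6      dLogHf 11.954233   -14.325 0.9047 0.0489   4
#> 7     up0LogD -0.006768     0.121 0.2142 0.5371   4
```

Rows 1–2 are the family-level regressions (n = 120 families); rows 3–7
the cross-group regressions over the 4 groups whose fits pass the validity
screen (converged, not separated, positive slope) — exclusions are listed
with reasons in `res$exclusions`. File-based inputs work the same way via
`runPipeline(treePath =, apparencyPath =, matrixPath =, ...)`.

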