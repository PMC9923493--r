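---
title: "Evolved plasticity along gradients and the interpretation of reaction norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolved plasticity along gradients and the interpretation of reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastrange)
```

## The model

`plastrange` simulates a monoecious, diploid population expanding over a
one-dimensional habitat of `M` demes, each with carrying capacity `K`. One
quantitative trait is under Gaussian stabilizing selection towards a
deme-specific optimum `theta_i`. Each individual's phenotype is the sum of a
nonplastic component and a plastic component proportional to the local
optimum:

    u = z + g * theta_i

`z` (the nonplastic component) and `g` (plasticity, the proportionality
coefficient) are additive polygenic traits: each is controlled by `L`
biallelic loci whose two alleles contribute +/- `alpha/2` (for `z`) or
+/- `beta/2` (for `g`) per copy. Plasticity is labile — on transplant, `u`
is re-expressed with the `theta` of the new environment.

Fitness combines logistic density regulation, stabilizing selection, and a
direct cost of plasticity:

    W = max(0, 1 - delta * |g|^gamma) * exp(r_m * (1 - N/K) - (theta - u)^2 / (2 * V_S))

The *fitness-indicator trait* `w` is the phenotype-dependent part of `W`
(the expression above with the density term removed, i.e. `N = K`). It
stands for any measured trait that is correlated with fitness but
selectively neutral with respect to the environmental axis: if adaptive
plasticity keeps an individual near its optimum in a new environment, `w`
barely moves (phenotypic buffering); if not, `w` drops in the new
environment for both populations of a transplant pair. This asymmetry — an
adaptive trait moves in *opposite* directions for the two origins of a
reciprocal transplant, a fitness indicator moves in the *same* direction —
is the core interpretive rule the package quantifies
(`directionConcordance()`).

## Parameters

`simParams()` collects all constants. Defaults are the headline study
design:

| parameter | default | meaning |
|---|---|---|
| `nDemes` (M) | 220 | habitat length, demes numbered -109..110 |
| `carryingCapacity` (K) | 100 | individuals per deme |
| `growthRate` (r_m) | 2 | maximal intrinsic growth rate |
| `selectionWidth` (V_S) | 2 | Gaussian selection width (squared trait units) |
| `mutationRate` (mu) | 1e-6 | per allele copy per generation |
| `nLoci` (L) | 799 | loci per trait component |
| `effectZ` (alpha) | 0.1 | z-substitution effect |
| `effectG` (beta) | 2/L = 0.0025 | g-substitution effect |
| `dispersalSd` (sigma) | 1 | dispersal kernel sd (demes) |
| `costShape` (gamma) | 0.5 | plasticity-cost shape |
| `costScale` (delta) | 0.5 | plasticity-cost scale |
| `nGenerations` (T) | 100000 | generations simulated |

The z-allele effect is reported ambiguously in the source material (one
table prints `(1/10)^(1/2)` where a figure caption prints `alpha = 1/10`);
the package defaults to `alpha = 0.1` and exposes the value in
configuration, so either reading can be run.

## Lifecycle and numerical choices

The per-generation order is fixed: mating and recombination, mutation,
death of adults, dispersal of juveniles. Specific choices:

* **Reproduction** — every adult acts once as mother; its offspring count is
  Poisson with mean `2 W`, the father drawn uniformly from the mother's
  deme (selfing allowed). This is the only simple scheme consistent with a
  well-adapted, density-free individual leaving ~15 offspring at
  `r_m = 2` (`2 e^2 = 14.8`). A consequence worth knowing: per-capita
  growth is `2 exp(r_m (1 - N/K))`, so an isolated, perfectly adapted deme
  fluctuates around `K (1 + ln 2 / r_m)` (about `1.35 K`), not `K`; the
  test suite asserts this closed form.
* **Recombination** is free: each transmitted haplotype picks one of the
  parent's two copies independently per locus (a compiled kernel drawing
  32 copy-choice bits per RNG call).
* **Dispersal** discretizes a Gaussian by rounding (`d` has the kernel mass
  on `(d-1/2, d+1/2]`); destinations beyond the habitat are reflected at
  the edges, which conserves individuals in the finite stepping-stone
  habitat.
* **Cost clamping** — `1 - delta |g|^gamma` turns negative for
  `|g| > (1/delta)^(1/gamma)`; the factor is clamped at 0 so `W` remains a
  valid reproduction rate, and `|g|` is used inside the power so negative
  plasticity (which allele sums permit) is costed symmetrically. Evolved
  `g` stays in roughly [0, 1], where neither choice binds.
* **Founding** — founder demes are filled to `K` with individuals whose
  plasticity alleles are exactly balanced (`g = 0`) and whose `z` either
  matches the local optimum to the nearest achievable allele count
  (`"adapted"`) or is zero (`"blank"`).
* **Determinism** — one user seed is expanded into independent per-stage
  streams (`expansion`, each `transplant`, the synthetic generator), so
  adding realizations to one stage never perturbs another. Checkpoints are
  plain text (JSON header plus one haplotype-string line per individual)
  and round-trip bit-exactly; the RNG state itself is not serialized —
  reproducibility is by explicit seeds.

## Environments

Three profile families are provided. The default steepening family is

    theta(x) = a * sinh(x / s)

odd-symmetric about the habitat centre, near-linear there (slope `a/s`),
and increasingly steep toward the edges. The published description of the
steepening gradient is qualitative in the main text (the exact formula
lives in supplementary material), so the sinh family is this package's
own smooth representative of that shape; the full-habitat default anchors
the edge optimum at 162.54 (the outermost sampling-location optimum of the
source study) with `s = 20`. Exact reproduction of the original optima
requires the original formula, which can be supplied via `tableProfile()`
or a `kind: table` configuration. `calibrateProfile()` least-squares-fits
`(a, s)` (or `a` with `s` fixed, closed form) to anchor `(position, theta)`
pairs. Linear profiles `theta = b x` are the contrast case: they evolve a
much narrower spatial range of plasticity.

## Reciprocal transplants in silico

`reciprocalTransplant()` re-samples the *fixed* final population state —
evolution is not re-run per realization, since replication attaches to
sampling and measurement, not to the 1e5-generation history. Each
realization samples 10 mothers per origin deme, forms 10 half-sib offspring
each (random local father, selfing possible, same recombination and
mutation rules as the simulator), and splits every family 5/5 between the
native and the new environment. `u` and `w` are computed in the assigned
environment; no survival or density feedback acts during the experiment.

`analyzeTransplant()` then applies, per realization and trait, a
Kruskal-Wallis omnibus over the four (origin x environment) groups followed
by Dunn-type native-vs-new post hoc contrasts on the pooled mid-ranks with
tie-corrected variance, Bonferroni-adjusted with `m = 2` (the number of
post hoc contrasts per trait; `m` is configurable since the source does not
state it). A contrast counts as significant when both the omnibus and the
adjusted post hoc p fall below `alpha`; adjusted p-values are capped at 1
and print as ">0.99" above 0.99. Glass' delta uses the native group as
control: `(mean_new - mean_native) / sd_native` with the `n - 1` sample
standard deviation. Note the chi-square reference for the rank statistics
is an approximation: at pooled sizes of ten or fewer it can deviate
substantially from the exact permutation law except in the rejection tail,
which the test suite documents; at the experiment's n = 50 per group it is
accurate.

Each realization's four significance flags map onto a qualitative outcome
ladder (`classifyPattern()`): with origin 1 the lower-plasticity deme,
(No,No | Yes,Yes) is "very low plasticity", (No,Yes | Yes,Yes) "low",
(Yes,Yes | Yes,Yes) "intermediate", (Yes,Yes | Yes,No) "high", and
(Yes,Yes | No,No) "very high plasticity" — the footprint of buffering
switching from absent to complete as local plasticity rises.

`pickTransplantPairs()` reproduces the sampling design: five pairs placed
along the evolved plasticity gradient by windows on deme-mean plasticity
relative to its habitat maximum (< 0.2, 0.25-0.45, 0.45-0.65, 0.75-0.95,
> 0.95), with the very-low pair spanning the widest optimum difference
available inside its window — in a scaled habitat the within-deme
plasticity variance (hence the noise floor of the fitness-indicator trait)
is larger than in the full model, so the indicator signal needs a larger
optimum difference to surface — and the high pair minimizing the
nonplastic difference so its reaction norms are driven by plasticity
alone.

## Scaled study conditions used by the tests

The headline habitat (220 demes x K = 100 x 2 x 799 loci x 1e5
generations) is a long-running computation; the package's replication
suite runs a scaled habitat chosen once: `M = 40`, `L = 50`, `K = 50`,
`T = 2000`, steepening gradient with the full model's relative shape
(edge position / length scale = 5.5, i.e. `s = 20/5.5`) and edge optimum
30, so that the achievable nonplastic range (`alpha * L = 5`) covers only
the central demes and plasticity is the only route to adaptation at the
edges; the matched linear gradient shares the edge optimum (`b = 1.5`).
Under these conditions the tests verify that edge demes evolve high and
central demes near-zero plasticity, that linear gradients evolve a
narrower plasticity range, that the five pair choices reproduce the
outcome ladder as modal patterns over 200 realizations, and that the
direction-concordance rules hold in focal-deme scans. What the scaled runs
do *not* show: the absolute plasticity values and optimum differences of
the full-scale run (e.g. its printed per-deme averages), which require the
full parameterization.

## The empirical path and its synthetic generator

`analyzeEmpirical()` mirrors the transplant statistics on a two-population
by two-salinity phenotype table: responses are standardized by dividing by
`ln(weight)` (read literally from "standardized by the natural logarithm of
the weight"; division by raw weight is available as a configuration since
the source phrasing also admits that reading), respiration is analysed on
the log10 scale on which it is approximately normal, rank tests and Glass'
delta run on untrimmed data, and a two-way ANOVA (population x salinity,
type-III sums of squares for the unbalanced design, sum contrasts) runs
after iterative two-sided Grubbs trimming within groups. Outlier removal
affects only the ANOVA — never the rank tests or effect sizes — and the
test suite asserts exactly that.

`generateSyntheticRecords()` emulates the structure of such a dataset so
the path is testable without the original raw data (which the source does
not print): group sizes 75/75/50/50, `ln(weight)` normal (mean 1, sd 0.3,
truncated so weight > 1.05 g — the standardization requires
`ln(weight) > 0`), Gaussian responses on the standardized scales
back-transformed through each individual's weight so the raw table carries
the weight covariance the analysis must remove, treatment effects
specified per population in control-sd (Glass delta) units, and optional
injected gross outliers. It does not emulate: repeated-measure structure
of the oxygen readings, non-Gaussian response tails, correlations between
grazing and respiration within individuals, or family structure. Passing
tests therefore show the pipeline's statistics are calibrated for data of
this shape, not that the model captures isopod physiology.

## Known limitations

* The sinh gradient is a stand-in for the original (supplementary-material)
  steepening formula; per-deme optima differ from the published ones.
* No environmental-cue unreliability, no temporal fluctuation of optima,
  no biotic interactions, and no neutral marker loci (genotype PCA uses
  the selected loci themselves).
* The rank tests' chi-square reference is approximate at very small group
  sizes (see above).
* Checkpoints serialize genomes and metadata but not the RNG state.
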