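---
title: "Measuring and tracking service efficiency: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and tracking service efficiency: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcfdea)
```

`ltcfdea` analyses panels of decision-making units (DMUs) — here,
province-year aggregates of long-term care facilities — that convert tagged
inputs into outputs. This vignette records the models the package fits, the
parameters that matter and why their defaults are what they are, what the
synthetic generators do and do not emulate, and the numerical and design
choices a maintainer would want written down.

## 1. Efficiency measurement

### Radial models

The input-oriented CCR program evaluates DMU 0 by the smallest uniform
input contraction θ that a convex-cone combination of observed units could
achieve:

$$\min\ \theta \quad \text{s.t.}\quad X\lambda \le \theta x_0,\quad
Y\lambda \ge y_0,\quad \lambda \ge 0 .$$

The optimum is technical efficiency (TE). Adding the convexity constraint
$\sum_j \lambda_j = 1$ gives the BCC program and pure technical efficiency
(PTE); scale efficiency is the ratio SE = TE/PTE, so TE = PTE × SE holds by
construction. Slacks are taken from a second-stage maximization at the
optimal θ rather than from a non-Archimedean ε in the objective: the
two-stage form is the numerically robust standard and avoids choosing an
arbitrary infinitesimal.

Returns-to-scale labels use the sum of reference weights at the CCR
optimum: Σλ < 1 increasing, Σλ > 1 decreasing, otherwise constant. Because
degenerate problems admit alternate optima with different Σλ, the package
brackets Σλ by minimizing and maximizing it over the optimal face and
declares CRS whenever the interval touches 1 (tolerance 1e-6). On unique
optima this reduces exactly to the plain rule.

### Slack-based measures

The non-oriented SBM score
$$\rho = \frac{1 - \frac1m \sum_i s_i^-/x_{i0}}
              {1 + \frac1s \sum_r s_r^+/y_{r0}}$$
penalizes every input and output slack, equals 1 exactly when all slacks
vanish, and is solved through the Charnes–Cooper linearization. For
SBM-efficient units the super-efficiency variant re-solves against the
reference set *excluding* the unit, yielding scores in (1, ∞) and hence a
complete ranking; inefficient units keep their SBM score. A unit that is
radial-efficient but not slack-free can therefore legitimately carry a
super-score at or above 1 while TE < 1 classifications differ — the two
families measure different things, and the package reports both.

SBM requires strictly positive data for the evaluated unit (the score
divides by $x_0$ and $y_0$); zeros raise a domain error naming the
variable rather than being silently perturbed.

### Linear programming

No LP solver suitable for these programs is available as a dependency, so
the package carries a small dense two-phase primal simplex
(`R/lp.R`). DEA programs are heavily degenerate — many reference weights
tie at zero — so pivoting uses Bland's rule, which cannot cycle; problems
here are tens of variables, where a tableau method is fast and exact to
machine precision (the test suite pins solver output to closed-form
oracles at 1e-7 and observes agreement at ~1e-15).

## 2. Productivity change

Between adjacent years the package computes four CRS cross-period radial
distances and two own-period VRS distances per unit, then

* TEC = catch-up, the ratio of own-period CCR scores,
* TC = frontier shift, the geometric mean of the two cross-period ratios,
* PTEC from the VRS scores, SEC = TEC/PTEC, TFPC = TEC × TC.

Over a horizon the per-pair records are chained by component-wise geometric
means; because the geometric mean of products is the product of geometric
means, both identities survive chaining exactly. Chaining (rather than a
fixed base year) matches the convention behind single 2013–2020 summaries.
Mixed-period VRS programs can be infeasible; such pairs are dropped from
the affected unit's geometric mean with a count kept, the pragmatic
standard treatment.

## 3. Distribution dynamics

Continuous score panels are discretized into k = 4 quantile states
(L, ML, MH, H — lowest to top quarter) by default; the quartile rule is the
common convergence-literature convention and k is configurable. Cut points
are computed on the whole pooled panel by default (matching two-period
transition tables; per-year pooling is a flag), intervals are right-closed
so ties on a cut fall to the lower state, and a degenerate pool (collapsing
cut points) is an error rather than an arbitrary split.

Transition matrices pool all unit-year moves, Mᵢⱼ = nᵢⱼ/nᵢ; rows never
visited are reported as NA, not zero-filled or uniform — silent imputation
would corrupt the homogeneity statistics downstream. The spatial Markov
decomposition conditions each origin-year transition on the quantile state
of the unit's spatial lag (the lag series is classified on its own pooled
quantile scheme, since score and lag live on different scales);
conditional counts aggregate cell-wise to the unconditional counts by
construction, and units without neighbors are excluded from both sides
with a warning.

The Anderson–Goodman test compares per-sub-period matrices with the pooled
matrix via the Pearson χ² statistic and the likelihood ratio, with
(T−1) Σᵢ(cᵢ−1) degrees of freedom adjusted for structurally empty cells.
Calibration was checked by simulation at the study design (31 units,
8 years, breakpoint after year 5) under a diagonal-dominant chain with all
row entries ≥ 0.15, chosen so that expected cell counts stay near the
classical adequacy threshold of the χ² approximation: the Pearson variant
holds its 5% level (empirical size ≈ 0.05–0.07) while the LR variant is
anticonservative at these sparse counts — inference should lean on the
Pearson statistic, which is what the acceptance checks use. Power against
a halfway switch to a row-permuted matrix is essentially 1.

## 4. Spatial autocorrelation

Global Moran's I uses row-standardized contiguity weights by default (the
familiar [−1, 1] range and the LISA sum identity both presuppose it);
binary weights remain available and are what the 4-cycle worked example
uses. Inference is by random relabeling with the (r+1)/(n+1) pseudo-p
correction, two-sided by doubling the smaller tail (empirical null
rejection at the 5% level stays within [0.03, 0.07] in 500-replicate
checks). Local statistics standardize by the population standard
deviation so that Σᵢ LISAᵢ = n·I exactly under row-standardized weights,
use the GeoDa-style conditional permutation (unit i held fixed, the rest
permuted across its neighbors), and default to 999 permutations with seed
20130101. Significant quadrants map to effect labels at α = 0.05:
HH → diffusion, LL → lagging, HL → polarization (reflux),
LH → centrifugal.

Units with missing scores are dropped pairwise for Moran's I (the weights
submatrix is re-standardized), while DEA stages treat missing cells as
hard errors — the LP needs complete rows, the cross-product statistic does
not.

## 5. Censored regression of determinants

Efficiency scores piled up at a bound motivate the Tobit model: latent
Y\* = α + Xβ + ε, ε ~ N(0, σ²), observed Y clipped. The likelihood mixes
the normal density inside the bounds with probit mass at them; the package
maximizes it by BFGS in (β, log σ) from the least-squares start, so with
zero censored observations the fit reproduces least squares to numerical
precision. Standard errors come from the observed information;
"panel Tobit" is interpreted as the pooled MLE with optional
cluster-robust (by unit) sandwich errors, since the estimator behind that
phrase is otherwise underdetermined — a random-effects variant is out of
scope. The default censoring is left-at-0 only, matching the printed
model; a `right = 1` bound is available since DEA scores are bounded
above, as a documented divergence switch. Covariate normalization defaults
to min-max onto [0, 1] (the stated practice, method unstated), with the
transform recorded and replayed at prediction. The reported R² is
McFadden's 1 − ℓ/ℓ₀ and is labelled as such; LR = 2(ℓ − ℓ₀) against the
intercept-only model. Published-table quirks are preserved in the fixture
rather than corrected (the 35–45 age coefficient is printed negative while
the surrounding text reads positive).

No two-stage bias correction for regressing DEA scores (Simar–Wilson
style) is attempted; that is a known methodological alternative, not an
omission by accident.

## 6. What the synthetic generators emulate

* `generate_frontier_panel()` — inputs log-normal; outputs Cobb–Douglas
  with equal exponents (summing to 1 under the default constant returns,
  0.8 under the VRS flag) times a technology level drifting
  `tech_drift` per year, damped by half-normal multiplicative
  inefficiency (`inefficiency_sd` 0.25, drift 0.02 by default — moderate
  values typical of service-sector efficiency studies). The Cobb–Douglas
  frontier makes true efficiency well-defined, so DEA recovery is exactly
  checkable; with one input and one output the CCR score is the
  normalized output/input ratio and rank-identical to the truth.
* `generate_sar_field()` — x = (I − ρW)⁻¹ε, the textbook simultaneous
  autoregressive field, for probing Moran's I with a known ρ.
* `generate_markov_states()` — independent evolution by a known
  row-stochastic matrix; with probability `spatial_coupling` a unit's row
  is blended 50/50 with a point mass on its modal neighbor state. The
  coupling is a structural stand-in (transition-row blending, not a
  parametric spatial process) because the mechanism being emulated is
  descriptive only.
* `generate_tobit_data()` — standard-normal covariates, known (α, β, σ),
  clipping at the bounds.

Every generator is a pure function of its arguments and seed, and each
output passes the package's own validation. What they deliberately do
**not** emulate: the marginal distributions, serial persistence of inputs,
measurement error, or administrative reporting artifacts of any real
yearbook panel. Passing recovery tests therefore demonstrates estimator
correctness under the stated models, not agreement with published
provincial values — those enter only through the packaged fixture tables,
whose internal arithmetic (counts, identities, rankings) the reporting
layer reproduces.

## 7. Pipeline conventions and problem sizes

`run_pipeline()` echoes its configuration verbatim into the output
directory, derives every stochastic seed from the single `seed` key, and
records per-stage status, outputs and timing in `manifest.json`; reruns
with the same configuration are byte-identical. The two-period transition
tables count transitions whose both endpoints fall inside a period, while
the homogeneity test partitions transitions by origin year — the two
conventions are each standard and are kept side by side deliberately.

The bundled study-scale scenario (31 units × 8 years × 5 inputs ×
5 outputs, three efficiency series) runs the full pipeline in well under a
minute on one CPU; test-suite simulation sizes (1000 null replications for
test calibration, 200 recovery fits at n = 2000, 500 permutation checks)
were chosen to keep Monte-Carlo error comfortably inside the asserted
bands while the whole suite stays in the tens of seconds.

## 8. Known limitations

* Input orientation only; no output-oriented radial models, window
  analysis, weight restrictions, or bootstrapped DEA intervals.
* Adjacent-pair chained Malmquist only (no sequential or global-frontier
  variants, no bias correction).
* No ergodic projections or mobility indices on the chains; no Geary's C
  or Getis–Ord statistics; no geometry handling — weights are supplied,
  not derived from polygons, and the packaged 31-unit contiguity matrix is
  a stated convention (Hainan joined to Guangdong), not a reconstruction
  of any particular study's unpublished matrix.
* The human / non-human input partition is schema-driven configuration;
  published studies rarely state their exact partition, so comparability
  of those two series across sources is limited by that ambiguity.
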