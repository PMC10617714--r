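---
title: "Predicting condition-specific enzyme allocation by minimal adjustment"
author: "parrot package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting condition-specific enzyme allocation by minimal adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parrot)
```

## The problem and the model

Protein-constrained genome-scale metabolic models (pcGEMs) couple
metabolic flux to enzyme abundance through turnover numbers: a reaction
$j$ catalysed by enzyme $i$ can carry at most
$v_j \le k_{cat,ij}\,E_i$ flux per unit enzyme. Given quantitative
proteomics for a *reference* growth condition, this package asks what
the enzyme allocation looks like in an *alternative* condition whose
physiology (growth rate $\mu$, nutrient uptake bounds, protein content)
has been measured but whose proteome has not. The working hypothesis is
minimization of adjustment: cells reallocate their proteome as little as
possible between conditions, in analogy to MOMA for fluxes.

Writing $e = E_s/E_{s,tot}$ and $a = E_{ref}/E_{ref,tot}$ for allocation
fractions, the package solves one of four convex programs over fluxes
$v$ and abundances $E_s$:

* **LP1** — minimize $\lVert a - e\rVert_1$ (Manhattan distance of
  allocations);
* **QP1** — minimize $\lVert a - e\rVert_2^2$ (squared Euclidean
  distance);
* **LP2** — minimize
  $\lVert a - e\rVert_1 + \lambda\,\lVert v_{ref} - v\rVert_1$;
* **QP2** — minimize
  $\lVert a - e\rVert_2^2 + \lambda\,\lVert v_{ref} - v\rVert_2^2$;

subject to steady state $N v = 0$, flux bounds with the biomass flux
confined to a growth interval around the measured rate, the per-enzyme
kcat capacity constraint
$\sum_j v_j / k_{cat,ij} \le E_{s,i}$ (the GECKO convention: a complex
draws on every subunit at its own kcat, and the single-enzyme case
reduces to $v_j \le k_{cat,ij} E_i$), and the total-enzyme constraint
$\sum_i E_{s,i} = E_{s,tot}$.

Three conventions deserve explicit statement because they are genuine
design choices:

* **Quadratic variants minimize squared norms.** A sum of two unsquared
  Euclidean norms is a second-order-cone objective, not a quadratic
  program; the standard minimization-of-adjustment reading (and the one
  that makes QP1/QP2 solvable as convex QPs) squares them. Reported
  objective values follow the same convention.
* **The total-enzyme constraint changes sense with the objective.** The
  distance variants need the equality $\sum E_s = E_{s,tot}$, because
  allocation *fractions* are only comparable at a fixed total. For the
  minimization problems — the experimental baseline
  ($\min \lVert E\rVert_1$ or $\min \lVert E\rVert_2^2$), parsimonious
  FBA and its enzyme-weighted variant — an equality would make the
  objective vacuous (a non-negative vector of fixed sum has a fixed
  1-norm), so there the total acts as a pool upper bound.
* **$E_{s,tot}$ is a fixed parameter**, derived from the alternative
  condition's measured protein content. Treating it as a decision
  variable would make the fraction-matching objective non-convex.

The distance is summed over enzymes present in the reference allocation
(`distanceSupport = "reference"`). Model enzymes without a measured
reference value are free, pool-limited variables excluded from the
distance: real reference proteomes cover a few hundred of a model's
thousands of enzymes, and including the unmeasured ones as zeros would
let them dominate the objective. A `"all"` mode (reference 0) is
available for sensitivity analysis.

## Reference construction and the baseline

Measured reference proteomics are integrated by **flexibilization**
(`flexibilize()`): measured abundances become per-enzyme upper bounds
(capped by any intrinsic capacity bound the model already carries, with
a $10^{-6}$ relative slack so a measurement equal to the minimal
supporting abundance does not produce a knife-edge feasible set).  While
the maximal growth rate falls short of the target
$\mu(1-f)$, the measured bound that most limits growth is released, one
enzyme per iteration. Limitation is ranked by a finite-difference growth
sensitivity (re-solving with the bound scaled up by $10^{-3}$); ties
break lexicographically by enzyme id so the audit trail is
deterministic. Released enzymes return to the pool-limited regime, and
the reference allocation keeps the original measured values for
untouched enzymes while released ones take their usage at the final
optimum. The flux vector of that final maximum-growth optimum serves as
the default $v_{ref}$ for the two-term variants.

Predictions are never compared to raw measurements: a model allocates
only the enzyme actually needed to carry flux, so raw abundances (which
include unused protein) would bias every comparison. Instead the
alternative condition's measurements are re-projected through the model
(`computeBaseline()`): integrated as upper bounds, flexibilized against
the condition's growth rate, and reduced to the norm-minimal allocation
consistent with all constraints. The 1-norm baseline is the default;
the 2-norm variant exists to check robustness of conclusions to the
baseline construction.

## Evaluation

Predicted and baseline allocations are aligned on the intersection of
enzymes above a usage floor ($10^{-12}$ mmol/gDW) in both — the only
support on which $\log_{10}$ comparison is well defined without
pseudo-counts — then compared by Pearson correlation and the root
median squared error
$\mathrm{RMdSE} = \sqrt{\mathrm{median}_i\,(x_i - y_i)^2}$ of the log10
values. Method score lists across conditions are compared pairwise with
the two-sided Wilcoxon rank-sum test (exact below 10 scores per group,
normal approximation with continuity correction otherwise), Bonferroni
multiplied by the number of method pairs and capped at 1.
`sweepLambda()` solves LP2/QP2 over a $\lambda$ grid (default step 0.1
on $[0,1]$) and reports the $\lambda$ with the highest correlation to
the baseline, resolving ties toward smaller $\lambda$ — the
proteome-aware limit.

## Solvers

All problems reduce to linear or diagonally-quadratic programs over
$[v, e]$ with absolute values encoded by split non-negative auxiliary
variables. Problems are assembled in allocation *fractions*
($e = E/E_{tot}$), which keeps coefficients within a few orders of
magnitude of 1 despite kcats spanning $10^2$–$10^5\,h^{-1}$ and
abundances $10^{-6}$–$10^{-2}$ mmol/gDW; enzyme-capacity rows are
additionally row-normalized. Pure LPs are solved exactly by the
two-phase simplex of `boot::simplex` (variables fixed by
`lb == ub` are eliminated first; if the simplex fails on a degenerate
tableau the ridged QP path is used as a fallback). Quadratic programs go
through `quadprog::solve.QP` with a $10^{-9}$ ridge on zero-curvature
variables, which also acts as a deterministic least-norm tie-break on
degenerate optimal faces. Reported objective values are recomputed from
the solution vector, never taken from the (ridged) solver objective.
Among exactly-tied alternative optima the first solver vertex is
returned; determinism is guaranteed for a fixed backend, not across
backends.

## The synthetic generator

`generateToyPcgem()` builds the study system for all tests: a substrate
uptake feeding `nLinear` metabolic steps (default 6), each catalysed by
`nBranches` parallel isozyme reactions (default 2) with log-uniform
kcats in $[10^2, 10^5]\,h^{-1}$, ending in a biomass pseudo-reaction;
molecular weights are lognormal around 40 g/mmol, and the planted
growth rate is 0.4 h$^{-1}$. The ground truth is the 1-norm-minimal
allocation supporting that growth rate, and the model's pool is 1.2
times the planted total — a modest proteome reserve.

One generator feature is essential and deliberately chosen: each
isozyme carries an intrinsic expression-capacity bound of
`capFraction = 0.7` of the planted flux. Without it, a toy network's
minimal-enzyme truth concentrates each step on its best isozyme, every
projection problem collapses onto the same forced usage vector, and all
methods become indistinguishable at this scale. With the caps the truth
itself must co-express isozymes — the distributed isozyme usage seen in
measured proteomes — so the baseline inherits per-enzyme measurement
structure (binding caps carry noise; overflow flux records the
complement) while flux-parsimony, blind to kcats, distributes splits
arbitrarily. This is precisely the regime in which the methods differ
at genome scale.

`simulateCondition()` derives an alternative condition by perturbation
— closing the dominant isozyme of the first step (`block_branch`),
scaling the uptake bound (`scale_uptake`, default factor 0.38, which
brings the uptake just below the reference demand so capacity caps stay
binding), or degrading the kcats of the truth-carrying isozymes
(`shift_kcat`) — and recomputes the alternative ground truth either by
minimal adjustment from the noise-free reference truth (`aligned` mode:
the hypothesis under which the distance variants are exact by
construction) or by independent re-optimization (`adversarial` mode, to
probe the failure case). Proteomics for both conditions are the truths
multiplied by lognormal noise $10^{\sigma z}$ with per-enzyme standard
normal draws $z$ and $\sigma = 0.2$ log10 units by default (a typical
proteomics coefficient-of-variation regime). The draws $z$ are fixed by
the seed and scaled by $\sigma$, so comparisons across noise levels
share randomness (common random numbers); this makes the recovery-error
curve in the tests deterministic-monotone rather than monotone only in
expectation.

What the generator does **not** emulate: genome-scale topology
(cofactor coupling, loops, compartments), enzyme complexes with shared
subunits, condition-dependent kcats, measurement missingness beyond the
truth support, and systematic (non-lognormal) quantification biases.
Passing tests therefore demonstrate correctness of the optimization
stack and the qualitative behaviour of the methods under the stated
assumptions — not predictive performance on real proteomes.

## Worked example

```{r example, eval = FALSE}
toy <- generateToyPcgem(ToySpec(seed = 1))
sim <- simulateCondition(toy, perturbation = "scale_uptake")
bm <- benchmarkCondition(toy, sim,
                         methods = c("LP1", "PFBA", "NULL"))
bm$scores
```

The test suite runs this workflow over 20 seeded condition pairs and
checks that the median log10 Pearson correlation of the Manhattan
variant exceeds parsimonious FBA's, and that both exceed the kcat null
model (whose correlation is strongly negative here: minimal allocations
scale as $v/k_{cat}$, so kcat pseudo-abundances anti-correlate with
any usage-shaped baseline). `scripts/acceptance.R` recomputes the same
quantities from scratch.

## Numerical choices and problem sizes

* Growth flexibility is a symmetric interval
  $[\mu(1-f), \mu(1+f)]$, $f = 0.05$ by default; sidedness is not
  dictated by the biology, so the least-informative symmetric reading
  is used and $f$ is configurable.
* Uptake-bound relaxation is multiplicative, $+1\%$ of the current
  bound per round applied to all measured uptake bounds simultaneously,
  with the round count capped (`maxFlexRounds`, default 200); the log
  of rounds is returned and bounds are only ever relaxed.
* The enzyme pool derived from protein content uses the GECKO-style
  mass rule $E_{tot} = P_{tot} \cdot f \cdot \sigma / \overline{MW}$
  with $f = \sigma = 0.5$ defaults; molar accounting is the default
  throughout, mass-weighted accounting is available through the
  molecular weights.
* The usage floor defining allocation membership is $10^{-12}$
  mmol/gDW.
* The kcat null model aggregates an enzyme's kcats by maximum (rule
  configurable: mean, first), since a raw pseudo-abundance is undefined
  for multi-reaction enzymes.
* Test problems use networks of at most ~25 irreversible reactions and
  ~12 enzymes; the benchmark suite uses 20 seeded condition pairs and
  the noise sweep 4 levels x 20 seeds. These sizes make every
  optimum checkable against an independent solver and keep the whole
  suite to a couple of minutes on one CPU.

## Known limitations

* Alternative optima of the LPs are vertex-dependent; parked pool mass
  on distance-free enzymes is reproducible for a fixed backend but not
  meaningful enzyme by enzyme.
* The two-term variants inherit MOMA's sensitivity to the reference
  flux vector; $v_{ref}$ from the flexibilized maximum-growth optimum
  is one defensible choice among several.
* Isozymes are modelled as independent capacity channels and complexes
  as all-subunit requirements; partial complexes and promiscuous
  kinetics are out of scope.
* The SBML reader supports the GECKO dialect (level 3 with fbc bounds);
  it is not a general SBML importer.
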