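---
title: "Finding isles of robustness for harvest control rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding isles of robustness for harvest control rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustisles)
```

## The problem

Fishery managers rarely know the true state of the stocks they regulate.
Natural mortality, mean weight-at-age, recruitment and gear selectivity are
all uncertain, and probability distributions for them are usually
unavailable. Info-gap decision theory asks a different question than the
usual probabilistic risk analysis: *how wrong can our parameter estimates be
before a chosen management rule stops meeting its goal?* The answer -- the
horizon of uncertainty that can be tolerated -- is easy to derive for
analytic toy models but not for a simulation model of a mixed fishery.

`robustisles` implements a pragmatic route for simulation models. A
deterministic fishery simulator evaluates a reward (here, final spawning
biomass) for any combination of management parameters `Q` and states of
Nature `U`. The joint space is normalized so every axis runs over [0, 1]
with the reference parameterisation at 0.5, explored with a Latin hypercube
design, and each run is labelled a success or failure against a critical
value (e.g. SSB at or above 8000 t). Variance decomposition ranks the
natural axes; two stages of conditional-inference classification trees then
carve the space into boxes -- a main tree on `Q` alone, and per-leaf
subtrees on the influential `U` axes. Leaves whose success proportion
reaches a threshold (99% by default) and that carry enough records are the
*isles of robustness*: the natural-axis sides of such a box, measured from
0.5 to the binding bound, are exactly the tolerated uncertainty margins.

## The simulator

The population submodel is a standard monthly-step age-structured model of
the kind stock-assessment working groups use. Each population carries ages
from recruitment to a plus-group; monthly survival is exponential with
`Z = F + M` (annual rates, applied as `Z/12`), catch follows the Baranov
relation `C = (F/Z)(1 - e^{-Z/12}) N`, and cohorts age each January, when
scheduled recruits enter the first age class (forced assessment estimates
for the first three simulated years, a constant thereafter). Numbers
balance exactly every month -- `run_simulation()` tracks the worst relative
residual and the tests require it below 1e-9.

Fishing pressure comes from fleets practising metiers (gear + target +
season). Per-age fishing mortality is
`F(a) = Q_pop * sum_m TF_m * sel_gear(L(a)) * E_m`, with von Bertalanffy
length-at-age feeding a logistic (or knife-edge) length-based selectivity.
Effort is reallocated across a fleet's metiers every year by a gravity
model blending fishing habits with last year's value per unit effort.
Minimum landing sizes force discarding of undersized fish; once a
population's TAC is exhausted, metiers targeting it stop (their effort
moving to the same-gear metier with the highest attractivity, an ordering
that prefers alternatives within the fleet's own strategy), while bycatch
of the closed species is discarded. A species-dependent fraction of
discards survives and rejoins its year class.

Management follows the ICES-style MSY transition: three forced years with
the historical TACs, then a harvest control rule. Each year the rule blends
the realized pre-transition fishing mortality with `Fmsy`, the blend weight
growing by `1/transition_years` per year (20 points per year at the
reference duration of 5), caps the result at `Fpa`, and scales it by
`SSB/MsyBtrigger` when spawning biomass is below the trigger (a hard-floor
variant is available via `btrigger_rule = "hard_floor"`). The target F is
converted to a TAC by a deterministic one-year Baranov forecast from the
current abundance, using last year's realized selectivity-at-age pattern
rescaled to the target; the proposed TAC is finally clamped to ±15% of the
previous one. Several of these steps are not published for the original
platform, so the package makes the simplest consistent choices and records
them here:

* **F-to-TAC conversion** is a status-quo-recruitment one-year forecast --
  monotone in the target F and zero at zero, which makes it testable.
* **The ±`varTAC` bound anchors on the last fixed TAC** (the 2010 value)
  when the rule first applies, and both the `Fpa` cap and the bound are
  applied, bound last. Note the historical 2008-2010 TACs themselves moved
  by more than 15%; the bound is a property of the rule, so the package
  asserts it from the anchor year onwards.
* **The pre-transition F is measured inside the simulation** as the
  realized mean F of the third simulated year rather than supplied
  externally.
* **Realized annual F** is reported as the catch-consistent inversion of
  the Baranov relation against January abundance, averaged over a
  configurable age range (ages 2+ by default); a simpler summed-monthly-F
  accessor is attached to the simulation output.
* **Space is collapsed to one homogeneous zone per population** and the
  recruitment birthday is fixed to January, with SSB evaluated at the same
  instant.

## The demonstration scenario

`make_demo_scenario()` builds a reduced two-population Eastern English
Channel fishery: sole and plaice in ICES division 7D, gillnetters focusing
on sole and beam trawlers targeting both flatfish. All published constants
are used as-is: forced recruitments, fixed TACs for 2008-2010, minimum
landing sizes of 24 cm (sole) and 27 cm (plaice), and the management
reference values (`Fmsy` 0.29/0.23, `Fpa` 0.40/0.45, trigger biomass
8000 t, 5-year transition, 15% TAC variation, discard survival 0.25).
Life-history vectors that are not published -- weight-at-age, maturity
ogives, initial abundance, selectivity parameters, efforts, catchability
and the habit weight -- are synthetic placeholders flagged in the
`synthetic` field of each population and chosen once for realistic
magnitudes (sole SSB near 14 000 t and mean F near 0.4 in the forced phase,
plaice harder-pressed than sole). The scenario therefore exercises every
mechanism at sensible scales but is *not* a calibrated assessment model,
and no numeric result obtained from it should be read as advice about the
real fishery. That is also why the package's acceptance checks target the
published rule constants and the method's statistical properties rather
than any stock-specific simulation output.

```{r demo, eval = FALSE}
scenario <- make_demo_scenario()
sim <- run_simulation(scenario)
plot_simulation(sim)
attr(sim, "tac_log")
```

## Exploring the uncertainty space

`build_space()` gives every registered axis a ±50% window around its
reference (the width managers typically concede for stock estimates), an
affine map onto [0, 1] with the reference at 0.5, and a Q/U partition.
Axes whose reference sits at an edge carry explicit ranges -- discard
survival is explored on [0, 0.5] -- and negative references (the growth
origin `T0`) use ±50% of the magnitude so windows stay ordered. A zero
reference without an explicit range is rejected.

`lhs_design()` wraps a plain random Latin hypercube (uniform placement
within each stratum, not midpoints, so repeated seeds explore different
within-stratum positions); one point per axis per stratum is guaranteed and
asserted exhaustively in the tests. `run_campaign()` evaluates the
simulator once per design row -- runs are independent, failures are
recorded as failed rows without stopping the campaign -- and
`label_success()` applies the non-strict success rules (an output exactly
at the critical value counts as a success). The campaign size is a
trade-off between tree stability and computing time; 5000 runs is the
package default for the demo scenario, while the test-suite examples use
800-5000 records so the whole suite stays interactive.

## Ranking inputs

First-order indices `S_i = Var(E[Y|X_i]) / Var(Y)` are estimated by the
binned correlation ratio: equal-count bins on the input (one bin per ~100
records, at least 10), between-bin variance of the output means over total
variance. The estimator works on any design, so the single LHS campaign
feeds both the sensitivity ranking and the trees; no paired pick-freeze
re-simulation is needed (a pick-freeze backend, `sobol_pick_freeze()`, is
provided as an independent cross-check and agrees on analytic toys).
Pairwise interactions use the same construction on a 2-D equal-count grid.
Accuracy on closed-form cases (additive linear shares, the Ishigami
function) is within ±0.05 at the tested sample sizes; the estimator has a
small positive bias of order `bins/n`, which the default bin count keeps
near 0.01. `rank_and_select()` picks the influential set, by default at
the largest relative drop in the sorted indices ("the parameters that
really stand out"), reporting the variance fraction the selection explains.

## Classification trees and stability

`fit_ctree()` follows the conditional-inference framework: at each node the
standardized linear statistic between each axis and the binary response is
tested by Monte-Carlo permutation (9999 draws by default; an asymptotic
normal option exists for speed), Bonferroni-corrected across axes. If the
smallest adjusted p-value exceeds `alpha` (0.05) the node stops -- this
significance-based stopping avoids the selection bias and post-hoc pruning
of exhaustive-search trees. Otherwise the winning axis is split at the
cutpoint maximizing the absolute standardized two-sample statistic, subject
to `min_leaf` (50) records per side; among tied cutpoints the one closest
to the axis median is chosen, deterministically. Under the null the root
splits at rate ≈ `alpha` (checked over 500 replicates), and on noise-free
thresholds the split lands within one inter-point gap of the truth,
agreeing with an independent CART fit.

The two-stage procedure mirrors the decision problem: the main tree on
management axes answers "which rules could work?", the per-leaf subtrees on
the influential natural axes answer "under which states of Nature do they
work?". `label_robust_leaves()` marks leaves with at least 99% successes
*and* at least 5% of the root records (`min_weight`; boxes supported by a
handful of simulations are flagged `low_weight` instead) -- both thresholds
are configurable, since the tolerance for a few boundary mislabels is a
risk-attitude choice.

Because tree topology can be unstable, `stability_analysis()` refits on 500
random 95% subsets, fingerprints each topology as the depth-tagged
breadth-first sequence of split axes (split values are deliberately
ignored; this is the package's operational definition of a "tree type"),
and reports the modal topology's per-node mean split values and standard
deviations. On separable data the modal topology appears in all replicates
with split deviations at the data resolution.

`extract_regions()` converts each robust leaf into box constraints in
normalized and natural units. For every natural axis the tolerated margin
is the normalized distance from 0.5 to the nearest binding bound (0.5 when
unconstrained, 0 when the box excludes the reference), also expressed as a
percentage of the reference value: for a symmetric ±50% window a normalized
margin of 0.24 means the parameter may deviate up to 24% from its reference
before the goal is in doubt. Boxes containing 0.5 on all natural axes are
compatible with current knowledge; the rest are reachable only by changing
management. Finally `robustness_horizon()` gives the classic info-gap
summary on any management box: the Chebyshev distance from the reference to
the nearest explored failure, which the tests require to agree exactly with
an exhaustive scan.

```{r pipeline, eval = FALSE}
toy <- make_toy_scenario("box-recovery", noise = 0.01)
space <- build_space(toy)
design <- lhs_design(space, 5000, seed = 1)
records <- label_success(run_campaign(design, toy), toy$rules)

main <- fit_ctree(records, c("q1", "q2"), seed = 1) |> label_robust_leaves()
subs <- grow_subtrees(main, records, c("u1", "u2"), seed = 1) |>
  lapply(label_robust_leaves)
extract_regions(main, subs, space)
```

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one estimator `(1 + exceedances) /
  (n_perm + 1)`, so they are never zero; ties with the observed statistic
  count as exceedances (within 1e-12).
* Pure nodes and nodes smaller than `2 * min_leaf` become leaves without
  testing; a constant response is rejected up front, as is a constant
  output in the sensitivity estimator ("degenerate output").
* The Baranov inversion brackets F in [0, 20] / yr and returns the cap if
  the observed catch is unattainable (it never is in practice; returned
  discard survivors can push realized catch slightly above the no-return
  Baranov curve, which the inversion absorbs).
* The label-noise option of the box-recovery toy draws a *random* label for
  the selected fraction of records (so 1% noise leaves an expected 99.5%
  success rate inside the true box) -- noise models mislabelling, not
  systematic inversion.
* All randomness is seed-controlled and local: design generation,
  permutation draws and stability subsets save and restore the global RNG
  state, so campaigns are reproducible end to end from (scenario, seeds).

## What the toys do and do not show

The analytic toys (`single-cohort-analytic`, `box-recovery`,
`null-calibration`) have closed-form answers, which makes them exact
oracles for the simulator's catch accounting, the tree machinery and the
horizon estimator. They share the axis-box structure of real problems but
none of their hard parts: real success boundaries are curved and
interaction-driven, real campaigns contain simulation noise at the boundary
only through parameter discreteness, and real trees must cope with
correlated axes. Passing the toys therefore validates the machinery, not
the ecological realism of any particular scenario; the demonstration
scenario adds realistic mechanism coverage but, with synthetic life-history
placeholders, still no calibration. Results on a real fishery require the
full calibrated model those placeholders stand in for.

## Known limitations

* One homogeneous zone per population: no spatial management, migration or
  zone-specific effort can be represented.
* The success boundary is approximated by axis-aligned boxes; strongly
  curved or diagonal boundaries inflate the number of leaves and shrink
  the reported margins (conservative, but coarse).
* Subtrees are grown from the single main tree fitted on the full dataset,
  not from a consensus tree across resamples; the stability report
  quantifies, but does not propagate, topology uncertainty.
* Single-output analysis only: goals on several outputs must be analysed
  one at a time and intersected manually.
* The binned correlation ratio slightly overestimates very small indices;
  rankings are unaffected but absolute values below ~0.02 should be read
  as "negligible".
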