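---
title: "Models and design decisions in sprawlrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in sprawlrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sprawlrisk simulates the expansion of multiple construction-land classes —
urban built-up (UB), industrial and mining (IM), rural settlements (RS) —
across an 8-class land-use mosaic, and maps the ecological risk that this
expansion imposes on the surrounding ecosystem. This vignette explains each
model, its assumptions, the tunable parameters, and the decisions taken where
the underlying formulations leave room for interpretation.

## The demand model

Land demand is a homogeneous Markov chain on class areas: the transition
probability matrix `P` is the row-normalised cross-tabulation of two
calibration maps, and demand projects as `d(t+1) = d(t) %*% P`. Two
assumptions matter:

* **One-step projection.** The matrix estimated over a calibration interval
  (say 13 years) is applied as a single step to project an equally long
  horizon, not annualised into a 13-step chain. Annualising a row-stochastic
  matrix requires a matrix root that need not exist or be stochastic; the
  one-step reading is also what reproduces the bundled Quanzhou demand table
  from its printed matrix.
* **Published matrices are used as printed.** Entries rounded to four
  decimals leave row sums off unity by up to 2e-4, so
  `transition_matrix()` takes a row-sum tolerance (`tol = 1e-9` default for
  estimated matrices, `1e-3` for printed ones) and never renormalises
  silently; area conservation under projection is exact only for exactly
  stochastic matrices.

Planning scenarios revise the matrix toward a target built-up class *j*:
every other row's *j*-column entry is scaled by `mu_j` (the ratio of planned
to Markov-predicted new area), and the remaining entries of each row *i* are
rebalanced by `mu_i = (1 - mu_j P_ij) / (sum_k P_ik - P_ij)`, which preserves
each row sum identically. The row of class *j* itself — the renewal of
existing built-up land — is deliberately untouched. `sum_k P_ik` is taken as
the full row sum: with exactly stochastic rows this gives
`mu_i = (1 - mu_j P_ij)/(1 - P_ij)`, the reading that reproduces the bundled
urban-transformation matrix from the baseline block at `mu_j = 2.16` to all
four printed decimals. The bundled industry-priority matrix is *not*
consistent with its quoted coefficient 1.54 — its IM column sits uniformly at
about 1.71 times the baseline — so the package ships that matrix as data and
does not attempt to re-derive it. Scenario demand targets stated as "x%
above baseline" are applied with `scale_demand()` on the projected baseline
demand.

Revisions with `mu_j * P_ij >= 1` for any row are rejected as infeasible
(the rebalanced rest-of-row would need negative mass).

## Transition-rule mining

Rule mining is a per-class binary classification: positives are cells newly
converted to class *k* between the calibration dates, negatives are cells
that did not change class at all, both sampled uniformly without replacement
at a common sampling rate (default 0.05 in the pipeline runner; tests use
higher rates on small grids). Negatives are drawn from *all* unchanged
cells, not only class-adjacent ones, since the problem statement is "newly
developed vs not".

A probability forest (ranger, classification trees with probability
averaging) supplies each class's development-probability surface as the
positive-class vote fraction at every cell, with defaults of 20 trees and
`mtry = 9` clamped to the number of available drivers. For binary 0/1
targets this equals the vote fraction of a regression forest on the labels.
Driver contributions are mean impurity decreases normalised to sum one.
Fits run single-threaded with a fixed seed, so surfaces are bit-reproducible
regardless of the host's core count.

## The cellular automaton

Each iteration recomputes, per class, the Moore-neighbourhood cover fraction
`Omega` from the start-of-iteration map (synchronous neighbourhoods —
whether the reference implementation updates within an iteration is
unknowable from its description, and the synchronous choice avoids
raster-order artifacts; it is recorded here as a divergence risk). Border
cells average over their available neighbours, so a uniform map scores 1
everywhere. The overall probability is

* organic: `P * Omega * I_k` where `Omega > 0`;
* spontaneous: `P * (r * mu_k) * I_k` where `Omega = 0`, a fresh uniform
  draw `r < P`, and the cell passes the percent-of-seeds gate (a seeded
  uniform draw below PoS). With `P = 1`, `mu_k = 0.9` the seeded branch has
  conditional expectation 0.45, which the tests verify.

The inertia `I_k` starts at 1 and adapts from the residual history
`G = developed - demand`: unchanged when `|G1| <= |G2|`, scaled by `G2/G1`
when `G1 < G2 < 0` and by `G1/G2` when `G1 > G2 > 0`. The formulation covers
only same-sign worsening residuals; sign changes and zeros leave `I`
unchanged (conservative).

Cells roulette-draw a candidate class proportionally to the overall
probabilities; the conversion commits iff the candidate's *development*
probability exceeds the decreasing threshold `tau = delta^l * r` (`delta` =
0.1 by default; `r` truncated normal on (0, 2) with mean 1 — the stated
support and mean leave the spread free, and sd 1 before truncation is used),
the cost matrix permits the transition, the candidate class still needs
cells, and the donor class can shed them. The decay counter `l` increments
whenever an iteration improves the summed absolute residuals by less than
`Step` (default 50 cells). Committing in a seeded random permutation with
running per-class counters makes every iteration demand-feasible, monotone
in total residual, and deterministic given the seed. Classes at demand are
frozen as destinations. Demand vectors in hectares are converted to cells
with rounding repaired on the largest class; a discrepancy beyond 0.5% of
the map is rejected before iterating. Convergence tolerance per class is 1%
of the demanded change or 10 cells, whichever is larger; hitting
`max_iterations` returns the best map with a warning rather than an error.

The default cost matrix permits every transition (the calibration matrices
show nonzero transitions even out of water), and neighbourhood weights
default to 1 for every class; both are configurable.

## Validation metrics

Overall accuracy is the diagonal share of the observed-vs-simulated
confusion matrix; Kappa corrects by the marginal-product expectation. The
figure of merit superimposes initial, observed and simulated maps:
hits (observed change simulated identically), misses (observed change,
simulated persistence), wrong hits (observed change, different simulated
change), false alarms (observed persistence, simulated change). Per-class
FoM conditions on the *destination* class only — a cell counts for class *k*
when *k* is the destination of the observed or simulated transition — and
"urban" FoM takes the union of the three construction classes. Conditioning
on source classes too is a defensible alternative; destination-only is
implemented and documented because the aggregate is described as the FoM of
the simulated construction land.

## Ecological indicators

The three service formulas multiply normalised [0, 1] factors:
`WR = NPP*Fsic*Fpre*(1-Fslo)`, `Spro = NPP*(1-k)*(1-Fslo)`,
`Sbio = NPP*Fpre*Ftem*(1-Falt)`. Two printed forms are corrected
deliberately: a soil-conservation factor printed as `(k-1)` would make the
service uniformly non-positive for erodibility `k` in [0, 1], so `(1-k)` is
used (protection falls as erodibility rises); and a soil-erosion term
printed as `C_i 4` is read as the fourth root of the four-factor product
`(R*K*LS*C)^(1/4)` — the geometric-mean sensitivity formulation — rather
than a dimensionally arbitrary product times four. Soil fertility is the
stated weighted sum (0.15, 0.3, 0.4, 0.15 on N, P, K, organic matter).
Normalising inputs is the caller's duty; `normalize_minmax()` is provided.

Riverside sensitivity comes from minimal cumulative resistance: a least-cost
surface over the 8-connected grid where a step costs the step length (cell
size, x sqrt(2) diagonally, for metric consistency) times the mean
resistance of its two cells, from water-cell sources. It is computed by
Dijkstra's algorithm through a zero-cost super-source; unreachable cells get
`Inf`. The land-cover-to-resistance table is the caller's input — any
bundled default would be illustrative only, so none is imposed.

Grading uses exact Fisher–Jenks natural breaks (dynamic programming over
the sorted unique values, minimising total within-class squared deviation),
verified in the tests against exhaustive search on small instances. Fewer
distinct values than classes is an error, not a silent collapse.

## The risk index

The study extent is tiled into square zones (default 600 m, which nests
30 m cells exactly at 20 x 20); edge zones are clipped so zone areas sum to
the extent. Stress occupancy per zone and construction class counts core
cells at the class's stress level (defaults IM 3, UB 2, RS 1) and
buffer-ring cells — within the class's buffer distance (1.5, 1, 2 km) but
outside the core — at half that level. The zone's ERI multiplies the summed
stress occupancy fraction by the weighted mean of the six indicator values.

The indicator term is the open design point: the formulation refers to
"changes in the indicators in the risk zone" without a formula. The package
averages the *graded* indicator (grade / 5, in [0, 1]) over the zone's cells
converted to construction land between the base and scenario maps — the
graded ecological value actually exposed to loss — falling back to
buffer-exposed cells, then to all zone cells, when no conversion occurred.
Zones with zero stress occupancy have ERI exactly 0 regardless. Indicator
weights default to 1/6 each; all weights, levels, buffers and the
attenuation are configurable. Zone ERIs are classified into five levels by
the same natural-breaks routine; a degenerate (constant) ERI distribution is
reported as an error.

## The synthetic generator

`generate_region()` emulates the data structure the pipeline consumes: a
patchy 8-class mosaic grown by seeded random accretion from random patch
seeds to a target mixture (default: agriculture 35%, woodland 25%, grassland
15%, water 6%, UB 8%, beach 3%, RS 5%, IM 3% — a plausible coastal-province
profile dominated by farmland and forest); drivers as a west–east gradient,
the distance transform from the grid centre, and smoothed white noise, each
with known monotone effect coefficients on the growing classes; and
ecological fields as moving-average-smoothed noise clipped to [0, 1]
(dependency-light, seeded, with a controllable correlation length — chosen
over Gaussian-process simulation for reproducibility and speed).
`evolve_reference_growth()` then adds ground-truth growth: the organic share
attaches 8-connected to existing patches at the highest-scoring frontier
cells, the spontaneous share founds the demanded number of detached seeds
(sampled proportionally to the score, kept non-adjacent at placement) and
grows them locally, recording each cell's true growth mode.

What the generator does *not* emulate: real landscape autocorrelation
structure, anisotropic drivers, multi-date driver dynamics, measurement
error in class maps, or the areal statistics of any real region. Passing
tests therefore demonstrate that the algorithms recover structure they are
specified to recover, not that the pipeline is calibrated for any
particular real landscape.

Default scales: the generator's documented conditions are stated at
200 x 200 cells of 30 m with growth of 600/400/200 cells (UB/IM/RS); the
test suite exercises the pipeline at 30–100 cells a side with growth scaled
proportionally, and the stage runner scales the recipe by grid area.
Property suites use 20 seeded replicates where replicate counts are part of
the property (driver-recovery rate, patch-count monotonicity in PoS, the
shuffled-surface null comparison).

## Known limitations

* Raster I/O is ESRI ASCII grid only; no reprojection or resampling is
  offered, and grids must be exactly aligned (shape, cell size, origin).
* The allocator treats demand as exact cell counts; fractional-hectare
  demands are rounded, with the residual absorbed by the largest class.
* Per-class FoM with destination-only conditioning can differ from
  source-conditioned variants reported elsewhere.
* The adaptive-inertia rule is only defined for same-sign residual
  histories; prolonged oscillation around demand leaves `I` at its last
  value.
* Scenario-surface weights (traffic/centre/aggregation, socio-economic
  factors, the endowment exponent `sigma`) have no data-driven defaults;
  the shipped values (0.4/0.3/0.3, uniform, 0.5) are conventions to be
  overridden per study. In the endowment term `El^sigma`, the exponent
  reading is used; an `El * sigma` reading is algebraically distinguishable
  only away from `sigma = 1` and is not offered.
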