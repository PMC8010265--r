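---
title: "Estimating critical soil-water thresholds from pot dry-downs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating critical soil-water thresholds from pot dry-downs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drydownr)
```

## The measurement problem

Comparing the drought behaviour of plant genotypes in the field confounds
genotype with water supply: two plots rarely dry at the same rate. The pot
dry-down protocol removes that confound. Plants grow in sealed pots watered
to container capacity; watering is then withheld from the drought
treatment, every pot is weighed daily, and paired control pots are refilled
each day with exactly the water they lost. Because the only unknown fluxes
are transpiration and soil surface evaporation (measured separately on bare
pots), the daily weight series *is* the water-balance record of each plant.

Two derived variables put every pot, trial and species on the same axes:

* **FTSW**, the fraction of transpirable soil water:
  `(weight_d - weight_final) / (weight_initial - weight_final)`, where
  initial and final are the first and last weighing of the trial. FTSW is 1
  at container capacity and 0 when the plant has exhausted the water it can
  extract.
* **NTR**, the normalized transpiration rate. A drought pot's daily loss is
  first divided by the mean loss of its irrigated controls (the
  *transpiration ratio*, TR, which cancels day-to-day swings in evaporative
  demand), then divided by the pot's own well-watered baseline, taken as the
  mean TR of days 3 and 5. NTR is therefore ~1 while water is ample.

Plotted against each other, the points trace a characteristic shape: NTR
holds near 1 until a critical threshold **FTSWc**, then falls roughly
linearly to 0. The threshold is read as the onset of stomatal closure: a
low FTSWc genotype keeps transpiring in drier soil (an advantage in short
droughts), a high FTSWc genotype banks water early (an advantage in long
ones).

## The two fitted response models

**Plateau (breakpoint) regression** is the estimator of FTSWc. The model is
the continuous two-segment curve

```
NTR(f) = plateau,                f >= c
NTR(f) = plateau * f / c,        f <  c        (through-origin default)
```

`fit_plateau()` profiles out the linear parameters in closed form at each
candidate breakpoint, grid-searches `c` over `[0.02, 0.95]` in steps of
0.005 (candidates must leave at least two points on each side, ties go to
the smaller threshold), then refines the winner between its neighbouring
grid points with `stats::optimize()`. Because the refinement only ever
lowers the SSE, the fit can never be beaten by `grid_breakpoint_oracle()`,
the deliberately brute-force check kept in the package — this dominance is
asserted on random data in the test suite. The through-origin constraint
(`slope = plateau/c`) encodes the observation that transpiration declines
linearly *to zero*; `free_slope = TRUE` relaxes it, and under that
relaxation rescaling NTR by a constant rescales plateau and slope but
leaves the breakpoint untouched. The plateau level is estimated rather than
pinned at 1 because empirical baselines drift; `fix_plateau = 1` pins it.

Uncertainty for the breakpoint comes from a seeded percentile bootstrap
over response points (500 draws by default). No analytic interval is
offered: the SSE profile at a breakpoint is not smooth, so the usual
asymptotics are unreliable at these sample sizes.

**Logistic regression**, `NTR = 1 / (1 + A exp(B FTSW))`, is the smooth
companion description of the same response. `fit_logistic()` uses
nonlinear least squares (`minpack.lm::nlsLM`, falling back to
`stats::nls(algorithm = "port")`) started from the log-linearization
`log(1/NTR - 1) = log A + B f` plus a fixed multi-start grid
(`A` in 10/50/200, `B` in -5/-15/-30); if no start converges the fit is
returned flagged, never silently replaced. Curves of two cultivars are
called *distinct* only when the 95% confidence interval of `A` or of `B`
fails to overlap (`compare_cultivar_curves()`).

## Pipeline conventions and edge cases

Several choices in `build_response_points()` deserve explicit statement:

* **TR as a loss ratio.** TR is computed from daily water *losses*, not raw
  pot weights, because only the loss ratio makes NTR ~ 1 under ample water;
  the literal weight ratio remains available as `tr_mode = "weight_ratio"`.
* **Rewatered controls.** Irrigated pots are recorded pre-rewatering and
  refilled to their day-1 weight, so their daily loss is
  `weight[1] - weight[d]` (`daily_water_loss(rewatered = TRUE)`).
* **Evaporation correction.** The mean bare-pot loss is subtracted from
  drought and control pots symmetrically (keeping TR unbiased) and
  corrected losses are floored at zero. Whether the original protocol
  corrected or merely monitored evaporation is not documented; symmetric
  subtraction is the neutral choice.
* **Pairing.** Each drought pot is compared with the average of *all*
  control replicates of its cultivar in the same experiment — pairing is
  not documented in the protocol, and averaging minimizes control noise.
* **Interval timing.** The loss over `d-1 -> d` is paired with the FTSW at
  the *start* of that interval: the soil state that actually drove the
  day's transpiration. `ftsw_day = "end"` is available for comparison.
* **Degenerate inputs.** Days where the controls lost no water leave TR
  undefined; such points are flagged and excluded from fitting, and
  cultivars that cannot be processed at all (no controls, dead baseline)
  are reported in a `skipped` attribute rather than dropped silently.
  FTSW is clamped to `[0, 1]` against weighing noise; its endpoints are 1
  and 0 by construction.

Multiple experiments of different lengths can sit in one dataset; each
pot's FTSW normalization makes them commensurate, and points are pooled
per cultivar (per-replicate fitting then averaging is possible by
splitting the point table, but pooling is the default).

## What the simulator emulates

`simulate_experiment()` generates the full two-treatment, replicated
design with bare evaporation pots, one RNG stream per pot (derived from
the design seed and the pot index, so row order can never change a
result). Each drought pot follows an explicit daily Euler water balance:
transpiration demand is `t_pot * response_function(FTSW)` evaluated at
start-of-day FTSW, transpiration and then surface evaporation draw down
the transpirable pool, each capped by what remains, and the pool never
goes negative. Daily stepping from the start-of-day state is chosen
deliberately: it matches the daily weighing cadence *and* makes noiseless
simulated response points fall exactly on the generating curve, which is
what gives the parameter-recovery tests a sharp truth to recover. Weighing
noise is pure observation noise added to the reported weights; the
underlying balance stays exact.

Defaults describe a plausible 4 L glasshouse pot: 5000 g saturated weight,
800 g transpirable water, 10 g/day bare-soil evaporation, 64 g/day
potential transpiration, 19-day trial (the longer of the two trial lengths
in the motivating design), two technical replicates, ten bare pots. The
64/800 pairing was chosen once so that (i) a pot crossing its threshold
takes several days to exhaust the remainder — the declining segment is
sampled at the daily cadence even for thresholds near 0.1, since the
below-threshold depletion rate `t_pot/(c * transpirable)` stays below 1 —
and (ii) pots dry out within the trial, with about 10–14 days to the end
of transpiration, consistent with the reported timing of the motivating
trials. One artefact of the daily step is worth knowing: on the final
drying day there is too little water left to supply the full bare-pot
evaporation, so the evaporation-corrected loss under-reports transpiration
by at most `evap_g_day / t_pot_g` (~0.16 NTR) on that single point. The
recovery tests show its influence on the estimated threshold is below
0.004.

What the simulator does *not* emulate: soil hydraulics (retention curves,
conductivity limits), root growth, within-day demand dynamics, canopy
energy balance, or biomass gain by default (a `growth_g_day` confound
exists to probe sensitivity, since raw weights are never growth-corrected
downstream). Passing recovery tests therefore demonstrate that the
*estimator chain* is faithful, not that real glasshouse data are this
clean. An optional hook scales daily demand by `vpd/mean(vpd)` from a
supplied weather table, reflecting the qualitative link between
transpiration and vapor pressure deficit; VPD itself is computed from the
Tetens-type saturation curve (kPa throughout — the 0.6108 constant fixes
the unit) with relative humidity accepted in percent only. A
fraction-looking humidity series triggers a warning, never a silent
conversion.

## Recovery performance under the default conditions

The acceptance layer of the test suite re-runs the whole chain
(simulate -> pipeline -> plateau regression) at fixed seeds: 20 cultivars
noiselessly, where every estimated threshold must land within 0.02 of
truth (observed: within 0.004), and 50 cultivars with thresholds drawn
uniform(0.1, 0.5) under weighing noise of 0.05 on the NTR scale, where the
mean absolute error must stay below 0.03 (observed: ~0.007). The noise is
specified on the NTR scale; since a daily loss is the difference of two
noisy weights, the generator receives `noise_sd_g = 0.05 * t_pot/sqrt(2)`.

## The decade trend

Across a panel of cultivars released over nine decades, the question is
whether the mean threshold drifted with breeding era. The trend of the
per-decade means is modeled as a linear spline with one knot:

```
mean FTSWc = a + b * Time + c * max(0, Time - 5)
```

with `Time = (decade - 1915)/10`, so slopes are per decade and the knot
index 5 corresponds to 1965 — midway between the 1960 and 1970 design
points, where both natural codings fit identical piecewise shapes.
`b` is the pre-1965 slope, `b + c` the post-1965 slope (standard error
propagated through the coefficient covariance), and the p-value of `c`
tests whether the trend actually changes. Inference is two-sided t with
`n - 3` degrees of freedom. The fit is unweighted by default — it is the
trend *of the decade averages* — with `weighted = TRUE` available to
weight by cultivar count. Missing thresholds are excluded, never imputed.

On the packaged reference table the fit gives a rise of ~+0.029 per decade
before 1965 and a fall of ~-0.025 per decade after (r² ~ 0.67) — the
rise-then-fall structure, echoing the two recognised eras of white clover
improvement. The exact published coefficients for this panel cannot be
regenerated from the table itself (its prose and tabulated decade means
disagree, e.g. 0.38 vs 0.30 for the 1960s), so only the sign structure is
asserted in the acceptance tests.

## The packaged reference table

`load_table1_fixture()` ships the 80-cultivar white clover panel
(1920–2010; 59 defined thresholds, a "/" meaning the dry-down never
yielded one). Loading validates the row count, dry weights, leaf-size
tallies and an md5 digest of the file. Known internal discrepancies of the
source are resolved in favour of the table: the threshold range is
0.12–0.52 (prose: 0.11–0.50), Kotare's threshold is 0.42 (prose: 0.44; the
top-five ranking still reproduces because the 0.42 three-way tie breaks
alphabetically to Kotare), the drought dry-weight maximum is 23.33 g
(prose: 23.32), and the tabulated leaf sizes tally 1 small / 52 medium /
27 large (prose: 53 medium / 26 large). Summary statistics are kept at
full precision internally and rounded half-to-even to two decimals only
for presentation (`round2()`).

## Worked example

```{r example}
profiles <- sample_cultivar_profiles(4, seed = 42)
design <- drydown_design(noise_sd_g = 2, seed = 43)
ds <- simulate_experiment(profiles, design)

pts <- build_response_points(ds)
res <- fit_all_cultivars(pts, boot = 200, seed = 44)
res[, c("cultivar", "ftswc", "ftswc_lo", "ftswc_hi", "plateau")]
attr(ds, "truth")

fit_spline_trend(decade_means(load_table1_fixture()))
```

## Known limitations

* The daily Euler step overshoots the decline for thresholds below about
  `t_pot/transpirable` (0.08 under defaults): a pot can cross from plateau
  to dry in a single day, leaving the declining segment unsampled. The
  profile constructor accepts thresholds down to 0.05, but recovery
  guarantees are stated for 0.1 and above.
* Breakpoint bootstrap intervals are percentile intervals; they are
  honest about asymmetry but, like all bootstrap intervals at n ~ 30
  points, can undercover for thresholds near the edge of the sampled FTSW
  range.
* The trend model fixes its knot; it estimates the change in slope at
  1965, it does not search for the change point.
* Analysis-of-variance comparisons among cultivar groups are out of scope
  here; standard tools (`aov()`, `emmeans`) apply directly to the fitted
  threshold table.
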