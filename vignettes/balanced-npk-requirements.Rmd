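---
title: "Balanced N-P-K uptake requirements with queftsNPK"
author: "queftsNPK authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced N-P-K uptake requirements with queftsNPK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queftsNPK)
```

## The problem

Fertilizer recommendations for soybean need to know how much nitrogen,
phosphorus and potassium the crop must take up into its above-ground biomass
to produce a given seed yield, and in what N:P:K proportion. Plot-level trial
data answer this only noisily: the *internal efficiency* (IE, kg seed
produced per kg nutrient taken up) of any single plot reflects luxury uptake,
deficiency, and every other stress the season offered. The QUEFTS family of
models turns the *distribution* of observed IEs into a requirement estimate:
the envelope of the IE cloud defines, per nutrient, a maximum-accumulation
borderline `a` (lowest plausible IE — luxury uptake) and a maximum-dilution
borderline `d` (highest plausible IE — maximally diluted tissue), and a yield
engine built on those borderlines is inverted to find the *balanced* uptake,
the uptake combination at which no nutrient is in surplus or deficit relative
to the others.

`queftsNPK` implements that pipeline end to end: data screening and IE
computation, percentile calibration of the envelope, the forward
uptake-to-yield engine, the reverse balanced-uptake solver, seed-removal
accounting, and RMSE-based validation statistics, plus a synthetic trial
generator so everything is testable without field data.

## From plots to envelopes

Observations carry seed yield (13.5% moisture marketing basis), straw dry
matter, seed and straw nutrient concentrations (g/kg) and the harvest index.
Uptake is concentration times dry weight, with seed dry matter equal to
`(1 - 0.135)` times the marketed yield; IE divides the marketed yield by the
above-ground uptake, matching how trial tables report it. Records with
harvest index below 0.4 are excluded before calibration (the default,
adjustable threshold): a soybean crop with HI that low is assumed stressed by
something other than nutrition, and would contaminate the envelope.

Calibration reads `a` and `d` off symmetric outer percentiles of each
nutrient's IE distribution. Three standard exclusion sets are provided
(2.5/97.5, 5/95, 7.5/92.5); widening the exclusion can only narrow the
envelope, which the test suite checks as a property. Percentiles interpolate
linearly at rank `p (n - 1)` (R's type 7); with thousands of observations the
choice of convention moves the third significant digit at most, but it is
fixed and documented because the envelope values depend on it.
`soybean_envelope_sets()` ships the published soybean calibration (Set I for
N: 13.5–21.4, P: 60.4–234.6, K: 27.8–79.9 kg/kg) so the solver can be used
without raw trial data.

## The forward engine

For uptake `u_x` above the minimum uptake `r_x` (default 0), each nutrient
brackets yield between `ya = a (u - r)` and `yd = d (u - r)`, clamped to
`[0, ymax]` where `ymax` is the yield potential. Nutrients interact in pairs:
the estimate `YE(i, j)` — yield from the uptake of `j` when `i` is the other
potentially limiting nutrient — follows `j`'s maximum-dilution line while `j`
is scarce, then a parabola that meets the partner's ceiling `yd_i`
tangentially at the uptake where `j`'s accumulation line reaches it:

* `u_j <= ya_i / d_j`: `YE = d_j u_j` (scarce `j`, fully diluted);
* `u_j >= yd_i / a_j`: `YE = yd_i` (ample `j`, partner fully limiting);
* between, with `x = u_j - ya_i/d_j` and `den = yd_i/a_j - ya_i/d_j`:
  `YE = ya_i + (yd_i - ya_i)(2 x/den - (x/den)^2)`.

The two ordered estimates within each unordered pair are averaged, giving
three pair yields. `combined_yield()` then takes, by default, the **minimum
over the three pairs** — yield is set by the most limiting nutrient pair, a
law-of-the-minimum reading of the interaction structure. The classical plain
average of all six ordered estimates is available as `method = "average"`;
it is systematically more optimistic for unbalanced uptake combinations. The
limiting-pair form is the package default because it is the yield function
the reverse solver inverts exactly (next section), making forward and
reverse modes a consistent pair rather than two approximations.

## The balanced-uptake solver

"Balanced" needs a formalization. The one used here is **equal relative
dilution**: at the balanced point every nutrient's IE sits at the same
relative position inside its own accumulation–dilution band. On a
logarithmic scale the neutral midpoint of the band `[a, d]` is the geometric
mean `sqrt(a d)`, so balanced uptakes lie on the ray

```
u - r  proportional to  1 / sqrt(a_x d_x),
```

which fixes the N:P:K uptake ratio; with the shipped soybean Set I envelope
the ratio is 7.0 : 1 : 2.5. Along that ray `combined_yield()` is continuous
and non-decreasing and reaches `ymax` at a finite scale, so
`balanced_uptake()` finds the smallest scale meeting the target by monotone
bisection (200 halvings; relative tolerance 1e-9 on the bracket; no
randomness anywhere). The reverse solve is therefore an exact inverse of the
forward model — the round trip `combined_yield(balanced_uptake(Y)) = Y`
holds to solver precision for every attainable target.

Two consequences are worth stating plainly:

* **Linear phase.** With `r = 0` and targets far below the potential, the
  engine is degree-1 homogeneous, so the per-tonne requirement
  `1000 u / Y` is exactly constant: one number per nutrient characterizes
  the whole linear phase. With the soybean Set I envelope and
  `ymax = 6000` kg/ha the package computes 54.9 kg N, 7.8 kg P and
  19.8 kg K per tonne of seed (internal efficiencies 18.2, 127.6 and
  50.5 kg/kg) — the worked example in the README prints these from code.
* **Potential invariance.** Both the ray and the capping scale with `ymax`,
  so the linear-phase per-tonne requirement is identical for any yield
  potential; the test suite checks 3–6 t/ha agree to well under 0.5%.

The balanced point is minimal *subject to the balance constraint*: along the
ray no smaller uptake meets the target (a brute-force scan of the scale,
refined twice, verifies this in the tests). It is deliberately **not** the
globally cheapest uptake for the target — off the ray, the non-limiting
pairs carry slack, so a cost minimizer would drift toward whichever
nutrient is cheapest and abandon balance. Balance, not cost, is the design
objective here, since the requirement tables feed maintenance
fertilization.

### Where the curve bends

As the target approaches the potential, the `ymax` clamps on `ya`/`yd`
deform the engine and the per-tonne requirement rises: the familiar
linear–parabolic–plateau shape. In this implementation the first clamp to
bind on the balanced ray is the P dilution yield (`d_P u_P` crosses `ymax`
at about 54% of the potential with the soybean envelope), so the curve
leaves the linear phase somewhat earlier, and climbs the plateau more
steeply, than the published soybean tables, which place the bend at 60–70%
of the potential and reach 81 kg N/t at the potential itself. Those
published plateau-zone rows cannot be reproduced together with the
published linear-phase values by any single capped, homogeneous engine we
tested: ray-scaling the six-estimate average matches the published 5.0–5.8
t/ha rows to 0.2% but sits 4% below the published linear constant, and the
value at the potential lies in a region where yield changes by under 1%
while uptake changes by 20%, so it is dominated by the original solver's
stopping tolerance. We chose fidelity to the linear phase — the headline
per-tonne requirements and IEs — and document the plateau-zone discrepancy
rather than split the model into inconsistent regimes.

## Seed removal

`seed_removal()` repeats the balanced solve under a seed-compartment
envelope (calibrated from seed-yield over seed-nutrient IEs by the same
percentile machinery) and reports per-tonne seed removal and its share of
the above-ground requirement — the quantities maintenance fertilization
needs. No seed envelope is shipped: the published seed-removal table does
not include the coefficients behind it, so the function requires
user-supplied ones and refuses any envelope that would put more nutrient in
the seed than in the whole plant.

## Validation statistics

`rmse()` and `n_rmse()` implement the usual agreement measures between
simulated and measured uptakes, `sqrt(mean((s - m)^2))` and
`100 rmse / mean(m)`. `validation_summary()` tabulates them per nutrient
with the mean bias. They are descriptive; no significance machinery is
attached. Published field-validation RMSE values depend on unpublished farm
measurements, so the tests exercise these functions on synthetic pairs with
known noise instead, where the expected n-RMSE is simply the configured
coefficient of variation.

## The synthetic generator

`generate_observations()` emulates the structure of a multi-site soybean
trial network: yields normal with mean 2472 and sd 683 kg/ha truncated to
[300, 6500]; harvest index normal (0.46, 0.06) truncated to (0.2, 0.7);
nutrient harvest indices around 0.84/0.67/0.58 for N/P/K; per-nutrient IEs
drawn from a beta(2, 2) rescaled and positioned so that its 2.5th and
97.5th percentiles fall exactly on the "true" envelope — the tails extend
beyond the envelope, as real IE distributions do, and percentile
calibration at the matching exclusion recovers the generating envelope (the
parameter-recovery test uses n = 5000 at zero noise and demands 2%).
Measurement error is mean-one multiplicative lognormal on the uptakes
(default CV 0.08); concentrations are derived *after* noising, so every
record satisfies the concentration-times-dry-weight consistency invariant
exactly. One integer seed drives everything through per-record substreams,
so enlarging the dataset never reshuffles existing records.

What the generator does **not** emulate: site and year effects (records are
exchangeable), covariance between yield and IE, soil covariates, and
non-lognormal measurement error. Passing tests therefore demonstrate
correctness of the pipeline's arithmetic and calibration under the stated
dispersion model, not robustness to structured real-world heterogeneity.

## Numerical choices and limitations

* Percentile convention: type 7 everywhere (rank `p (n - 1)`).
* Solver: bisection on a bracketed monotone function; deterministic;
  convergence verified post hoc and failure raised loudly, never returned
  as a best effort.
* Degenerate inputs: zero target returns zero uptake; targets above `ymax`
  error; constant IE distributions refuse calibration (`a = d`); records
  with inconsistent stored uptakes are rejected at construction.
* Test problem sizes: the property tests use hundreds to a few thousand
  synthetic records and 50-point target grids, chosen to exercise the
  asymptotics while keeping the default suite fast.
* The plateau zone is convention-dependent (see above); per-tonne values
  there should be read as model output under this package's capping rules,
  not as reproductions of any particular published table row.
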