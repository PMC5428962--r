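# queftsNPK

Balanced nitrogen–phosphorus–potassium uptake requirements for soybean,
estimated from field-trial data with the QUEFTS (Quantitative Evaluation of
the Fertility of Tropical Soils) yield model.

The package is for agronomists and nutrient-management researchers who need
to turn multi-site trial records — seed yield, straw dry matter, tissue
nutrient concentrations, harvest index — into crop nutrient requirement
tables: how many kg of N, P and K the crop must accumulate in its
above-ground parts per tonne of seed, how that requirement rises as the
target yield approaches the yield potential, and how much of it leaves the
field in the harvested seed.

## The model in brief

For each nutrient, the observed internal efficiencies
(IE = seed yield / above-ground uptake, kg/kg) are trimmed at symmetric
outer percentiles to give an envelope: the maximum-accumulation borderline
*a* (low IE, luxury uptake) and the maximum-dilution borderline *d* (high
IE, maximally diluted tissue). The forward engine brackets yield per
nutrient between *a*(u−r) and *d*(u−r), clamped at the yield potential
Ymax, combines nutrients pairwise (dilution line → parabola → plateau at
the partner's dilution ceiling), averages the two estimates within each
pair, and takes the minimum over the three pairs: yield is set by the most
limiting nutrient pair.

The reverse solver defines *balanced* uptake as equal relative dilution —
every nutrient's IE at the same relative position inside its [a, d] band —
which places uptakes on the ray u ∝ 1/√(a·d) and fixes the N:P:K ratio
(7.0 : 1 : 2.5 for the shipped soybean calibration). Bisection along the
ray makes the reverse solve an exact inverse of the forward engine, so the
per-tonne requirement 1000·u/Y is exactly constant in the linear phase and
bends upward only as the Ymax caps engage (linear–parabolic–plateau).

## Worked example

Requirement estimation with the shipped soybean envelope (Set I, 2.5th/97.5th
percentiles of ~2200 plot IEs per nutrient) at a yield potential of 6 t/ha:

```r
library(queftsNPK)

p <- quefts_params(soybean_envelope_sets()$I, ymax = 6000)
u <- balanced_uptake(3000, p)   # kg/ha at a 3 t/ha target
round(1000 * u / 3000, 1)       # kg per tonne of seed
#>    N    P    K
#> 54.9  7.8 19.8
round(3000 / u, 1)              # internal efficiencies, kg seed / kg nutrient
#>     N     P     K
#>  18.2 127.6  50.5
```

So producing 1000 kg of soybean seed requires about 55 kg N, 8 kg P and
20 kg K in the above-ground biomass while yields are below roughly half the
potential; the full curve shows the climb toward the plateau:

```r
requirement_curve(p, targets = c(0, 1000, 2000, 3000, 4500, 5400, 6000))
#> Balanced nutrient requirement curve (ymax = 6000 kg/ha)
#> Linear phase up to ~3000 kg/ha (50% of potential)
#>  target_yield uptake_n uptake_p uptake_k per_ton_n per_ton_p per_ton_k ie_n  ie_p ie_k
#>             0      0.0      0.0      0.0       0.0       0.0       0.0   NA    NA   NA
#>          1000     54.9      7.8     19.8      54.9       7.8      19.8 18.2 127.6 50.5
#>          2000    109.7     15.7     39.6      54.9       7.8      19.8 18.2 127.6 50.5
#>          3000    164.6     23.5     59.4      54.9       7.8      19.8 18.2 127.6 50.5
#>          4500    272.6     38.9     98.3      60.6       8.7      21.9 16.5 115.6 45.8
#>          5400    379.8     54.2    137.0      70.3      10.0      25.4 14.2  99.6 39.4
#>          6000    598.5     85.5    215.8      99.7      14.2      36.0 10.0  70.2 27.8
```

Calibrating an envelope from (here: synthetic) plot data, after the
harvest-index screen:

```r
obs  <- generate_observations(generator_config(n_obs = 2000, rng_seed = 42))
kept <- filter_by_hi(obs, 0.4)
#> filter_by_hi: kept 1671 of 2000 records (329 below 0.4, 0 missing hi, dropped)
calibrate_envelope(compute_ie(kept)$ie)
#> QUEFTS envelope coefficients (kg seed per kg nutrient)
#>                          N      P     K
#> a (max accumulation) 13.00  59.67 27.28
#> d (max dilution)     22.94 244.08 83.55
```

With the default 8% measurement noise the recovered envelope is slightly
wider than the generating one (N 13.5–21.4), as outer percentiles of a
noised distribution must be; at zero noise the generator's envelope is
recovered to well under 2%.

Validation statistics for paired simulated/measured uptakes:

```r
pairs <- generate_validation_pairs(generator_config(n_obs = 100,
                                                    noise_cv = 0.1,
                                                    rng_seed = 7), p)
validation_summary(pairs)   # per-nutrient n, RMSE (kg/ha), n-RMSE (%), bias
```

## Package layout

* `observations()`, `compute_uptake()`, `compute_ie()`, `filter_by_hi()`,
  `summarize_trials()` — plot-level data model and derived quantities
* `calibrate_envelope()`, `standard_percentile_sets()`,
  `soybean_envelope_sets()` — envelope calibration
* `quefts_params()`, `yield_bounds()`, `pairwise_yield()`,
  `combined_yield()` — forward engine
* `balanced_uptake()`, `requirement_curve()`, `seed_removal()` — reverse
  solver and requirement tables
* `rmse()`, `n_rmse()`, `validation_summary()` — agreement statistics
* `generator_config()`, `generate_observations()`,
  `generate_validation_pairs()` — synthetic trial generator

The methods vignette (`vignettes/balanced-npk-requirements.Rmd`) documents
the model assumptions, the balance formalization, numerical conventions and
known limitations, including where the plateau zone of the requirement
curve is convention-dependent.
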