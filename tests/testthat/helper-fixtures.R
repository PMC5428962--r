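# Small hand-built observation tables used across test files.

# One fully-specified plot: seed dm 2000 kg/ha at 50 g/kg, straw 2000 kg/ha
# at 10 g/kg for every nutrient -> uptake 120 kg/ha each.
toy_obs <- function() {
  observations(data.frame(
    site_id = "S001", year = 2010L, treatment = "OPT",
    seed_yield_kg_ha = 2000 / 0.865,   # so seed dry matter is exactly 2000
    straw_dm_kg_ha = 2000,
    n_seed_g_kg = 50, p_seed_g_kg = 50, k_seed_g_kg = 50,
    n_straw_g_kg = 10, p_straw_g_kg = 10, k_straw_g_kg = 10,
    hi = 0.5
  ))
}

set1_params <- function(ymax = 6000, r = c(N = 0, P = 0, K = 0)) {
  quefts_params(soybean_envelope_sets()$I, ymax = ymax, r = r)
}

# Straight-line re-implementation of the limiting-pair yield, written
# independently of the package internals (different code organization),
# used as the brute-force oracle.
oracle_yield <- function(u, a, d, r, ymax, average = FALSE) {
  ue <- pmax(u - r, 0)
  est <- function(i, j) {
    ya <- min(a[i] * ue[i], ymax); yd <- min(d[i] * ue[i], ymax)
    if (ue[j] * d[j] <= ya) return(min(d[j] * ue[j], ymax))
    if (ue[j] * a[j] >= yd) return(yd)
    x <- ue[j] - ya / d[j]
    den <- yd / a[j] - ya / d[j]
    ya + 2 * (yd - ya) * (x / den) - (yd - ya) * (x / den)^2
  }
  pm <- c((est("N", "P") + est("P", "N")) / 2,
          (est("N", "K") + est("K", "N")) / 2,
          (est("P", "K") + est("K", "P")) / 2)
  y <- if (average) mean(pm) else min(pm)
  min(max(y, 0), ymax)
}
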