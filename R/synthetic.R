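#' Configuration for the synthetic field-trial generator
#'
#' Describes the study conditions the generator emulates: a multi-site,
#' multi-year soybean trial network with yields around 2.47 t/ha (sd 0.68),
#' harvest indices around 0.46 (sd 0.06), and internal-efficiency dispersion
#' wide enough that the outer-percentile envelope matches the supplied "true"
#' envelope.
#'
#' Internal efficiencies are drawn per nutrient from a scaled beta
#' distribution positioned so that its `ie_anchor` percentiles (default
#' 2.5/97.5) fall exactly on the true envelope coefficients `a` and `d`; the
#' tails extend beyond the envelope, as real trial data do. Measurement error
#' is multiplicative lognormal on the uptakes with coefficient of variation
#' `noise_cv` (mean-one, so it adds scatter without bias).
#'
#' One integer seed governs all draws; each record uses a deterministic
#' substream derived from it, so increasing `n_obs` extends the table without
#' reshuffling earlier records.
#'
#' @param n_obs Number of plot records.
#' @param true_envelope A `quefts_envelope`; default the calibrated soybean
#'   Set I envelope.
#' @param ymax Upper truncation for yields, kg/ha.
#' @param yield_mean,yield_sd Yield distribution (kg/ha), truncated to
#'   `[300, ymax]`.
#' @param hi_mean,hi_sd,hi_bounds Harvest-index distribution, truncated.
#' @param ie_shape Beta shape parameters for the IE dispersion.
#' @param ie_anchor Percentiles (percent) of the IE distribution pinned to
#'   `a` and `d`.
#' @param seed_nutrient_hi Mean nutrient harvest indices (seed share of
#'   above-ground nutrient).
#' @param seed_nutrient_hi_sd Their standard deviations.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise on uptakes.
#' @param rng_seed Integer master seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_obs = 500,
                             true_envelope = soybean_envelope_sets()$I,
                             ymax = 6500,
                             yield_mean = 2472, yield_sd = 683,
                             hi_mean = 0.46, hi_sd = 0.06,
                             hi_bounds = c(0.2, 0.7),
                             ie_shape = c(2, 2),
                             ie_anchor = c(2.5, 97.5),
                             seed_nutrient_hi = c(N = 0.84, P = 0.67, K = 0.58),
                             seed_nutrient_hi_sd = c(N = 0.04, P = 0.09, K = 0.08),
                             noise_cv = 0.08,
                             rng_seed = 1L) {
  stopifnot(inherits(true_envelope, "quefts_envelope"))
  if (!is.numeric(n_obs) || length(n_obs) != 1L || n_obs < 0 ||
      n_obs != round(n_obs)) {
    stop("'n_obs' must be a non-negative integer", call. = FALSE)
  }
  if (hi_bounds[1] >= hi_bounds[2]) stop("'hi_bounds' inverted", call. = FALSE)
  if (yield_sd < 0 || hi_sd < 0 || noise_cv < 0) {
    stop("dispersion parameters must be non-negative", call. = FALSE)
  }
  if (!(ie_anchor[1] > 0 && ie_anchor[1] < ie_anchor[2] && ie_anchor[2] < 100)) {
    stop("'ie_anchor' must satisfy 0 < lower < upper < 100", call. = FALSE)
  }
  structure(list(
    n_obs = as.integer(n_obs), true_envelope = true_envelope, ymax = ymax,
    yield_mean = yield_mean, yield_sd = yield_sd,
    hi_mean = hi_mean, hi_sd = hi_sd, hi_bounds = hi_bounds,
    ie_shape = ie_shape, ie_anchor = ie_anchor,
    seed_nutrient_hi = as_npk(seed_nutrient_hi, "seed_nutrient_hi"),
    seed_nutrient_hi_sd = as_npk(seed_nutrient_hi_sd, "seed_nutrient_hi_sd"),
    noise_cv = noise_cv, rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
}

# Deterministic per-record substream (keeps earlier records stable when
# n_obs grows). 2147483629 is prime and < 2^31.
.record_seed <- function(master, i, stream = 0L) {
  (as.numeric(master) * 48271 + i * 16807 + stream * 69621) %% 2147483629
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  for (k in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[k] <- v
  }
  out
}

# mean-one multiplicative lognormal factor with coefficient of variation cv
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Scaled-beta IE draw whose ie_anchor percentiles coincide with [a, d].
.draw_ie <- function(n, a, d, shape, anchor) {
  q <- stats::qbeta(anchor / 100, shape[1], shape[2])
  width <- (d - a) / (q[2] - q[1])
  lower <- a - q[1] * width
  lower + width * stats::rbeta(n, shape[1], shape[2])
}

#' Generate a synthetic plot-level trial table
#'
#' Draws, for each record: a seed yield, a harvest index, per-nutrient
#' internal efficiencies (so uptake = yield / IE), and nutrient harvest
#' indices that split each uptake between seed and straw. Multiplicative
#' lognormal measurement noise is applied to the uptakes, and seed/straw
#' concentrations are then derived from the noisy uptakes and the dry
#' weights, so every record is internally consistent (concentration times
#' dry weight reproduces the stored uptake exactly).
#'
#' @param cfg A `generator_config`.
#' @return A `quefts_obs` table with `cfg$n_obs` rows.
#' @examples
#' obs <- generate_observations(generator_config(n_obs = 50, rng_seed = 7))
#' summary(obs$seed_yield_kg_ha)
#' @export
generate_observations <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_obs
  a <- cfg$true_envelope$a; d <- cfg$true_envelope$d
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.record_seed(cfg$rng_seed, i))
    yield <- .rtrunc_norm(1, cfg$yield_mean, cfg$yield_sd, 300, cfg$ymax)
    hi <- .rtrunc_norm(1, cfg$hi_mean, cfg$hi_sd,
                       cfg$hi_bounds[1], cfg$hi_bounds[2])
    ie <- npk(.draw_ie(1, a["N"], d["N"], cfg$ie_shape, cfg$ie_anchor),
              .draw_ie(1, a["P"], d["P"], cfg$ie_shape, cfg$ie_anchor),
              .draw_ie(1, a["K"], d["K"], cfg$ie_shape, cfg$ie_anchor))
    uptake <- yield / ie * .lognoise(3, cfg$noise_cv)
    nhi <- npk(.rtrunc_norm(1, cfg$seed_nutrient_hi["N"],
                            cfg$seed_nutrient_hi_sd["N"], 0.05, 0.98),
               .rtrunc_norm(1, cfg$seed_nutrient_hi["P"],
                            cfg$seed_nutrient_hi_sd["P"], 0.05, 0.98),
               .rtrunc_norm(1, cfg$seed_nutrient_hi["K"],
                            cfg$seed_nutrient_hi_sd["K"], 0.05, 0.98))
    seed_dm <- yield * 0.865
    straw_dm <- seed_dm * (1 / hi - 1)
    seed_content <- nhi * uptake
    straw_content <- uptake - seed_content
    rows[[i]] <- data.frame(
      site_id = sprintf("S%03d", ((i - 1L) %% 40L) + 1L),
      year = 2001L + ((i - 1L) %% 15L),
      treatment = c("OPT", "FP", "N0", "P0", "K0")[((i - 1L) %% 5L) + 1L],
      seed_yield_kg_ha = yield,
      straw_dm_kg_ha = straw_dm,
      n_seed_g_kg = 1000 * seed_content["N"] / seed_dm,
      p_seed_g_kg = 1000 * seed_content["P"] / seed_dm,
      k_seed_g_kg = 1000 * seed_content["K"] / seed_dm,
      n_straw_g_kg = 1000 * straw_content["N"] / straw_dm,
      p_straw_g_kg = 1000 * straw_content["P"] / straw_dm,
      k_straw_g_kg = 1000 * straw_content["K"] / straw_dm,
      n_uptake_kg_ha = uptake["N"],
      p_uptake_kg_ha = uptake["P"],
      k_uptake_kg_ha = uptake["K"],
      hi = hi,
      row.names = NULL
    )
  }
  df <- if (n > 0) do.call(rbind, rows) else data.frame(
    site_id = character(0), year = integer(0), treatment = character(0),
    seed_yield_kg_ha = numeric(0), straw_dm_kg_ha = numeric(0),
    n_seed_g_kg = numeric(0), p_seed_g_kg = numeric(0), k_seed_g_kg = numeric(0),
    n_straw_g_kg = numeric(0), p_straw_g_kg = numeric(0), k_straw_g_kg = numeric(0),
    n_uptake_kg_ha = numeric(0), p_uptake_kg_ha = numeric(0),
    k_uptake_kg_ha = numeric(0), hi = numeric(0))
  observations(df, moisture_fraction = 0.135)
}

#' Generate paired simulated/measured uptakes for validation
#'
#' Emulates an on-farm validation campaign: each site gets a yield, the
#' model's balanced uptake at that yield is the simulated value, and the
#' "measured" value is the simulated one perturbed by mean-one lognormal
#' noise with the configured CV. With known noise the expected n-RMSE is
#' approximately `100 * noise_cv`, which makes the validation statistics
#' themselves testable.
#'
#' @param cfg A `generator_config` (`n_obs` = number of sites; noise from
#'   `noise_cv`; seed from `rng_seed`).
#' @param params A `quefts_params` for the simulating model.
#' @return Data frame with columns `site`, `nutrient`, `target_yield`,
#'   `simulated`, `measured` (kg/ha).
#' @export
generate_validation_pairs <- function(cfg, params) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(params, "quefts_params"))
  n <- cfg$n_obs
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.record_seed(cfg$rng_seed, i, stream = 1L))
    yield <- .rtrunc_norm(1, cfg$yield_mean, cfg$yield_sd, 300,
                          min(cfg$ymax, 0.95 * params$ymax))
    sim <- balanced_uptake(yield, params)
    meas <- sim * .lognoise(3, cfg$noise_cv)
    rows[[i]] <- data.frame(site = i, nutrient = .nutrients,
                            target_yield = yield,
                            simulated = as.numeric(sim),
                            measured = as.numeric(meas), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
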