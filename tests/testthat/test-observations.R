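test_that("uptake is concentration times dry weight summed over seed and straw", {
  u <- compute_uptake(toy_obs())
  expect_equal(unname(u[1, ]), c(120, 120, 120))  # 2000*0.05 + 2000*0.01

  # single-term product: straw absent, seed dm 1000 kg at 53.5 g/kg
  obs <- observations(data.frame(
    seed_yield_kg_ha = 1000 / 0.865, straw_dm_kg_ha = 0,
    n_seed_g_kg = 53.5, p_seed_g_kg = 0, k_seed_g_kg = 0,
    n_straw_g_kg = 0, p_straw_g_kg = 0, k_straw_g_kg = 0, hi = 0.99))
  expect_equal(unname(compute_uptake(obs)[1, "N"]), 53.5)

  # all-zero concentrations give zero uptake, not NA
  obs0 <- observations(data.frame(
    seed_yield_kg_ha = 2000, straw_dm_kg_ha = 1500,
    n_seed_g_kg = 0, p_seed_g_kg = 0, k_seed_g_kg = 0,
    n_straw_g_kg = 0, p_straw_g_kg = 0, k_straw_g_kg = 0, hi = 0.5))
  expect_equal(unname(compute_uptake(obs0)[1, ]), c(0, 0, 0))
})

test_that("uptake is linear in concentrations and dry weights", {
  base <- data.frame(
    seed_yield_kg_ha = 2500, straw_dm_kg_ha = 1800,
    n_seed_g_kg = 50, p_seed_g_kg = 7, k_seed_g_kg = 13,
    n_straw_g_kg = 9, p_straw_g_kg = 3, k_straw_g_kg = 8, hi = 0.46)
  u1 <- compute_uptake(observations(base))
  doubled_conc <- base
  doubled_conc[c("n_seed_g_kg", "p_seed_g_kg", "k_seed_g_kg",
                 "n_straw_g_kg", "p_straw_g_kg", "k_straw_g_kg")] <-
    2 * doubled_conc[c("n_seed_g_kg", "p_seed_g_kg", "k_seed_g_kg",
                       "n_straw_g_kg", "p_straw_g_kg", "k_straw_g_kg")]
  expect_equal(compute_uptake(observations(doubled_conc)), 2 * u1)
  doubled_dm <- base
  doubled_dm$seed_yield_kg_ha <- 2 * base$seed_yield_kg_ha
  doubled_dm$straw_dm_kg_ha <- 2 * base$straw_dm_kg_ha
  expect_equal(compute_uptake(observations(doubled_dm)), 2 * u1)
})

test_that("missing data yields NA with a warning, never silent zero", {
  obs <- observations(data.frame(
    seed_yield_kg_ha = 2000, straw_dm_kg_ha = 1500,
    n_seed_g_kg = NA_real_, p_seed_g_kg = 7, k_seed_g_kg = 13,
    n_straw_g_kg = 9, p_straw_g_kg = 3, k_straw_g_kg = 8, hi = 0.5))
  expect_warning(u <- compute_uptake(obs), "insufficient|lack")
  expect_true(is.na(u[1, "N"]))
  expect_false(is.na(u[1, "P"]))
})

test_that("stored uptakes are cross-checked against concentrations", {
  df <- as.data.frame(toy_obs())
  df$n_uptake_kg_ha <- 120      # consistent
  expect_silent(observations(df))
  df$n_uptake_kg_ha <- 140      # 17% off
  expect_error(observations(df), "disagrees")
})

test_that("IE and RIE are reciprocal (ie * rie = 1000) and edge cases flag", {
  obs <- observations(data.frame(
    seed_yield_kg_ha = 1000, straw_dm_kg_ha = 0,
    n_uptake_kg_ha = 50, p_uptake_kg_ha = 10, k_uptake_kg_ha = 20, hi = 0.5))
  e <- compute_ie(obs)
  expect_equal(unname(e$ie[1, "N"]), 20)
  expect_equal(unname(e$rie[1, "N"]), 50)
  expect_equal(unname(e$ie[1, ] * e$rie[1, ]), rep(1000, 3))

  zero_y <- observations(data.frame(
    seed_yield_kg_ha = 0, straw_dm_kg_ha = 0,
    n_uptake_kg_ha = 50, p_uptake_kg_ha = 10, k_uptake_kg_ha = 20, hi = 0.5))
  ez <- compute_ie(zero_y)
  expect_equal(unname(ez$ie[1, ]), rep(0, 3))
  expect_true(all(is.na(ez$rie[1, ])))

  zero_u <- observations(data.frame(
    seed_yield_kg_ha = 1000, straw_dm_kg_ha = 0,
    n_uptake_kg_ha = 0, p_uptake_kg_ha = 10, k_uptake_kg_ha = 20, hi = 0.5))
  expect_warning(eu <- compute_ie(zero_u), "zero uptake")
  expect_true(is.na(eu$ie[1, "N"]))
})

test_that("nutrient harvest index is seed share of total uptake", {
  obs <- toy_obs()  # seed content 100, total 120 per nutrient
  nhi <- compute_nutrient_hi(obs)
  expect_equal(unname(nhi[1, ]), rep(100 / 120, 3))

  all_seed <- observations(data.frame(
    seed_yield_kg_ha = 1000 / 0.865, straw_dm_kg_ha = 1000,
    n_seed_g_kg = 84, p_seed_g_kg = 10, k_seed_g_kg = 10,
    n_straw_g_kg = 0, p_straw_g_kg = 5, k_straw_g_kg = 5, hi = 0.5))
  expect_equal(unname(compute_nutrient_hi(all_seed)[1, "N"]), 1)
})

test_that("harvest-index filter keeps the boundary, is idempotent and order-preserving", {
  df <- data.frame(seed_yield_kg_ha = c(1000, 2000, 3000, 4000),
                   straw_dm_kg_ha = 0,
                   n_uptake_kg_ha = 1, p_uptake_kg_ha = 1, k_uptake_kg_ha = 1,
                   hi = c(0.26, 0.40, 0.47, 0.66))
  obs <- observations(df)
  f <- filter_by_hi(obs, 0.4, quiet = TRUE)
  expect_equal(nrow(f), 3L)                      # 0.40 is kept (>= threshold)
  expect_equal(f$hi, c(0.40, 0.47, 0.66))        # order preserved
  expect_equal(attr(f, "n_removed"), 1L)
  f2 <- filter_by_hi(f, 0.4, quiet = TRUE)
  expect_equal(f2$hi, f$hi)                      # idempotent
  expect_equal(f2$seed_yield_kg_ha, f$seed_yield_kg_ha)
  expect_equal(attr(f2, "n_removed"), 0L)

  expect_equal(nrow(filter_by_hi(obs, 1e-9, quiet = TRUE)), 4L)
  empty <- filter_by_hi(obs[0, ], 0.4, quiet = TRUE)
  expect_equal(nrow(empty), 0L)

  # missing hi dropped by default, kept on request
  df$hi[2] <- NA
  obs2 <- observations(df)
  expect_equal(nrow(filter_by_hi(obs2, 0.4, quiet = TRUE)), 2L)
  expect_equal(nrow(filter_by_hi(obs2, 0.4, keep_missing = TRUE, quiet = TRUE)), 3L)
})

test_that("seven-number summary matches hand arithmetic and is permutation invariant", {
  s <- summarize_values(1:5)
  expect_equal(s$mean, 3); expect_equal(s$median, 3)
  expect_equal(s$minimum, 1); expect_equal(s$maximum, 5)
  expect_equal(s$sd, sqrt(2.5), tolerance = 1e-12)

  expect_equal(summarize_values(7),
               data.frame(n_obs = 1L, mean = 7, sd = 0, minimum = 7, q25 = 7,
                          median = 7, q75 = 7, maximum = 7))
  const <- summarize_values(rep(4.2, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$q25, const$q75)

  set.seed(11)
  v <- rnorm(137)
  expect_equal(summarize_values(v), summarize_values(sample(v)))
  expect_error(summarize_values(numeric(0)), "no finite")
})

test_that("CSV round trip preserves the observation table", {
  obs <- toy_obs()
  path <- tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_s3_class(back, "quefts_obs")
  expect_equal(back$seed_yield_kg_ha, obs$seed_yield_kg_ha)
  expect_equal(compute_uptake(back), compute_uptake(obs))
  unlink(path)
})
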