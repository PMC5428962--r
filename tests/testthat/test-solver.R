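test_that("balanced uptake hits trivial and error cases", {
  p <- set1_params()
  expect_equal(unname(balanced_uptake(0, p)), c(0, 0, 0))
  expect_error(balanced_uptake(6001, p), "exceeds")
  expect_error(balanced_uptake(-5, p))
})

test_that("reverse solve is an exact inverse of the forward model", {
  p <- set1_params()
  targets <- seq(60, 6000, length.out = 50)
  for (y in targets) {
    u <- balanced_uptake(y, p)
    expect_equal(combined_yield(u, p), y, tolerance = 1e-6)
  }
})

test_that("balanced uptake keeps every nutrient at the same envelope position", {
  p <- set1_params()
  env <- p$envelope
  u <- balanced_uptake(2500, p)
  # IE relative to the geometric mean of (a, d) is identical across nutrients
  rel <- (2500 / u) / sqrt(env$a * env$d)
  expect_lt(diff(range(rel)) / mean(rel), 1e-9)
})

test_that("solver is minimal along the balanced ray (fine 1-D scan oracle)", {
  p <- set1_params()
  target <- 3000
  u_star <- balanced_uptake(target, p)
  w <- 1 / sqrt(p$envelope$a * p$envelope$d)
  # exhaustive scan over the scale, coarse step sized so the largest uptake
  # component moves 0.5 kg/ha, then refined twice (x10 each)
  step <- 0.5 / max(w)
  s_hi <- 2 * max(u_star / w)
  grid_min <- function(lo, hi, by) {
    s <- seq(lo, hi, by = by)
    ok <- vapply(s, function(si) combined_yield(si * w, p) >= target, logical(1))
    s[which(ok)[1]]
  }
  s1 <- grid_min(0, s_hi, step)
  s2 <- grid_min(s1 - step, s1, step / 10)
  s3 <- grid_min(s2 - step / 10, s2, step / 100)
  u_oracle <- s3 * w
  expect_true(all(abs(u_oracle - u_star) <= (step / 100) * w / min(w) + 1e-9))
})

test_that("per-tonne requirement is constant in the linear phase and never decreases", {
  p <- set1_params()
  rc <- requirement_curve(p)
  pt <- rc$per_ton_n[rc$target_yield > 0]
  y <- rc$target_yield[rc$target_yield > 0]
  # constant to numerical precision over the low-target range
  low <- y <= 0.5 * attr(rc, "ymax")
  expect_lt(diff(range(pt[low])) / mean(pt[low]), 1e-6)
  # monotone non-decreasing overall, strictly increasing near the plateau
  expect_true(all(diff(pt) >= -1e-9))
  expect_gt(pt[length(pt)], pt[1])
  expect_true(is.finite(attr(rc, "linear_limit")))
  # identity ie * per_ton = 1000
  ies <- internal_efficiencies(rc)
  expect_equal(unname(ies[-1, "N"] * pt), rep(1000, length(pt)),
               tolerance = 1e-9)
})

test_that("linear-phase requirement is invariant to the yield potential", {
  pts <- sapply(c(3000, 4000, 5000, 6000), function(ym) {
    p <- set1_params(ymax = ym)
    u <- balanced_uptake(0.3 * ym, p)
    1000 * u / (0.3 * ym)
  })
  for (i in 1:3) {
    expect_equal(unname(pts[i, ]), rep(unname(pts[i, 1]), 4), tolerance = 0.005)
  }
})

test_that("requirement grid handles the degenerate single-zero case", {
  p <- set1_params()
  rc0 <- requirement_curve(p, targets = 0)
  expect_equal(nrow(rc0), 1L)
  expect_equal(rc0$uptake_n, 0)
  expect_true(is.na(rc0$ie_n))
})

test_that("seed removal splits the requirement and enforces the invariant", {
  p <- set1_params()
  rc <- requirement_curve(p, targets = c(0, 1000, 2000, 3000))
  # identity envelope: seed demand equals above-ground demand, fractions 100%
  rc_id <- seed_removal(rc, p$envelope, p)
  pos <- rc_id$target_yield > 0
  expect_equal(rc_id$seed_fraction_n[pos], rep(100, sum(pos)), tolerance = 1e-9)
  expect_true(all(rc_id$seed_per_ton_k <= rc_id$per_ton_k + 1e-9))

  # uniformly scaled envelope: per-tonne seed demand scales exactly by 1/k
  k <- 1 / 0.871
  seed_env <- envelope(a = k * p$envelope$a, d = k * p$envelope$d)
  rc_s <- seed_removal(rc, seed_env, p)
  expect_equal(rc_s$seed_fraction_n[pos], rep(87.1, sum(pos)), tolerance = 1e-6)
  expect_equal(rc_s$seed_per_ton_p[pos], rc_s$per_ton_p[pos] * 0.871,
               tolerance = 1e-9)

  # a seed compartment demanding more than the whole plant is rejected
  bad_env <- envelope(a = p$envelope$a / 4, d = p$envelope$d / 4)
  expect_error(seed_removal(rc, bad_env, p), "exceeds")
})
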