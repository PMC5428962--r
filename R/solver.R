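#' Balanced uptake for a target yield
#'
#' Inverts the forward engine: finds the uptake triple at which the three
#' nutrients are taken up in balance and the combined yield equals the
#' target.
#'
#' Balance is formalized as equal relative dilution: every nutrient's
#' internal efficiency sits at the same relative position inside its
#' accumulation-dilution envelope, which places the uptakes on the ray
#' `u - r` proportional to `1 / sqrt(a * d)` (the geometric-mean IE rule).
#' Along that ray the solver returns the smallest scale at which
#' [combined_yield()] (method `"limiting-pair"`) reaches the target, by
#' monotone bisection; the reverse solve is therefore an exact inverse of the
#' forward model, and in the linear phase the per-tonne requirement is
#' constant. Deterministic, no randomness.
#'
#' @param target Target seed yield, kg/ha, in `[0, ymax]`.
#' @param params A `quefts_params`.
#' @param tol Relative convergence tolerance on yield (default 1e-9).
#' @return Named uptake vector (kg/ha). Target 0 returns zeros.
#' @examples
#' p <- quefts_params(soybean_envelope_sets()$I, ymax = 6000)
#' u <- balanced_uptake(3000, p)
#' 1000 * u / 3000   # kg nutrient per tonne of seed
#' @export
balanced_uptake <- function(target, params, tol = 1e-9) {
  stopifnot(inherits(params, "quefts_params"))
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) || target < 0) {
    stop("'target' must be a single non-negative yield (kg/ha)", call. = FALSE)
  }
  if (target > params$ymax * (1 + 1e-12)) {
    stop(sprintf("target %g exceeds the yield potential ymax = %g", target,
                 params$ymax), call. = FALSE)
  }
  if (target == 0) return(npk(0, 0, 0))

  a <- params$envelope$a; d <- params$envelope$d
  w <- 1 / sqrt(a * d)            # balanced ray direction
  f <- function(s) combined_yield(params$r + s * w, params)

  # bracket the smallest scale with f(s) >= target; f is continuous,
  # non-decreasing and reaches ymax at finite s
  hi <- target * sqrt(max(a * d))
  it <- 0
  while (f(hi) < target * (1 - 1e-12)) {
    hi <- hi * 2; it <- it + 1
    if (it > 200) stop("balanced_uptake failed to bracket the target yield; ",
                       "check envelope and ymax", call. = FALSE)
  }
  lo <- 0
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target * (1 - 1e-15)) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * hi) break
  }
  u <- params$r + hi * w
  got <- combined_yield(u, params)
  if (abs(got - target) > 1e-3 * target + 1e-9) {
    stop(sprintf("balanced_uptake did not converge: yield %g vs target %g (gap %.3g%%)",
                 got, target, 100 * abs(got - target) / target), call. = FALSE)
  }
  u
}

#' Default target-yield grid
#'
#' The presentation grid used for requirement tables: 0, then 0.8 to 3.6 t/ha
#' by 0.4, 3.9 to 4.8 by 0.3, and 5.0 to 6.0 by 0.2, scaled proportionally
#' when the yield potential differs from 6 t/ha.
#'
#' @param ymax Yield potential, kg/ha.
#' @return Numeric vector of target yields (kg/ha), sorted, within `[0, ymax]`.
#' @export
default_target_grid <- function(ymax) {
  base <- c(0, seq(800, 3600, by = 400), seq(3900, 4800, by = 300),
            seq(5000, 6000, by = 200))
  base * ymax / 6000
}

#' Balanced requirement curve
#'
#' Solves the balanced uptake for a grid of target yields and tabulates the
#' requirement curve: absolute uptakes, per-tonne requirements
#' (`1000 * u / target`), and internal efficiencies (`1000 / per_ton`). The
#' curve is linear (constant per-tonne requirement) at low targets, bends as
#' the yield-potential cap makes nutrients work harder, and ends at the
#' plateau.
#'
#' `linear_limit` is the largest target whose per-tonne N requirement is
#' within `linear_tol` (default 0.5%) of the small-target constant.
#'
#' @param params A `quefts_params`.
#' @param targets Target yields (kg/ha); default [default_target_grid()].
#' @param linear_tol Relative tolerance defining the linear phase.
#' @return Object of class `requirement_curve`: a data frame with columns
#'   `target_yield`, `uptake_n/p/k`, `per_ton_n/p/k`, `ie_n/p/k`, plus
#'   attributes `ymax` and `linear_limit`.
#' @export
requirement_curve <- function(params, targets = default_target_grid(params$ymax),
                              linear_tol = 0.005) {
  stopifnot(inherits(params, "quefts_params"))
  targets <- sort(unique(as.numeric(targets)))
  if (any(targets < 0 | targets > params$ymax)) {
    stop("all targets must lie in [0, ymax]", call. = FALSE)
  }
  rows <- lapply(targets, function(y) {
    u <- balanced_uptake(y, params)
    pt <- if (y > 0) 1000 * u / y else npk(0, 0, 0)
    ie <- ifelse(pt > 0, 1000 / pt, NA_real_)
    data.frame(target_yield = y,
               uptake_n = u["N"], uptake_p = u["P"], uptake_k = u["K"],
               per_ton_n = pt["N"], per_ton_p = pt["P"], per_ton_k = pt["K"],
               ie_n = ie["N"], ie_p = ie["P"], ie_k = ie["K"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  pos <- out$target_yield > 0
  linear_limit <- NA_real_
  if (any(pos)) {
    ref <- out$per_ton_n[pos][1]
    ok <- abs(out$per_ton_n / ref - 1) <= linear_tol & pos
    linear_limit <- max(out$target_yield[ok])
  }
  structure(out, ymax = params$ymax, linear_limit = linear_limit,
            class = c("requirement_curve", "data.frame"))
}

#' @export
print.requirement_curve <- function(x, digits = 1, ...) {
  cat(sprintf("Balanced nutrient requirement curve (ymax = %g kg/ha)\n",
              attr(x, "ymax")))
  ll <- attr(x, "linear_limit")
  if (is.finite(ll)) {
    cat(sprintf("Linear phase up to ~%g kg/ha (%.0f%% of potential)\n",
                ll, 100 * ll / attr(x, "ymax")))
  }
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Internal efficiencies of a requirement row or curve
#'
#' IE = target yield / balanced uptake = 1000 / per-tonne requirement, in kg
#' seed per kg nutrient. The identity `ie * per_ton = 1000` holds exactly.
#'
#' @param curve A `requirement_curve` (or a subset of its rows).
#' @return Matrix with columns `N`, `P`, `K`, one row per target.
#' @export
internal_efficiencies <- function(curve) {
  stopifnot(inherits(curve, "requirement_curve") || is.data.frame(curve))
  out <- as.matrix(curve[, c("ie_n", "ie_p", "ie_k")])
  colnames(out) <- .nutrients
  out
}

#' Seed nutrient removal along the requirement curve
#'
#' Repeats the balanced solve under a seed-based envelope (calibrated on
#' seed-yield over seed-nutrient IEs by the same percentile method) to
#' estimate nutrient removal in harvested seed, and expresses it per tonne
#' and as a percentage of the above-ground requirement. These are the
#' quantities behind maintenance fertilization: what leaves the field with
#' the harvest.
#'
#' @param curve A `requirement_curve` from [requirement_curve()].
#' @param seed_envelope A `quefts_envelope` for the seed compartment.
#' @param params The `quefts_params` used to build `curve`.
#' @return The curve with added columns `seed_per_ton_n/p/k` (kg/t) and
#'   `seed_fraction_n/p/k` (percent). Errors if the seed requirement would
#'   exceed the above-ground requirement for any row.
#' @export
seed_removal <- function(curve, seed_envelope, params) {
  stopifnot(inherits(curve, "requirement_curve"),
            inherits(seed_envelope, "quefts_envelope"),
            inherits(params, "quefts_params"))
  sp <- quefts_params(seed_envelope, ymax = params$ymax, r = params$r)
  seed <- t(vapply(curve$target_yield, function(y) {
    u <- balanced_uptake(y, sp)
    if (y > 0) 1000 * u / y else npk(0, 0, 0)
  }, numeric(3)))
  colnames(seed) <- .nutrients
  tot <- as.matrix(curve[, c("per_ton_n", "per_ton_p", "per_ton_k")])
  if (any(seed > tot * (1 + 1e-9) & tot > 0)) {
    stop("seed requirement exceeds above-ground requirement; ",
         "seed envelope is inconsistent with the above-ground envelope",
         call. = FALSE)
  }
  curve$seed_per_ton_n <- seed[, "N"]
  curve$seed_per_ton_p <- seed[, "P"]
  curve$seed_per_ton_k <- seed[, "K"]
  frac <- 100 * seed / tot
  frac[tot == 0] <- NA_real_
  curve$seed_fraction_n <- frac[, "N"]
  curve$seed_fraction_p <- frac[, "P"]
  curve$seed_fraction_k <- frac[, "K"]
  curve
}
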