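#' QUEFTS engine parameters
#'
#' Bundles everything the forward yield engine needs: the envelope
#' coefficients, the per-nutrient minimum uptakes `r` at which yield is still
#' zero (kg/ha; default 0, which makes the requirement curve pass through the
#' origin), and the yield potential `ymax` (kg/ha), the climate- and
#' genotype-determined ceiling at which the response plateaus.
#'
#' @param env A `quefts_envelope`.
#' @param ymax Yield potential, kg/ha, positive.
#' @param r Minimum uptakes, length-3 non-negative (kg/ha).
#' @return Object of class `quefts_params`.
#' @examples
#' quefts_params(soybean_envelope_sets()$I, ymax = 6000)
#' @export
quefts_params <- function(env, ymax, r = c(N = 0, P = 0, K = 0)) {
  stopifnot(inherits(env, "quefts_envelope"))
  if (!is.numeric(ymax) || length(ymax) != 1L || !is.finite(ymax) || ymax <= 0) {
    stop("'ymax' must be a single positive number (kg/ha)", call. = FALSE)
  }
  r <- as_npk(r, "r", nonnegative = TRUE)
  structure(list(envelope = env, ymax = ymax, r = r), class = "quefts_params")
}

#' @export
print.quefts_params <- function(x, ...) {
  cat(sprintf("QUEFTS parameters: ymax = %g kg/ha, r = (%g, %g, %g) kg/ha\n",
              x$ymax, x$r["N"], x$r["P"], x$r["K"]))
  print(x$envelope)
  invisible(x)
}

#' Per-nutrient yield bounds
#'
#' For each nutrient, the yield range its uptake can support on its own:
#' `ya = a * (u - r)` if the nutrient were maximally accumulated and
#' `yd = d * (u - r)` if maximally diluted, both clamped to `[0, ymax]`.
#'
#' @param u Above-ground uptake, length-3 (kg/ha).
#' @param params A `quefts_params`.
#' @return List with named vectors `ya` and `yd` (kg/ha), `0 <= ya <= yd <= ymax`.
#' @examples
#' p <- quefts_params(soybean_envelope_sets()$I, ymax = 10000)
#' yield_bounds(c(N = 100, P = 100, K = 100), p)
#' @export
yield_bounds <- function(u, params) {
  stopifnot(inherits(params, "quefts_params"))
  u <- as_npk(u, "u", nonnegative = TRUE)
  ue <- pmax(u - params$r, 0)
  list(ya = pmin(params$envelope$a * ue, params$ymax),
       yd = pmin(params$envelope$d * ue, params$ymax))
}

# Yield estimate from the uptake of nutrient j, bounded by the yield range of
# partner nutrient i. Three branches in u_j:
#   scarce j  (u_j <= YA_i/d_j):  fully diluted, yield = d_j * u_j
#   ample j   (u_j >= YD_i/a_j):  even full accumulation meets i's ceiling,
#                                 yield = YD_i
#   between:  parabola through (YA_i/d_j, YA_i), tangent to the plateau YD_i
#             at u_j = YD_i/a_j
# YA_i/YD_i are i's accumulation/dilution yields capped at ymax.
.pair_estimate <- function(i, j, ue, a, d, ymax) {
  ya_i <- min(a[i] * ue[i], ymax)
  yd_i <- min(d[i] * ue[i], ymax)
  uj <- ue[j]
  if (uj <= ya_i / d[j]) return(min(d[j] * uj, ymax))
  if (uj >= yd_i / a[j]) return(yd_i)
  x <- uj - ya_i / d[j]
  den <- yd_i / a[j] - ya_i / d[j]
  t <- x / den
  ya_i + (yd_i - ya_i) * (2 * t - t * t)
}

#' Pairwise yield estimate
#'
#' The yield supported by the uptake of nutrient `j` when nutrient `i` is the
#' other potentially limiting factor: linear in `u_j` along the maximum
#' dilution line while `j` is scarce, then a parabola that bends over to meet
#' the partner's dilution ceiling `yd_i` tangentially where `j`'s
#' accumulation yield reaches it.
#'
#' @param i,j Distinct nutrient names among `"N"`, `"P"`, `"K"`; `j` is the
#'   nutrient whose uptake drives the estimate, `i` supplies the ceiling.
#' @param u Uptake vector (kg/ha).
#' @param params A `quefts_params`.
#' @return Yield estimate in kg/ha, within `[0, min(yd_i, ymax)]`.
#' @export
pairwise_yield <- function(i, j, u, params) {
  stopifnot(inherits(params, "quefts_params"))
  i <- match.arg(i, .nutrients); j <- match.arg(j, .nutrients)
  if (i == j) stop("'i' and 'j' must be distinct nutrients", call. = FALSE)
  u <- as_npk(u, "u", nonnegative = TRUE)
  ue <- pmax(u - params$r, 0)
  unname(.pair_estimate(i, j, ue, params$envelope$a, params$envelope$d,
                        params$ymax))
}

.pair_ids <- list(c("N", "P"), c("N", "K"), c("P", "K"))

# Average of the two ordered estimates for each unordered pair.
.pair_means <- function(ue, a, d, ymax) {
  vapply(.pair_ids, function(p) {
    (.pair_estimate(p[1], p[2], ue, a, d, ymax) +
       .pair_estimate(p[2], p[1], ue, a, d, ymax)) / 2
  }, numeric(1))
}

#' Combined yield estimate
#'
#' Combines the six ordered pairwise estimates into a single attainable
#' yield, capped at the potential `ymax`.
#'
#' The default, `method = "limiting-pair"`, averages the two ordered
#' estimates within each unordered nutrient pair and takes the minimum over
#' the three pairs: yield is set by the most limiting pair, a law-of-the-
#' minimum reading of the pairwise interactions. This is the yield function
#' the balanced-uptake solver inverts exactly. `method = "average"` is the
#' classical plain mean of all six estimates, kept for comparison; it is
#' systematically more optimistic for unbalanced uptakes.
#'
#' @param u Uptake vector (kg/ha).
#' @param params A `quefts_params`.
#' @param method `"limiting-pair"` (default) or `"average"`.
#' @return Yield in kg/ha, in `[0, ymax]`.
#' @examples
#' p <- quefts_params(soybean_envelope_sets()$I, ymax = 6000)
#' combined_yield(c(N = 120, P = 20, K = 45), p)
#' @export
combined_yield <- function(u, params, method = c("limiting-pair", "average")) {
  stopifnot(inherits(params, "quefts_params"))
  method <- match.arg(method)
  u <- as_npk(u, "u", nonnegative = TRUE)
  ue <- pmax(u - params$r, 0)
  pm <- .pair_means(ue, params$envelope$a, params$envelope$d, params$ymax)
  y <- if (method == "limiting-pair") min(pm) else mean(pm)
  unname(min(max(y, 0), params$ymax))
}
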