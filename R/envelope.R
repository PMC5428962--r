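#' Accumulation/dilution envelope coefficients
#'
#' The QUEFTS engine brackets each nutrient's internal efficiency between a
#' maximum-accumulation borderline `a` (low IE: the crop takes up luxury
#' amounts per kg of seed) and a maximum-dilution borderline `d` (high IE:
#' tissue maximally diluted). Both are in kg seed per kg nutrient and must
#' satisfy `0 < a < d` per nutrient.
#'
#' @param a,d Length-3 numeric vectors (N, P, K order or named).
#' @return Object of class `quefts_envelope`: list with components `a`, `d`.
#' @examples
#' soybean_envelope_sets()$I
#' envelope(a = c(13.5, 60.4, 27.8), d = c(21.4, 234.6, 79.9))
#' @export
envelope <- function(a, d) {
  a <- as_npk(a, "a"); d <- as_npk(d, "d")
  if (any(a <= 0)) stop("accumulation coefficients 'a' must be positive", call. = FALSE)
  if (any(a >= d)) {
    stop("each dilution coefficient d must exceed its accumulation coefficient a",
         call. = FALSE)
  }
  structure(list(a = a, d = d), class = "quefts_envelope")
}

#' @export
print.quefts_envelope <- function(x, ...) {
  cat("QUEFTS envelope coefficients (kg seed per kg nutrient)\n")
  m <- rbind(`a (max accumulation)` = x$a, `d (max dilution)` = x$d)
  print(round(m, 2))
  invisible(x)
}

#' Standard symmetric percentile exclusion sets
#'
#' The three exclusion sets conventionally used to trim internal-efficiency
#' distributions before reading off the envelope: Set I drops the outer 2.5%
#' on each side (envelope at the 2.5th/97.5th percentiles), Set II 5%, and
#' Set III 7.5%.
#'
#' @return Named list of three `percentile_set` objects (`I`, `II`, `III`),
#'   each with `label`, `lower_pct`, `upper_pct`.
#' @export
standard_percentile_sets <- function() {
  list(
    I   = percentile_set("I", 2.5, 97.5),
    II  = percentile_set("II", 5, 95),
    III = percentile_set("III", 7.5, 92.5)
  )
}

#' @rdname standard_percentile_sets
#' @param label Set label.
#' @param lower_pct,upper_pct Percentiles in percent, `0 < lower < upper < 100`.
#' @export
percentile_set <- function(label, lower_pct, upper_pct) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!(lower_pct > 0 && lower_pct < upper_pct && upper_pct < 100)) {
    stop("need 0 < lower_pct < upper_pct < 100", call. = FALSE)
  }
  structure(list(label = label, lower_pct = lower_pct, upper_pct = upper_pct),
            class = "percentile_set")
}

#' Calibrate envelope coefficients from internal efficiencies
#'
#' Reads the accumulation borderline `a` off the lower percentile and the
#' dilution borderline `d` off the upper percentile of each nutrient's
#' observed IE distribution (symmetric exclusion of extremes). Percentiles
#' interpolate linearly at rank `p * (n - 1)` (R type 7). Calibration is
#' normally run on the harvest-index-filtered dataset (see [filter_by_hi()]).
#'
#' @param ie Matrix or data frame of positive IE values with columns `N`,
#'   `P`, `K` (e.g. `compute_ie(obs)$ie`), or a list of three numeric vectors.
#' @param set A `percentile_set`; default Set I (2.5/97.5).
#' @param min_n Minimum number of finite IE values required per nutrient.
#' @return A `quefts_envelope`, with attributes `set_label` and `n_used`.
#' @export
calibrate_envelope <- function(ie, set = standard_percentile_sets()$I,
                               min_n = 20L) {
  stopifnot(inherits(set, "percentile_set"))
  cols <- if (is.list(ie) && !is.data.frame(ie)) ie else
    lapply(.nutrients, function(nu) ie[, nu])
  names(cols) <- .nutrients
  a <- d <- npk(1, 1, 1)
  n_used <- integer(3); names(n_used) <- .nutrients
  for (nut in .nutrients) {
    v <- cols[[nut]]
    v <- v[is.finite(v)]
    if (any(v <= 0)) stop("IE values must be positive", call. = FALSE)
    if (length(v) < min_n) {
      stop(sprintf("only %d finite IE values for %s; need at least %d",
                   length(v), nut, min_n), call. = FALSE)
    }
    q <- stats::quantile(v, c(set$lower_pct, set$upper_pct) / 100,
                         type = 7, names = FALSE)
    if (q[1] >= q[2]) {
      stop(sprintf("degenerate IE distribution for %s: percentiles coincide (a >= d)",
                   nut), call. = FALSE)
    }
    a[nut] <- q[1]; d[nut] <- q[2]
    n_used[nut] <- length(v)
  }
  out <- envelope(a, d)
  attr(out, "set_label") <- set$label
  attr(out, "n_used") <- n_used
  out
}

#' Published soybean envelope coefficient sets
#'
#' Envelope coefficients for soybean in China calibrated from roughly 2200
#' plot-level internal efficiencies per nutrient under the three standard
#' exclusion sets. Set I (outer 2.5% excluded on each side) is the set used
#' for requirement estimation; the tighter sets are retained for sensitivity
#' work.
#'
#' @return Named list of three `quefts_envelope` objects (`I`, `II`, `III`).
#' @examples
#' soybean_envelope_sets()$I
#' @export
soybean_envelope_sets <- function() {
  list(
    I   = envelope(a = c(N = 13.5, P = 60.4, K = 27.8),
                   d = c(N = 21.4, P = 234.6, K = 79.9)),
    II  = envelope(a = c(N = 14.3, P = 65.4, K = 30.6),
                   d = c(N = 20.6, P = 205.7, K = 74.1)),
    III = envelope(a = c(N = 15.1, P = 68.9, K = 33.3),
                   d = c(N = 20.3, P = 191.0, K = 71.0))
  )
}
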