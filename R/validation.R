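#' Root mean square error
#'
#' `sqrt(mean((simulated - measured)^2))`, in the units of the inputs.
#'
#' @param simulated,measured Numeric vectors of equal positive length.
#' @return RMSE (same units as inputs).
#' @examples
#' rmse(c(1, 2), c(0, 0))  # sqrt(2.5)
#' @export
rmse <- function(simulated, measured) {
  .check_pairs(simulated, measured)
  sqrt(mean((simulated - measured)^2))
}

#' Normalized root mean square error
#'
#' RMSE divided by the mean of the measured series, reported in percent.
#' Scale-free: a common unit change of both series leaves it untouched.
#'
#' @inheritParams rmse
#' @return n-RMSE in percent.
#' @export
n_rmse <- function(simulated, measured) {
  .check_pairs(simulated, measured)
  m_bar <- mean(measured)
  if (m_bar == 0) stop("mean of measured series is zero; n-RMSE undefined",
                       call. = FALSE)
  100 * rmse(simulated, measured) / m_bar
}

.check_pairs <- function(simulated, measured) {
  if (!is.numeric(simulated) || !is.numeric(measured)) {
    stop("simulated and measured must be numeric", call. = FALSE)
  }
  if (length(simulated) != length(measured)) {
    stop("simulated and measured must have the same length", call. = FALSE)
  }
  if (length(simulated) < 1L) stop("need at least one pair", call. = FALSE)
  if (anyNA(simulated) || anyNA(measured)) {
    stop("missing values in paired series", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-nutrient validation summary
#'
#' Agreement statistics between simulated and measured above-ground uptakes:
#' n, RMSE, n-RMSE and mean bias (simulated minus measured) per nutrient.
#' Descriptive only; no inferential claims are attached.
#'
#' @param pairs Data frame with columns `nutrient`, `simulated`, `measured`
#'   (e.g. from [generate_validation_pairs()]).
#' @return Data frame with one row per nutrient.
#' @export
validation_summary <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("nutrient", "simulated", "measured") %in% names(pairs)))
  out <- do.call(rbind, lapply(split(pairs, pairs$nutrient), function(d) {
    data.frame(nutrient = d$nutrient[1],
               n = nrow(d),
               rmse_kg_ha = rmse(d$simulated, d$measured),
               n_rmse_pct = n_rmse(d$simulated, d$measured),
               mean_bias_kg_ha = mean(d$simulated - d$measured))
  }))
  rownames(out) <- NULL
  out[order(match(out$nutrient, .nutrients)), , drop = FALSE]
}
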