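#' Named N-P-K triple
#'
#' Builds a named numeric vector `c(N =, P =, K =)`, the basic currency of the
#' package: depending on context it holds above-ground uptakes (kg/ha),
#' internal efficiencies (kg seed per kg nutrient) or per-tonne requirements
#' (kg per 1000 kg seed).
#'
#' @param n,p,k Finite numeric scalars.
#' @return Named numeric vector of length three.
#' @examples
#' npk(131.5, 21.8, 47.6)
#' @export
npk <- function(n, p, k) {
  out <- c(N = as.numeric(n), P = as.numeric(p), K = as.numeric(k))
  if (any(!is.finite(out))) {
    stop("all components of an N-P-K triple must be finite", call. = FALSE)
  }
  out
}

#' @keywords internal
.nutrients <- c("N", "P", "K")

# Coerce user input (length-3 vector, named or positional) to a canonical
# N/P/K-named vector; errors loudly on anything else.
as_npk <- function(x, what = "value", nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 3L) {
    stop(sprintf("'%s' must be a numeric vector of length 3 (N, P, K)", what),
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), .nutrients)) {
      stop(sprintf("'%s' must be named with N, P and K", what), call. = FALSE)
    }
    x <- x[.nutrients]
  } else {
    names(x) <- .nutrients
  }
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' has non-finite components", what), call. = FALSE)
  }
  if (nonnegative && any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", what), call. = FALSE)
  }
  x
}
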