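#' Plot-level field-trial observations
#'
#' Validates and classes a data frame of plot-level soybean records. Each row
#' is one plot-season: seed yield (at 13.5% moisture unless stated otherwise),
#' straw dry matter, seed and straw nutrient concentrations, optional
#' precomputed above-ground uptakes, and the harvest index.
#'
#' Expected columns (missing values as `NA`; unknown extra columns are kept):
#' \describe{
#'   \item{site_id, year, treatment}{identifiers (optional).}
#'   \item{seed_yield_kg_ha}{seed yield, kg/ha, 13.5% moisture basis.}
#'   \item{straw_dm_kg_ha}{straw (stem + leaves + pod shell) oven-dry mass, kg/ha.}
#'   \item{n_seed_g_kg, p_seed_g_kg, k_seed_g_kg}{seed concentrations, g/kg dry matter.}
#'   \item{n_straw_g_kg, p_straw_g_kg, k_straw_g_kg}{straw concentrations, g/kg.}
#'   \item{n_uptake_kg_ha, p_uptake_kg_ha, k_uptake_kg_ha}{above-ground uptakes, kg/ha (optional).}
#'   \item{hi}{harvest index, kg/kg.}
#' }
#'
#' When both concentrations and precomputed uptakes are present they must
#' agree to `uptake_tol` relative (default 1e-3); inconsistent records are
#' rejected with an error rather than silently preferred one way.
#'
#' @param x A data frame.
#' @param moisture_fraction Seed moisture fraction used to convert seed yield
#'   to seed dry matter when computing uptakes. Default 0.135.
#' @param uptake_tol Relative tolerance for the concentration/uptake
#'   consistency check.
#' @return `x` with class `quefts_obs` and the moisture fraction attached as
#'   an attribute.
#' @seealso [compute_uptake()], [filter_by_hi()], [read_observations()]
#' @export
observations <- function(x, moisture_fraction = 0.135, uptake_tol = 1e-3) {
  if (!is.data.frame(x)) stop("'x' must be a data frame", call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.numeric(moisture_fraction) || length(moisture_fraction) != 1L ||
      moisture_fraction < 0 || moisture_fraction >= 1) {
    stop("'moisture_fraction' must be a single number in [0, 1)", call. = FALSE)
  }

  num_cols <- c("seed_yield_kg_ha", "straw_dm_kg_ha",
                "n_seed_g_kg", "p_seed_g_kg", "k_seed_g_kg",
                "n_straw_g_kg", "p_straw_g_kg", "k_straw_g_kg",
                "n_uptake_kg_ha", "p_uptake_kg_ha", "k_uptake_kg_ha", "hi")
  for (cl in intersect(num_cols, names(x))) {
    x[[cl]] <- as.numeric(x[[cl]])
    bad <- !is.na(x[[cl]]) & x[[cl]] < 0
    if (cl != "hi" && any(bad)) {
      stop(sprintf("negative values in column '%s' (rows %s)", cl,
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  if ("hi" %in% names(x)) {
    bad <- !is.na(x$hi) & (x$hi <= 0 | x$hi >= 1)
    if (any(bad)) {
      stop(sprintf("harvest index must lie in (0, 1); offending rows: %s",
                   paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    }
  }

  attr(x, "moisture_fraction") <- moisture_fraction
  class(x) <- unique(c("quefts_obs", class(x)))

  # Cross-check stored uptakes against concentration-derived ones where both
  # exist; a disagreement is a data error, not something to paper over.
  derived <- .uptake_from_concentrations(x, moisture_fraction)
  for (nut in .nutrients) {
    col <- paste0(tolower(nut), "_uptake_kg_ha")
    if (!col %in% names(x)) next
    have_both <- !is.na(x[[col]]) & !is.na(derived[, nut])
    if (!any(have_both)) next
    rel <- abs(x[[col]][have_both] - derived[have_both, nut]) /
      pmax(abs(derived[have_both, nut]), 1e-12)
    if (any(rel > uptake_tol)) {
      rows <- which(have_both)[rel > uptake_tol]
      stop(sprintf(
        "stored %s uptake disagrees with concentrations x dry weights beyond %g relative (rows %s)",
        nut, uptake_tol, paste(utils::head(rows, 5), collapse = ", ")),
        call. = FALSE)
    }
  }
  x
}

# seed/straw concentration (g/kg) x dry matter (kg/ha) / 1000 -> kg/ha.
# Seed dry matter removes the moisture fraction from the marketed yield.
.uptake_from_concentrations <- function(x, moisture_fraction) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, .nutrients))
  if (!all(c("seed_yield_kg_ha", "straw_dm_kg_ha") %in% names(x))) return(out)
  seed_dm <- x$seed_yield_kg_ha * (1 - moisture_fraction)
  for (nut in .nutrients) {
    cs <- paste0(tolower(nut), "_seed_g_kg")
    ct <- paste0(tolower(nut), "_straw_g_kg")
    if (!all(c(cs, ct) %in% names(x))) next
    out[, nut] <- seed_dm * x[[cs]] / 1000 + x$straw_dm_kg_ha * x[[ct]] / 1000
  }
  out
}

#' Above-ground nutrient uptake per plot
#'
#' Uptake of N, P and K in above-ground biomass, computed as nutrient
#' concentration times plant dry weight, summed over seed and straw:
#' `u = conc_seed * seed_dm / 1000 + conc_straw * straw_dm / 1000` (kg/ha).
#' Seed dry matter is the marketed yield times `1 - moisture_fraction`.
#' Records that carry precomputed uptakes (already cross-checked by
#' [observations()]) use those directly.
#'
#' @param obs A `quefts_obs` table from [observations()].
#' @return Numeric matrix, one row per record, columns `N`, `P`, `K` (kg/ha).
#'   Records with insufficient data get `NA` and a warning; they are never
#'   silently zero.
#' @export
compute_uptake <- function(obs) {
  stopifnot(inherits(obs, "quefts_obs"))
  mf <- attr(obs, "moisture_fraction")
  out <- .uptake_from_concentrations(obs, mf)
  for (nut in .nutrients) {
    col <- paste0(tolower(nut), "_uptake_kg_ha")
    if (col %in% names(obs)) {
      use <- is.na(out[, nut]) & !is.na(obs[[col]])
      out[use, nut] <- obs[[col]][use]
    }
  }
  if (anyNA(out)) {
    warning(sprintf("%d record(s) lack the data needed for at least one uptake; returned NA",
                    sum(apply(is.na(out), 1, any))), call. = FALSE)
  }
  out
}

#' Internal efficiency and its reciprocal
#'
#' Internal efficiency (IE) is seed yield per unit of above-ground nutrient
#' uptake (kg seed per kg nutrient); the reciprocal internal efficiency
#' (RIE = 1000/IE) is the uptake needed per tonne of seed (kg/t). Seed yield
#' stays on its 13.5%-moisture marketing basis, matching how IE is reported
#' in soybean trial summaries.
#'
#' @param obs A `quefts_obs` table.
#' @return List with matrices `ie` and `rie` (rows = records, columns N/P/K).
#'   Zero uptake gives `NA` IE with a warning; zero yield gives IE 0 and `NA`
#'   RIE.
#' @export
compute_ie <- function(obs) {
  stopifnot(inherits(obs, "quefts_obs"))
  u <- compute_uptake(obs)
  y <- obs$seed_yield_kg_ha
  ie <- y / u
  ie[u == 0 & !is.na(u)] <- NA_real_
  if (any(u == 0, na.rm = TRUE)) {
    warning("zero uptake in some records: IE undefined there (NA)", call. = FALSE)
  }
  ie[!is.na(y) & y == 0] <- 0
  rie <- 1000 / ie
  rie[ie == 0 & !is.na(ie)] <- NA_real_
  list(ie = ie, rie = rie)
}

#' Nutrient harvest index
#'
#' Fraction of total above-ground nutrient content located in the seed
#' (kg/kg), computed per nutrient from concentrations and dry weights.
#'
#' @param obs A `quefts_obs` table.
#' @return Matrix with columns `N`, `P`, `K`, each in `(0, 1]`. Seed content
#'   exceeding the total (impossible by construction here, but possible with
#'   inconsistent inputs) raises an error.
#' @export
compute_nutrient_hi <- function(obs) {
  stopifnot(inherits(obs, "quefts_obs"))
  mf <- attr(obs, "moisture_fraction")
  seed_dm <- obs$seed_yield_kg_ha * (1 - mf)
  out <- matrix(NA_real_, nrow(obs), 3, dimnames = list(NULL, .nutrients))
  total <- compute_uptake(obs)
  for (nut in .nutrients) {
    cs <- paste0(tolower(nut), "_seed_g_kg")
    if (!cs %in% names(obs)) next
    seed_content <- seed_dm * obs[[cs]] / 1000
    bad <- !is.na(seed_content) & !is.na(total[, nut]) &
      seed_content > total[, nut] * (1 + 1e-9)
    if (any(bad)) {
      stop(sprintf("seed %s content exceeds total above-ground content (rows %s)",
                   nut, paste(utils::head(which(bad), 5), collapse = ", ")),
           call. = FALSE)
    }
    out[, nut] <- seed_content / total[, nut]
  }
  out
}

#' Exclude low harvest-index records
#'
#' Plots with a harvest index below the threshold are assumed to have
#' suffered stresses other than nutrient deficiency and are removed before
#' envelope calibration. The comparison is `hi < threshold` excluded, so a
#' record exactly at the threshold is kept.
#'
#' @param obs A `quefts_obs` table.
#' @param threshold Harvest-index cutoff in (0, 1); default 0.4.
#' @param keep_missing Keep records with missing `hi`? Default `FALSE`
#'   (they are dropped and counted in the message).
#' @param quiet Suppress the removal-count message.
#' @return The filtered `quefts_obs` table, with attributes `n_removed` and
#'   `n_missing` recording what was dropped.
#' @export
filter_by_hi <- function(obs, threshold = 0.4, keep_missing = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(obs, "quefts_obs"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("'threshold' must be a single number in [0, 1)", call. = FALSE)
  }
  if (!"hi" %in% names(obs)) stop("no 'hi' column to filter on", call. = FALSE)
  miss <- is.na(obs$hi)
  keep <- (!miss & obs$hi >= threshold) | (miss & keep_missing)
  out <- obs[keep, , drop = FALSE]
  attr(out, "moisture_fraction") <- attr(obs, "moisture_fraction")
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_missing") <- sum(miss)
  class(out) <- class(obs)
  if (!quiet) {
    message(sprintf("filter_by_hi: kept %d of %d records (%d below %.2g, %d missing hi%s)",
                    nrow(out), nrow(obs), sum(!miss & obs$hi < threshold),
                    threshold, sum(miss),
                    if (keep_missing) ", retained" else ", dropped"))
  }
  out
}

#' Seven-number summary
#'
#' Mean, sample standard deviation and the five order statistics
#' (minimum, 25% quartile, median, 75% quartile, maximum) used in trial
#' summary tables. Quartiles use linear interpolation at rank `p * (n - 1)`
#' (R quantile type 7), the same convention the envelope calibration uses.
#'
#' @param values Numeric vector with at least one finite value; `NA`s dropped.
#' @return One-row data frame: `n_obs`, `mean`, `sd`, `minimum`, `q25`,
#'   `median`, `q75`, `maximum`. For a single value `sd` is 0 by convention.
#' @examples
#' summarize_values(c(1, 2, 3, 4, 5))
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize", call. = FALSE)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  data.frame(
    n_obs = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    minimum = q[1], q25 = q[2], median = q[3], q75 = q[4], maximum = q[5]
  )
}

#' Trial-table summary of a set of observations
#'
#' Applies [summarize_values()] to yield, harvest index, uptakes, internal
#' efficiencies and reciprocal internal efficiencies, producing a long
#' summary in the layout of multi-site soybean trial reports.
#'
#' @param obs A `quefts_obs` table.
#' @return Data frame with one row per summarized quantity.
#' @export
summarize_trials <- function(obs) {
  stopifnot(inherits(obs, "quefts_obs"))
  u <- compute_uptake(obs)
  e <- suppressWarnings(compute_ie(obs))
  pieces <- list(
    seed_yield_kg_ha = obs$seed_yield_kg_ha,
    hi = if ("hi" %in% names(obs)) obs$hi else numeric(0),
    uptake_n_kg_ha = u[, "N"], uptake_p_kg_ha = u[, "P"], uptake_k_kg_ha = u[, "K"],
    ie_n = e$ie[, "N"], ie_p = e$ie[, "P"], ie_k = e$ie[, "K"],
    rie_n = e$rie[, "N"], rie_p = e$rie[, "P"], rie_k = e$rie[, "K"]
  )
  pieces <- pieces[vapply(pieces, function(v) any(is.finite(v)), logical(1))]
  out <- do.call(rbind, lapply(names(pieces), function(nm) {
    cbind(parameter = nm, summarize_values(pieces[[nm]]))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write observation tables
#'
#' Plain-CSV I/O for the plot-level schema documented in [observations()]
#' (UTF-8, empty cells as missing values).
#'
#' @param path File path.
#' @param ... Passed on to [observations()] (e.g. `moisture_fraction`).
#' @return `read_observations()` returns a validated `quefts_obs` table.
#' @export
read_observations <- function(path, ...) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                       fileEncoding = "UTF-8")
  observations(x, ...)
}

#' @rdname read_observations
#' @param obs A `quefts_obs` table to write.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "quefts_obs"))
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
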