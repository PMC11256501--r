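## Closed-chamber CH4 flux estimation.
##
## A chamber series is a data.frame with one row per analyzer reading and the
## columns listed in `chamber_series_columns()`. Physical metadata (pressure,
## jar volume, headspace temperature, soil dry mass) travel with every row so
## a series survives CSV round-trips unchanged.

#' Required columns of a chamber concentration series
#'
#' @return Character vector of column names.
#' @export
chamber_series_columns <- function() {
  c("jar_id", "site", "temperature", "flooding", "replicate", "day",
    "time_s", "ch4_ppm", "pressure_atm", "volume_L", "temp_K",
    "soil_dry_mass_g")
}

.check_chamber_series <- function(series) {
  missing_cols <- setdiff(c("time_s", "ch4_ppm", "pressure_atm", "volume_L",
                            "temp_K", "soil_dry_mass_g"), names(series))
  if (length(missing_cols))
    stop("chamber series is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(series) < 2L)
    stop("chamber series needs at least 2 readings", call. = FALSE)
  if (is.unsorted(series$time_s, strictly = TRUE))
    stop("reading times must be strictly increasing", call. = FALSE)
  invisible(series)
}

#' Convert a CH4 mixing ratio to headspace CH4 mass
#'
#' Ideal-gas conversion of a mixing ratio (ppm, i.e. micromol CH4 per mol of
#' headspace gas) to the mass of CH4 contained in the chamber headspace:
#' `mass_ug = ppm * molar_mass * (P * V) / (R * T)` with
#' R = 0.082 L atm mol^-1 K^-1. Because ppm is micromol/mol the result is in
#' micrograms directly.
#'
#' @param ppm CH4 mixing ratio (micromol/mol). Vectorized.
#' @param pressure_atm Headspace pressure (atm).
#' @param volume_L Chamber headspace volume (L).
#' @param temp_K Headspace temperature (K).
#' @param molar_mass_g_mol Molar mass used for the conversion (g/mol);
#'   defaults to CH4 (16.043).
#' @return CH4 mass in micrograms, same length as `ppm`.
#' @examples
#' ppm_to_mass(2, pressure_atm = 1, volume_L = 1.5, temp_K = 300.15)
#' @export
ppm_to_mass <- function(ppm, pressure_atm, volume_L, temp_K,
                        molar_mass_g_mol = .MM_CH4) {
  if (any(pressure_atm <= 0) || any(volume_L <= 0) || any(temp_K <= 0) ||
      molar_mass_g_mol <= 0)
    stop("pressure, volume, temperature and molar mass must be positive",
         call. = FALSE)
  if (any(ppm < 0)) stop("ppm must be non-negative", call. = FALSE)
  ppm * molar_mass_g_mol * (pressure_atm * volume_L) /
    (.GAS_CONSTANT_L_ATM * temp_K)
}

#' Drop the chamber stabilization transient
#'
#' Closed-loop chamber measurements need roughly a minute to stabilize after
#' the lid is closed; readings in the first `exclude_first_s` seconds are
#' discarded and the fit window ends at `end_s`. With the default 10-s cadence
#' over 600 s this keeps the 50 readings between 100 and 600 s.
#'
#' @param series Chamber series data.frame (see [chamber_series_columns()]).
#' @param exclude_first_s Seconds to exclude from the start (strict:
#'   a reading at exactly `exclude_first_s` is dropped).
#' @param end_s Last second retained (inclusive).
#' @return The retained sub-series, order preserved.
#' @export
trim_window <- function(series, exclude_first_s = 100, end_s = 600) {
  .check_chamber_series(series)
  keep <- series$time_s > exclude_first_s & series$time_s <= end_s
  if (!any(keep))
    stop("no readings left in (", exclude_first_s, ", ", end_s,
         "] s: insufficient data", call. = FALSE)
  series[keep, , drop = FALSE]
}

#' Estimate a CH4 flux from a trimmed chamber series
#'
#' Converts each reading to a headspace CH4 mass (ideal gas law, see
#' [ppm_to_mass()]), fits ordinary least squares of mass (ug) on time (s), and
#' scales the slope to a soil-mass-specific hourly flux:
#' `flux = slope_ug_per_s * 3600 / soil_dry_mass_g`, optionally expressed per
#' mass of carbon (factor 12.011/16.043, the default reporting convention
#' "ug C-CH4 g dw^-1 h^-1"). Negative slopes indicate net CH4 consumption and
#' are preserved.
#'
#' r-squared of a zero-variance mass response is defined as 0.
#'
#' @param series A (typically trimmed) chamber series.
#' @param mass_basis `"C"` to report ug of CH4-carbon (default) or `"CH4"`
#'   for ug of whole CH4.
#' @return Object of class `flux_estimate`: list with `flux`
#'   (ug g dw^-1 h^-1 on `mass_basis`), `slope_ug_per_h`, `intercept` (ug),
#'   `r2`, `n_points`, `window_s`, `qc_pass` (NA until [qc_flux()]),
#'   `mass_basis`, and the series' identifying metadata.
#' @export
fit_flux <- function(series, mass_basis = c("C", "CH4")) {
  mass_basis <- match.arg(mass_basis)
  .check_chamber_series(series)
  t <- series$time_s
  if (length(unique(t)) < 2L)
    stop("all reading times identical: singular fit", call. = FALSE)
  mass_ug <- ppm_to_mass(series$ch4_ppm, series$pressure_atm,
                         series$volume_L, series$temp_K)
  fit <- lm(mass_ug ~ t)
  slope_s <- unname(coef(fit)[2L])
  sst <- sum((mass_ug - mean(mass_ug))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  soil <- series$soil_dry_mass_g[1L]
  if (soil <= 0) stop("soil dry mass must be positive", call. = FALSE)
  flux <- slope_s * 3600 / soil
  if (mass_basis == "C") flux <- flux * .MM_C / .MM_CH4
  meta <- lapply(c("jar_id", "site", "temperature", "flooding",
                   "replicate", "day"),
                 function(col) if (col %in% names(series)) series[[col]][1L]
                               else NA)
  names(meta) <- c("jar_id", "site", "temperature", "flooding",
                   "replicate", "day")
  structure(
    c(meta,
      list(slope_ug_per_h = slope_s * 3600,
           flux = flux,
           intercept = unname(coef(fit)[1L]),
           r2 = r2,
           n_points = length(t),
           window_s = range(t),
           qc_pass = NA,
           mass_basis = mass_basis)),
    class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  unit <- if (x$mass_basis == "C") "ug C-CH4 g dw-1 h-1" else
    "ug CH4 g dw-1 h-1"
  cat(sprintf("Chamber flux estimate (jar %s, day %s)\n",
              as.character(x$jar_id), as.character(x$day)))
  cat(sprintf("  flux: %.6g %s  (r2 = %.4f, n = %d, window %g-%g s)\n",
              x$flux, unit, x$r2, x$n_points,
              x$window_s[1], x$window_s[2]))
  if (!is.na(x$qc_pass))
    cat(sprintf("  QC (r2 threshold): %s\n",
                if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Flag flux estimates by regression quality
#'
#' Marks estimates whose regression r-squared strictly exceeds the threshold
#' (default 0.9, the conventional closed-chamber QC bound). Estimates at
#' exactly the threshold fail. Failures are flagged, never dropped here.
#'
#' @param estimate A `flux_estimate`, or a data.frame with an `r2` column
#'   (e.g. from [estimate_fluxes()]).
#' @param r2_threshold QC bound on r-squared.
#' @return Input with `qc_pass` set.
#' @export
qc_flux <- function(estimate, r2_threshold = 0.9) {
  if (is.data.frame(estimate)) {
    estimate$qc_pass <- estimate$r2 > r2_threshold
    return(estimate)
  }
  estimate$qc_pass <- estimate$r2 > r2_threshold
  estimate
}

#' Fit and QC fluxes for every jar x day series in a readings table
#'
#' Convenience wrapper: splits a long readings table by jar and day, trims
#' each series ([trim_window()]), fits ([fit_flux()]) and flags
#' ([qc_flux()]).
#'
#' @param readings Long data.frame of readings (all chamber series stacked).
#' @param exclude_first_s,end_s Passed to [trim_window()].
#' @param mass_basis Passed to [fit_flux()].
#' @param r2_threshold Passed to [qc_flux()].
#' @return data.frame with one row per jar x day: metadata columns plus
#'   `flux`, `slope_ug_per_h`, `intercept`, `r2`, `n_points`, `qc_pass`.
#' @export
estimate_fluxes <- function(readings, exclude_first_s = 100, end_s = 600,
                            mass_basis = c("C", "CH4"), r2_threshold = 0.9) {
  mass_basis <- match.arg(mass_basis)
  key <- interaction(readings$jar_id, readings$day, drop = TRUE)
  rows <- lapply(split(readings, key), function(series) {
    series <- series[order(series$time_s), , drop = FALSE]
    est <- qc_flux(fit_flux(trim_window(series, exclude_first_s, end_s),
                            mass_basis = mass_basis),
                   r2_threshold = r2_threshold)
    data.frame(jar_id = est$jar_id, site = est$site,
               temperature = est$temperature, flooding = est$flooding,
               replicate = est$replicate, day = est$day,
               flux = est$flux, slope_ug_per_h = est$slope_ug_per_h,
               intercept = est$intercept, r2 = est$r2,
               n_points = est$n_points, qc_pass = est$qc_pass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$temperature, out$flooding, out$replicate,
            out$day), , drop = FALSE]
}

#' Daily treatment-mean fluxes
#'
#' Averages replicate fluxes within each treatment (site x temperature x
#' flooding) and sampling day, recording replicate count and standard
#' deviation. QC failures are retained unless `qc_drop = TRUE`.
#'
#' @param estimates data.frame of flux estimates (from [estimate_fluxes()]).
#' @param qc_drop Drop estimates with `qc_pass == FALSE` before averaging.
#' @return data.frame: `site`, `temperature`, `flooding`, `day`,
#'   `mean_flux`, `sd_flux`, `n`.
#' @export
daily_treatment_flux <- function(estimates, qc_drop = FALSE) {
  if (qc_drop && "qc_pass" %in% names(estimates))
    estimates <- estimates[is.na(estimates$qc_pass) | estimates$qc_pass, ,
                           drop = FALSE]
  if (nrow(estimates) == 0L)
    stop("no flux estimates to average", call. = FALSE)
  grp <- estimates[c("site", "temperature", "flooding", "day")]
  mean_df <- aggregate(estimates$flux, grp, mean)
  sd_df <- aggregate(estimates$flux, grp, function(x)
    if (length(x) > 1L) sd(x) else NA_real_)
  n_df <- aggregate(estimates$flux, grp, length)
  out <- mean_df
  names(out)[5L] <- "mean_flux"
  out$sd_flux <- sd_df$x
  out$n <- n_df$x
  out[order(out$site, out$temperature, out$flooding, out$day), ,
      drop = FALSE]
}

#' Cumulative CH4 emission by linear interpolation of daily fluxes
#'
#' Integrates daily mean fluxes over the experimental window by the
#' trapezoidal rule (linear interpolation between successive sampling days):
#' `sum over pairs of 0.5 * (f_i + f_(i+1)) * 24 * (d_(i+1) - d_i)`,
#' yielding a cumulative emission in ug g dw^-1 (same mass basis as the
#' fluxes). Absent days are simply interpolated across.
#'
#' @param day Sampling days (numeric, strictly increasing).
#' @param flux Daily mean flux for each day (ug g dw^-1 h^-1).
#' @return Cumulative emission (ug g dw^-1), signed.
#' @examples
#' cumulative_emission(c(0, 30), c(0.001, 0.001))  # 0.72
#' @export
cumulative_emission <- function(day, flux) {
  if (length(day) != length(flux))
    stop("day and flux must have equal length", call. = FALSE)
  if (length(day) < 2L)
    stop("need at least two sampling days", call. = FALSE)
  if (anyNA(day) || anyNA(flux))
    stop("missing values in day or flux", call. = FALSE)
  if (is.unsorted(day, strictly = TRUE))
    stop("days must be sorted and distinct", call. = FALSE)
  i <- seq_len(length(day) - 1L)
  sum(0.5 * (flux[i] + flux[i + 1L]) * 24 * diff(day))
}

#' Cumulative emissions per treatment
#'
#' Applies [cumulative_emission()] to each site x temperature x flooding
#' group of a daily-means table.
#'
#' @param daily Output of [daily_treatment_flux()].
#' @return data.frame with one row per treatment and a `cumulative` column
#'   (ug g dw^-1).
#' @export
cumulative_by_treatment <- function(daily) {
  key <- interaction(daily$site, daily$temperature, daily$flooding,
                     drop = TRUE)
  rows <- lapply(split(daily, key), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    data.frame(site = d$site[1L], temperature = d$temperature[1L],
               flooding = d$flooding[1L],
               cumulative = cumulative_emission(d$day, d$mean_flux),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$temperature, out$flooding), , drop = FALSE]
}
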