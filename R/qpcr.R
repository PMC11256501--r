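## qPCR absolute quantification: dilution-series standard curves and
## conversion of quantification cycles (Cq) to gene copies per gram dry soil.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 template copies over a dilution
#' series. Amplification efficiency follows the universal convention
#' `E = 10^(-1/slope) - 1` (slope -3.3219 cycles per decade = perfect
#' doubling = 100%).
#'
#' @param log10_copies log10 of template copies per reaction (e.g. 0..6).
#' @param cq Quantification cycles, same length.
#' @return Object of class `standard_curve`: `slope` (cycles per log10),
#'   `intercept` (cycles at 1 copy), `r2`, `efficiency` (fraction, e.g. 1.0
#'   = 100%), `n_levels`, `valid` (FALSE with a warning when the slope is
#'   non-negative).
#' @examples
#' cv <- fit_standard_curve(0:6, 38 - 3.3219 * (0:6))
#' cv$efficiency  # 1 (100%)
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  if (length(log10_copies) != length(cq))
    stop("log10_copies and cq must have equal length", call. = FALSE)
  ok <- !is.na(log10_copies) & !is.na(cq)
  log10_copies <- log10_copies[ok]; cq <- cq[ok]
  if (length(unique(log10_copies)) < 3L)
    stop("standard curve needs at least 3 dilution levels", call. = FALSE)
  fit <- lm(cq ~ log10_copies)
  slope <- unname(coef(fit)[2L])
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  valid <- slope < 0
  if (!valid)
    warning("non-negative standard-curve slope: curve flagged invalid",
            call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1L]),
                 r2 = r2,
                 efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
                 n_levels = length(unique(log10_copies)),
                 n_points = length(cq),
                 valid = valid),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.4f, intercept %.2f, r2 = %.4f (%d levels)\n",
    x$slope, x$intercept, x$r2, x$n_levels))
  if (x$valid)
    cat(sprintf("  efficiency: %.1f%%\n", 100 * x$efficiency))
  else
    cat("  INVALID curve (non-negative slope)\n")
  invisible(x)
}

#' Soil dry-mass equivalent of one qPCR reaction
#'
#' Helper multiplying out the extraction chain: grams of dry soil whose DNA
#' ends up in a single reaction,
#' `soil_extracted_g_dw * (template_volume_uL / elution_volume_uL) / dilution`.
#' All factors are explicit; there are no hidden defaults for dilution.
#'
#' @param soil_extracted_g_dw Dry soil mass per DNA extraction (g), default
#'   0.25.
#' @param template_volume_uL Template volume per reaction (uL), default 1.
#' @param elution_volume_uL DNA elution volume per extraction (uL), default
#'   100.
#' @param dilution Fold-dilution of the template before the reaction.
#' @return Grams dry soil per reaction.
#' @export
soil_equivalent <- function(soil_extracted_g_dw = 0.25,
                            template_volume_uL = 1,
                            elution_volume_uL = 100,
                            dilution = 1) {
  if (soil_extracted_g_dw <= 0 || template_volume_uL <= 0 ||
      elution_volume_uL <= 0 || dilution <= 0)
    stop("all extraction-chain factors must be positive", call. = FALSE)
  soil_extracted_g_dw * (template_volume_uL / elution_volume_uL) / dilution
}

#' Convert sample Cq values to gene copies per gram dry soil
#'
#' Inverts the standard curve, `copies = 10^((Cq - intercept) / slope)`, and
#' scales to the soil mass represented in one reaction. Replicate Cq values
#' are averaged on the cycle scale before inversion (cycler-software
#' convention); set `aggregate = "copies"` to invert first and average
#' copies instead. Replicate scatter above `cq_sd_gate` flags (never drops)
#' the estimate.
#'
#' @param cq Replicate Cq values for one sample/gene.
#' @param curve A valid [fit_standard_curve()] object.
#' @param soil_equivalent_g_dw Grams of dry soil per reaction, see
#'   [soil_equivalent()].
#' @param aggregate `"cq"` (default) or `"copies"`.
#' @param cq_sd_gate Flag threshold on the replicate Cq standard deviation
#'   (cycles).
#' @return Object of class `abundance_estimate`: `copies_per_g_dw`,
#'   `log10_copies_per_g_dw`, `copies_per_reaction`, `cq_mean`, `cq_sd`,
#'   `n_replicates`, `flagged`.
#' @export
quantify_copies <- function(cq, curve, soil_equivalent_g_dw,
                            aggregate = c("cq", "copies"),
                            cq_sd_gate = 0.5) {
  aggregate <- match.arg(aggregate)
  if (!inherits(curve, "standard_curve"))
    stop("curve must be a standard_curve", call. = FALSE)
  if (!curve$valid)
    stop("cannot quantify against an invalid standard curve", call. = FALSE)
  if (length(soil_equivalent_g_dw) != 1L || soil_equivalent_g_dw <= 0)
    stop("soil_equivalent_g_dw must be a single positive number",
         call. = FALSE)
  cq <- cq[!is.na(cq)]
  if (!length(cq)) stop("no Cq values", call. = FALSE)
  cq_sd <- if (length(cq) > 1L) sd(cq) else NA_real_
  inv <- function(q) 10^((q - curve$intercept) / curve$slope)
  copies_rxn <- switch(aggregate,
                       cq = inv(mean(cq)),
                       copies = mean(inv(cq)))
  copies_g <- copies_rxn / soil_equivalent_g_dw
  structure(list(copies_per_g_dw = copies_g,
                 log10_copies_per_g_dw = log10(copies_g),
                 copies_per_reaction = copies_rxn,
                 cq_mean = mean(cq),
                 cq_sd = cq_sd,
                 n_replicates = length(cq),
                 flagged = !is.na(cq_sd) && cq_sd > cq_sd_gate),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf(
    "Abundance: %.3g copies g dw-1 (log10 = %.2f; Cq %.2f +/- %s, n = %d)%s\n",
    x$copies_per_g_dw, x$log10_copies_per_g_dw, x$cq_mean,
    ifelse(is.na(x$cq_sd), "NA", sprintf("%.2f", x$cq_sd)),
    x$n_replicates,
    if (isTRUE(x$flagged)) "  [FLAGGED: replicate scatter]" else ""))
  invisible(x)
}
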