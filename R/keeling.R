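## Stable-isotope arithmetic, Keeling-plot source partitioning, and
## methanogenic-pathway classification from (delta13C, delta2H) signatures.

#' Delta notation from isotope ratios
#'
#' `delta = (r_sample / r_standard - 1) * 1000` per mil, relative to an
#' international reference ratio (VPDB for 13C/12C, VSMOW for 2H/1H).
#'
#' @param r_sample Isotope ratio of the sample (heavy/light). Vectorized.
#' @param r_standard Reference ratio (> 0).
#' @return Delta value in per mil.
#' @seealso [ratio_from_delta()] for the exact inverse.
#' @export
delta_value <- function(r_sample, r_standard) {
  if (any(r_standard <= 0))
    stop("reference ratio must be positive", call. = FALSE)
  (r_sample / r_standard - 1) * 1000
}

#' Isotope ratio from a delta value
#'
#' Exact inverse of [delta_value()]: `r = r_standard * (1 + delta / 1000)`.
#'
#' @param delta Delta value (per mil). Vectorized.
#' @param r_standard Reference ratio (> 0).
#' @return Isotope ratio.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(r_standard <= 0))
    stop("reference ratio must be positive", call. = FALSE)
  r_standard * (1 + delta / 1000)
}

#' Keeling-plot estimate of the CH4 source isotopic signature
#'
#' Regresses the measured delta value against inverse CH4 concentration
#' (ordinary least squares). Under two-member conservative mixing of an
#' atmospheric background with an added source, the measured mixture obeys
#' `delta_mix = delta_src + C_bg * (delta_bg - delta_src) / C_tot`, a line in
#' 1/C whose intercept (1/C -> 0) is the delta of the mean source. The
#' atmospheric background sample is an ordinary point on the mixing line.
#'
#' @param samples data.frame with columns `ch4_ppm` and the delta column for
#'   the requested system (`d13C` or `d2H`); typically includes a background
#'   air sample.
#' @param isotope_system `"13C"` or `"2H"`.
#' @return Object of class `keeling_fit`: `intercept` (per mil, mean-source
#'   delta), `slope` (per mil * ppm), `r2`, `n`, `isotope_system`.
#' @export
keeling_intercept <- function(samples, isotope_system = c("13C", "2H")) {
  isotope_system <- match.arg(isotope_system)
  dcol <- if (isotope_system == "13C") "d13C" else "d2H"
  if (!all(c("ch4_ppm", dcol) %in% names(samples)))
    stop("samples need columns ch4_ppm and ", dcol, call. = FALSE)
  conc <- samples$ch4_ppm
  delta <- samples[[dcol]]
  ok <- !is.na(conc) & !is.na(delta)
  conc <- conc[ok]; delta <- delta[ok]
  if (length(conc) < 3L)
    stop("Keeling fit needs at least 3 samples", call. = FALSE)
  if (any(conc <= 0))
    stop("CH4 concentrations must be positive", call. = FALSE)
  if (length(unique(conc)) < 2L)
    stop("all CH4 concentrations identical: degenerate Keeling design",
         call. = FALSE)
  inv <- 1 / conc
  fit <- lm(delta ~ inv)
  sst <- sum((delta - mean(delta))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  structure(list(intercept = unname(coef(fit)[1L]),
                 slope = unname(coef(fit)[2L]),
                 r2 = r2,
                 n = length(conc),
                 isotope_system = isotope_system),
            class = "keeling_fit")
}

#' @export
print.keeling_fit <- function(x, ...) {
  cat(sprintf(
    "Keeling fit (delta%s): source intercept %.2f permil (slope %.3g, r2 = %.4f, n = %d)\n",
    x$isotope_system, x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}

#' Default isotopic regions for CH4 production pathways
#'
#' Characteristic dual-isotope boxes for biogenic CH4: hydrogenotrophic
#' methanogenesis (CO2/H2 reduction) has delta13C in \[-110, -60\] and
#' delta2H in \[-250, -170\] per mil; acetoclastic (acetate fermentation)
#' has delta13C in \[-60, -50\] and delta2H in \[-400, -250\]. Signatures
#' enriched beyond both oxidation thresholds (defaults: the upper edges of
#' the production boxes, delta13C > -50 and delta2H > -170) indicate
#' residual CH4 enriched by oxidation.
#'
#' @return Named list with elements `hydrogenotrophic`, `acetoclastic`
#'   (each `list(d13C = c(lo, hi), d2H = c(lo, hi))`) and
#'   `oxidation_thresholds` (`list(d13C =, d2H =)`).
#' @export
pathway_regions <- function() {
  list(
    hydrogenotrophic = list(d13C = c(-110, -60), d2H = c(-250, -170)),
    acetoclastic = list(d13C = c(-60, -50), d2H = c(-400, -250)),
    oxidation_thresholds = list(d13C = -50, d2H = -170)
  )
}

.check_regions <- function(regions) {
  need <- c("hydrogenotrophic", "acetoclastic", "oxidation_thresholds")
  if (!all(need %in% names(regions)))
    stop("region config needs elements: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (box in regions[c("hydrogenotrophic", "acetoclastic")]) {
    if (!all(c("d13C", "d2H") %in% names(box)) ||
        length(box$d13C) != 2L || length(box$d2H) != 2L ||
        box$d13C[1] > box$d13C[2] || box$d2H[1] > box$d2H[2])
      stop("each region box needs ordered d13C and d2H ranges",
           call. = FALSE)
  }
  h <- regions$hydrogenotrophic; a <- regions$acetoclastic
  open_overlap <- function(x, y) max(x[1], y[1]) < min(x[2], y[2])
  if (open_overlap(h$d13C, a$d13C) && open_overlap(h$d2H, a$d2H))
    stop("production boxes overlap on both axes: invalid region config",
         call. = FALSE)
  invisible(regions)
}

.in_box <- function(x, range) x >= range[1] & x <= range[2]

.axis_distance <- function(x, range) {
  ifelse(x < range[1], x - range[1], ifelse(x > range[2], x - range[2], 0))
}

#' Classify the CH4 source pathway from its dual-isotope signature
#'
#' Point-in-box classification of a Keeling-derived source signature against
#' the configured production regions. Box membership is inclusive; a point on
#' the shared delta13C = -60 edge is resolved to the hydrogenotrophic (lower
#' delta13C) box. Points enriched beyond both oxidation thresholds are
#' labelled `oxidation-enriched`; everything else is `mixed/indeterminate`
#' (e.g. concurrent hydrogenotrophic and acetoclastic production).
#'
#' @param d13C_source,d2H_source Source signature (per mil). Vectorized.
#' @param regions Region configuration, see [pathway_regions()].
#' @return Object of class `pathway_signature`: a data.frame with
#'   `d13C_source`, `d2H_source`, `category` (factor with levels
#'   hydrogenotrophic, acetoclastic, oxidation-enriched,
#'   mixed/indeterminate), and signed per-axis distances to each production
#'   box (0 inside the axis range, negative below, positive above).
#' @examples
#' classify_pathway(-80, -200)   # hydrogenotrophic
#' classify_pathway(-55, -300)   # acetoclastic
#' @export
classify_pathway <- function(d13C_source, d2H_source,
                             regions = pathway_regions()) {
  .check_regions(regions)
  if (length(d13C_source) != length(d2H_source))
    stop("d13C_source and d2H_source must have equal length", call. = FALSE)
  if (any(!is.finite(d13C_source)) || any(!is.finite(d2H_source)))
    stop("source signatures must be finite", call. = FALSE)
  h <- regions$hydrogenotrophic
  a <- regions$acetoclastic
  ox <- regions$oxidation_thresholds
  in_h <- .in_box(d13C_source, h$d13C) & .in_box(d2H_source, h$d2H)
  in_a <- !in_h & .in_box(d13C_source, a$d13C) & .in_box(d2H_source, a$d2H)
  oxid <- !in_h & !in_a & d13C_source > ox$d13C & d2H_source > ox$d2H
  category <- factor(
    ifelse(in_h, "hydrogenotrophic",
           ifelse(in_a, "acetoclastic",
                  ifelse(oxid, "oxidation-enriched", "mixed/indeterminate"))),
    levels = c("hydrogenotrophic", "acetoclastic", "oxidation-enriched",
               "mixed/indeterminate"))
  out <- data.frame(
    d13C_source = d13C_source,
    d2H_source = d2H_source,
    category = category,
    dist_hydro_d13C = .axis_distance(d13C_source, h$d13C),
    dist_hydro_d2H = .axis_distance(d2H_source, h$d2H),
    dist_aceto_d13C = .axis_distance(d13C_source, a$d13C),
    dist_aceto_d2H = .axis_distance(d2H_source, a$d2H))
  class(out) <- c("pathway_signature", "data.frame")
  out
}
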