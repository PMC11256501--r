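## Synthetic-data generator: emulates a full factorial microcosm incubation
## (3 sites x 2 temperatures x 2 flooding levels x 4 replicates over 9
## sampling days) so that every analysis stage has realistic, fully known
## inputs. Generators share only the physical model with the estimators,
## never code paths: conversions are written out as their algebraic
## inverses.

#' Configuration of a factorial microcosm experiment
#'
#' @param sites Site labels.
#' @param temperatures Incubation temperature levels (degrees C).
#' @param flooding Flooding levels.
#' @param replicates Replicates per treatment.
#' @param days Ordered sampling days, starting at 0.
#' @param jar_volume_L Jar headspace volume (L).
#' @param fresh_soil_g Fresh soil per jar (g).
#' @param moisture_fraction Gravimetric moisture of the fresh soil; dry mass
#'   defaults to `fresh_soil_g * (1 - moisture_fraction)`.
#' @param soil_dry_mass_g Dry soil per jar (g); overrides the derivation.
#' @param pressure_atm Headspace pressure (atm). The jars are assumed at
#'   room pressure; exposed because it is an assumption, not a measurement.
#' @param cadence_s Seconds between analyzer readings.
#' @param duration_s Length of a chamber measurement (s);
#'   `duration_s / cadence_s` must be a whole number of readings.
#' @param rng_seed Integer seed used by [gen_experiment()].
#' @return Object of class `experiment_config` (a validated list).
#' @export
experiment_config <- function(sites = c("FP1", "FP2", "PFO"),
                              temperatures = c(27, 30),
                              flooding = c("wet", "dry"),
                              replicates = 4,
                              days = c(0, 1, 3, 6, 9, 13, 17, 23, 30),
                              jar_volume_L = 1.5,
                              fresh_soil_g = 400,
                              moisture_fraction = 0.30,
                              soil_dry_mass_g = NULL,
                              pressure_atm = 1,
                              cadence_s = 10,
                              duration_s = 600,
                              rng_seed = 1L) {
  if (length(days) < 2L || days[1L] != 0 || is.unsorted(days, strictly = TRUE))
    stop("days must start at 0 and be strictly increasing", call. = FALSE)
  if (cadence_s <= 0 || duration_s <= 0)
    stop("cadence and duration must be positive", call. = FALSE)
  n_readings <- duration_s / cadence_s
  if (abs(n_readings - round(n_readings)) > 1e-9)
    stop("duration_s / cadence_s must be a whole number of readings",
         call. = FALSE)
  if (moisture_fraction < 0 || moisture_fraction >= 1)
    stop("moisture_fraction must be in [0, 1)", call. = FALSE)
  if (is.null(soil_dry_mass_g))
    soil_dry_mass_g <- fresh_soil_g * (1 - moisture_fraction)
  if (jar_volume_L <= 0 || soil_dry_mass_g <= 0 || pressure_atm <= 0)
    stop("jar volume, soil dry mass and pressure must be positive",
         call. = FALSE)
  structure(list(sites = sites, temperatures = temperatures,
                 flooding = flooding, replicates = as.integer(replicates),
                 days = days, jar_volume_L = jar_volume_L,
                 soil_dry_mass_g = soil_dry_mass_g,
                 pressure_atm = pressure_atm,
                 cadence_s = cadence_s, duration_s = duration_s,
                 n_readings = as.integer(round(n_readings)),
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_config")
}

#' True parameters of one simulated chamber series
#'
#' @param true_flux Net surface flux (ug C-CH4 g dw^-1 h^-1; negative =
#'   consumption). Default 0.005, a strong soil emission.
#' @param transient_amplitude Amplitude (ppm) of the closing transient that
#'   decays over the stabilization period.
#' @param transient_timescale e-folding time (s) of the transient; the
#'   default 30 s makes it negligible after the 100-s trim.
#' @param noise_sd Reading noise sd (ppm); default 0.005, the ppb-level
#'   precision of a cavity-enhanced analyzer.
#' @param baseline_ppm Headspace CH4 at closing (ppm); default ambient 1.9.
#' @return Object of class `chamber_truth`.
#' @export
chamber_truth <- function(true_flux = 0.005, transient_amplitude = 0.5,
                          transient_timescale = 30, noise_sd = 0.005,
                          baseline_ppm = 1.9) {
  if (transient_timescale <= 0)
    stop("transient_timescale must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (baseline_ppm < 0)
    stop("baseline_ppm must be non-negative", call. = FALSE)
  structure(list(true_flux = true_flux,
                 transient_amplitude = transient_amplitude,
                 transient_timescale = transient_timescale,
                 noise_sd = noise_sd, baseline_ppm = baseline_ppm),
            class = "chamber_truth")
}

#' Simulate one chamber concentration time series
#'
#' Readings at `cadence_s, 2 cadence_s, ..., duration_s` follow
#' `baseline + transient_amplitude * exp(-t / transient_timescale) +
#' slope * t` plus independent Gaussian noise, where the linear slope is the
#' exact ideal-gas inverse of the flux arithmetic: a true flux F
#' (ug C-CH4 g dw^-1 h^-1) corresponds to a ppm/s slope of
#' `F * soil_dw * (16.043/12.011) / 3600 * (R * T) / (16.043 * P * V)`.
#'
#' @param config An [experiment_config()].
#' @param truth A [chamber_truth()].
#' @param jar Named list of jar metadata (`jar_id`, `site`, `temperature`
#'   in degrees C, `flooding`, `replicate`, `day`); physical metadata
#'   (`volume_L`, `soil_dry_mass_g`, `pressure_atm`) default to the config.
#' @param seed Optional seed for the reading noise.
#' @return A chamber series data.frame (see [chamber_series_columns()]).
#' @export
gen_chamber_series <- function(config, truth,
                               jar = list(jar_id = "jar1", site = "FP1",
                                          temperature = 27,
                                          flooding = "wet", replicate = 1L,
                                          day = 0),
                               seed = NULL) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(truth, "chamber_truth"))
  volume_L <- jar$volume_L %||% config$jar_volume_L
  soil_dw <- jar$soil_dry_mass_g %||% config$soil_dry_mass_g
  pressure <- jar$pressure_atm %||% config$pressure_atm
  temp_K <- jar$temp_K %||% (jar$temperature + 273.15)
  t <- seq(config$cadence_s, config$duration_s, by = config$cadence_s)
  ## inverse of the mass/flux chain: ppm per ug, then ug/h per flux unit
  ppm_per_ug <- (.GAS_CONSTANT_L_ATM * temp_K) /
    (.MM_CH4 * pressure * volume_L)
  slope_ppm_s <- truth$true_flux * soil_dw * (.MM_CH4 / .MM_C) / 3600 *
    ppm_per_ug
  expected <- truth$baseline_ppm +
    truth$transient_amplitude * exp(-t / truth$transient_timescale) +
    slope_ppm_s * t
  noise <- if (truth$noise_sd == 0) 0 else {
    draw <- function() rnorm(length(t), 0, truth$noise_sd)
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  data.frame(jar_id = jar$jar_id, site = jar$site,
             temperature = jar$temperature, flooding = jar$flooding,
             replicate = jar$replicate, day = jar$day,
             time_s = t, ch4_ppm = expected + noise,
             pressure_atm = pressure, volume_L = volume_L,
             temp_K = temp_K, soil_dry_mass_g = soil_dw,
             stringsAsFactors = FALSE)
}

#' True parameters of a two-member isotope mixing set
#'
#' @param source_d13C,source_d2H Source CH4 signature (per mil vs VPDB /
#'   VSMOW).
#' @param background_ppm Atmospheric background CH4 (ppm).
#' @param background_d13C,background_d2H Background signature (per mil);
#'   defaults are typical tropospheric CH4 values.
#' @param added_ppm_levels CH4 increments above background; at least 3
#'   distinct totals (including the background itself) are required, and
#'   not all increments may be zero.
#' @return Object of class `mixing_truth`.
#' @export
mixing_truth <- function(source_d13C = -60, source_d2H = -300,
                         background_ppm = 1.9,
                         background_d13C = -47.2,
                         background_d2H = -86,
                         added_ppm_levels = c(0.5, 1, 2, 5, 10)) {
  if (background_ppm <= 0)
    stop("background_ppm must be positive", call. = FALSE)
  if (any(added_ppm_levels < 0))
    stop("added CH4 must be non-negative", call. = FALSE)
  if (all(added_ppm_levels == 0))
    stop("all added CH4 levels are zero: degenerate mixing design",
         call. = FALSE)
  totals <- background_ppm + c(0, added_ppm_levels)
  if (length(unique(totals)) < 3L)
    stop("need at least 3 distinct total concentrations", call. = FALSE)
  structure(list(source_d13C = source_d13C, source_d2H = source_d2H,
                 background_ppm = background_ppm,
                 background_d13C = background_d13C,
                 background_d2H = background_d2H,
                 added_ppm_levels = added_ppm_levels),
            class = "mixing_truth")
}

#' Simulate an isotope sample set on an exact mixing line
#'
#' Each sample adds source CH4 on top of the atmospheric background;
#' measured deltas follow exact conservative two-member mixing,
#' `delta_mix = (C_bg * delta_bg + C_add * delta_src) / C_tot`, for both
#' isotope systems, with optional Gaussian noise on the deltas. The
#' background itself is returned as one sample with `is_background = TRUE`.
#'
#' @param truth A [mixing_truth()].
#' @param noise_sd_delta Gaussian sd (per mil) added to each measured delta.
#' @param seed Optional seed for the noise.
#' @return data.frame: `sample_id`, `ch4_ppm`, `d13C`, `d2H`,
#'   `is_background`.
#' @export
gen_keeling_set <- function(truth, noise_sd_delta = 0, seed = NULL) {
  stopifnot(inherits(truth, "mixing_truth"))
  add <- truth$added_ppm_levels
  tot <- truth$background_ppm + add
  mix <- function(d_bg, d_src)
    (truth$background_ppm * d_bg + add * d_src) / tot
  d13 <- mix(truth$background_d13C, truth$source_d13C)
  d2 <- mix(truth$background_d2H, truth$source_d2H)
  out <- data.frame(
    sample_id = c(paste0("mix", seq_along(add)), "background"),
    ch4_ppm = c(tot, truth$background_ppm),
    d13C = c(d13, truth$background_d13C),
    d2H = c(d2, truth$background_d2H),
    is_background = c(rep(FALSE, length(add)), TRUE),
    stringsAsFactors = FALSE)
  if (noise_sd_delta > 0) {
    draw <- function() matrix(rnorm(2L * nrow(out), 0, noise_sd_delta),
                              ncol = 2L)
    eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    out$d13C <- out$d13C + eps[, 1L]
    out$d2H <- out$d2H + eps[, 2L]
  }
  out
}

#' Simulate a sample x taxon amplicon count table
#'
#' Taxon mean abundances are lognormal; per-sample counts are multinomial
#' draws at a configurable sequencing depth. A configurable fraction of taxa
#' carries curated methanogen/methanotroph names (at reduced abundance, as
#' CH4-cycling guilds are rare in soil); configurable numbers of taxa are
#' enriched in one of two sample groups (specialists), the rest uniform
#' (generalists).
#'
#' @param n_samples Number of samples (split evenly into groups A and B).
#' @param n_taxa Number of taxa (>= 10).
#' @param guild_fraction Fraction of taxa carrying guild names, in \[0, 1\].
#' @param specialist_structure List with `n_specialist_A`, `n_specialist_B`
#'   (taxa enriched in each group) and `enrichment` (abundance fold-change
#'   in the preferred group).
#' @param depth_distribution Function `n -> integer depths`, or a vector of
#'   depths; default draws around 35,000 reads.
#' @param groups Optional explicit group assignment (`"A"`/`"B"`, length
#'   `n_samples`); default alternates samples between the groups.
#' @param seed Optional integer seed.
#' @return List: `counts` (integer matrix samples x taxa), `taxonomy`
#'   (named lineage strings), `metadata` (data.frame `sample`, `group`),
#'   `guild_taxa` (names of planted guild taxa),
#'   `specialist_taxa` (list A/B).
#' @export
gen_count_table <- function(n_samples = 24, n_taxa = 300,
                            guild_fraction = 0.05,
                            specialist_structure = list(
                              n_specialist_A = 10, n_specialist_B = 10,
                              enrichment = 8),
                            depth_distribution = function(n)
                              pmax(1000L, as.integer(round(
                                rnorm(n, 35000, 2500)))),
                            groups = NULL,
                            seed = NULL) {
  if (n_taxa < 10L) stop("n_taxa must be at least 10", call. = FALSE)
  if (guild_fraction < 0 || guild_fraction > 1)
    stop("guild_fraction must be in [0, 1]", call. = FALSE)
  if (!is.null(groups) &&
      (length(groups) != n_samples || !all(groups %in% c("A", "B"))))
    stop("groups must be length n_samples with values 'A'/'B'",
         call. = FALSE)
  gen <- function() {
    taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
    base <- rlnorm(n_taxa, meanlog = 0, sdlog = 1.5)
    n_guild <- floor(guild_fraction * n_taxa)
    guilds <- curated_guilds()
    guild_names <- character(0L)
    taxonomy <- sprintf(
      "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%03d;f__Family%03d;g__Genus%03d",
      seq_len(n_taxa) %% 20L, seq_len(n_taxa) %% 40L, seq_len(n_taxa),
      seq_len(n_taxa), seq_len(n_taxa))
    if (n_guild > 0L) {
      pool <- c(guilds$methanogens, guilds$methanotrophs)
      guild_names <- rep_len(pool, n_guild)
      idx <- seq_len(n_guild)
      taxonomy[idx] <- sprintf(
        "d__Archaea;p__GuildPhylum;c__GuildClass;o__GuildOrder;f__GuildFamily;g__%s",
        guild_names)
      base[idx] <- base[idx] * 0.1  # guilds are rare
    }
    names(taxonomy) <- taxa
    group <- groups %||% rep(c("A", "B"), length.out = n_samples)
    nsA <- specialist_structure$n_specialist_A %||% 0L
    nsB <- specialist_structure$n_specialist_B %||% 0L
    enr <- specialist_structure$enrichment %||% 8
    if (nsA + nsB > n_taxa - n_guild)
      stop("too many specialist taxa for n_taxa", call. = FALSE)
    free <- setdiff(seq_len(n_taxa), seq_len(n_guild))
    specA <- free[seq_len(nsA)]
    specB <- free[nsA + seq_len(nsB)]
    depths <- if (is.function(depth_distribution))
      depth_distribution(n_samples) else
      rep_len(as.integer(depth_distribution), n_samples)
    counts <- matrix(0L, n_samples, n_taxa,
                     dimnames = list(sprintf("sample_%02d",
                                             seq_len(n_samples)), taxa))
    for (i in seq_len(n_samples)) {
      lam <- base
      if (group[i] == "A") lam[specA] <- lam[specA] * enr
      else lam[specB] <- lam[specB] * enr
      counts[i, ] <- as.integer(rmultinom(1L, depths[i], lam / sum(lam)))
    }
    list(counts = counts, taxonomy = taxonomy,
         metadata = data.frame(sample = rownames(counts), group = group,
                               stringsAsFactors = FALSE),
         guild_taxa = taxa[seq_len(n_guild)],
         specialist_taxa = list(A = taxa[specA], B = taxa[specB]))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a qPCR dilution-series standard table
#'
#' `Cq = intercept + slope * log10(copies) + noise` over the dilution
#' levels (default seven decades, 10^0 .. 10^6 copies).
#'
#' @param true_slope,true_intercept Curve parameters (cycles per decade;
#'   cycles at 1 copy).
#' @param noise_sd_cq Gaussian Cq noise sd (cycles).
#' @param levels log10 copies of the dilution levels (>= 3).
#' @param replicates Technical replicates per level.
#' @param seed Optional seed.
#' @return data.frame: `log10_copies`, `replicate`, `cq`.
#' @export
gen_qpcr_standards <- function(true_slope = -3.3219, true_intercept = 38,
                               noise_sd_cq = 0, levels = 0:6,
                               replicates = 3, seed = NULL) {
  if (length(unique(levels)) < 3L)
    stop("a standard curve needs at least 3 dilution levels: degenerate",
         call. = FALSE)
  gen <- function() {
    grid <- expand.grid(log10_copies = levels,
                        replicate = seq_len(replicates))
    grid <- grid[order(grid$log10_copies, grid$replicate), , drop = FALSE]
    grid$cq <- true_intercept + true_slope * grid$log10_copies +
      if (noise_sd_cq > 0) rnorm(nrow(grid), 0, noise_sd_cq) else 0
    rownames(grid) <- NULL
    grid
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
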