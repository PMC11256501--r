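## Full-experiment bundle generator and plain-text I/O. The bundle mirrors
## everything a real incubation campaign hands to the analysis: chamber
## series for every jar x sampling day, a day-30 isotope sample set per
## treatment, count tables for days 0 and 30, and qPCR standard plus
## unknown tables for the four assayed genes. All truths are retained so
## tests can compare recovered quantities with the simulated ones.

## Treatment-level flux truth (ug C-CH4 g dw^-1 h^-1): wet jars emit,
## dry jars consume; warming amplifies emission and suppresses consumption.
.base_flux <- function(site, flooding) {
  wet <- c(FP1 = 0.003, FP2 = 0.002, PFO = 0.001)
  dry <- c(FP1 = -8e-4, FP2 = -1e-3, PFO = -1.5e-3)
  if (flooding == "wet") {
    if (site %in% names(wet)) unname(wet[site]) else 0.002
  } else {
    if (site %in% names(dry)) unname(dry[site]) else -1e-3
  }
}

.temp_factor <- function(temperature, flooding) {
  if (temperature <= 27) 1
  else if (flooding == "wet") 1.6 else 0.4
}

.qpcr_genes <- function() c("16S-archaea", "16S-bacteria", "mcrA", "pmoA")

## log10 copies per g dw, centered on the magnitudes typical of these soils
.qpcr_base_log10 <- function(gene, site) {
  floodplain <- site %in% c("FP1", "FP2")
  switch(gene,
         "16S-archaea" = 8,
         "16S-bacteria" = 10,
         "mcrA" = if (floodplain) 6.5 else 2.5,
         "pmoA" = if (floodplain) 5.5 else 3.5)
}

#' Simulate a complete factorial microcosm experiment
#'
#' Deterministic under the config seed: regenerating with the same config
#' yields an identical bundle. Jars are indexed site x temperature x
#' flooding x replicate; each jar gets one chamber series per sampling day,
#' one day-30 isotope sample set per treatment, count tables on days 0 and
#' 30 only, and qPCR standards/unknowns for the four assayed genes.
#'
#' @param config An [experiment_config()].
#' @return Object of class `experiment_bundle`: list with `config`,
#'   `design` (one row per jar), `chamber` (long readings table),
#'   `isotopes`, `counts` (`day0`, `day30` from [gen_count_table()]),
#'   `qpcr` (`standards`, `unknowns`, `curve_truth`), and `truth`
#'   (`flux` per jar x day, `mixing` per treatment, `qpcr_log10` per
#'   sample).
#' @export
gen_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  withr::with_seed(config$rng_seed, .gen_experiment_impl(config))
}

.gen_experiment_impl <- function(config) {
  design <- expand.grid(replicate = seq_len(config$replicates),
                        flooding = config$flooding,
                        temperature = config$temperatures,
                        site = config$sites,
                        stringsAsFactors = FALSE)
  design <- design[c("site", "temperature", "flooding", "replicate")]
  design$jar_id <- sprintf("%s_T%g_%s_r%d", design$site,
                           design$temperature, design$flooding,
                           design$replicate)
  design$volume_L <- config$jar_volume_L
  design$soil_dry_mass_g <- config$soil_dry_mass_g
  design$pressure_atm <- config$pressure_atm

  ## per-jar baseline multiplier: field sampling points differ
  rep_mult <- exp(rnorm(nrow(design), 0, 0.3))

  flux_truth <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    jar <- design[i, ]
    base <- .base_flux(jar$site, jar$flooding) *
      .temp_factor(jar$temperature, jar$flooding) * rep_mult[i]
    ramp <- if (jar$flooding == "wet") 0.5 + config$days / 30 else
      rep(1, length(config$days))
    data.frame(jar_id = jar$jar_id, day = config$days,
               true_flux = base * ramp, stringsAsFactors = FALSE)
  }))

  chamber <- do.call(rbind, lapply(seq_len(nrow(flux_truth)), function(k) {
    jar <- design[match(flux_truth$jar_id[k], design$jar_id), ]
    truth <- chamber_truth(true_flux = flux_truth$true_flux[k])
    gen_chamber_series(config, truth,
                       jar = c(as.list(jar), list(day = flux_truth$day[k])))
  }))
  rownames(chamber) <- NULL

  ## day-30 isotope sets: one Keeling set per treatment; the source delta
  ## depends on flooding (production under water, oxidation residue when dry)
  treatments <- unique(design[c("site", "temperature", "flooding")])
  mixing_list <- list()
  isotopes <- do.call(rbind, lapply(seq_len(nrow(treatments)), function(i) {
    tr <- treatments[i, ]
    wet <- tr$flooding == "wet"
    truth <- mixing_truth(
      source_d13C = if (wet) -72 else -40,
      source_d2H = if (wet) -230 else 50,
      added_ppm_levels = if (wet) c(1, 2, 4, 8) else c(0.2, 0.4, 0.8, 1.6))
    key <- sprintf("%s_T%g_%s", tr$site, tr$temperature, tr$flooding)
    mixing_list[[key]] <<- truth
    set <- gen_keeling_set(truth, noise_sd_delta = 0.2)
    cbind(tr[rep(1L, nrow(set)), , drop = FALSE], set,
          row.names = NULL)
  }))

  flooding_groups <- ifelse(design$flooding == "wet", "A", "B")
  counts <- lapply(c(day0 = 0, day30 = 30), function(d) {
    tbl <- gen_count_table(n_samples = nrow(design),
                           groups = flooding_groups)
    ids <- paste0(design$jar_id, "_d", d)
    rownames(tbl$counts) <- ids
    tbl$metadata <- cbind(
      data.frame(sample = ids, stringsAsFactors = FALSE),
      design[c("site", "temperature", "flooding", "replicate")],
      data.frame(day = d, group = tbl$metadata$group,
                 stringsAsFactors = FALSE))
    tbl
  })

  genes <- .qpcr_genes()
  curve_truth <- data.frame(
    gene = genes,
    slope = runif(length(genes), -3.5, -3.15),
    intercept = runif(length(genes), 36, 40),
    stringsAsFactors = FALSE)
  standards <- do.call(rbind, lapply(seq_along(genes), function(g) {
    std <- gen_qpcr_standards(true_slope = curve_truth$slope[g],
                              true_intercept = curve_truth$intercept[g],
                              noise_sd_cq = 0.1)
    cbind(gene = genes[g], std, stringsAsFactors = FALSE)
  }))
  soil_eq <- soil_equivalent()
  qpcr_days <- c(0, 30)
  unknown_grid <- expand.grid(jar = design$jar_id, day = qpcr_days,
                              gene = genes, stringsAsFactors = FALSE)
  truth_log10 <- vapply(seq_len(nrow(unknown_grid)), function(i) {
    jar <- design[match(unknown_grid$jar[i], design$jar_id), ]
    g <- unknown_grid$gene[i]
    base <- .qpcr_base_log10(g, jar$site)
    eff <- 0
    if (g %in% c("16S-archaea", "16S-bacteria"))
      eff <- eff - 0.3 * (jar$temperature > 27) * (unknown_grid$day[i] > 0)
    if (g == "mcrA")
      eff <- eff + 0.5 * (jar$temperature > 27) * (unknown_grid$day[i] > 0)
    if (g == "pmoA")
      eff <- eff - 0.3 * (jar$flooding == "wet") * (unknown_grid$day[i] > 0)
    base + eff + rnorm(1L, 0, 0.15)
  }, numeric(1L))
  unknowns <- do.call(rbind, lapply(seq_len(nrow(unknown_grid)), function(i) {
    g <- match(unknown_grid$gene[i], genes)
    cq0 <- curve_truth$intercept[g] + curve_truth$slope[g] *
      (truth_log10[i] + log10(soil_eq))
    data.frame(gene = unknown_grid$gene[i],
               sample_id = paste0(unknown_grid$jar[i], "_d",
                                  unknown_grid$day[i]),
               day = unknown_grid$day[i],
               replicate = 1:3,
               cq = cq0 + rnorm(3L, 0, 0.1),
               stringsAsFactors = FALSE)
  }))
  qpcr_truth <- cbind(unknown_grid,
                      data.frame(log10_copies_per_g_dw = truth_log10))

  structure(list(
    config = config,
    design = design,
    chamber = chamber,
    isotopes = isotopes,
    counts = counts,
    qpcr = list(standards = standards, unknowns = unknowns,
                curve_truth = curve_truth,
                soil_equivalent_g_dw = soil_eq),
    truth = list(flux = flux_truth, mixing = mixing_list,
                 qpcr_log10 = qpcr_truth)),
    class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf(
    "Simulated microcosm experiment: %d jars (%d sites x %d temperatures x %d flooding x %d replicates), %d sampling days\n",
    nrow(x$design), length(x$config$sites), length(x$config$temperatures),
    length(x$config$flooding), x$config$replicates, length(x$config$days)))
  cat(sprintf("  chamber readings: %d; isotope samples: %d; count tables: days 0/30 (%d x %d); qPCR rows: %d\n",
              nrow(x$chamber), nrow(x$isotopes),
              nrow(x$counts$day0$counts), ncol(x$counts$day0$counts),
              nrow(x$qpcr$standards) + nrow(x$qpcr$unknowns)))
  invisible(x)
}

#' Write an experiment bundle to plain-text files
#'
#' Writes the same CSV/TSV schemas the analysis functions read:
#' `design.csv`, `chamber.csv`, `isotopes.csv`, `counts_day0.tsv`,
#' `counts_day30.tsv` (taxa as rows with a taxonomy column), and
#' `qpcr.csv` (standards and unknowns combined, `role` column).
#'
#' @param bundle An [gen_experiment()] bundle.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(design = file.path(dir, "design.csv"),
             chamber = file.path(dir, "chamber.csv"),
             isotopes = file.path(dir, "isotopes.csv"),
             counts_day0 = file.path(dir, "counts_day0.tsv"),
             counts_day30 = file.path(dir, "counts_day30.tsv"),
             qpcr = file.path(dir, "qpcr.csv"))
  write.csv(bundle$design, paths["design"], row.names = FALSE)
  write.csv(bundle$chamber, paths["chamber"], row.names = FALSE)
  write.csv(bundle$isotopes, paths["isotopes"], row.names = FALSE)
  for (d in c("day0", "day30")) {
    tbl <- bundle$counts[[d]]
    out <- data.frame(taxon = colnames(tbl$counts),
                      taxonomy = unname(tbl$taxonomy[colnames(tbl$counts)]),
                      t(tbl$counts), check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(out, paths[paste0("counts_", d)], sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  std <- cbind(gene = bundle$qpcr$standards$gene, role = "standard",
               sample_id = NA_character_,
               bundle$qpcr$standards[c("log10_copies", "cq", "replicate")],
               stringsAsFactors = FALSE)
  unk <- data.frame(gene = bundle$qpcr$unknowns$gene, role = "unknown",
                    sample_id = bundle$qpcr$unknowns$sample_id,
                    log10_copies = NA_real_,
                    cq = bundle$qpcr$unknowns$cq,
                    replicate = bundle$qpcr$unknowns$replicate,
                    stringsAsFactors = FALSE)
  write.csv(rbind(std, unk), paths["qpcr"], row.names = FALSE)
  invisible(paths)
}

#' Read a chamber readings CSV
#' @param path File written by [write_experiment()] (or the same schema).
#' @return Long readings data.frame.
#' @export
read_chamber_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read an isotope sample CSV
#' @param path CSV with columns including `ch4_ppm`, `d13C`, `d2H`,
#'   `is_background`.
#' @return data.frame.
#' @export
read_isotope_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  out$is_background <- as.logical(out$is_background)
  out
}

#' Read a taxa x samples count TSV
#' @param path TSV with `taxon` and `taxonomy` columns followed by one
#'   column per sample.
#' @return List: `counts` (integer matrix, samples x taxa), `taxonomy`
#'   (named character vector).
#' @export
read_counts_tsv <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxonomy <- setNames(raw$taxonomy, raw$taxon)
  mat <- as.matrix(raw[, setdiff(names(raw), c("taxon", "taxonomy")),
                       drop = FALSE])
  rownames(mat) <- raw$taxon
  counts <- t(mat)
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = taxonomy)
}

#' Read a qPCR standards/unknowns CSV
#' @param path CSV with columns `gene`, `role`, `sample_id`,
#'   `log10_copies`, `cq`, `replicate`.
#' @return data.frame.
#' @export
read_qpcr_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
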