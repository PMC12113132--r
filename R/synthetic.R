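# In-silico MS2 spectrum simulator: the inverse of the annotation engine.
#
# Fragment templates place every diagnostic ion and neutral loss of a
# class's rulebook at its theoretical m/z, with rank intensities (tiers
# 100/60/30/10) reflecting the qualitative dominant/prominent language of
# lipid fragmentation descriptions. Simulated spectra add seeded Gaussian
# m/z jitter, multiplicative log-normal intensity noise and uniform noise
# peaks, giving the pipeline a fully testable synthetic dataset.

#' Simulation configuration
#'
#' @param seed Integer seed; identical seed + species give byte-identical
#'   output.
#' @param n_noise_peaks Number of random noise peaks per spectrum.
#' @param noise_rel_intensity_max Noise peak intensity ceiling, as a
#'   fraction of the base (most intense template) peak.
#' @param mz_jitter_sd Gaussian m/z jitter s.d. in Da applied to fragment
#'   and precursor m/z.
#' @param intensity_log_sd S.d. of the log-normal multiplicative intensity
#'   noise on template peaks.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_noise_peaks = 0L,
                              noise_rel_intensity_max = 0.05,
                              mz_jitter_sd = 0, intensity_log_sd = 0.2) {
  stopifnot(n_noise_peaks >= 0, noise_rel_intensity_max >= 0,
            noise_rel_intensity_max < 1, mz_jitter_sd >= 0, intensity_log_sd >= 0)
  structure(list(seed = as.integer(seed),
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_rel_intensity_max = noise_rel_intensity_max,
                 mz_jitter_sd = mz_jitter_sd,
                 intensity_log_sd = intensity_log_sd),
            class = "simulation_config")
}

.tmpl <- function(kind, formula, intensity) {
  data.frame(kind = kind, formula = formula, intensity = intensity,
             stringsAsFactors = FALSE)
}

# carboxylate anion formula string of an acyl chain (c, d, extra O z)
.carboxylate_formula <- function(c, d, z = 0L) {
  format_formula(c(C = as.integer(c), H = as.integer(2 * c - 1 - 2 * d),
                   O = as.integer(2 + z)))
}

#' Fragment template of a lipid species
#'
#' Lists the fragments an MS2 spectrum of the given class/polarity/chain
#' composition is expected to display: each entry is either a fixed-m/z
#' `ion` or a `loss` relative to the precursor ion, with a relative rank
#' intensity (dominant fragments 100, prominent 40-80, minor 10-30).
#' Chain-specific entries (carboxylate anions, chain-release complements,
#' the ceramide ketene loss) are generated from the chain set.
#'
#' @param class_id Lipid class id.
#' @param polarity `"positive"` or `"negative"`.
#' @param chains Chain-set data frame (see [parse_shorthand()]).
#' @return Data frame with columns `mz`, `intensity`, `kind`, `formula`;
#'   `mz` is theoretical (no jitter). Errors for a class/polarity pair
#'   without a defined fragmentation pattern.
#' @export
fragment_template <- function(class_id, polarity, chains) {
  M <- species_formula(class_id, chains)
  prec <- adduct_mz(M, polarity)
  acyl <- chains[chains$linkage == "acyl", , drop = FALSE]
  ether <- chains[chains$linkage == "ether", , drop = FALSE]
  key <- paste(class_id, polarity, sep = "/")
  t <- switch(key,
    "GPI/positive" = rbind(
      .tmpl("loss", "C6H13O9P", 100),
      .tmpl("ion", "C9H20O11P", 60), .tmpl("ion", "C6H14O9P", 60),
      .tmpl("ion", "C9H18O10P", 30), .tmpl("ion", "C6H12O8P", 30),
      .tmpl("loss", "H2O", 30),
      .tmpl("loss", "C9H19O11P", 40), .tmpl("loss", "C6H12O6", 30)),
    "GPI/negative" = rbind(
      .tmpl("ion", "C6H12O9P", 100),
      .tmpl("ion", "C6H10O8P", 40), .tmpl("ion", "C6H8O7P", 20),
      if (nrow(acyl)) rbind(.tmpl("ion", "C9H18O11P", 60),
                            .tmpl("ion", "C9H16O10P", 30)),
      .tmpl("ion", "C3H8O6P", 30), .tmpl("ion", "C3H6O5P", 20)),
    "GPG/positive" = rbind(
      .tmpl("ion", "C6H16O8P", 80), .tmpl("ion", "C3H10O6P", 60),
      .tmpl("ion", "C6H14O7P", 30), .tmpl("ion", "C3H8O5P", 25),
      .tmpl("loss", "H2O", 30),
      .tmpl("loss", "C3H7O5P", 50), .tmpl("loss", "C3H6O2", 40)),
    "GPG/negative" = if (nrow(acyl)) rbind(
      .tmpl("loss", "C6H13O7P", 100),
      .tmpl("ion", "C6H14O8P", 40), .tmpl("ion", "C6H12O7P", 20),
      .tmpl("ion", "C3H8O6P", 30), .tmpl("ion", "C3H6O5P", 20)
    ) else rbind(
      .tmpl("loss", "C3H6O2", 100),
      .tmpl("ion", "C3H8O6P", 60), .tmpl("ion", "C3H6O5P", 30)),
    "GPE/positive" = rbind(
      .tmpl("loss", "C2H8NO4P", 100), .tmpl("loss", "H2O", 40),
      .tmpl("loss", "C2H5N", 30), .tmpl("loss", "C2H7NO", 30),
      .tmpl("loss", "C3H9O6P", 40)),
    "GPE/negative" = rbind(
      .tmpl("loss", "C5H12NO5P", 100),
      .tmpl("ion", "C5H13NO6P", 30), .tmpl("ion", "C5H11NO5P", 15),
      .tmpl("ion", "C2H7NO4P", 25), .tmpl("ion", "C3H6O5P", 15)),
    "GPA/positive" = rbind(
      .tmpl("loss", "H3O4P", 100), .tmpl("loss", "H2O", 60),
      .tmpl("ion", "C3H10O6P", 50)),
    "GPA/negative" = rbind(
      .tmpl("loss", "C3H7O5P", 100),
      .tmpl("ion", "C3H8O6P", 70), .tmpl("ion", "H2O4P", 60),
      .tmpl("ion", "C3H6O5P", 25)),
    "cGPA/negative" = rbind(
      .tmpl("ion", "C3H6O5P", 100), .tmpl("loss", "C3H5O4P", 80)),
    "GPS/positive" = rbind(
      .tmpl("loss", "C3H8NO6P", 100), .tmpl("loss", "C3H7NO3", 60),
      .tmpl("ion", "C6H15NO8P", 50), .tmpl("ion", "C6H13NO7P", 25),
      .tmpl("ion", "C3H8NO3", 40), .tmpl("ion", "C3H6NO2", 20),
      .tmpl("loss", "H2O", 30)),
    "GPS/negative" = rbind(
      .tmpl("loss", "C3H5NO2", 100), .tmpl("loss", "C3H7NO3", 40),
      .tmpl("loss", "C6H12NO7P", 70), .tmpl("ion", "C3H8O6P", 30)),
    "GPC/positive" = rbind(
      .tmpl("ion", "C5H15NO4P", 100), .tmpl("ion", "C5H14NO", 40),
      .tmpl("ion", "C8H21NO6P", 35), .tmpl("ion", "C8H19NO5P", 15),
      .tmpl("loss", "H2O", 30), .tmpl("loss", "C5H14NO4P", 60)),
    "IPC/positive" = rbind(
      .tmpl("loss", "C6H15O10P", 100), .tmpl("loss", "C6H17O11P", 40),
      .tmpl("loss", "H2O", 30)),
    "IPC/negative" = rbind(
      .tmpl("ion", "C6H12O9P", 100), .tmpl("ion", "C6H10O8P", 70),
      .tmpl("loss", "C6H10O5", 50), .tmpl("loss", "C6H12O6", 25)),
    "PG/negative" = rbind(
      .tmpl("loss", "H2O", 100), .tmpl("loss", "H4O2", 70),
      .tmpl("loss", "CH2O3", 60), .tmpl("loss", "CO2", 40),
      .tmpl("loss", "CH4O4", 30)),
    stop("no fragmentation template for ", class_id, " in ", polarity, " mode")
  )
  # chain-specific evidence fragments
  if (polarity == "negative" && class_id %in% names(.BACKBONE) && nrow(acyl)) {
    tiers <- c(50, 35, 25)
    for (i in seq_len(nrow(acyl))) {
      t <- rbind(t, .tmpl("ion",
        .carboxylate_formula(acyl$carbons[i], acyl$db[i], acyl$oxy[i]),
        tiers[min(i, length(tiers))]))
    }
  }
  if (polarity == "negative" && class_id %in% names(.BACKBONE) && nrow(ether) &&
      !nrow(acyl) && class_id == "GPI") {
    # monoalkyl GPI: chain information only via the precursor series
    t <- rbind(t, .tmpl("loss", "C6H12O6", 25))
  }
  if (class_id == "IPC" && polarity == "positive" && nrow(acyl)) {
    ket <- c(C = acyl$carbons[1L],
             H = as.integer(2 * acyl$carbons[1L] - 2 - 2 * acyl$db[1L]), O = 1L)
    comb <- format_formula(formula_add(parse_formula("C6H15O10P"), ket))
    t <- rbind(t, .tmpl("loss", comb, 35))
  }
  mz <- vapply(seq_len(nrow(t)), function(i) {
    if (t$kind[i] == "ion") {
      ion_mz(t$formula[i], if (polarity == "positive") +1L else -1L)
    } else {
      prec - monoisotopic_mass(t$formula[i])
    }
  }, numeric(1))
  out <- data.frame(mz = mz, intensity = t$intensity, kind = t$kind,
                    formula = t$formula, stringsAsFactors = FALSE)
  out <- out[out$mz > 50, , drop = FALSE]
  out[order(out$mz), , drop = FALSE]
}

#' Simulate one MS2 spectrum of a lipid species
#'
#' Places the species' fragment template at theoretical m/z, applies
#' seeded Gaussian m/z jitter and log-normal intensity noise, and adds
#' uniform-random noise peaks below the configured relative intensity.
#' Noise peaks are rejected within 0.1 Da of any template peak or the
#' precursor so that they cannot collide with diagnostic ions.
#'
#' @param name Species shorthand (e.g. `"LPI 18:0"`), parsed with
#'   [parse_shorthand()].
#' @param polarity `"positive"` or `"negative"`.
#' @param config A [simulation_config()].
#' @param feature_id Feature id for the resulting spectrum.
#' @param rt Retention time in minutes.
#' @param rng_offset Integer added to the seed so that each spectrum of a
#'   dataset draws an independent, reproducible stream.
#' @return An [ms2_spectrum].
#' @export
simulate_spectrum <- function(name, polarity, config = simulation_config(),
                              feature_id = name, rt = 0, rng_offset = 0L) {
  ps <- parse_shorthand(name)
  tmpl <- fragment_template(ps$class_id, polarity, ps$chains)
  M <- species_formula(ps$class_id, ps$chains)
  prec <- adduct_mz(M, polarity)
  set.seed(config$seed + as.integer(rng_offset))
  mz <- tmpl$mz
  inten <- tmpl$intensity
  if (config$mz_jitter_sd > 0) {
    mz <- mz + stats::rnorm(length(mz), 0, config$mz_jitter_sd)
    prec_obs <- prec + stats::rnorm(1L, 0, config$mz_jitter_sd)
  } else {
    prec_obs <- prec
  }
  if (config$intensity_log_sd > 0) {
    inten <- inten * exp(stats::rnorm(length(inten), 0, config$intensity_log_sd))
  }
  if (config$n_noise_peaks > 0L) {
    base <- max(inten)
    lo <- 60; hi <- prec + 20
    nmz <- numeric(0)
    guard <- 0L
    while (length(nmz) < config$n_noise_peaks && guard < 1000L) {
      cand <- stats::runif(1L, lo, hi)
      if (all(abs(cand - c(tmpl$mz, prec)) > 0.1)) nmz <- c(nmz, cand)
      guard <- guard + 1L
    }
    ninten <- stats::runif(length(nmz), 0, config$noise_rel_intensity_max * base)
    mz <- c(mz, nmz); inten <- c(inten, ninten)
  }
  ms2_spectrum(feature_id, prec_obs, polarity, rt, mz, inten)
}

#' Synthetic regeneration of the reference dataset
#'
#' Builds MS2 spectra for every reference species in every polarity in
#' which it was detected (68 spectra over 55 species), plus the matching
#' feature quantification table with three-extract abundance profiles.
#'
#' @param config A [simulation_config()].
#' @param species Species table; defaults to [reference_species()]. A
#'   subset (e.g. only the ceramide phosphoinositols) can be passed.
#' @return List with `spectra` (list of [ms2_spectrum]) and `features`
#'   (data frame in the [read_feature_table()] layout, samples `hexane`,
#'   `CHCl3`, `MeOH`).
#' @export
reference_fixture <- function(config = simulation_config(),
                              species = reference_species()) {
  spectra <- list(); rows <- list()
  fid <- 0L
  for (i in seq_len(nrow(species))) {
    for (pol in c("positive", "negative")) {
      printed <- if (pol == "positive") species$mz_pos[i] else species$mz_neg[i]
      if (is.na(printed)) next
      fid <- fid + 1L
      id <- sprintf("F%03d", fid)
      s <- simulate_spectrum(species$name[i], pol, config, feature_id = id,
                             rt = species$rt[i], rng_offset = fid)
      spectra[[fid]] <- s
      rows[[fid]] <- data.frame(
        feature_id = id, precursor_mz = s$precursor_mz, rt = species$rt[i],
        hexane = species$hexane[i] * species$total_area[i],
        CHCl3 = species$CHCl3[i] * species$total_area[i],
        MeOH = species$MeOH[i] * species$total_area[i],
        name = species$name[i], stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  truth <- features$name
  features$name <- NULL
  attr(features, "samples") <- c("hexane", "CHCl3", "MeOH")
  attr(features, "true_species") <- truth
  list(spectra = spectra, features = features)
}

#' Write a simulated dataset to MGF and CSV files
#'
#' @param dir Output directory (created if absent).
#' @param config A [simulation_config()].
#' @param species Species table (defaults to the full reference set).
#' @param basename File basename; writes `<basename>.mgf` and
#'   `<basename>_quant.csv`.
#' @return Named character vector with elements `mgf` and `csv`.
#' @export
simulate_dataset <- function(dir, config = simulation_config(),
                             species = reference_species(),
                             basename = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- reference_fixture(config, species)
  mgf <- file.path(dir, paste0(basename, ".mgf"))
  csv <- file.path(dir, paste0(basename, "_quant.csv"))
  write_mgf(fx$spectra, mgf)
  write_feature_table(fx$features, csv)
  c(mgf = mgf, csv = csv)
}
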