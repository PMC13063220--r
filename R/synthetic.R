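# Seeded forward simulator of AGC-regulated Orbitrap acquisitions: Poisson
# ion statistics, electrospray suppression, linear drift, space-charge ratio
# bias, in-window contaminants. The test bed standing in for instrument data.

#' Define a simulated species
#'
#' @param label Species label.
#' @param ion_flux Ions per second reaching the trap at unit concentration
#'   (1 uM), before suppression.
#' @param concentration Concentration in uM.
#' @param true_ratio True heavy/light isotopologue ratio in (0, 1); `0` is
#'   allowed for single-peak contaminants.
#' @param mz_light,mz_heavy m/z of the light and heavy isotopologue peaks
#'   (`mz_heavy` ignored when `true_ratio = 0`).
#' @param role `"analyte"` or `"contaminant"` (annotation only; both ionize,
#'   suppress, and consume AGC charge).
#' @return List of class `"orbiso_species"`.
#' @export
species_spec <- function(label, ion_flux, concentration, true_ratio,
                         mz_light, mz_heavy = mz_light + 1.003355,
                         role = c("analyte", "contaminant")) {
  role <- match.arg(role)
  if (ion_flux < 0) stop("ion_flux must be >= 0")
  if (true_ratio < 0 || true_ratio >= 1) stop("true_ratio must be in [0, 1)")
  structure(list(label = label, ion_flux = ion_flux,
                 concentration = concentration, true_ratio = true_ratio,
                 mz_light = mz_light, mz_heavy = mz_heavy, role = role),
            class = "orbiso_species")
}

#' Simulator configuration
#'
#' The generative model per scan at sequence time `t` (minutes):
#' effective flux `F_i = ion_flux_i * conc_i * exp(-suppression_coefficient *
#' total_conc)`; injection time `IT = clamp(agc_target / sum(F_i), it_floor,
#' it_ceiling)` (the AGC feedback, with its hardware floor and ceiling);
#' per-species ions `~ Poisson(F_i * IT * mu)` split heavy/light by a
#' binomial with `p = R(t) / (1 + R(t))` where
#' `R(t) = true_ratio * (1 + drift_rate * t) * (1 - space_charge_beta *
#' max(0, Q/agc_target - 1))` and `Q = sum(F_i) * IT` is the accumulated
#' charge per fill (exceeds the target only when the flux is so high that the
#' injection-time floor binds). `spray_noise_cv > 0` adds lognormal scan-to-
#' scan fluctuation of the total electrospray flux; AGC feedback absorbs it
#' while the injection time is between its bounds, but at the ceiling the
#' fluctuations pass straight into the ion counts, and at the floor they
#' modulate the excess charge and hence the space-charge bias per scan — the
#' two mechanisms that degrade precision at the extremes of the
#' concentration range. `variance_inflation > 1` adds lognormal
#' scan-to-scan ratio noise sized so the per-scan ratio variance is inflated
#' by that factor over the shot-noise expectation. Intensities are
#' back-computed by inverting the ion-count model at the configured noise
#' floor; `TIC` is the per-fill current, so `TIC x IT = agc_target` under
#' stable AGC control.
#'
#' @param species List of [species_spec()] objects.
#' @param agc_target AGC target in charges (default 1e6).
#' @param it_ceiling_ms,it_floor_ms Injection-time ceiling/floor in ms
#'   (defaults 100 and 0.1).
#' @param microscans,resolution,reference_resolution Acquisition settings
#'   (defaults 2, 60000, 240000).
#' @param empirical_constant Ion-count constant used to invert the model
#'   (default 3).
#' @param noise_floor Baseline noise in intensity units (default 1000).
#' @param suppression_coefficient Electrospray suppression rate per uM of
#'   total solute (default 0.05; 0 disables).
#' @param drift_rate Relative ratio drift per minute (default 0).
#' @param space_charge_beta Relative ratio bias per unit of excess charge
#'   load (default 0).
#' @param spray_noise_cv Coefficient of variation of scan-to-scan total-flux
#'   fluctuation (default 0: Poisson-only statistics).
#' @param variance_inflation Ratio-variance inflation factor >= 1 (default 1).
#' @param n_scans Scans per acquisition (default 600).
#' @param scan_period_s Seconds between scans (default 1).
#' @param seed Mandatory RNG seed.
#' @return List of class `"orbiso_sim_config"`.
#' @export
sim_config <- function(species, agc_target = 1e6, it_ceiling_ms = 100,
                       it_floor_ms = 0.1, microscans = 2, resolution = 60000,
                       reference_resolution = 240000, empirical_constant = 3,
                       noise_floor = 1000, suppression_coefficient = 0.05,
                       drift_rate = 0, space_charge_beta = 0,
                       spray_noise_cv = 0, variance_inflation = 1,
                       n_scans = 600, scan_period_s = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory for reproducibility")
  if (inherits(species, "orbiso_species")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "orbiso_species")),
            variance_inflation >= 1, it_floor_ms > 0,
            it_floor_ms < it_ceiling_ms, n_scans >= 1)
  vals <- c(agc_target, microscans, resolution, reference_resolution,
            noise_floor, suppression_coefficient, drift_rate,
            space_charge_beta, spray_noise_cv, scan_period_s)
  if (any(!is.finite(vals))) stop("all configuration rates must be finite")
  if (spray_noise_cv < 0) stop("spray_noise_cv must be >= 0")
  structure(list(species = species, agc_target = agc_target,
                 it_ceiling_ms = it_ceiling_ms, it_floor_ms = it_floor_ms,
                 microscans = microscans, resolution = resolution,
                 reference_resolution = reference_resolution,
                 empirical_constant = empirical_constant,
                 noise_floor = noise_floor,
                 suppression_coefficient = suppression_coefficient,
                 drift_rate = drift_rate,
                 space_charge_beta = space_charge_beta,
                 spray_noise_cv = spray_noise_cv,
                 variance_inflation = variance_inflation,
                 n_scans = n_scans, scan_period_s = scan_period_s,
                 seed = as.integer(seed)),
            class = "orbiso_sim_config")
}

# Deterministic AGC solution shared by the simulator and its tests.
.sim_it_ms <- function(config) {
  flux <- .sim_fluxes(config)
  total <- sum(flux)
  if (total <= 0) stop("total ion flux is zero: empty scan")
  min(max(1000 * config$agc_target / total, config$it_floor_ms),
      config$it_ceiling_ms)
}

.sim_fluxes <- function(config) {
  total_conc <- sum(vapply(config$species, function(s) s$concentration,
                           numeric(1)))
  vapply(config$species, function(s) {
    s$ion_flux * s$concentration *
      exp(-config$suppression_coefficient * total_conc)
  }, numeric(1))
}

#' Simulate one acquisition
#'
#' @param config An [sim_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @param t_offset_min Start time of this acquisition on the sequence clock,
#'   minutes (drives drift across a bracketed sequence).
#' @param source_id,role,block_index Stored on the resulting acquisition.
#' @return An `orbiso_acquisition` with attribute `truth` recording the
#'   latent parameters (fluxes, injection time, per-scan true ratio of the
#'   first analyte, accumulated charge).
#' @export
simulate_acquisition <- function(config, seed = config$seed,
                                 t_offset_min = 0, source_id = "sim",
                                 role = NA_character_,
                                 block_index = NA_integer_) {
  stopifnot(inherits(config, "orbiso_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ns <- config$n_scans
  t_min <- t_offset_min + (seq_len(ns) - 1) * config$scan_period_s / 60
  flux <- .sim_fluxes(config)
  total_flux <- sum(flux)
  if (total_flux <= 0) stop("total ion flux is zero: empty scan")
  # scan-to-scan electrospray fluctuation of the total flux (lognormal,
  # mean 1); AGC absorbs it only while IT sits between its bounds
  mult <- if (config$spray_noise_cv > 0) {
    sig2 <- log(1 + config$spray_noise_cv^2)
    exp(stats::rnorm(ns, -sig2 / 2, sqrt(sig2)))
  } else rep(1, ns)
  it_ms <- pmin(pmax(1000 * config$agc_target / (total_flux * mult),
                     config$it_floor_ms), config$it_ceiling_ms)
  it_s <- it_ms / 1000
  q_fill <- total_flux * mult * it_s
  excess <- pmax(0, q_fill / config$agc_target - 1)
  sc_factor <- 1 - config$space_charge_beta * excess
  mu <- config$microscans
  inv_factor <- config$empirical_constant *
    sqrt(config$reference_resolution / config$resolution) * mu
  meta <- data.frame(scan_index = seq_len(ns), rt_min = t_min - t_offset_min,
                     it_ms = it_ms,
                     tic = (q_fill / it_ms),  # per-fill current: TIC*IT = Q
                     microscans = mu, resolution = config$resolution,
                     agc_target = config$agc_target)
  peaks <- vector("list", length(config$species))
  truth_ratio <- NULL
  for (k in seq_along(config$species)) {
    sp <- config$species[[k]]
    lam <- flux[k] * mult * it_s * mu
    n_ions <- stats::rpois(ns, lam)
    r_t <- sp$true_ratio * (1 + config$drift_rate * t_min) * sc_factor
    if (config$variance_inflation > 1 && sp$true_ratio > 0 && all(lam > 0)) {
      lam_h <- lam * sp$true_ratio / (1 + sp$true_ratio)
      lam_l <- lam - lam_h
      sig2 <- (config$variance_inflation - 1) * (1 / lam_h + 1 / lam_l)
      r_t <- r_t * exp(stats::rnorm(ns, -sig2 / 2, sqrt(sig2)))
    }
    if (sp$true_ratio > 0) {
      heavy <- stats::rbinom(ns, n_ions, r_t / (1 + r_t))
    } else {
      heavy <- rep(0L, ns)
    }
    light <- n_ions - heavy
    if (is.null(truth_ratio) && sp$role == "analyte") {
      truth_ratio <- sp$true_ratio * (1 + config$drift_rate * t_min) * sc_factor
    }
    to_intensity <- function(ions) ions * config$noise_floor / inv_factor
    pl <- data.frame(scan_index = seq_len(ns), mz = sp$mz_light,
                     intensity = to_intensity(light),
                     noise = config$noise_floor)
    ph <- if (sp$true_ratio > 0) {
      data.frame(scan_index = seq_len(ns), mz = sp$mz_heavy,
                 intensity = to_intensity(heavy),
                 noise = config$noise_floor)
    }
    pk <- rbind(pl, ph)
    peaks[[k]] <- pk[pk$intensity > 0, , drop = FALSE]
  }
  acq <- acquisition(meta, do.call(rbind, peaks), source_id = source_id,
                     role = role, block_index = block_index,
                     t0 = t_offset_min)
  attr(acq, "truth") <- list(fluxes = flux, it_ms = it_ms,
                             charge_per_fill = q_fill,
                             excess_load = excess,
                             space_charge_factor = sc_factor,
                             true_ratio_per_scan = truth_ratio, seed = seed)
  acq
}

#' Simulate a single scan
#'
#' One-scan convenience wrapper around [simulate_acquisition()].
#'
#' @param config An [sim_config()].
#' @param t_min Sequence time of the scan, minutes.
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `meta` (one-row data.frame) and `peaks`.
#' @export
simulate_scan <- function(config, t_min = 0, seed = config$seed) {
  cfg <- config
  cfg$n_scans <- 1L
  acq <- simulate_acquisition(cfg, seed = seed, t_offset_min = t_min)
  list(meta = acq$meta, peaks = acq$peaks, truth = attr(acq, "truth"))
}

#' Simulate a bracketed standard/sample sequence
#'
#' Writes the canonical alternating design: standards at odd block positions,
#' samples at even positions (default seven blocks), contiguous in time so
#' drift runs across the whole sequence. For zero-enrichment the sample
#' config is the standard config and the true delta is 0 per mil.
#'
#' @param config Standard-block [sim_config()].
#' @param sample_config Sample-block config (default: `config`, i.e.
#'   zero-enrichment).
#' @param n_blocks Number of blocks (default 7).
#' @param seed Base seed (defaults to `config$seed`); block `k` uses
#'   `seed + k`.
#' @return List of class `"orbiso_sim_sequence"`: `acquisitions` (list of
#'   `orbiso_acquisition` with roles/blocks/t0 set), `truth` (true delta in
#'   per mil, drift rate, per-block latent records).
#' @export
simulate_sequence <- function(config, sample_config = config, n_blocks = 7,
                              seed = config$seed) {
  stopifnot(inherits(config, "orbiso_sim_config"),
            inherits(sample_config, "orbiso_sim_config"), n_blocks >= 3)
  block_min <- config$n_scans * config$scan_period_s / 60
  acqs <- vector("list", n_blocks)
  for (k in seq_len(n_blocks)) {
    std <- k %% 2 == 1
    cfg <- if (std) config else sample_config
    acqs[[k]] <- simulate_acquisition(
      cfg, seed = (seed + k) %% .Machine$integer.max,
      t_offset_min = (k - 1) * block_min,
      source_id = sprintf("block%02d_%s", k, if (std) "standard" else "sample"),
      role = if (std) "standard" else "sample", block_index = k)
  }
  r_std <- .first_analyte_ratio(config)
  r_smp <- .first_analyte_ratio(sample_config)
  structure(list(acquisitions = acqs,
                 truth = list(true_delta_permil = (r_smp / r_std - 1) * 1000,
                              drift_rate = config$drift_rate,
                              block_minutes = block_min,
                              blocks = lapply(acqs, attr, "truth"))),
            class = "orbiso_sim_sequence")
}

.first_analyte_ratio <- function(config) {
  for (s in config$species) if (s$role == "analyte") return(s$true_ratio)
  stop("config has no analyte species")
}

#' Named simulator presets
#'
#' Scenario fixtures: `zero_enrichment` (pure standard, Poisson only),
#' `suppressed_mix` (analyte in a heavily suppressing matrix),
#' `low_signal_ceiling` (flux so low the injection time pins at the ceiling),
#' `contaminant` (an undeclared in-window ion at ~12% of the analyte signal),
#' `space_charge` (flux so high the injection-time floor binds, biasing the
#' ratio), and `drift` (1e-3/min linear ratio drift). Analyte geometry mimics
#' a deprotonated C11 naphthenic acid (m/z 175.076 / 176.080, 13R about
#' 0.121).
#'
#' @param name Preset name; omit to list available names.
#' @param seed Seed stored in the returned config (default 1).
#' @param n_scans,scan_period_s Optional overrides of acquisition length.
#' @return An `orbiso_sim_config`, or a character vector of names.
#' @export
sim_preset <- function(name = NULL, seed = 1, n_scans = 600,
                       scan_period_s = 1) {
  thn <- function(conc, flux = 3.125e8) {
    species_spec("THN-like", ion_flux = flux, concentration = conc,
                 true_ratio = 0.1214, mz_light = 175.0765,
                 mz_heavy = 176.0798)
  }
  presets <- list(
    zero_enrichment = function() sim_config(
      list(thn(5)), suppression_coefficient = 0, seed = seed,
      n_scans = n_scans, scan_period_s = scan_period_s),
    suppressed_mix = function() sim_config(
      list(thn(5),
           species_spec("matrix", ion_flux = 3.125e8, concentration = 60,
                        true_ratio = 0.05, mz_light = 141.055,
                        role = "contaminant")),
      suppression_coefficient = 0.05, seed = seed, n_scans = n_scans,
      scan_period_s = scan_period_s),
    low_signal_ceiling = function() sim_config(
      list(thn(0.02)), suppression_coefficient = 0.05, seed = seed,
      n_scans = n_scans, scan_period_s = scan_period_s),
    contaminant = function() sim_config(
      list(thn(5),
           species_spec("fragment-177", ion_flux = 3.125e8 * 0.12,
                        concentration = 5, true_ratio = 0,
                        mz_light = 177.0710, role = "contaminant")),
      suppression_coefficient = 0, seed = seed, n_scans = n_scans,
      scan_period_s = scan_period_s),
    space_charge = function() sim_config(
      list(thn(50)), suppression_coefficient = 0, space_charge_beta = 0.01,
      spray_noise_cv = 0.1, seed = seed, n_scans = n_scans,
      scan_period_s = scan_period_s),
    drift = function() sim_config(
      list(thn(5)), suppression_coefficient = 0, drift_rate = 1e-3,
      seed = seed, n_scans = n_scans, scan_period_s = scan_period_s)
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]()
}
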