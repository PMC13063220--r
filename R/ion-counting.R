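# Ion-count core: S/N -> theoretical ion counts with resolution correction,
# per-scan and count-weighted aggregate 13R, robust outlier rejection,
# acquisition error and shot-noise diagnostics.

#' Ion-count model parameters
#'
#' The theoretical ion count of an isotopologue peak is
#' `(S/N) * c * sqrt(Rn / r) * mu`, where `S` is centroid signal intensity,
#' `N` the baseline noise, `r` the resolution setting of the measurement,
#' `mu` the number of microscans, and `sqrt(Rn/r)` corrects ion statistics to
#' a reference resolution `Rn` of 240,000 at which the empirical constant
#' `c = 3` was determined (`c = 4.4` is selectable for small organic acids;
#' `c` cancels in every isotope ratio, so the choice does not affect delta
#' values).
#'
#' @param reference_resolution Reference resolution `Rn` (default 240000).
#' @param empirical_constant Empirical constant `c` (default 3; 4.4
#'   selectable).
#' @return A list of class `"orbiso_params"`.
#' @export
ion_count_params <- function(reference_resolution = 240000,
                             empirical_constant = 3) {
  if (reference_resolution <= 0) stop("reference_resolution must be > 0")
  if (empirical_constant <= 0) stop("empirical_constant must be > 0")
  structure(list(reference_resolution = reference_resolution,
                 empirical_constant = empirical_constant),
            class = "orbiso_params")
}

#' Theoretical ion count from signal-to-noise
#'
#' @param s Signal intensity (vectorized).
#' @param n Baseline noise, same units as `s`; must be > 0.
#' @param resolution Resolution setting `r` of the measurement.
#' @param microscans Number of microscans `mu`.
#' @param params An [ion_count_params()] object.
#' @return Dimensionless theoretical ion count(s).
#' @examples
#' ion_count(100 * 20, 20, resolution = 60000, microscans = 2) # 1200
#' @export
ion_count <- function(s, n, resolution, microscans = 1,
                      params = ion_count_params()) {
  if (any(resolution <= 0)) stop("resolution must be > 0")
  if (any(n <= 0)) stop("noise must be > 0")
  (s / n) * params$empirical_constant *
    sqrt(params$reference_resolution / resolution) * microscans
}

#' Match a target's peak in every scan
#'
#' For each scan the peak nearest the target's theoretical m/z within the
#' match tolerance is selected; absence is a value (`NA` row), not an error.
#'
#' @param acq An `orbiso_acquisition`.
#' @param target An `orbiso_target`.
#' @return data.frame with one row per scan: `scan_index`, `mz`, `intensity`,
#'   `noise` (`NA` where no peak fell inside the tolerance).
#' @export
match_peaks <- function(acq, target) {
  stopifnot(inherits(acq, "orbiso_acquisition"),
            inherits(target, "orbiso_target"))
  tol <- target_tolerance_da(target)
  pk <- acq$peaks
  dev <- abs(pk$mz - target$theoretical_mz)
  cand <- pk[dev <= tol, , drop = FALSE]
  cdev <- dev[dev <= tol]
  out <- data.frame(scan_index = acq$meta$scan_index,
                    mz = NA_real_, intensity = NA_real_, noise = NA_real_)
  if (nrow(cand)) {
    ord <- order(cand$scan_index, cdev)
    cand <- cand[ord, , drop = FALSE]
    best <- cand[!duplicated(cand$scan_index), , drop = FALSE]
    i <- match(best$scan_index, out$scan_index)
    out$mz[i] <- best$mz
    out$intensity[i] <- best$intensity
    out$noise[i] <- best$noise
  }
  out
}

#' Match a target within a single scan's peak list
#'
#' @param peaks data.frame with columns `mz`, `intensity`, `noise`.
#' @param target An `orbiso_target`.
#' @return One-row data.frame, or `NULL` if no peak lies within tolerance.
#' @export
match_peak <- function(peaks, target) {
  tol <- target_tolerance_da(target)
  dev <- abs(peaks$mz - target$theoretical_mz)
  ok <- which(dev <= tol)
  if (!length(ok)) return(NULL)
  peaks[ok[which.min(dev[ok])], c("mz", "intensity", "noise"), drop = FALSE]
}

#' Per-scan ion counts and isotope ratios for a light/heavy target pair
#'
#' Computes, for every scan, the matched signal-to-noise and theoretical ion
#' count of each isotopologue and the per-scan ratio
#' `13R = (S13/N13) / (S12/N12)`, which equals the ion-count ratio exactly
#' because the constant, resolution and microscan factors cancel. Scans where
#' either isotopologue is unmatched are masked `no_match`; scans at the
#' injection-time ceiling are flagged (`it_ceiling`) and optionally dropped.
#'
#' @param acq An `orbiso_acquisition`.
#' @param light,heavy `orbiso_target`s for the 12C and one-13C species (or a
#'   list with `$light`/`$heavy` passed as `light`).
#' @param params [ion_count_params()].
#' @param it_ceiling_ms Injection-time ceiling in ms (default 100); scans with
#'   `it_ms >= it_ceiling_ms - 0.1` are flagged.
#' @param drop_it_ceiling If `TRUE`, flagged scans are masked out of ratio
#'   work (default `FALSE`: diagnose, do not silently remove).
#' @return data.frame of class `"orbiso_series"`, one row per scan, with
#'   columns `scan_index`, `rt_min`, `sn_light`, `sn_heavy`, `count_light`,
#'   `count_heavy`, `ratio`, `at_it_ceiling`, `filtered_reason`
#'   (`"none"|"no_match"|"outlier"|"it_ceiling"|"user"`).
#' @export
ion_count_series <- function(acq, light, heavy = NULL,
                             params = ion_count_params(),
                             it_ceiling_ms = 100,
                             drop_it_ceiling = FALSE) {
  if (is.list(light) && !inherits(light, "orbiso_target") &&
      !is.null(light$light)) {
    heavy <- light$heavy
    light <- light$light
  }
  ml <- match_peaks(acq, light)
  mh <- match_peaks(acq, heavy)
  meta <- acq$meta
  sn_l <- ml$intensity / ml$noise
  sn_h <- mh$intensity / mh$noise
  # same model as ion_count(), written NA-tolerant for unmatched scans
  fac <- params$empirical_constant *
    sqrt(params$reference_resolution / meta$resolution) * meta$microscans
  cl <- sn_l * fac
  ch <- sn_h * fac
  ratio <- sn_h / sn_l
  at_ceiling <- meta$it_ms >= it_ceiling_ms - 0.1
  reason <- rep("none", nrow(meta))
  reason[is.na(ratio) | !is.finite(ratio) | (!is.na(sn_l) & sn_l == 0)] <- "no_match"
  if (drop_it_ceiling) reason[reason == "none" & at_ceiling] <- "it_ceiling"
  out <- data.frame(scan_index = meta$scan_index, rt_min = meta$rt_min,
                    sn_light = sn_l, sn_heavy = sn_h,
                    count_light = cl, count_heavy = ch,
                    ratio = ratio, at_it_ceiling = at_ceiling,
                    filtered_reason = reason)
  attr(out, "params") <- params
  attr(out, "labels") <- c(light = light$label, heavy = heavy$label)
  class(out) <- c("orbiso_series", "data.frame")
  out
}

#' Per-scan isotope ratio from matched signal-to-noise
#'
#' `13R = (S13/N13) / (S12/N12)`; identical to the ion-count ratio since all
#' model constants cancel.
#'
#' @param sn_heavy,sn_light Signal-to-noise of heavy and light isotopologue.
#' @return The per-scan ratio (NA where the light S/N is 0 or missing).
#' @export
scan_ratio <- function(sn_heavy, sn_light) {
  r <- sn_heavy / sn_light
  r[!is.finite(r)] <- NA_real_
  r
}

#' Robust outlier rejection on the per-scan ratio series
#'
#' Single-pass median/MAD rule: retained scans whose ratio falls outside
#' `median +/- k * 1.4826 * MAD` are masked `outlier`. With `k = Inf` this is
#' the identity. When the MAD is exactly 0 but values diverge, the rule
#' degenerates; the fallback retains only scans exactly equal to the median
#' and warns.
#'
#' @param series An `orbiso_series`.
#' @param k Rejection multiplier (default 5).
#' @return The series with outlier scans masked.
#' @export
reject_outliers <- function(series, k = 5) {
  stopifnot(inherits(series, "orbiso_series"))
  use <- series$filtered_reason == "none"
  if (sum(use) < 5) stop("outlier rejection needs >= 5 usable scans")
  if (!is.finite(k)) return(series)
  r <- series$ratio[use]
  med <- stats::median(r)
  mad <- stats::median(abs(r - med))
  if (mad == 0) {
    if (any(r != med)) {
      warning("MAD is 0 with divergent ratios; retaining exact-median scans only")
      bad <- use & series$ratio != med
      series$filtered_reason[bad] <- "outlier"
    }
    return(series)
  }
  lim <- k * 1.4826 * mad
  bad <- use & abs(series$ratio - med) > lim
  series$filtered_reason[bad] <- "outlier"
  series
}

#' Aggregate ratio, acquisition error and shot-noise diagnostics
#'
#' The primary aggregate `13R` is the ratio of summed ion counts over retained
#' scans (count-weighted — the minimum-variance choice for Poisson counts);
#' the unweighted mean of per-scan ratios is reported alongside. The
#' acquisition error is the relative standard error of the per-scan ratio
#' series, `1000 * sd(R)/(mean(R) * sqrt(n))`, in per mil. The shot-noise
#' limit is the counting-statistics floor
#' `1000 * sqrt(1/sum(N13) + 1/sum(N12))` per mil, and `shot_noise_ratio =
#' acquisition_error / shot_noise_limit` is ~1 for pure Poisson data.
#'
#' @param series An `orbiso_series`.
#' @return List of class `"orbiso_ratio_summary"`: `ratio` (count-weighted),
#'   `ratio_scan_mean`, `n_scans_used`, `acquisition_error_permil`,
#'   `shot_noise_limit_permil`, `shot_noise_ratio`, `total_count_light`,
#'   `total_count_heavy`.
#' @export
aggregate_ratio <- function(series) {
  stopifnot(inherits(series, "orbiso_series"))
  use <- series$filtered_reason == "none"
  n <- sum(use)
  if (n < 2) stop("aggregate ratio needs >= 2 usable scans")
  tot_l <- sum(series$count_light[use])
  tot_h <- sum(series$count_heavy[use])
  r <- series$ratio[use]
  acq_err <- 1000 * stats::sd(r) / (mean(r) * sqrt(n))
  snl <- shot_noise_limit(tot_h, tot_l)
  structure(list(ratio = tot_h / tot_l,
                 ratio_scan_mean = mean(r),
                 n_scans_used = n,
                 acquisition_error_permil = acq_err,
                 shot_noise_limit_permil = snl,
                 shot_noise_ratio = acq_err / snl,
                 total_count_light = tot_l,
                 total_count_heavy = tot_h),
            class = "orbiso_ratio_summary")
}

#' @export
print.orbiso_ratio_summary <- function(x, ...) {
  cat(sprintf(paste0("<orbiso_ratio_summary> 13R = %.6g (scan-mean %.6g), ",
                     "n = %d\n  acquisition error %.3f permil, shot-noise limit ",
                     "%.3f permil (ratio %.2f)\n  total counts: light %.4g, ",
                     "heavy %.4g\n"),
              x$ratio, x$ratio_scan_mean, x$n_scans_used,
              x$acquisition_error_permil, x$shot_noise_limit_permil,
              x$shot_noise_ratio, x$total_count_light, x$total_count_heavy))
  invisible(x)
}

#' Theoretical shot-noise limit of a two-isotopologue ratio
#'
#' Minimum achievable relative error (per mil) of a ratio of two
#' Poisson-counted ion populations: `1000 * sqrt(1/N_heavy + 1/N_light)`.
#'
#' @param total_heavy,total_light Total theoretical ion counts accumulated
#'   over retained scans.
#' @return Shot-noise limit in per mil.
#' @examples
#' shot_noise_limit(1e4, 1e6) # 10.05
#' @export
shot_noise_limit <- function(total_heavy, total_light) {
  if (any(total_heavy <= 0) || any(total_light <= 0)) {
    stop("shot-noise limit requires positive total counts for both isotopologues")
  }
  1000 * sqrt(1 / total_heavy + 1 / total_light)
}

#' Full single-acquisition processing convenience wrapper
#'
#' Cull to the time window, build the ion-count series, reject outliers, and
#' aggregate.
#'
#' @inheritParams ion_count_series
#' @param pair Target pair from [target_pair()] (or list with
#'   `$light`/`$heavy`).
#' @param window Length-2 retention-time window in minutes (default
#'   `c(2, 8)`); `NULL` to skip culling.
#' @param k_outlier Outlier multiplier; `Inf` disables rejection.
#' @return List with `series` (`orbiso_series`) and `summary`
#'   (`orbiso_ratio_summary`).
#' @export
process_acquisition <- function(acq, pair, params = ion_count_params(),
                                window = c(2, 8), k_outlier = 5,
                                it_ceiling_ms = 100,
                                drop_it_ceiling = FALSE) {
  if (!is.null(window)) acq <- cull_time_window(acq, window[1], window[2])
  ser <- ion_count_series(acq, pair, params = params,
                          it_ceiling_ms = it_ceiling_ms,
                          drop_it_ceiling = drop_it_ceiling)
  if (is.finite(k_outlier) && sum(ser$filtered_reason == "none") >= 5) {
    ser <- reject_outliers(ser, k = k_outlier)
  }
  list(series = ser, summary = aggregate_ratio(ser))
}
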