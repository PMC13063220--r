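# Acquisition-health diagnostics: AGC regulation, selected-ion current,
# suppression indices, in-window contaminant detection.

#' Classify the AGC regulation regime of each scan
#'
#' The product `TIC x IT` approximates the total ion load delivered to the
#' C-trap per fill and is a direct diagnostic of automatic gain control:
#' under stable regulation it sits near the AGC target. Scans whose load
#' falls below `low` times the target — or whose injection time has hit the
#' ceiling, which removes the feedback loop — are `sub_target`; loads above
#' `high` times the target are `over_target`; the rest are `controlled`.
#'
#' @param tic Total ion current per scan (vectorized).
#' @param it_ms Injection time per scan, ms.
#' @param agc_target AGC target (charges), > 0.
#' @param it_ceiling_ms Injection-time ceiling, ms (default 100); "at
#'   ceiling" means within 0.1 ms of it.
#' @param low,high Regime thresholds relative to the target (defaults 0.7 and
#'   1.3).
#' @return Character vector: `"controlled"`, `"sub_target"`, `"over_target"`.
#' @export
agc_classify <- function(tic, it_ms, agc_target, it_ceiling_ms = 100,
                         low = 0.7, high = 1.3) {
  if (any(agc_target <= 0)) stop("agc_target must be > 0")
  rel <- (tic * it_ms) / agc_target
  at_ceiling <- it_ms >= it_ceiling_ms - 0.1
  ifelse(at_ceiling | rel < low, "sub_target",
         ifelse(rel > high, "over_target", "controlled"))
}

#' AGC diagnostics for an acquisition
#'
#' @param acq An `orbiso_acquisition`.
#' @param agc_target AGC target; defaults to the value recorded in the scan
#'   metadata.
#' @inheritParams agc_classify
#' @return List of class `"orbiso_agc_diagnostics"`: per-scan data.frame
#'   (`scan_index`, `tic_it`, `regime`, `at_it_ceiling`), `fraction_at_ceiling`,
#'   `median_tic_it`, `agc_target`, `fraction_controlled`.
#' @export
agc_diagnostics <- function(acq, agc_target = NULL, it_ceiling_ms = 100,
                            low = 0.7, high = 1.3) {
  stopifnot(inherits(acq, "orbiso_acquisition"))
  m <- acq$meta
  agc_target <- agc_target %||% unique(m$agc_target)[1]
  if (is.na(agc_target) || agc_target <= 0) {
    stop("agc_target is not recorded in the scan table; pass it explicitly")
  }
  regime <- agc_classify(m$tic, m$it_ms, agc_target, it_ceiling_ms, low, high)
  per_scan <- data.frame(scan_index = m$scan_index,
                         tic_it = m$tic * m$it_ms,
                         regime = regime,
                         at_it_ceiling = m$it_ms >= it_ceiling_ms - 0.1)
  structure(list(per_scan = per_scan,
                 fraction_at_ceiling = mean(per_scan$at_it_ceiling),
                 fraction_controlled = mean(regime == "controlled"),
                 median_tic_it = stats::median(per_scan$tic_it),
                 agc_target = agc_target),
            class = "orbiso_agc_diagnostics")
}

#' Selected-ion current of a target pair
#'
#' Per-scan sum of the matched intensities of the target's isotopologues,
#' plus the mean over scans — the direct measure of the analyte's
#' electrospray response.
#'
#' @param acq An `orbiso_acquisition`.
#' @param pair Target pair (list with `$light`, `$heavy`) or a single
#'   `orbiso_target`.
#' @return List: `per_scan` (data.frame `scan_index`, `sic`), `mean_sic`.
#' @export
sic_series <- function(acq, pair) {
  targets <- if (inherits(pair, "orbiso_target")) list(pair)
             else Filter(Negate(is.null), pair[c("light", "heavy")])
  mats <- lapply(targets, function(t) {
    m <- match_peaks(acq, t)
    ifelse(is.na(m$intensity), 0, m$intensity)
  })
  sic <- Reduce(`+`, mats)
  list(per_scan = data.frame(scan_index = acq$meta$scan_index, sic = sic),
       mean_sic = mean(sic))
}

#' Suppression index: pure vs matrix-suppressed response
#'
#' Ratio of the analyte's mean selected-ion current measured pure to its mean
#' in a matrix. Values >= 1 indicate suppression; severe matrices can push
#' this to 3 or more.
#'
#' @param pure_sic,mixed_sic Mean SIC of the pure standard and of the matrix
#'   run.
#' @return Dimensionless suppression index.
#' @export
suppression_index <- function(pure_sic, mixed_sic) {
  if (any(mixed_sic <= 0)) stop("mixed SIC must be > 0")
  pure_sic / mixed_sic
}

#' Detect in-window contaminant ions
#'
#' Mass-resolved ions that fall inside the quadrupole isolation window
#' coaccumulate with the analyte, compete for the AGC charge budget, and can
#' bias the measured ratio once they exceed roughly 10% of the analyte
#' signal. This scans the acquisition window for peaks not matching any
#' declared isotopologue, clusters them by m/z (cluster half-width = the
#' targets' match tolerance), and ranks clusters by mean abundance relative
#' to the analyte selected-ion current.
#'
#' @param acq An `orbiso_acquisition`.
#' @param targets List of declared `orbiso_target`s (analyte isotopologues).
#' @param window Length-2 m/z range of the acquisition window; defaults to
#'   the observed peak range.
#' @param warn_pct,fail_pct Relative-abundance thresholds in percent
#'   (defaults 1 and 10). The 10% default is a documented heuristic.
#' @return List of class `"orbiso_interference_report"`: `contaminants`
#'   (data.frame `mz`, `mean_intensity`, `relative_abundance_pct`,
#'   `n_scans_present`), `flag` (`"clean"|"warn"|"fail"`), `analyte_mean_sic`.
#' @export
detect_interference <- function(acq, targets, window = NULL,
                                warn_pct = 1, fail_pct = 10) {
  stopifnot(inherits(acq, "orbiso_acquisition"))
  if (inherits(targets, "orbiso_target")) targets <- list(targets)
  if (!is.null(targets$light)) targets <- Filter(Negate(is.null),
                                                 targets[c("light", "heavy")])
  pk <- acq$peaks
  if (is.null(window)) window <- range(pk$mz)
  pk <- pk[pk$mz >= window[1] & pk$mz <= window[2], , drop = FALSE]
  sic <- 0
  declared <- rep(FALSE, nrow(pk))
  for (t in targets) {
    tol <- target_tolerance_da(t)
    declared <- declared | abs(pk$mz - t$theoretical_mz) <= tol
    m <- match_peaks(acq, t)
    sic <- sic + ifelse(is.na(m$intensity), 0, m$intensity)
  }
  mean_sic <- mean(sic)
  if (mean_sic <= 0) stop("no analyte signal matched; cannot scale interference")
  extra <- pk[!declared, , drop = FALSE]
  cluster_tol <- max(vapply(targets, target_tolerance_da, numeric(1)))
  nsc <- nrow(acq$meta)
  if (!nrow(extra)) {
    contaminants <- data.frame(mz = numeric(0), mean_intensity = numeric(0),
                               relative_abundance_pct = numeric(0),
                               n_scans_present = integer(0))
  } else {
    o <- order(extra$mz)
    extra <- extra[o, , drop = FALSE]
    grp <- cumsum(c(1, diff(extra$mz) > 2 * cluster_tol))
    agg <- lapply(split(extra, grp), function(g) {
      data.frame(mz = stats::weighted.mean(g$mz, g$intensity),
                 mean_intensity = sum(g$intensity) / nsc,
                 n_scans_present = length(unique(g$scan_index)))
    })
    contaminants <- do.call(rbind, agg)
    contaminants$relative_abundance_pct <-
      100 * contaminants$mean_intensity / mean_sic
    contaminants <- contaminants[order(-contaminants$relative_abundance_pct),
                                 c("mz", "mean_intensity",
                                   "relative_abundance_pct",
                                   "n_scans_present")]
    rownames(contaminants) <- NULL
  }
  flag <- if (nrow(contaminants) &&
              any(contaminants$relative_abundance_pct >= fail_pct)) "fail"
          else if (nrow(contaminants) &&
                   any(contaminants$relative_abundance_pct >= warn_pct)) "warn"
          else "clean"
  structure(list(contaminants = contaminants, flag = flag,
                 analyte_mean_sic = mean_sic,
                 thresholds = c(warn_pct = warn_pct, fail_pct = fail_pct)),
            class = "orbiso_interference_report")
}

#' @export
print.orbiso_interference_report <- function(x, ...) {
  cat(sprintf("<orbiso_interference_report> flag: %s (%d contaminant cluster(s))\n",
              x$flag, nrow(x$contaminants)))
  if (nrow(x$contaminants)) {
    print(utils::head(x$contaminants, 5))
  }
  invisible(x)
}
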