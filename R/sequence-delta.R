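# Bracketed-sequence processing: standard-block drift regression, predicted
# reference ratios, per-block delta-13C, reproducibility error.

#' Build a bracketed sequence layout
#'
#' The canonical zero-enrichment design is seven blocks acquired alternately:
#' standards at odd block positions (1, 3, 5, 7) and samples at even
#' positions (2, 4, 6). Any alternation with at least two standard blocks is
#' accepted. The drift regressor for each block is its mean acquisition time
#' on the sequence clock (`t0 + mean(rt)`) when start times are known, and
#' the block index otherwise — drift is physical in time.
#'
#' @param acquisitions List of `orbiso_acquisition` objects, in acquisition
#'   order.
#' @param roles Character vector `"standard"`/`"sample"` per block; defaults
#'   to each acquisition's `role` field, then to the odd-standard/even-sample
#'   template.
#' @param regressor `"time"` (default; falls back to index when any `t0` is
#'   missing) or `"index"`.
#' @return List of class `"orbiso_layout"` with `blocks` (data.frame:
#'   `block_index`, `role`, `position`) and `acquisitions`.
#' @export
sequence_layout <- function(acquisitions, roles = NULL,
                            regressor = c("time", "index")) {
  regressor <- match.arg(regressor)
  stopifnot(length(acquisitions) >= 3,
            all(vapply(acquisitions, inherits, TRUE, "orbiso_acquisition")))
  nb <- length(acquisitions)
  if (is.null(roles)) {
    roles <- vapply(acquisitions, function(a) a$role, character(1))
    if (anyNA(roles)) {
      roles <- ifelse(seq_len(nb) %% 2 == 1, "standard", "sample")
    }
  }
  if (!all(roles %in% c("standard", "sample"))) {
    stop("roles must be 'standard' or 'sample'")
  }
  if (sum(roles == "standard") < 2) {
    stop("drift regression requires >= 2 standard blocks")
  }
  t0 <- vapply(acquisitions, function(a) a$t0, numeric(1))
  if (regressor == "time" && anyNA(t0)) regressor <- "index"
  pos <- if (regressor == "time") {
    t0 + vapply(acquisitions, function(a) mean(a$meta$rt_min), numeric(1))
  } else {
    as.numeric(seq_len(nb))
  }
  structure(list(blocks = data.frame(block_index = seq_len(nb), role = roles,
                                     position = pos),
                 acquisitions = acquisitions, regressor = regressor),
            class = "orbiso_layout")
}

#' Ordinary least-squares drift fit over standard-block ratios
#'
#' A linear regression of standard-block mean isotope ratios against block
#' position models the instrumental drift; it is later evaluated at the
#' sample-block positions to give time-resolved reference ratios (instead of
#' simple bracketing). Unweighted: the canonical design has only four
#' standard points.
#'
#' @param ratios Aggregate `13R` of each standard block.
#' @param positions Block positions (time or index), same length.
#' @return List of class `"orbiso_drift_fit"`: `slope`, `intercept`,
#'   `residuals`, `positions`, `r_squared` (NA with 2 points).
#' @export
drift_fit <- function(ratios, positions) {
  if (length(ratios) < 2 || length(positions) != length(ratios)) {
    stop("drift fit requires >= 2 standard blocks with matching positions")
  }
  if (anyNA(ratios) || anyNA(positions)) stop("NA in drift-fit inputs")
  if (stats::var(positions) == 0) stop("standard-block positions are identical")
  xbar <- mean(positions); ybar <- mean(ratios)
  slope <- sum((positions - xbar) * (ratios - ybar)) /
    sum((positions - xbar)^2)
  intercept <- ybar - slope * xbar
  res <- ratios - (intercept + slope * positions)
  ss_tot <- sum((ratios - ybar)^2)
  structure(list(slope = slope, intercept = intercept, residuals = res,
                 positions = positions,
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot
                             else NA_real_),
            class = "orbiso_drift_fit")
}

#' Predict the reference ratio at a block position
#'
#' @param fit An `orbiso_drift_fit`.
#' @param position Block position(s) to evaluate.
#' @param warn_extrapolation Warn when predicting outside the fitted range
#'   (default `TRUE`).
#' @return Predicted reference `13R` value(s).
#' @export
predict_reference <- function(fit, position, warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "orbiso_drift_fit"))
  if (warn_extrapolation &&
      any(position < min(fit$positions) | position > max(fit$positions))) {
    warning("predicting reference ratio outside the standard-block range ",
            "(extrapolation)")
  }
  fit$intercept + fit$slope * position
}

#' Isotope delta value in per mil
#'
#' `delta = ((R_sample / R_std) - 1) * 1000`. Zero when sample and reference
#' ratios agree; monotone increasing in the sample ratio.
#'
#' @param r_sample Measured sample ratio(s).
#' @param r_std Reference ratio(s); must be > 0.
#' @return Delta in per mil.
#' @examples
#' delta_value(0.1208, 0.1214) # about -4.94 permil
#' @export
delta_value <- function(r_sample, r_std) {
  if (any(r_std <= 0)) stop("reference ratio must be > 0")
  (r_sample / r_std - 1) * 1000
}

#' Drift-corrected delta-13C over a bracketed sequence
#'
#' Processes every block through the ion-count pipeline, fits the drift
#' regression on standard-block aggregate ratios, predicts the reference
#' ratio at each sample block, and converts each sample block to a delta
#' value. The final delta-13C is the arithmetic mean of the sample-block
#' deltas; their sample standard deviation (n-1) is the reproducibility
#' error, reported as `NA` (undefined, not 0) with a single sample block.
#'
#' @param layout An `orbiso_layout`, or a list of acquisitions (passed to
#'   [sequence_layout()]).
#' @param pair Target pair from [target_pair()].
#' @param params [ion_count_params()].
#' @param window Retention-time cull window (default `c(2, 8)` min); `NULL`
#'   to skip.
#' @param k_outlier Outlier multiplier (default 5; `Inf` disables).
#' @param it_ceiling_ms,drop_it_ceiling See [ion_count_series()].
#' @param ... Passed to [sequence_layout()] when `layout` is a plain list.
#' @return List of class `"orbiso_delta_result"`: `blocks` (per-block
#'   data.frame with measured ratio, predicted reference, delta),
#'   `delta_permil`, `reproducibility_error_permil`, `fit`, `summaries`.
#' @export
sequence_delta <- function(layout, pair, params = ion_count_params(),
                           window = c(2, 8), k_outlier = 5,
                           it_ceiling_ms = 100, drop_it_ceiling = FALSE,
                           ...) {
  if (!inherits(layout, "orbiso_layout")) {
    layout <- sequence_layout(layout, ...)
  }
  blocks <- layout$blocks
  res <- lapply(layout$acquisitions, function(a) {
    tryCatch(process_acquisition(a, pair, params = params, window = window,
                                 k_outlier = k_outlier,
                                 it_ceiling_ms = it_ceiling_ms,
                                 drop_it_ceiling = drop_it_ceiling),
             error = function(e) e)
  })
  failed <- vapply(res, inherits, TRUE, "error")
  if (any(failed & blocks$role == "sample")) {
    stop("sample block(s) without a usable ratio: ",
         paste(blocks$block_index[failed & blocks$role == "sample"],
               collapse = ", "))
  }
  if (sum(!failed & blocks$role == "standard") < 2) {
    stop("fewer than 2 standard blocks produced usable ratios")
  }
  ratios <- vapply(res, function(r) if (inherits(r, "error")) NA_real_
                   else r$summary$ratio, numeric(1))
  std <- blocks$role == "standard" & !failed
  fit <- drift_fit(ratios[std], blocks$position[std])
  samp <- which(blocks$role == "sample")
  pred <- predict_reference(fit, blocks$position[samp],
                            warn_extrapolation = FALSE)
  deltas <- delta_value(ratios[samp], pred)
  blocks$measured_ratio <- ratios
  blocks$predicted_reference <- NA_real_
  blocks$predicted_reference[samp] <- pred
  blocks$delta_permil <- NA_real_
  blocks$delta_permil[samp] <- deltas
  structure(list(blocks = blocks,
                 delta_permil = mean(deltas),
                 reproducibility_error_permil =
                   if (length(deltas) >= 2) stats::sd(deltas) else NA_real_,
                 fit = fit,
                 summaries = lapply(res, function(r)
                   if (inherits(r, "error")) NULL else r$summary)),
            class = "orbiso_delta_result")
}

#' @export
print.orbiso_delta_result <- function(x, ...) {
  cat(sprintf(paste0("<orbiso_delta_result> delta13C = %.3f permil, ",
                     "reproducibility error %.3f permil (%d sample blocks)\n",
                     "  drift fit: slope %.3e per position unit, intercept %.6g\n"),
              x$delta_permil, x$reproducibility_error_permil,
              sum(x$blocks$role == "sample"), x$fit$slope, x$fit$intercept))
  invisible(x)
}

#' Cross-level delta matrix
#'
#' Delta of every sample acquisition against every standard acquisition
#' (e.g. concentration levels crossed), using each acquisition's aggregate
#' ratio. Missing or failing cells are `NA`, never 0.
#'
#' @param standards,samples Named lists of `orbiso_acquisition` objects.
#' @param pair Target pair.
#' @param ... Passed to [process_acquisition()].
#' @return Long-format data.frame: `sample`, `standard`, `delta_permil`.
#' @export
delta_matrix <- function(standards, samples, pair, ...) {
  ratio_of <- function(a) {
    tryCatch(process_acquisition(a, pair, ...)$summary$ratio,
             error = function(e) NA_real_)
  }
  rs <- vapply(standards, ratio_of, numeric(1))
  rsamp <- vapply(samples, ratio_of, numeric(1))
  names(rs) <- names(rs) %||% paste0("std", seq_along(rs))
  names(rsamp) <- names(rsamp) %||% paste0("smp", seq_along(rsamp))
  grid <- expand.grid(sample = names(rsamp), standard = names(rs),
                      stringsAsFactors = FALSE)
  grid$delta_permil <- mapply(function(s, d) {
    if (is.na(rsamp[[s]]) || is.na(rs[[d]])) NA_real_
    else delta_value(rsamp[[s]], rs[[d]])
  }, grid$sample, grid$standard)
  grid
}
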