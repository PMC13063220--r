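# Ion-count model and ratio statistics. Frozen values verified by hand:
# 100 * 3 * sqrt(240000/60000) * 2 = 1200; 250 * 4.4 * sqrt(2) = 1555.63;
# 1000 * sqrt(1e-4 + 1e-6) = 10.05.

test_that("ion_count evaluates the S/N model", {
  expect_equal(ion_count(s = 100 * 7, n = 7, resolution = 60000,
                         microscans = 2), 1200)
  expect_equal(ion_count(50, 1, resolution = 240000, microscans = 1), 150)
  p44 <- ion_count_params(empirical_constant = 4.4)
  expect_equal(ion_count(5000, 20, resolution = 120000, microscans = 1,
                         params = p44), 1555.63, tolerance = 1e-5)
  expect_error(ion_count(1, 1, resolution = -1), "resolution")
  expect_error(ion_count(1, 0, resolution = 60000), "noise")
  expect_error(ion_count_params(empirical_constant = 0), "empirical")
})

test_that("peak matching picks the nearest peak within tolerance", {
  tgt <- isotopologue_target("C11H12O2")  # 175.0765, tol 5 ppm (~0.00088 Da)
  peaks <- data.frame(mz = c(175.0761, 170.0), intensity = c(10, 99),
                      noise = c(1, 1))
  expect_equal(match_peak(peaks, tgt)$mz, 175.0761)  # within 2.3 ppm
  # two candidates: nearer by m/z wins
  peaks2 <- data.frame(mz = 175.0765 + c(5e-4, -8e-4),
                       intensity = c(1, 2), noise = c(1, 1))
  expect_equal(match_peak(peaks2, tgt)$mz, 175.0765 + 5e-4)
  # brute-force nearest search over random in-tolerance peaks
  set.seed(11)
  tol <- target_tolerance_da(tgt)
  for (i in 1:25) {
    mzs <- tgt$theoretical_mz + stats::runif(6, -3 * tol, 3 * tol)
    pk <- data.frame(mz = mzs, intensity = seq_along(mzs), noise = 1)
    got <- match_peak(pk, tgt)
    inside <- abs(mzs - tgt$theoretical_mz) <= tol
    if (!any(inside)) {
      expect_null(got)
    } else {
      expect_equal(got$mz,
                   mzs[which.min(ifelse(inside,
                                        abs(mzs - tgt$theoretical_mz), Inf))])
    }
  }
  expect_null(match_peak(data.frame(mz = 100, intensity = 1, noise = 1), tgt))
})

test_that("per-scan ratio equals the ion-count ratio for any model constants", {
  set.seed(7)
  for (i in 1:50) {
    s13 <- stats::runif(1, 1, 1e6); n13 <- stats::runif(1, 1, 1e3)
    s12 <- stats::runif(1, 1, 1e7); n12 <- stats::runif(1, 1, 1e3)
    r <- stats::runif(1, 1e4, 5e5); mu <- sample(1:4, 1)
    p <- ion_count_params(reference_resolution = stats::runif(1, 1e5, 5e5),
                          empirical_constant = stats::runif(1, 0.5, 10))
    expect_equal(scan_ratio(s13 / n13, s12 / n12),
                 ion_count(s13, n13, r, mu, p) / ion_count(s12, n12, r, mu, p),
                 tolerance = 1e-12)
  }
  expect_equal(scan_ratio(1.1, 10), 0.11)
  expect_equal(scan_ratio(3.3, 3.3), 1)
  expect_true(is.na(scan_ratio(1, 0)))
})

test_that("median/MAD outlier rejection masks exactly the divergent scans", {
  set.seed(5)
  acq <- make_acq(n_scan = 100)
  ser <- ion_count_series(acq, thn_pair())
  # inject per-scan ratio scatter then one gross outlier
  ser$ratio <- 0.011 * (1 + stats::rnorm(100, 0, 0.01))
  ser$ratio[37] <- 0.5
  out <- reject_outliers(ser, k = 5)
  # brute-force check of the rule
  r <- ser$ratio
  med <- stats::median(r); lim <- 5 * 1.4826 * stats::median(abs(r - med))
  expect_identical(which(out$filtered_reason == "outlier"),
                   which(abs(r - med) > lim))
  expect_identical(sum(out$filtered_reason == "outlier"), 1L)
  # all-identical ratios: none masked; k = Inf: identity
  ser2 <- ion_count_series(make_acq(n_scan = 10), thn_pair())
  expect_identical(reject_outliers(ser2, 5)$filtered_reason,
                   ser2$filtered_reason)
  expect_identical(reject_outliers(out, Inf), out)
  expect_error(reject_outliers(ser[1:3, ], 5), "5 usable")
})

test_that("MAD = 0 with divergent values falls back with a warning", {
  acq <- make_acq(n_scan = 9)
  ser <- ion_count_series(acq, thn_pair())
  ser$ratio <- c(rep(0.11, 8), 0.2)
  expect_warning(out <- reject_outliers(ser, 5), "MAD")
  expect_identical(sum(out$filtered_reason == "outlier"), 1L)
})

test_that("aggregate ratio is count-weighted with per-scan acquisition error", {
  acq <- make_acq(n_scan = 2)
  ser <- ion_count_series(acq, thn_pair())
  ser$count_heavy <- c(10, 20); ser$count_light <- c(1000, 2000)
  ser$ratio <- ser$count_heavy / ser$count_light
  s <- aggregate_ratio(ser)
  expect_equal(s$ratio, 0.01)
  expect_equal(s$acquisition_error_permil, 0)
  expect_equal(s$shot_noise_ratio, 0)
  expect_error(aggregate_ratio(ser[1, ]), "2 usable")
  # identical scans -> zero error
  ser0 <- ion_count_series(make_acq(n_scan = 6), thn_pair())
  expect_equal(aggregate_ratio(ser0)$acquisition_error_permil, 0)
})

test_that("aggregate ratio is invariant under uniform intensity scaling", {
  acq <- make_acq(n_scan = 20)
  set.seed(3)
  acq$peaks$intensity <- acq$peaks$intensity * stats::runif(40, 0.5, 2)
  base <- aggregate_ratio(ion_count_series(acq, thn_pair()))
  scaled <- acq
  scaled$peaks$intensity <- scaled$peaks$intensity * 137.5
  scaled$peaks$noise <- scaled$peaks$noise * 137.5
  got <- aggregate_ratio(ion_count_series(scaled, thn_pair()))
  expect_equal(got$ratio, base$ratio, tolerance = 1e-12)
  expect_equal(got$acquisition_error_permil, base$acquisition_error_permil,
               tolerance = 1e-9)
})

test_that("shot-noise limit follows two-Poisson counting statistics", {
  expect_equal(shot_noise_limit(1e4, 1e6), 10.05, tolerance = 1e-3)
  expect_lt(shot_noise_limit(1e14, 1e16), 1e-3)  # -> 0 for large counts
  expect_error(shot_noise_limit(0, 10), "positive")
})

test_that("simulated Poisson series recovers the true ratio within 3 SE", {
  cfg <- sim_config(species_spec("x", ion_flux = 2e8, concentration = 5,
                                 true_ratio = 0.1214, mz_light = 175.0765),
                    suppression_coefficient = 0, n_scans = 300, seed = 99)
  acq <- simulate_acquisition(cfg)
  s <- aggregate_ratio(ion_count_series(acq, thn_pair()))
  se_rel <- s$shot_noise_limit_permil / 1000
  expect_lt(abs(s$ratio - 0.1214), 3 * se_rel * 0.1214)
})

test_that("IT-ceiling scans are flagged and optionally dropped", {
  acq <- make_acq(n_scan = 6, it_ms = 10)
  acq$meta$it_ms[5:6] <- c(99.95, 100)
  ser <- ion_count_series(acq, thn_pair(), it_ceiling_ms = 100)
  expect_identical(ser$at_it_ceiling, c(rep(FALSE, 4), TRUE, TRUE))
  expect_true(all(ser$filtered_reason == "none"))  # flagged, not dropped
  ser2 <- ion_count_series(acq, thn_pair(), it_ceiling_ms = 100,
                           drop_it_ceiling = TRUE)
  expect_identical(ser2$filtered_reason[5:6], rep("it_ceiling", 2))
})
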