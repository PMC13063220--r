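# Bracketed-sequence drift correction and delta computation.

test_that("drift_fit reproduces exact linear standard data", {
  fit <- drift_fit(c(0.1100, 0.1102, 0.1104, 0.1106), c(1, 3, 5, 7))
  expect_equal(fit$slope, 1e-4, tolerance = 1e-12)
  expect_equal(predict_reference(fit, 4), 0.1103, tolerance = 1e-12)
  # constant ratios: zero slope, intercept = mean
  fit0 <- drift_fit(rep(0.12, 4), c(1, 3, 5, 7))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$intercept, 0.12)
  expect_error(drift_fit(0.1, 1), "2 standard")
  expect_error(drift_fit(c(0.1, 0.2), c(2, 2)), "identical")
  expect_warning(predict_reference(fit, 9), "extrapolation")
})

test_that("drift_fit agrees with the lm() closed-form oracle on noisy data", {
  set.seed(21)
  for (i in 1:20) {
    x <- sort(stats::runif(6, 0, 70))
    y <- 0.12 + 1e-5 * x + stats::rnorm(6, 0, 1e-5)
    fit <- drift_fit(y, x)
    ora <- stats::lm(y ~ x)
    expect_equal(fit$slope, unname(stats::coef(ora)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(stats::coef(ora)[1]),
                 tolerance = 1e-10)
  }
})

test_that("delta_value implements the per-mil definition", {
  expect_equal(delta_value(0.12, 0.12), 0)
  expect_equal(delta_value(0.1208, 0.1214), -4.94, tolerance = 5e-3)
  expect_equal(delta_value(1.1 * 0.2, 0.2), 100, tolerance = 1e-9)
  expect_error(delta_value(0.1, 0), "reference")
  # monotone increasing in the sample ratio
  rs <- seq(0.1, 0.2, by = 0.01)
  expect_true(all(diff(delta_value(rs, 0.15)) > 0))
})

test_that("seven-block fixture matches the spreadsheet-style hand computation", {
  # standards (blocks 1,3,5,7) exactly linear in block index; samples offset
  r_std <- c(0.1100, 0.1102, 0.1104, 0.1106)
  r_smp <- c(0.1102, 0.1105, 0.1104)
  ratios <- c(0.1100, 0.1102, 0.1102, 0.1105, 0.1104, 0.1104, 0.1106)
  acqs <- lapply(seq_len(7), function(k) {
    make_acq(n_scan = 5, ratio = ratios[k],
             role = if (k %% 2 == 1) "standard" else "sample")
  })
  res <- sequence_delta(acqs, thn_pair(), window = NULL)
  # hand computation: OLS on (1,3,5,7) gives slope 1e-4, intercept 0.1099;
  # predictions at 2,4,6 are 0.1101, 0.1103, 0.1105
  pred <- 0.1099 + 1e-4 * c(2, 4, 6)
  d_hand <- (r_smp / pred - 1) * 1000
  expect_equal(res$blocks$predicted_reference[c(2, 4, 6)], pred,
               tolerance = 1e-10)
  expect_equal(res$blocks$delta_permil[c(2, 4, 6)], d_hand,
               tolerance = 1e-9)
  expect_equal(res$delta_permil, mean(d_hand), tolerance = 1e-9)
  expect_equal(res$reproducibility_error_permil, stats::sd(d_hand),
               tolerance = 1e-9)
  expect_equal(res$blocks$measured_ratio[c(1, 3, 5, 7)], r_std,
               tolerance = 1e-12)
})

test_that("identical blocks give zero delta and zero reproducibility error", {
  acqs <- lapply(1:7, function(k) make_acq(n_scan = 5, ratio = 0.11))
  res <- sequence_delta(acqs, thn_pair(), window = NULL)
  expect_equal(res$delta_permil, 0, tolerance = 1e-10)
  expect_equal(res$reproducibility_error_permil, 0, tolerance = 1e-10)
})

test_that("exact linear drift is removed exactly in the noise-free case", {
  true_delta <- 2.5  # per mil
  d <- 0.002         # relative drift per block position
  base <- 0.1214
  ratios <- vapply(1:7, function(k) {
    r <- base * (1 + d * k)
    if (k %% 2 == 0) r * (1 + true_delta / 1000) else r
  }, numeric(1))
  acqs <- lapply(1:7, function(k) make_acq(n_scan = 5, ratio = ratios[k]))
  res <- sequence_delta(acqs, thn_pair(), window = NULL)
  expect_equal(res$delta_permil, true_delta, tolerance = 1e-8)
  expect_equal(res$reproducibility_error_permil, 0, tolerance = 1e-6)
})

test_that("common linear-in-position scaling leaves delta unchanged to first order", {
  set.seed(31)
  ratios <- 0.1214 * (1 + stats::rnorm(7, 0, 2e-4))
  acqs0 <- lapply(1:7, function(k) make_acq(n_scan = 5, ratio = ratios[k]))
  base <- sequence_delta(acqs0, thn_pair(), window = NULL)
  for (amp in c(0.002, 0.01)) {  # up to 1% drift across the sequence
    scaled <- ratios * (1 + amp * (1:7) / 7)
    acqs <- lapply(1:7, function(k) make_acq(n_scan = 5, ratio = scaled[k]))
    res <- sequence_delta(acqs, thn_pair(), window = NULL)
    expect_equal(res$delta_permil, base$delta_permil, tolerance = amp)
  }
})

test_that("layout validation and failure modes are explicit", {
  acqs <- lapply(1:7, function(k) make_acq(n_scan = 5, ratio = 0.11))
  expect_error(sequence_layout(acqs, roles = rep("sample", 7)),
               "2 standard blocks")
  expect_error(sequence_layout(acqs[1:2]), "length")
  # a sample block with no matching peaks must be reported by block number
  broken <- acqs
  broken[[4]]$peaks$mz <- broken[[4]]$peaks$mz + 1  # out of tolerance
  expect_error(sequence_delta(broken, thn_pair(), window = NULL),
               "sample block.*4")
})

test_that("single sample block yields undefined (not zero) reproducibility", {
  acqs <- lapply(1:3, function(k) {
    make_acq(n_scan = 5, ratio = 0.11,
             role = c("standard", "sample", "standard")[k])
  })
  res <- sequence_delta(acqs, thn_pair(), window = NULL)
  expect_true(is.na(res$reproducibility_error_permil))
})

test_that("time regressor is used when block start times are known", {
  ratios <- c(0.1100, 0.1102, 0.1102, 0.1105, 0.1104, 0.1104, 0.1106)
  acqs <- lapply(1:7, function(k) {
    make_acq(n_scan = 5, ratio = ratios[k], t0 = (k - 1) * 10)
  })
  lay <- sequence_layout(acqs)
  expect_identical(lay$regressor, "time")
  expect_equal(lay$blocks$position, (0:6) * 10 + mean((0:4) * 0.1))
  lay_idx <- sequence_layout(acqs, regressor = "index")
  expect_identical(lay_idx$blocks$position, as.numeric(1:7))
  # positions are affine in index here, so both regressors agree on delta
  d_time <- sequence_delta(lay, thn_pair(), window = NULL)$delta_permil
  d_idx <- sequence_delta(lay_idx, thn_pair(), window = NULL)$delta_permil
  expect_equal(d_time, d_idx, tolerance = 1e-9)
})

test_that("delta matrix crosses every sample with every standard", {
  std <- list(s1 = make_acq(n_scan = 5, ratio = 0.1100),
              s2 = make_acq(n_scan = 5, ratio = 0.1102))
  smp <- list(a = make_acq(n_scan = 5, ratio = 0.1101),
              b = make_acq(n_scan = 5, ratio = 0.1103))
  dm <- delta_matrix(std, smp, thn_pair(), window = NULL)
  expect_equal(nrow(dm), 4L)
  got <- dm$delta_permil[dm$sample == "a" & dm$standard == "s1"]
  expect_equal(got, (0.1101 / 0.1100 - 1) * 1000, tolerance = 1e-9)
  # a failing cell is NA, never zero
  smp$b$peaks$mz <- smp$b$peaks$mz + 1
  dm2 <- delta_matrix(std, smp, thn_pair(), window = NULL)
  expect_true(all(is.na(dm2$delta_permil[dm2$sample == "b"])))
  expect_false(anyNA(dm2$delta_permil[dm2$sample == "a"]))
})
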