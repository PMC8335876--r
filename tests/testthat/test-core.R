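test_that("find_peak returns the maximum, breaking ties toward low frequency", {
  sweep <- make_sweep(n = 201, peak_db = -15.2, f_center = 57.56e6,
                      fwhm = 8e6)
  pk <- find_peak(sweep)
  expect_equal(pk$peak_amp_db, max(sweep$amp_db))
  expect_equal(pk$peak_freq_hz, sweep$freq_hz[which.max(sweep$amp_db)])
  expect_false(pk$at_boundary)

  freq <- seq(10e6, 90e6, by = 10e6)
  amp <- c(-30, -30, -30, -20, -30, -20, -30, -30, -30) # ties at 40 & 60 MHz
  tie <- find_peak(tibble::tibble(freq_hz = freq, amp_db = amp))
  expect_equal(tie$peak_freq_hz, 40e6)

  rising <- tibble::tibble(freq_hz = freq, amp_db = seq(-30, -22, by = 1))
  expect_true(find_peak(rising)$at_boundary)

  flat <- tibble::tibble(freq_hz = freq, amp_db = rep(-20, 9))
  expect_error(find_peak(flat), class = "abcpe_error_degenerate")
})

test_that("the 3 dB band of a Lorentzian matches its closed-form width", {
  ## densely sampled Lorentzian, half-power full width 4 MHz at 50 MHz
  sweep <- make_sweep(n = 2001, peak_db = -18, f_center = 50e6, fwhm = 4e6)
  band <- find_3db_band(sweep)
  step <- diff(sweep$freq_hz[1:2])
  expect_lt(abs(band$bandwidth_hz - three_db_width(4e6)), step)
  expect_lt(abs(band$bandwidth_hz - 4e6), step + 0.003 * 4e6)
  expect_true(band$f_lower_hz < band$peak_freq_hz)
  expect_true(band$f_upper_hz > band$peak_freq_hz)
  ## the interpolated edges sit exactly on the -3 dB level of the shape
  edge_amp <- lorentz_db(c(band$f_lower_hz, band$f_upper_hz), -18, 50e6, 4e6)
  expect_equal(edge_amp, rep(band$peak_amp_db - 3, 2), tolerance = 1e-4)
})

test_that("a missing crossing raises a band-incomplete error naming the side", {
  sweep <- make_sweep(n = 301, f_center = 95e6, fwhm = 30e6)
  expect_error(find_3db_band(sweep), "upper",
               class = "abcpe_error_band_incomplete")
  sweep_lo <- make_sweep(n = 301, f_center = 3e6, fwhm = 30e6)
  expect_error(find_3db_band(sweep_lo), "lower",
               class = "abcpe_error_band_incomplete")
})

test_that("a uniform dB shift leaves the band and point count unchanged", {
  sweep <- make_sweep(n = 301)
  shifted <- dplyr::mutate(sweep, amp_db = amp_db + 1)
  b0 <- find_3db_band(sweep)
  b1 <- find_3db_band(shifted)
  expect_equal(b1$f_lower_hz, b0$f_lower_hz)
  expect_equal(b1$f_upper_hz, b0$f_upper_hz)
  expect_equal(b1$n_points, b0$n_points)
  expect_equal(b1$peak_amp_db, b0$peak_amp_db + 1)
})

test_that("band_mean is the discrete mean over in-band grid points", {
  sweep <- tibble::tibble(freq_hz = (1:8) * 1e6,
                          amp_db = c(-30, -20, -21, -22, -30, -31, -32, -33))
  expect_equal(band_mean(sweep, 1.5e6, 4.5e6), -21)
  expect_equal(band_mean(sweep, 3.9e6, 4.1e6), -22) # single point
  expect_error(band_mean(sweep, 4.1e6, 4.9e6),
               class = "abcpe_error_empty_band")
  expect_error(band_mean(sweep, 5e6, 4e6), class = "abcpe_error_validation")

  set.seed(21)
  for (i in 1:100) {
    sw <- random_sweep()
    lims <- sort(runif(2, min(sw$freq_hz), max(sw$freq_hz)))
    got <- tryCatch(band_mean(sw, lims[1], lims[2]), error = function(e) e)
    want <- tryCatch(naive_band_mean(sw$freq_hz, sw$amp_db, lims[1], lims[2]),
                     error = function(e) e)
    if (inherits(want, "error")) {
      expect_s3_class(got, "abcpe_error_empty_band")
    } else {
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("extract_baseline composes peak, band and band mean at t0", {
  sweep <- make_sweep(n = 501)
  sweep$time_h <- 0
  base <- extract_baseline(sweep)
  expect_s3_class(base, "abcpe_baseline")
  expect_lte(base$mean_amp_db, base$peak_amp_db)
  expect_gte(base$mean_amp_db, base$peak_amp_db - 3 - 0.05)
  expect_identical(base, extract_baseline(sweep)) # purity

  later <- dplyr::mutate(sweep, time_h = 1)
  expect_error(extract_baseline(later), class = "abcpe_error_validation")
})

test_that("parameters are exactly zero against an identical sweep", {
  sweep <- make_sweep(n = 301, noise_db = 0.05)
  base <- extract_baseline(sweep)
  p <- extract_parameters(sweep, base)
  expect_identical(unname(unlist(p)), rep(0, 5))
})

test_that("a uniform +1 dB shift gives the hand-computed parameter vector", {
  ## construct a sweep whose A0 is exactly -20 dB, then shift it by +1 dB
  sweep <- make_sweep(n = 1001, peak_db = -20, f_center = 50.5e6)
  base <- extract_baseline(sweep)
  expect_equal(base$peak_amp_db, -20, tolerance = 1e-9)
  shifted <- dplyr::mutate(sweep, amp_db = amp_db + 1)
  p <- extract_parameters(shifted, base)
  expect_equal(p$alpha, 1 / (-20), tolerance = 1e-9)
  expect_equal(p$beta, 0)
  expect_equal(p$gamma, 0, tolerance = 1e-12)
  expect_equal(p$delta, 1 / base$mean_amp_db, tolerance = 1e-9)
  expect_equal(p$rho, p$delta, tolerance = 1e-12)
})

test_that("doubling the bandwidth at fixed peak gives gamma near 1", {
  sweep0 <- make_sweep(n = 2001, fwhm = 6e6, f_center = 50e6)
  sweep1 <- make_sweep(n = 2001, fwhm = 12e6, f_center = 50e6)
  base <- extract_baseline(sweep0)
  p <- extract_parameters(sweep1, base)
  step <- diff(sweep0$freq_hz[1:2])
  expect_equal(p$gamma, 1, tolerance = 2 * step / base$bandwidth_hz)
  expect_equal(p$beta, 0, tolerance = step / base$peak_freq_hz)
  expect_equal(p$alpha, 0, tolerance = 1e-6)
})

test_that("delta and rho coincide whenever the band does not move", {
  set.seed(31)
  sweep <- make_sweep(n = 501)
  base <- extract_baseline(sweep)
  for (c_db in runif(10, -2, 2)) {
    p <- extract_parameters(dplyr::mutate(sweep, amp_db = amp_db + c_db),
                            base)
    expect_equal(p$delta, p$rho, tolerance = 1e-12)
    expect_equal(p$alpha, c_db / base$peak_amp_db, tolerance = 1e-9)
    expect_equal(p$delta, c_db / base$mean_amp_db, tolerance = 1e-9)
    expect_equal(p$beta, 0)
    expect_equal(p$gamma, 0, tolerance = 1e-12)
  }
})

test_that("translating the curve in frequency moves beta and nothing else", {
  n <- 801
  sweep <- make_sweep(n = n, f_center = 40e6, fwhm = 8e6, floor_db = -80)
  base <- extract_baseline(sweep)
  step <- diff(sweep$freq_hz[1:2])
  for (k in c(5L, 20L, 100L)) {
    amp_shift <- c(rep(sweep$amp_db[1], k), head(sweep$amp_db, n - k))
    p <- extract_parameters(
      tibble::tibble(freq_hz = sweep$freq_hz, amp_db = amp_shift), base)
    expect_equal(p$beta, k * step / base$peak_freq_hz,
                 tolerance = step / base$peak_freq_hz)
    expect_equal(p$alpha, 0, tolerance = 1e-9)
    expect_equal(p$gamma, 0, tolerance = 2 * step / base$bandwidth_hz)
    expect_equal(p$rho, 0, tolerance = 1e-3) # band mean re-centred on new band
  }
})

test_that("extraction agrees with the brute-force oracle on random sweeps", {
  set.seed(41)
  for (i in 1:100) {
    freq <- seq(1e6, 100e6, length.out = sample(300:600, 1))
    amp0 <- lorentz_db(freq, runif(1, -30, -10), runif(1, 30e6, 70e6),
                       runif(1, 5e6, 15e6)) + rnorm(length(freq), 0, 0.03)
    amp1 <- lorentz_db(freq, runif(1, -30, -10), runif(1, 30e6, 70e6),
                       runif(1, 5e6, 15e6)) + rnorm(length(freq), 0, 0.03)
    base <- extract_baseline(tibble::tibble(freq_hz = freq, amp_db = amp0))
    got <- extract_parameters(tibble::tibble(freq_hz = freq, amp_db = amp1),
                              base)
    want <- naive_params(freq, amp0, amp1)
    expect_equal(unlist(got), want, tolerance = 1e-9)
  }
})

test_that("extract_series orders deterministically and collects errors", {
  cohort <- make_cohort(n_exp = 2, n_con = 1, times = c(0, 6, 12, 24))
  params <- extract_series(cohort)
  expect_equal(nrow(params), 3 * 3)
  expect_equal(params$subject, rep(c("C1", "E1", "E2"), each = 3))

  shuffled <- cohort[sample(nrow(cohort)), ]
  expect_equal(extract_series(shuffled), params, ignore_attr = TRUE)

  baselines_only <- cohort[cohort$time_h == 0, ]
  empty <- extract_series(baselines_only)
  expect_equal(nrow(empty), 0)

  ## flatten one record so its half-power level is never reached
  broken <- cohort
  idx <- broken$subject == "E1" & broken$time_h == 12
  broken$amp_db[idx] <- -20 + 0.1 * seq_len(sum(idx)) / sum(idx)
  expect_warning(params_b <- extract_series(broken), "failed")
  errs <- attr(params_b, "errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$subject, "E1")
  expect_equal(errs$time_h, 12)
  expect_equal(nrow(params_b), 8) # the other records survive
})
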