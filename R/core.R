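## Characteristic parameter extraction.
##
## Each measurement is compared with the subject's own first sweep (t0).
## From a sweep we take the resonance peak A(f), the 3 dB (half-power)
## band [f', f''] around it, the bandwidth F = f'' - f', the count N of
## grid points inside the band, and band mean amplitudes. The five
## dimensionless parameters are fractional changes relative to baseline:
##   alpha = (A_i - A_0) / A_0
##   beta  = (f_i - f_0) / f_0
##   gamma = (F_i - F_0) / F_0
##   delta = (abar_i  - abar_0) / abar_0   (mean over the baseline band F0)
##   rho   = (abar_i' - abar_0) / abar_0   (mean over the current band F_i)
## The formulas act literally on dB amplitudes, which are typically
## negative: a +1 dB amplitude rise at A_0 = -20 dB gives alpha = -0.05.
## Classification downstream is sign-agnostic, so only consistency matters.

## Grid points are counted inside the interpolated band with a small
## relative tolerance so a crossing that lands exactly on a grid point is
## never lost to floating-point rounding.
.band_eps <- 1e-9

#' Locate the resonance peak of a sweep
#'
#' Returns the maximum amplitude over the frequency grid and the frequency
#' at which it occurs (the characteristic frequency, where sensor-tissue
#' coupling is strongest). Ties are broken toward the lowest frequency. A
#' peak at either end of the sweep range is returned but flagged, since no
#' half-power band can be located around it.
#'
#' @param sweep A sweep data frame (`freq_hz`, `amp_db`).
#' @return A one-row tibble: `peak_amp_db`, `peak_freq_hz`, `at_boundary`.
#' @export
#' @examples
#' sweep <- tibble::tibble(freq_hz = 1:11 * 1e6,
#'                         amp_db = -((1:11) - 6)^2 - 15)
#' find_peak(sweep)
find_peak <- function(sweep) {
  sweep <- validate_sweep(sweep)
  amp <- sweep$amp_db
  if (max(amp) == min(amp)) {
    abort("Degenerate sweep: all amplitudes are equal, no peak exists.",
          class = "abcpe_error_degenerate")
  }
  idx <- which.max(amp) # first maximum = lowest frequency on ties
  tibble(
    peak_amp_db = amp[[idx]],
    peak_freq_hz = sweep$freq_hz[[idx]],
    at_boundary = idx == 1L || idx == length(amp)
  )
}

## Walk outward from the peak until the curve drops below `level`, then
## linearly interpolate the crossing between the bracketing grid samples.
## `side` is -1 (toward lower frequencies) or +1 (toward higher).
.crossing <- function(freq, amp, peak_idx, level, side) {
  n <- length(amp)
  i <- peak_idx
  repeat {
    j <- i + side
    if (j < 1L || j > n) {
      abort(paste0("Half-power level never crossed on the ",
                   if (side < 0) "lower" else "upper",
                   " side within the sweep range."),
            class = "abcpe_error_band_incomplete")
    }
    if (amp[[j]] < level) break
    i <- j
  }
  ## amp[i] >= level > amp[j]; interpolate between the two samples
  freq[[j]] + (level - amp[[j]]) / (amp[[i]] - amp[[j]]) *
    (freq[[i]] - freq[[j]])
}

#' Extract the 3 dB (half-power) band around the peak
#'
#' Finds the innermost frequencies below and above the peak where the
#' amplitude crosses `peak - 3` dB, each located by linear interpolation
#' between the bracketing grid samples (an exact-equality condition cannot
#' hold on a discrete grid). If the curve re-crosses the level further out
#' (side lobes), the crossings nearest the peak define the band, keeping it
#' contiguous around the characteristic frequency. `n_points` counts raw
#' grid points `f_n` with `f' <= f_n <= f''`.
#'
#' @param sweep A sweep data frame.
#' @param peak Optional result of [find_peak()] on the same sweep; computed
#'   if omitted.
#' @param drop_db Level drop below the peak defining the band, dB.
#' @return A one-row tibble: `peak_amp_db`, `peak_freq_hz`, `f_lower_hz`,
#'   `f_upper_hz`, `bandwidth_hz`, `n_points`.
#' @export
find_3db_band <- function(sweep, peak = NULL, drop_db = 3) {
  sweep <- validate_sweep(sweep)
  if (is.null(peak)) peak <- find_peak(sweep)
  level <- peak$peak_amp_db - drop_db
  peak_idx <- which(sweep$freq_hz == peak$peak_freq_hz)
  if (length(peak_idx) != 1) {
    abort("`peak` does not match the sweep grid; was it computed on the same record?",
          class = "abcpe_error_validation")
  }
  f_lower <- .crossing(sweep$freq_hz, sweep$amp_db, peak_idx, level, -1L)
  f_upper <- .crossing(sweep$freq_hz, sweep$amp_db, peak_idx, level, +1L)
  tol <- .band_eps * max(abs(f_lower), abs(f_upper))
  inside <- sweep$freq_hz >= f_lower - tol & sweep$freq_hz <= f_upper + tol
  tibble(
    peak_amp_db = peak$peak_amp_db,
    peak_freq_hz = peak$peak_freq_hz,
    f_lower_hz = f_lower,
    f_upper_hz = f_upper,
    bandwidth_hz = f_upper - f_lower,
    n_points = sum(inside)
  )
}

#' Mean amplitude over the grid points inside a frequency band
#'
#' Discrete arithmetic mean of `amp_db` over grid points `f_n` with
#' `f_lo <= f_n <= f_hi`; no interpolation is involved.
#'
#' @param sweep A sweep data frame.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`.
#' @return The mean amplitude in dB (a scalar).
#' @export
band_mean <- function(sweep, f_lo, f_hi) {
  sweep <- validate_sweep(sweep, min_points = 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo >= f_hi) {
    abort("`f_lo` must be strictly less than `f_hi`.",
          class = "abcpe_error_validation")
  }
  tol <- .band_eps * max(abs(f_lo), abs(f_hi))
  inside <- sweep$freq_hz >= f_lo - tol & sweep$freq_hz <= f_hi + tol
  if (!any(inside)) {
    abort("No grid point falls inside the requested band.",
          class = "abcpe_error_empty_band")
  }
  mean(sweep$amp_db[inside])
}

#' Derive the baseline reference from the t0 sweep
#'
#' Composes [find_peak()], [find_3db_band()] and [band_mean()] on the
#' baseline record: peak amplitude A0 and characteristic frequency f0, the
#' 3 dB band [f0', f0''] with bandwidth F0 and point count N0, and the mean
#' amplitude abar_0 over the N0 grid points inside the band. All later
#' measurements of the subject are referenced to this object.
#'
#' @param sweep The subject's baseline sweep; if a `time_h` column is
#'   present it must be 0.
#' @return A one-row tibble of class `abcpe_baseline`: the band summary
#'   columns plus `mean_amp_db`.
#' @export
extract_baseline <- function(sweep) {
  sweep <- validate_sweep(sweep)
  if ("time_h" %in% names(sweep) && any(sweep$time_h != 0)) {
    abort("Baseline must be the record at time_h == 0.",
          class = "abcpe_error_validation")
  }
  band <- find_3db_band(sweep)
  band$mean_amp_db <- band_mean(sweep, band$f_lower_hz, band$f_upper_hz)
  class(band) <- c("abcpe_baseline", class(band))
  band
}

#' Extract the five characteristic parameters for one measurement
#'
#' Computes alpha, beta, gamma, delta and rho for a sweep measured at time
#' t_i, relative to the subject's baseline reference (see the package
#' overview for the defining ratios). delta averages the current sweep over
#' the *baseline* band F0; rho averages it over the *current* band F_i, so
#' the two coincide whenever the band does not move.
#'
#' @param sweep The sweep at time t_i, on the same frequency grid as the
#'   baseline record.
#' @param baseline Result of [extract_baseline()] for the same subject.
#' @return A one-row tibble: `alpha`, `beta`, `gamma`, `delta`, `rho`.
#' @export
extract_parameters <- function(sweep, baseline) {
  sweep <- validate_sweep(sweep)
  if (!inherits(baseline, "abcpe_baseline")) {
    abort("`baseline` must be the result of extract_baseline().",
          class = "abcpe_error_validation")
  }
  if (baseline$peak_amp_db == 0 || baseline$mean_amp_db == 0 ||
      baseline$peak_freq_hz == 0 || baseline$bandwidth_hz == 0) {
    abort("Degenerate baseline: A0, abar_0, f0 and F0 must all be nonzero.",
          class = "abcpe_error_degenerate")
  }
  band_i <- find_3db_band(sweep)
  abar_i <- band_mean(sweep, baseline$f_lower_hz, baseline$f_upper_hz)
  abar_i_prime <- band_mean(sweep, band_i$f_lower_hz, band_i$f_upper_hz)
  tibble(
    alpha = (band_i$peak_amp_db - baseline$peak_amp_db) / baseline$peak_amp_db,
    beta  = (band_i$peak_freq_hz - baseline$peak_freq_hz) / baseline$peak_freq_hz,
    gamma = (band_i$bandwidth_hz - baseline$bandwidth_hz) / baseline$bandwidth_hz,
    delta = (abar_i - baseline$mean_amp_db) / baseline$mean_amp_db,
    rho   = (abar_i_prime - baseline$mean_amp_db) / baseline$mean_amp_db
  )
}

#' Extract characteristic parameters for every record of a cohort
#'
#' For each subject, builds the baseline reference from the `time_h == 0`
#' record and extracts the five parameters for every later record against
#' it. Records whose band extraction fails (e.g. the half-power level is
#' not reached inside the sweep range) are collected into a per-record
#' error report attached as `attr(result, "errors")` and reported via a
#' single warning; they never abort the whole cohort.
#'
#' @param cohort A validated long-format cohort table (see
#'   [validate_cohort()]).
#' @return A tibble with one row per non-baseline record, columns
#'   `subject`, `group`, `time_h`, `alpha`, `beta`, `gamma`, `delta`,
#'   `rho`, ordered by subject then time. The error report (columns
#'   `subject`, `time_h`, `message`) is attached as attribute `"errors"`.
#' @export
extract_series <- function(cohort) {
  cohort <- validate_cohort(cohort)
  errors <- list()
  rows <- list()
  for (subj in unique(cohort$subject)) {
    sub <- cohort[cohort$subject == subj, ]
    grp <- sub$group[[1]]
    baseline <- tryCatch(
      extract_baseline(sub[sub$time_h == 0, c("freq_hz", "amp_db")]),
      error = function(e) e
    )
    times <- setdiff(sort(unique(sub$time_h)), 0)
    if (inherits(baseline, "error")) {
      errors[[length(errors) + 1L]] <-
        tibble(subject = subj, time_h = 0,
               message = conditionMessage(baseline))
      next
    }
    for (t_i in times) {
      sweep <- sub[sub$time_h == t_i, c("freq_hz", "amp_db")]
      params <- tryCatch(extract_parameters(sweep, baseline),
                         error = function(e) e)
      if (inherits(params, "error")) {
        errors[[length(errors) + 1L]] <-
          tibble(subject = subj, time_h = t_i,
                 message = conditionMessage(params))
      } else {
        rows[[length(rows) + 1L]] <-
          dplyr::bind_cols(tibble(subject = subj, group = grp,
                                  time_h = t_i), params)
      }
    }
  }
  out <- if (length(rows) > 0) {
    purrr::list_rbind(rows) |> dplyr::arrange(.data$subject, .data$time_h)
  } else {
    tibble(subject = character(), group = character(), time_h = double(),
           alpha = double(), beta = double(), gamma = double(),
           delta = double(), rho = double())
  }
  err_tbl <- if (length(errors) > 0) {
    purrr::list_rbind(errors)
  } else {
    tibble(subject = character(), time_h = double(), message = character())
  }
  if (nrow(err_tbl) > 0) {
    warn(paste0(nrow(err_tbl), " record(s) failed parameter extraction; ",
                "see attr(result, \"errors\")."))
  }
  attr(out, "errors") <- err_tbl
  out
}
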