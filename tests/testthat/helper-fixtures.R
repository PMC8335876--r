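## Fixture builders. Sweeps are built from the closed-form Lorentzian
## line shape written out here (not via the package simulator) so that
## extraction oracles run on inputs the package code never touched.

lorentz_db <- function(freq, peak_db, f_center, fwhm, floor_db = -120) {
  p_peak <- 10^(peak_db / 10)
  p_floor <- 10^(floor_db / 10)
  10 * log10(p_floor + (p_peak - p_floor) /
               (1 + (2 * (freq - f_center) / fwhm)^2))
}

## -3 dB full width of that shape with a negligible floor: slightly
## narrower than the half-power (-3.0103 dB) width fwhm.
three_db_width <- function(fwhm) fwhm * sqrt(10^0.3 - 1)

make_sweep <- function(n = 201, f_min = 1e6, f_max = 100e6,
                       peak_db = -20, f_center = 50e6, fwhm = 10e6,
                       noise_db = 0, floor_db = -120) {
  freq <- seq(f_min, f_max, length.out = n)
  amp <- lorentz_db(freq, peak_db, f_center, fwhm, floor_db)
  if (noise_db > 0) amp <- amp + rnorm(n, 0, noise_db)
  tibble::tibble(freq_hz = freq, amp_db = amp)
}

random_sweep <- function() {
  make_sweep(
    n = sample(150:400, 1),
    peak_db = runif(1, -30, -10),
    f_center = runif(1, 30e6, 70e6),
    fwhm = runif(1, 4e6, 15e6),
    noise_db = runif(1, 0, 0.05)
  )
}

## Minimal long-format cohort: one Lorentzian per subject/time with a
## small deterministic drift for Exp subjects.
make_cohort <- function(n_exp = 2, n_con = 1, times = c(0, 6, 12, 24),
                        n_freq = 101) {
  rows <- list()
  subjects <- c(sprintf("E%d", seq_len(n_exp)), sprintf("C%d", seq_len(n_con)))
  groups <- c(rep("Exp", n_exp), rep("Con", n_con))
  for (s in seq_along(subjects)) {
    for (t in times) {
      drift <- if (groups[s] == "Exp") t / 24 else 0
      sw <- make_sweep(n = n_freq, peak_db = -20 + drift,
                       f_center = 50e6 * (1 + 0.01 * drift),
                       fwhm = 10e6 * (1 + 0.2 * drift))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = subjects[s], group = groups[s], time_h = t,
        freq_hz = sw$freq_hz, amp_db = sw$amp_db)
    }
  }
  dplyr::bind_rows(rows)
}

## A hand-written 2-port Touchstone file in the given numeric format.
write_ts_fixture <- function(path, freq, s21_db, format = "DB",
                             unit = "HZ") {
  factor <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[[unit]]
  mag <- 10^(s21_db / 20)
  pair <- switch(format,
    DB = cbind(s21_db, 0),
    MA = cbind(mag, 0),
    RI = cbind(mag, 0)) # phase 0: real part = magnitude
  filler <- switch(format, DB = "-200 0", MA = "1e-10 0", RI = "1e-10 0")
  lines <- c(paste("#", unit, "S", format, "R 50"),
             sprintf("%.15g %s %.15g %.15g %s %s",
                     freq / factor, filler, pair[, 1], pair[, 2],
                     filler, filler))
  writeLines(lines, path)
  path
}
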