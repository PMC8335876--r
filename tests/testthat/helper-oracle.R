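## Independent brute-force re-implementations used as oracles. Explicit
## loops throughout; no code shared with the package internals.

naive_peak <- function(freq, amp) {
  best <- 1
  for (i in seq_along(amp)) {
    if (amp[i] > amp[best]) best <- i
  }
  list(amp = amp[best], freq = freq[best], idx = best)
}

## Innermost -3 dB crossings by outward walk + linear interpolation.
naive_band <- function(freq, amp, drop_db = 3) {
  pk <- naive_peak(freq, amp)
  level <- pk$amp - drop_db
  lo <- NA_real_
  for (j in seq(pk$idx - 1, 1)) {
    if (pk$idx == 1) break
    if (amp[j] < level) {
      lo <- freq[j] + (level - amp[j]) / (amp[j + 1] - amp[j]) *
        (freq[j + 1] - freq[j])
      break
    }
  }
  hi <- NA_real_
  if (pk$idx < length(amp)) {
    for (j in seq(pk$idx + 1, length(amp))) {
      if (amp[j] < level) {
        hi <- freq[j] + (level - amp[j]) / (amp[j - 1] - amp[j]) *
          (freq[j - 1] - freq[j])
        break
      }
    }
  }
  if (is.na(lo) || is.na(hi)) stop("naive_band: level not crossed")
  n <- 0
  tol <- 1e-9 * max(abs(lo), abs(hi))
  for (f in freq) if (f >= lo - tol && f <= hi + tol) n <- n + 1
  list(peak_amp = pk$amp, peak_freq = pk$freq,
       f_lo = lo, f_hi = hi, bw = hi - lo, n = n)
}

naive_band_mean <- function(freq, amp, f_lo, f_hi) {
  s <- 0
  n <- 0
  tol <- 1e-9 * max(abs(f_lo), abs(f_hi))
  for (i in seq_along(freq)) {
    if (freq[i] >= f_lo - tol && freq[i] <= f_hi + tol) {
      s <- s + amp[i]
      n <- n + 1
    }
  }
  if (n == 0) stop("naive_band_mean: empty band")
  s / n
}

## All five characteristic parameters of `sweep_i` against `sweep_0`.
naive_params <- function(freq, amp0, amp_i) {
  b0 <- naive_band(freq, amp0)
  abar0 <- naive_band_mean(freq, amp0, b0$f_lo, b0$f_hi)
  bi <- naive_band(freq, amp_i)
  abar_i <- naive_band_mean(freq, amp_i, b0$f_lo, b0$f_hi)
  abar_i_prime <- naive_band_mean(freq, amp_i, bi$f_lo, bi$f_hi)
  c(alpha = (bi$peak_amp - b0$peak_amp) / b0$peak_amp,
    beta  = (bi$peak_freq - b0$peak_freq) / b0$peak_freq,
    gamma = (bi$bw - b0$bw) / b0$bw,
    delta = (abar_i - abar0) / abar0,
    rho   = (abar_i_prime - abar0) / abar0)
}

## Tie-aware Mann-Whitney pair statistic: (concordant + ties/2) / (np*nn).
naive_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}
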