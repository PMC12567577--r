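# Independent oracles and small fixture builders used across test files.

# Brute-force within-subject 2x2 sums of squares, written as explicit loops
# over subjects and factor levels (independent of the package's decomposition).
brute_force_ss <- function(tab) {
  n <- nrow(tab)
  y <- array(NA_real_, c(n, 2, 2)) # subject x time x limb
  y[, 1, 1] <- tab[, "PRE.dominant"]
  y[, 2, 1] <- tab[, "POST.dominant"]
  y[, 1, 2] <- tab[, "PRE.nondominant"]
  y[, 2, 2] <- tab[, "POST.nondominant"]
  gm <- mean(y)
  ss <- list(time = 0, limb = 0, txl = 0, ts = 0, ls = 0, tls = 0)
  tm <- sapply(1:2, function(j) mean(y[, j, ]))
  lm_ <- sapply(1:2, function(k) mean(y[, , k]))
  sm <- sapply(1:n, function(i) mean(y[i, , ]))
  for (j in 1:2) ss$time <- ss$time + 2 * n * (tm[j] - gm)^2
  for (k in 1:2) ss$limb <- ss$limb + 2 * n * (lm_[k] - gm)^2
  for (j in 1:2) {
    for (k in 1:2) {
      cjk <- mean(y[, j, k])
      ss$txl <- ss$txl + n * (cjk - tm[j] - lm_[k] + gm)^2
    }
  }
  for (i in 1:n) {
    for (j in 1:2) {
      stij <- mean(y[i, j, ])
      ss$ts <- ss$ts + 2 * (stij - sm[i] - tm[j] + gm)^2
    }
    for (k in 1:2) {
      slik <- mean(y[i, , k])
      ss$ls <- ss$ls + 2 * (slik - sm[i] - lm_[k] + gm)^2
    }
    for (j in 1:2) {
      for (k in 1:2) {
        cjk <- mean(y[, j, k])
        stij <- mean(y[i, j, ])
        slik <- mean(y[i, , k])
        ss$tls <- ss$tls +
          (y[i, j, k] - stij - slik - cjk + sm[i] + tm[j] + lm_[k] - gm)^2
      }
    }
  }
  ss
}

random_measure_table <- function(n) {
  matrix(rnorm(n * 4), n, 4, dimnames = list(
    sprintf("P%02d", seq_len(n)),
    c("PRE.dominant", "POST.dominant", "PRE.nondominant", "POST.nondominant")
  ))
}

# A trial whose magnitude is gravity plus a pure sinusoid of given amplitude.
sinusoid_trial <- function(f0, amplitude = 0.1, fs = 100, duration = 15,
                           participant = "P1", limb = "dominant", condition = "PRE") {
  t <- (seq_len(fs * duration) - 1) / fs
  triaxial_trial(participant, limb, condition, fs,
    ax = rep(0, length(t)), ay = rep(0, length(t)),
    az = 9.81 + amplitude * sin(2 * pi * f0 * t)
  )
}

# Amplitude and phase of a sinusoid at f0 in a series, by least squares on the
# central samples (edges excluded to keep the fit clear of filter transients).
fit_sinusoid <- function(values, fs, f0, edge = 200) {
  n <- length(values)
  keep <- (edge + 1):(n - edge)
  t <- (keep - 1) / fs
  s <- sin(2 * pi * f0 * t)
  c_ <- cos(2 * pi * f0 * t)
  co <- coef(lm(values[keep] ~ s + c_))
  list(
    amplitude = sqrt(co[["s"]]^2 + co[["c_"]]^2),
    phase = atan2(co[["c_"]], co[["s"]])
  )
}

# Demeaned-stage wrapper for raw numeric vectors.
as_demeaned <- function(x, fs = 100) magnitude_series(x, fs, stage = "demeaned")

# Hand-built spectral estimate on a 0.1 Hz grid (for index-level tests).
fake_spectrum <- function(psd, fs = 100, n = 1000) {
  structure(
    list(
      frequencies = (seq_along(psd) - 1) * fs / n, psd = psd,
      n_samples = n, sampling_rate = fs, window = "synthetic", stage = "lowpassed",
      provenance = NULL
    ),
    class = "spectral_estimate"
  )
}
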