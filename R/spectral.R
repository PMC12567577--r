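#' @title Spectral estimation and band indices
#' @name spectral
#' @description One-sided Welch PSD with a single full-length Hamming window
#'   (zero overlap, i.e. one modified periodogram) and the two band indices:
#'   L(f1,f2), the band-average natural-log PSD, and F(f1,f2), the
#'   power-weighted mean frequency.
NULL

#' Analysis band
#'
#' The two bands of interest are 2-4 Hz (slow, mechanical/reflex tremor,
#' analysed on the low-pass branch) and 10-20 Hz (classical physiological
#' tremor, high-pass branch). The band/branch pairing is fixed.
#'
#' @param f1,f2 Band edges in Hz, 0 < f1 < f2.
#' @param label Short label for reports.
#' @param source_branch Stage tag of the filter branch the band is read from.
#' @return A `band` object.
#' @export
band <- function(f1, f2, label = sprintf("%g-%g", f1, f2),
                 source_branch = c("lowpassed", "highpassed")) {
  source_branch <- match.arg(source_branch)
  if (!(0 < f1 && f1 < f2)) stop("band requires 0 < f1 < f2", call. = FALSE)
  structure(list(f1 = f1, f2 = f2, label = label, source_branch = source_branch),
    class = "band"
  )
}

#' @rdname band
#' @export
band_low <- function() band(2, 4, "2-4", "lowpassed")

#' @rdname band
#' @export
band_high <- function() band(10, 20, "10-20", "highpassed")

#' Welch power spectral density, single full-length Hamming window
#'
#' With one window spanning the whole segment and zero overlap, Welch's method
#' reduces to a single modified periodogram. The estimate is one-sided and
#' density-scaled with window power correction (divide by fs * sum(w^2)), so
#' sum(psd) * df equals the variance of the windowed input. No internal
#' detrending is applied: the series is demeaned upstream.
#'
#' @param series A `magnitude_series` at stage `"demeaned"`, `"lowpassed"` or
#'   `"highpassed"`.
#' @return A `spectral_estimate` with `frequencies` (0 to fs/2, step fs/N) and
#'   `psd` in (m/s^2)^2/Hz.
#' @export
welch_psd <- function(series) {
  require_stage(series, c("demeaned", "lowpassed", "highpassed"), "welch_psd()")
  x <- series$values
  n <- length(x)
  if (n < 16L) stop("welch_psd() needs at least 16 samples", call. = FALSE)
  fs <- series$sampling_rate
  w <- signal::hamming(n)
  X <- stats::fft(w * x)
  n_half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(n_half)])^2 / (fs * sum(w^2))
  # fold negative frequencies onto positive ones (DC and Nyquist are unique)
  dbl <- 2:(n_half - if (n %% 2 == 0) 1L else 0L)
  p[dbl] <- 2 * p[dbl]
  structure(
    list(
      frequencies = (seq_len(n_half) - 1) * fs / n,
      psd = p,
      n_samples = n,
      sampling_rate = fs,
      window = sprintf("hamming(%d), overlap 0", n),
      stage = series$stage,
      provenance = series$provenance
    ),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d bins, df = %g Hz, window %s\n",
    length(x$psd), x$sampling_rate / x$n_samples, x$window
  ))
  invisible(x)
}

band_bins <- function(spec, band) {
  idx <- which(spec$frequencies >= band$f1 - 1e-9 & spec$frequencies <= band$f2 + 1e-9)
  if (length(idx) < 2L) {
    stop(sprintf("band %s contains fewer than 2 spectral bins", band$label),
      call. = FALSE
    )
  }
  idx
}

#' Band log-amplitude indicator L(f1, f2)
#'
#' Mean of the natural logarithm of the PSD over the band:
#' L = 1/|f2 - f1| * integral of ln PSD(f) over f1..f2, evaluated by the
#' trapezoidal rule on the spectral grid restricted to the band (edges
#' inclusive). PSD values below `floor` are clamped so ln 0 never occurs.
#'
#' @param spec A `spectral_estimate`.
#' @param band A [band()].
#' @param floor PSD floor in (m/s^2)^2/Hz (default 1e-20); a warning reports
#'   how many bins were clamped when any are.
#' @return L in natural-log units.
#' @export
band_log_amplitude <- function(spec, band, floor = 1e-20) {
  idx <- band_bins(spec, band)
  f <- spec$frequencies[idx]
  p <- spec$psd[idx]
  n_floored <- sum(p < floor)
  if (n_floored > 0) {
    warning(sprintf(
      "band %s: %d PSD bin(s) below the floor %g were clamped",
      band$label, n_floored, floor
    ), call. = FALSE)
    p <- pmax(p, floor)
  }
  pracma::trapz(f, log(p)) / (f[length(f)] - f[1L])
}

#' Band mean frequency F(f1, f2)
#'
#' Power-weighted spectral centroid: integral of f * PSD(f) over the band
#' divided by the integral of PSD(f), both by the trapezoidal rule on the
#' grid. Always lies inside `[f1, f2]`.
#'
#' @inheritParams band_log_amplitude
#' @return F in Hz.
#' @export
band_mean_frequency <- function(spec, band) {
  idx <- band_bins(spec, band)
  f <- spec$frequencies[idx]
  p <- spec$psd[idx]
  denom <- pracma::trapz(f, p)
  if (!is.finite(denom) || denom <= 0) {
    stop(sprintf("band %s has zero total power: mean frequency undefined", band$label),
      call. = FALSE
    )
  }
  pracma::trapz(f, f * p) / denom
}

#' Extract band indices from one raw trial
#'
#' Runs the full fixed chain: magnitude -> trim -> demean -> dual-branch
#' zero-phase Butterworth filter -> Welch PSD -> (L, F) per band. The 2-4 Hz
#' band is read from the low-pass branch, the 10-20 Hz band from the
#' high-pass branch.
#'
#' @param trial A [triaxial_trial()].
#' @param trim_seconds Initial seconds discarded (default 5).
#' @param cutoff Branch-split cutoff in Hz (default 10).
#' @param design_order Single-pass Butterworth order (default 2).
#' @param bands List of two [band()]s (defaults: [band_low()], [band_high()]).
#' @param floor PSD floor passed to [band_log_amplitude()].
#' @param expected_duration Warn when the trial is shorter than this (s).
#' @return A tibble with one row per band: participant, limb, condition,
#'   band, L, F.
#' @export
extract_indices <- function(trial, trim_seconds = 5, cutoff = 10, design_order = 2,
                            bands = list(band_low(), band_high()),
                            floor = 1e-20, expected_duration = 15) {
  if (trial_duration(trial) < expected_duration) {
    warning(sprintf(
      "trial %s/%s/%s is %.3g s long; %g s expected",
      trial$participant, trial$limb, trial$condition,
      trial_duration(trial), expected_duration
    ), call. = FALSE)
  }
  ready <- demean(trim_initial(magnitude(trial), trim_seconds))
  branch <- list(
    lowpassed = filter_zero_phase(ready, filter_spec("lowpass", cutoff, design_order)),
    highpassed = filter_zero_phase(ready, filter_spec("highpass", cutoff, design_order))
  )
  spec_cache <- lapply(branch, welch_psd)
  rows <- lapply(bands, function(b) {
    sp <- spec_cache[[b$source_branch]]
    quick_tbl(
      participant = trial$participant,
      limb = trial$limb,
      condition = trial$condition,
      band = b$label,
      L = band_log_amplitude(sp, b, floor = floor),
      F = band_mean_frequency(sp, b)
    )
  })
  bind_tbl(rows)
}
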