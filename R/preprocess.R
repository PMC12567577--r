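#' @title Preprocessing: magnitude, trim, demean, zero-phase filtering
#' @name preprocess
#' @description Reduces a tri-axial trial to the analysis-ready scalar series.
#'   The pipeline order is fixed and enforced through stage tags:
#'   magnitude -> trim -> demean -> filter (low-pass or high-pass branch).
NULL

STAGE_LEVELS <- c("raw_magnitude", "trimmed", "demeaned", "lowpassed", "highpassed")

#' Construct a magnitude series
#'
#' @param values Numeric vector (m/s^2 for the raw magnitude stage).
#' @param sampling_rate Sampling rate in Hz.
#' @param stage One of `"raw_magnitude"`, `"trimmed"`, `"demeaned"`,
#'   `"lowpassed"`, `"highpassed"`; records where in the fixed pipeline the
#'   series sits, so out-of-order processing is a contract violation.
#' @param provenance Optional list (participant, limb, condition).
#' @return A `magnitude_series` object.
#' @export
magnitude_series <- function(values, sampling_rate, stage, provenance = NULL) {
  stage <- match.arg(stage, STAGE_LEVELS)
  if (!all(is.finite(values))) stop("non-finite values in magnitude series", call. = FALSE)
  if (stage == "raw_magnitude" && any(values < 0)) {
    stop("raw magnitude values must be >= 0", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  structure(
    list(
      values = as.numeric(values), sampling_rate = sampling_rate,
      stage = stage, provenance = provenance
    ),
    class = "magnitude_series"
  )
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf(
    "<magnitude_series:%s> %d samples @ %g Hz\n",
    x$stage, length(x$values), x$sampling_rate
  ))
  invisible(x)
}

require_stage <- function(series, allowed, op) {
  if (!series$stage %in% allowed) {
    stop(sprintf(
      "%s expects a series at stage %s, got '%s' (pipeline order is magnitude -> trim -> demean -> filter)",
      op, paste(sQuote(allowed), collapse = " or "), series$stage
    ), call. = FALSE)
  }
  invisible(series)
}

#' Total acceleration magnitude of a trial
#'
#' Elementwise Euclidean norm sqrt(ax^2 + ay^2 + az^2); the scalar series all
#' later stages operate on.
#'
#' @param trial A [triaxial_trial()].
#' @return A `magnitude_series` at stage `"raw_magnitude"`.
#' @export
magnitude <- function(trial) {
  stopifnot(inherits(trial, "triaxial_trial"))
  magnitude_series(
    sqrt(trial$ax^2 + trial$ay^2 + trial$az^2),
    trial$sampling_rate,
    stage = "raw_magnitude",
    provenance = list(
      participant = trial$participant, limb = trial$limb,
      condition = trial$condition
    )
  )
}

#' Drop the initial adaptation transient
#'
#' Removes the first `drop_seconds` of the recording (round(drop_seconds * fs)
#' samples), retaining the stationary tail: a 15-s trial at 100 Hz keeps
#' exactly 1000 samples.
#'
#' @param series A raw magnitude series.
#' @param drop_seconds Seconds to discard from the start (default 5).
#' @return The trimmed series (stage `"trimmed"`).
#' @export
trim_initial <- function(series, drop_seconds = 5) {
  require_stage(series, "raw_magnitude", "trim_initial()")
  n <- length(series$values)
  dur <- n / series$sampling_rate
  if (dur <= drop_seconds) {
    stop(sprintf(
      "trial duration %.3g s must exceed drop_seconds = %g s", dur, drop_seconds
    ), call. = FALSE)
  }
  n_drop <- round(drop_seconds * series$sampling_rate)
  out <- series
  out$values <- series$values[(n_drop + 1L):n]
  out$stage <- "trimmed"
  out
}

#' Remove the DC offset
#'
#' Subtracts the arithmetic mean (chiefly the ~9.81 m/s^2 gravity component of
#' the magnitude) so the spectrum reflects oscillatory content only.
#'
#' @param series A trimmed magnitude series.
#' @return The demeaned series (stage `"demeaned"`).
#' @export
demean <- function(series) {
  require_stage(series, "trimmed", "demean()")
  out <- series
  out$values <- series$values - mean(series$values)
  out$stage <- "demeaned"
  out
}

#' Butterworth filter specification
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency in Hz (default 10, the branch split).
#' @param design_order Order of the single-pass design (default 2). Zero-phase
#'   application squares the magnitude response, so the net attenuation is
#'   that of a 4th-order filter with zero net phase.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff = 10, design_order = 2) {
  kind <- match.arg(kind)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (design_order < 1) stop("design_order must be >= 1", call. = FALSE)
  structure(
    list(kind = kind, cutoff = cutoff, design_order = as.integer(design_order),
         zero_phase = TRUE),
    class = "filter_spec"
  )
}

# One causal IIR pass, direct form with zero initial conditions; the FIR
# numerator via convolution and the AR denominator via the recursive filter,
# both in compiled code.
iir_pass <- function(b, a, x) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  if (nb > 1L) {
    v <- stats::filter(c(rep(0, nb - 1L), x), b, method = "convolution", sides = 1L)
    v <- as.numeric(v)[-seq_len(nb - 1L)]
  } else {
    v <- b * x
  }
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Zero-phase Butterworth filtering (forward-backward)
#'
#' Applies the designed filter forward then backward in time so the net phase
#' response is zero and the net magnitude response is |H(f)|^2 of the
#' single-pass design. Edge transients are suppressed by odd-reflection
#' padding of the signal before filtering.
#'
#' @param series A demeaned magnitude series.
#' @param spec A [filter_spec()].
#' @param pad_len Reflection padding length in samples; default one second of
#'   signal (bounded by series length - 1), well above the 3 x order minimum,
#'   because 2 Hz transients are long relative to a 1000-sample segment.
#' @return The filtered series (stage `"lowpassed"` or `"highpassed"`).
#' @export
filter_zero_phase <- function(series, spec, pad_len = NULL) {
  require_stage(series, "demeaned", "filter_zero_phase()")
  stopifnot(inherits(spec, "filter_spec"))
  fs <- series$sampling_rate
  if (spec$cutoff >= fs / 2) {
    stop(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                 spec$cutoff, fs / 2), call. = FALSE)
  }
  x <- series$values
  n <- length(x)
  if (is.null(pad_len)) pad_len <- min(n - 1L, round(fs))
  pad_len <- max(pad_len, 3L * spec$design_order)
  pad_len <- min(pad_len, n - 1L)
  bt <- butter_design(spec$design_order, spec$cutoff / (fs / 2),
    type = if (spec$kind == "lowpass") "low" else "high"
  )
  # odd reflection about the end points
  head_pad <- 2 * x[1L] - x[(pad_len + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad_len)]
  xx <- c(head_pad, x, tail_pad)
  y <- iir_pass(bt$b, bt$a, xx)
  y <- rev(iir_pass(bt$b, bt$a, rev(y)))
  out <- series
  out$values <- y[(pad_len + 1L):(pad_len + n)]
  out$stage <- if (spec$kind == "lowpass") "lowpassed" else "highpassed"
  out
}

#' Theoretical zero-phase Butterworth magnitude gain
#'
#' Closed-form amplitude gain of the digital (bilinear-transform,
#' prewarped-cutoff) Butterworth design applied forward and backward:
#' with r = tan(pi f / fs) / tan(pi fc / fs), a single pass has
#' |H|^2 = 1 / (1 + r^(2k)) (low-pass) or r^(2k) / (1 + r^(2k)) (high-pass),
#' and the zero-phase amplitude gain is |H|^2.
#'
#' @param f Frequencies in Hz.
#' @param cutoff Cutoff in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param design_order Single-pass order (default 2).
#' @return Amplitude gain of the forward-backward filter at `f`.
#' @export
butter_zero_phase_gain <- function(f, cutoff, sampling_rate,
                                   kind = c("lowpass", "highpass"),
                                   design_order = 2) {
  kind <- match.arg(kind)
  r <- tan(pi * f / sampling_rate) / tan(pi * cutoff / sampling_rate)
  h2 <- if (kind == "lowpass") {
    1 / (1 + r^(2 * design_order))
  } else {
    r^(2 * design_order) / (1 + r^(2 * design_order))
  }
  h2 # amplitude gain after two passes = |H|^2
}
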