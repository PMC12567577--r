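#' @title Reading and writing accelerometer trials and cohort manifests
#' @name signal_io
#' @description Plain-text I/O for tri-axial trials (CSV/TSV, comma or tab
#'   autodetected, optional header and optional leading time column) and for
#'   cohort manifests mapping files to the participant x limb x condition
#'   design cells.
NULL

LIMB_LEVELS <- c("dominant", "nondominant")
CONDITION_LEVELS <- c("PRE", "POST")

canonical_limb <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  out <- ifelse(key %in% c("dominant", "dom", "d"), "dominant",
    ifelse(key %in% c("nondominant", "nondom", "nd", "n"), "nondominant", NA_character_)
  )
  if (anyNA(out)) {
    stop("unknown limb token(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
      " (expected dominant/nondominant)",
      call. = FALSE
    )
  }
  out
}

canonical_condition <- function(x) {
  key <- toupper(trimws(x))
  if (!all(key %in% CONDITION_LEVELS)) {
    stop("unknown condition token(s): ",
      paste(unique(x[!key %in% CONDITION_LEVELS]), collapse = ", "),
      " (expected PRE/POST)",
      call. = FALSE
    )
  }
  key
}

#' Construct a tri-axial accelerometer trial
#'
#' A trial is one raw recording of the three acceleration axes (m/s^2) at a
#' uniform sampling rate, labelled with its design cell (participant, limb,
#' condition).
#'
#' @param participant Participant identifier (opaque string).
#' @param limb `"dominant"` or `"nondominant"` (case-insensitive, punctuation
#'   ignored, so `"non-dominant"` is accepted).
#' @param condition `"PRE"` or `"POST"` (case-insensitive).
#' @param sampling_rate Sampling rate in Hz (nominal 100).
#' @param ax,ay,az Numeric acceleration vectors in m/s^2, equal length.
#' @return An object of class `triaxial_trial`.
#' @export
triaxial_trial <- function(participant, limb, condition, sampling_rate, ax, ay, az) {
  stopifnot(is.numeric(ax), is.numeric(ay), is.numeric(az))
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n) {
    stop("ax, ay, az must have identical length >= 1", call. = FALSE)
  }
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az))) {
    stop("non-finite acceleration values in trial", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(
      participant = as.character(participant),
      limb = canonical_limb(limb),
      condition = canonical_condition(condition),
      sampling_rate = sampling_rate,
      ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)
    ),
    class = "triaxial_trial"
  )
}

#' @export
print.triaxial_trial <- function(x, ...) {
  cat(sprintf(
    "<triaxial_trial> %s / %s / %s: %d samples @ %g Hz (%.2f s)\n",
    x$participant, x$limb, x$condition, length(x$ax), x$sampling_rate,
    length(x$ax) / x$sampling_rate
  ))
  invisible(x)
}

#' Trial duration in seconds
#' @param trial A `triaxial_trial`.
#' @return Duration in seconds.
#' @export
trial_duration <- function(trial) {
  length(trial$ax) / trial$sampling_rate
}

#' Read a tri-axial trial from a delimited text file
#'
#' Accepts comma- or tab-separated files with an optional header, either three
#' numeric columns (ax, ay, az) or four (time, ax, ay, az). When a time column
#' is present the median sampling interval must match `sampling_rate` within
#' 1%. Values may be recorded in g and converted explicitly via `units`.
#'
#' @param path File path.
#' @param participant,limb,condition Design-cell metadata attached to the trial.
#' @param sampling_rate Nominal sampling rate in Hz.
#' @param units `"ms2"` (default, no conversion) or `"g"` (values multiplied by
#'   9.81). Units are never guessed: a silent g/ms2 mix-up would shift every
#'   log-PSD level by ln(9.81^2), about 4.57.
#' @return A [triaxial_trial()].
#' @export
read_trial <- function(path, participant, limb, condition,
                       sampling_rate = 100, units = c("ms2", "g")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, header = "auto", sep = "auto", fill = FALSE,
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) {
      stop("failed to parse trial file ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (ncol(dt) < 3L) {
    stop("trial file ", path, " must have 3 (ax,ay,az) or 4 (time,ax,ay,az) columns",
      call. = FALSE
    )
  }
  if (ncol(dt) > 4L) dt <- dt[, seq_len(4L)]
  non_num <- !vapply(dt, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric column(s) in trial file ", path, ": ",
      paste(names(dt)[non_num], collapse = ", "),
      call. = FALSE
    )
  }
  if (ncol(dt) == 4L) {
    tcol <- dt[[1L]]
    if (length(tcol) > 1L) {
      dt_med <- stats::median(diff(tcol))
      if (!is.finite(dt_med) || abs(dt_med - 1 / sampling_rate) > 0.01 / sampling_rate) {
        stop(sprintf(
          "sampling interval in %s (median %.6g s) does not match 1/%g s within 1%%",
          path, dt_med, sampling_rate
        ), call. = FALSE)
      }
    }
    dt <- dt[, 2:4]
  }
  bad <- !vapply(dt, function(col) all(is.finite(col)), logical(1))
  if (any(bad)) {
    stop("non-finite values in trial file ", path, call. = FALSE)
  }
  scale <- if (units == "g") 9.81 else 1
  triaxial_trial(participant, limb, condition, sampling_rate,
    ax = dt[[1L]] * scale, ay = dt[[2L]] * scale, az = dt[[3L]] * scale
  )
}

#' Write a trial to CSV at full precision
#'
#' Values are formatted with 17 significant digits so a write/read round trip
#' reproduces the samples bit-identically.
#'
#' @param trial A [triaxial_trial()].
#' @param path Output file path.
#' @param time_column Prepend a time column (seconds from 0)?
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, time_column = FALSE) {
  fmt <- function(v) sprintf("%.17g", v)
  cols <- list(ax = fmt(trial$ax), ay = fmt(trial$ay), az = fmt(trial$az))
  if (time_column) {
    t <- (seq_along(trial$ax) - 1) / trial$sampling_rate
    cols <- c(list(time = fmt(t)), cols)
  }
  data.table::fwrite(as.data.frame(cols), path, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header `participant,limb,condition,file`, one row
#' per recorded trial. Duplicate (participant, limb, condition) keys are
#' rejected; limb/condition tokens are canonicalised.
#'
#' @param path Manifest file path.
#' @return A tibble of class `cohort_manifest` with canonical factor columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  needed <- c("participant", "limb", "condition", "file")
  if (!all(needed %in% names(dt))) {
    stop("manifest must have columns ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  as_manifest(dt[, needed])
}

#' Coerce a data frame to a cohort manifest
#' @param df Data frame with columns participant, limb, condition, file.
#' @return A `cohort_manifest` tibble.
#' @export
as_manifest <- function(df) {
  m <- tibble::tibble(
    participant = as.character(df$participant),
    limb = canonical_limb(df$limb),
    condition = canonical_condition(df$condition),
    file = as.character(df$file)
  )
  key <- paste(m$participant, m$limb, m$condition, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate (participant, limb, condition) key(s) in manifest: ",
      paste(unique(key[duplicated(key)]), collapse = ", "),
      call. = FALSE
    )
  }
  class(m) <- c("cohort_manifest", class(m))
  m
}

#' Check a manifest for missing design cells
#'
#' Every participant is expected in all four limb x condition cells.
#'
#' @param manifest A `cohort_manifest`.
#' @return A tibble with one row per participant missing at least one cell and
#'   a `missing` column listing the absent cells; zero rows when complete.
#' @export
manifest_completeness <- function(manifest) {
  cells <- as.vector(outer(CONDITION_LEVELS, LIMB_LEVELS, paste, sep = "."))
  have <- paste(manifest$condition, manifest$limb, sep = ".")
  out <- lapply(split(have, manifest$participant), function(h) {
    setdiff(cells, h)
  })
  miss <- Filter(length, out)
  tibble::tibble(
    participant = names(miss),
    missing = vapply(miss, paste, character(1), collapse = ";")
  )
}
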