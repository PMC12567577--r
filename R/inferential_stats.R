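#' @title Within-subject inference: 2x2 repeated-measures ANOVA and contrasts
#' @name inferential_stats
#' @description The statistical layer for the 2 (time: PRE/POST) x 2 (limb:
#'   dominant/non-dominant) within-subject design: normality screening,
#'   classical repeated-measures sums-of-squares decomposition with
#'   Greenhouse-Geisser epsilon and partial eta squared, and
#'   Bonferroni-adjusted pairwise paired t contrasts.
NULL

CELLS_2x2 <- c("PRE.dominant", "POST.dominant", "PRE.nondominant", "POST.nondominant")

#' Build the wide 2x2 measure table from a long indices table
#'
#' Participants missing any of the four cells are dropped listwise with a
#' warning naming them.
#'
#' @param indices Long table with columns participant, limb, condition, band
#'   and the measure columns (L, F).
#' @param band_label Band to select (e.g. `"2-4"`).
#' @param measure `"L"` or `"F"`.
#' @return A numeric matrix, rows = participants (rownames), columns =
#'   `PRE.dominant`, `POST.dominant`, `PRE.nondominant`, `POST.nondominant`.
#' @export
measure_table <- function(indices, band_label, measure = c("L", "F")) {
  measure <- match.arg(measure)
  d <- indices[indices$band == band_label, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for band ", band_label, call. = FALSE)
  cell <- paste(d$condition, d$limb, sep = ".")
  wide <- tapply(d[[measure]], list(d$participant, factor(cell, CELLS_2x2)), identity)
  wide <- wide[, CELLS_2x2, drop = FALSE]
  incomplete <- rownames(wide)[!stats::complete.cases(wide)]
  if (length(incomplete) > 0) {
    warning("dropping participant(s) with incomplete cells: ",
      paste(incomplete, collapse = ", "),
      call. = FALSE
    )
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  }
  if (nrow(wide) < 2L) stop("need >= 2 complete participants", call. = FALSE)
  storage.mode(wide) <- "double"
  wide
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the double-centred covariance matrix of the within-factor
#' level scores: epsilon = tr(D)^2 / ((k-1) * sum(D^2)). For a 2-level factor
#' the single difference variance makes epsilon identically 1 — sphericity
#' cannot be violated — so in the 2x2 design the correction never alters the
#' p-value; the general form is implemented and reported anyway.
#'
#' @param scores n x k matrix, one column per factor level.
#' @return Epsilon in \[1/(k-1), 1\].
#' @export
gg_epsilon <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2L) stop("factor needs >= 2 levels", call. = FALSE)
  if (k == 2L) {
    return(1) # a single difference variance: sphericity cannot be violated
  }
  S <- stats::cov(scores)
  D <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  sum(diag(D))^2 / ((k - 1) * sum(D^2))
}

#' Partial eta squared
#'
#' @param ss_effect,ss_error Sums of squares of the effect and of its
#'   effect-by-subject error term.
#' @return SS_effect / (SS_effect + SS_error) in \[0, 1\].
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) stop("sums of squares must be >= 0", call. = FALSE)
  if (ss_effect + ss_error == 0) {
    stop("partial eta squared undefined when both sums of squares are zero",
      call. = FALSE
    )
  }
  ss_effect / (ss_effect + ss_error)
}

#' @rdname partial_eta_squared
#' @param f F statistic.
#' @param df_num,df_den Numerator and denominator degrees of freedom.
#' @export
partial_eta_squared_from_f <- function(f, df_num, df_den) {
  f * df_num / (f * df_num + df_den)
}

#' Cohen's interpretation label for partial eta squared
#'
#' Cut-offs 0.01 / 0.06 / 0.14 for small / medium / large.
#'
#' @param pes Partial eta squared value(s).
#' @return Character label(s).
#' @export
cohen_label <- function(pes) {
  cut(pes,
    breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
    labels = c("negligible", "small", "medium", "large"),
    right = FALSE
  ) |> as.character()
}

#' 2x2 within-subject repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition with each 1-df effect tested
#' against its own effect-by-subject interaction: F = MS_effect /
#' MS_(effect x subject). In this design F(time) equals the squared paired t
#' statistic on the limb-averaged POST-PRE differences.
#'
#' @param table Wide matrix from [measure_table()] (columns `PRE.dominant`,
#'   `POST.dominant`, `PRE.nondominant`, `POST.nondominant`).
#' @return A tibble with one row per effect (time, limb, time:limb): SS_effect,
#'   SS_error, df_num, df_den, F, epsilon (Greenhouse-Geisser), p
#'   (epsilon-corrected df; inert here since epsilon = 1 for 2 levels),
#'   pes (partial eta squared) and Cohen label.
#' @export
rm_anova_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(CELLS_2x2 %in% colnames(table))) {
    stop("table must have columns ", paste(CELLS_2x2, collapse = ", "), call. = FALSE)
  }
  table <- table[, CELLS_2x2, drop = FALSE]
  n <- nrow(table)
  if (n < 2L) stop("need >= 2 participants", call. = FALSE)

  # index helpers: columns are (PRE,dom), (POST,dom), (PRE,nd), (POST,nd)
  time_of <- c(1L, 2L, 1L, 2L) # PRE = 1, POST = 2
  limb_of <- c(1L, 1L, 2L, 2L) # dominant = 1, nondominant = 2
  gm <- mean(table)
  subj <- rowMeans(table)
  t_mean <- vapply(1:2, function(j) mean(table[, time_of == j]), numeric(1))
  l_mean <- vapply(1:2, function(k) mean(table[, limb_of == k]), numeric(1))
  cm <- colMeans(table)
  cell <- matrix(NA_real_, 2, 2) # cell[j, k]: time j, limb k
  for (c_i in seq_len(4L)) cell[time_of[c_i], limb_of[c_i]] <- cm[c_i]
  st <- vapply(1:2, function(j) rowMeans(table[, time_of == j, drop = FALSE]), numeric(n))
  sl <- vapply(1:2, function(k) rowMeans(table[, limb_of == k, drop = FALSE]), numeric(n))

  ss_time <- 2 * n * sum((t_mean - gm)^2)
  ss_limb <- 2 * n * sum((l_mean - gm)^2)
  inter <- outer(t_mean, l_mean, `+`)
  ss_txl <- n * sum((cell - inter + gm)^2)
  ss_ts <- 2 * sum((st - subj - rep(t_mean, each = n) + gm)^2)
  ss_ls <- 2 * sum((sl - subj - rep(l_mean, each = n) + gm)^2)
  resid <- table
  for (c_i in seq_len(4L)) {
    j <- time_of[c_i]; k <- limb_of[c_i]
    resid[, c_i] <- table[, c_i] - st[, j] - sl[, k] - cell[j, k] +
      subj + t_mean[j] + l_mean[k] - gm
  }
  ss_tls <- sum(resid^2)

  eff <- tibble::tibble(
    effect = c("time", "limb", "time:limb"),
    SS_effect = c(ss_time, ss_limb, ss_txl),
    SS_error = c(ss_ts, ss_ls, ss_tls),
    df_num = 1,
    df_den = n - 1
  )
  # GG epsilon per within factor (k = 2 everywhere here, so identically 1)
  eps_time <- gg_epsilon(st)
  eps_limb <- gg_epsilon(sl)
  eff$epsilon <- c(eps_time, eps_limb, min(eps_time, eps_limb))
  eff$F <- ifelse(eff$SS_error == 0,
    ifelse(eff$SS_effect == 0, 0, Inf),
    (eff$SS_effect / eff$df_num) / (eff$SS_error / eff$df_den)
  )
  if (any(is.infinite(eff$F))) {
    warning("zero error sum of squares: F reported as Inf", call. = FALSE)
  }
  eff$p <- stats::pf(eff$F, eff$df_num * eff$epsilon, eff$df_den * eff$epsilon,
    lower.tail = FALSE
  )
  # a fully null effect (both SS zero) has no defined effect size
  eff$pes <- mapply(function(e, r) {
    if (e + r == 0) NA_real_ else partial_eta_squared(e, r)
  }, eff$SS_effect, eff$SS_error)
  eff$cohen <- ifelse(is.na(eff$pes), NA_character_, cohen_label(pmax(eff$pes, 0)))
  eff
}

#' Bonferroni-adjusted pairwise paired t contrasts
#'
#' All six unordered pairs among the four design cells are compared with
#' paired t-tests; adjusted p = min(1, m * p_raw) with m = 6 by default
#' (the family-wise threshold 0.05/6 ~ 0.008). Contrasts with zero-variance
#' difference scores are reported as degenerate rather than dropped.
#'
#' @param table Wide matrix from [measure_table()].
#' @param m Number of comparisons for the Bonferroni factor (default 6).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble with contrast, mean_diff, t, df, p_raw, p_adj, significant
#'   (adjusted p compared against `alpha`, equivalently raw p against
#'   `alpha / m`), degenerate flag.
#' @export
bonferroni_pairwise <- function(table, m = 6, alpha = 0.05) {
  table <- as.matrix(table)[, CELLS_2x2, drop = FALSE]
  pairs <- utils::combn(CELLS_2x2, 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- table[, pr[1L]] - table[, pr[2L]]
    degenerate <- stats::sd(d) == 0
    if (degenerate) {
      tibble::tibble(
        contrast = paste(pr, collapse = " - "),
        mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
        p_raw = NA_real_, p_adj = NA_real_,
        significant = NA, degenerate = TRUE
      )
    } else {
      tt <- stats::t.test(table[, pr[1L]], table[, pr[2L]], paired = TRUE)
      p_adj <- min(1, m * tt$p.value)
      tibble::tibble(
        contrast = paste(pr, collapse = " - "),
        mean_diff = unname(tt$estimate), t = unname(tt$statistic),
        df = unname(tt$parameter),
        p_raw = tt$p.value, p_adj = p_adj,
        significant = p_adj < alpha, degenerate = FALSE
      )
    }
  })
  do.call(rbind, rows)
}

#' Shapiro-Wilk normality screening
#'
#' Advisory screening per design cell (default) or on all pairwise difference
#' scores; the analysis does not branch on the outcome.
#'
#' @param table Wide matrix from [measure_table()].
#' @param on `"cells"` or `"differences"`.
#' @return Tibble with sample label, n, W, p and a degenerate flag for
#'   constant samples.
#' @export
shapiro_screen <- function(table, on = c("cells", "differences")) {
  on <- match.arg(on)
  table <- as.matrix(table)[, CELLS_2x2, drop = FALSE]
  samples <- if (on == "cells") {
    stats::setNames(lapply(CELLS_2x2, function(c_i) table[, c_i]), CELLS_2x2)
  } else {
    pairs <- utils::combn(CELLS_2x2, 2)
    stats::setNames(
      lapply(seq_len(ncol(pairs)), function(i) table[, pairs[1, i]] - table[, pairs[2, i]]),
      apply(pairs, 2, paste, collapse = " - ")
    )
  }
  rows <- lapply(names(samples), function(nm) {
    v <- samples[[nm]]
    if (length(v) < 3L) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
    if (stats::sd(v) == 0) {
      return(tibble::tibble(sample = nm, n = length(v), W = NA_real_,
                            p = NA_real_, degenerate = TRUE))
    }
    sw <- stats::shapiro.test(v)
    tibble::tibble(sample = nm, n = length(v), W = unname(sw$statistic),
                   p = sw$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}
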