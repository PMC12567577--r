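#' @title End-to-end cohort analysis
#' @name pipeline
#' @description Orchestration of the full analysis: extract band indices from
#'   every trial of a cohort (from a manifest on disk or an in-memory list of
#'   trials), then run the descriptive and inferential layer — one 2x2
#'   repeated-measures ANOVA plus pairwise contrasts per band x measure.
NULL

#' Extract band indices for a whole cohort
#'
#' @param x Either a `cohort_manifest` (or path to a manifest CSV) whose
#'   `file` column names trial CSVs, or a list of [triaxial_trial()] objects.
#' @param skip_bad If `TRUE`, unreadable trial files are skipped with a
#'   warning instead of aborting. Default `FALSE`: any unreadable trial aborts
#'   the run naming the file, so no silently partial output is produced.
#' @param ... Passed to [extract_indices()] (bands, trim, cutoff, floor...).
#' @return Long-format tibble: participant, limb, condition, band, L, F — one
#'   row per trial x band.
#' @export
run_extract <- function(x, skip_bad = FALSE, ...) {
  trials <- NULL
  if (is.character(x) && length(x) == 1L) x <- read_manifest(x)
  if (inherits(x, "cohort_manifest")) {
    trials <- vector("list", nrow(x))
    for (i in seq_len(nrow(x))) {
      tr <- tryCatch(
        read_trial(x$file[i], x$participant[i], x$limb[i], x$condition[i]),
        error = function(e) e
      )
      if (inherits(tr, "error")) {
        msg <- sprintf("trial %s (%s/%s/%s) unreadable: %s",
                       x$file[i], x$participant[i], x$limb[i], x$condition[i],
                       conditionMessage(tr))
        if (skip_bad) {
          warning(msg, call. = FALSE)
          next
        }
        stop(msg, call. = FALSE)
      }
      trials[[i]] <- tr
    }
    trials <- Filter(Negate(is.null), trials)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "triaxial_trial"))) {
    trials <- x
  } else {
    stop("x must be a manifest (path or object) or a list of triaxial_trial objects",
      call. = FALSE
    )
  }
  bind_tbl(lapply(trials, extract_indices, ...))
}

#' Descriptive statistics in the publication layout
#'
#' Mean and SD per design cell for each band x measure, with an asterisk on
#' POST cells whose within-limb PRE-POST pairwise contrast is significant.
#'
#' @param indices Long indices table from [run_extract()].
#' @param pairwise Optional named list of pairwise tables (per band x measure,
#'   names like `"L(2-4)"`) used to place significance marks.
#' @return Tibble: measure, band, cell, mean, sd, formatted `mean_sd` string.
#' @export
descriptives_table <- function(indices, pairwise = NULL) {
  rows <- list()
  for (b in unique(indices$band)) {
    for (msr in c("L", "F")) {
      d <- indices[indices$band == b, ]
      cell <- paste(d$condition, d$limb, sep = ".")
      mu <- tapply(d[[msr]], factor(cell, CELLS_2x2), mean)
      sdv <- tapply(d[[msr]], factor(cell, CELLS_2x2), stats::sd)
      key <- sprintf("%s(%s)", msr, b)
      star <- setNames(rep("", 4L), CELLS_2x2)
      if (!is.null(pairwise[[key]])) {
        pw <- pairwise[[key]]
        for (limb in LIMB_LEVELS) {
          ctr <- sprintf("PRE.%s - POST.%s", limb, limb)
          hit <- pw$contrast == ctr & !is.na(pw$significant) & pw$significant
          if (any(hit)) star[paste0("POST.", limb)] <- " *"
        }
      }
      rows[[key]] <- tibble::tibble(
        measure = msr, band = b, cell = CELLS_2x2,
        mean = as.numeric(mu), sd = as.numeric(sdv),
        mean_sd = sprintf("%.2f ± %.2f%s", mu, sdv, star[CELLS_2x2])
      )
    }
  }
  do.call(rbind, rows)
}

#' Run the full inferential analysis on an indices table
#'
#' For each band and each measure (L, F): Shapiro-Wilk screening per cell, the
#' 2x2 within-subject ANOVA (time x limb) and the six Bonferroni-adjusted
#' pairwise contrasts — four ANOVAs in total for the standard two bands.
#'
#' @param indices Long indices table from [run_extract()].
#' @param alpha Significance level for main effects/interactions (default 0.05).
#' @param m Bonferroni comparison count (default 6; threshold 0.05/6 ~ 0.008).
#' @return List with `descriptives`, `anova` (named list of per-analysis
#'   tibbles), `pairwise`, `shapiro`, and a `report` character vector in the
#'   publication reporting style.
#' @export
run_analyze <- function(indices, alpha = 0.05, m = 6) {
  bands <- unique(indices$band)
  anovas <- list(); pairwises <- list(); shapiros <- list()
  for (b in bands) {
    for (msr in c("L", "F")) {
      key <- sprintf("%s(%s)", msr, b)
      tbl <- measure_table(indices, b, msr)
      anovas[[key]] <- rm_anova_2x2(tbl)
      pairwises[[key]] <- bonferroni_pairwise(tbl, m = m, alpha = alpha)
      shapiros[[key]] <- shapiro_screen(tbl)
    }
  }
  desc <- descriptives_table(indices, pairwises)
  list(
    descriptives = desc,
    anova = anovas,
    pairwise = pairwises,
    shapiro = shapiros,
    report = format_report(anovas, pairwises, desc, alpha = alpha, m = m)
  )
}

fmt_p <- function(p) ifelse(p < 1e-4, "p < 0.0001", sprintf("p = %.3f", p))

#' Human-readable analysis report
#'
#' @param anovas,pairwises,descriptives Components as built by [run_analyze()].
#' @param alpha,m Significance settings (for the header).
#' @return Character vector of report lines.
#' @export
format_report <- function(anovas, pairwises, descriptives, alpha = 0.05, m = 6) {
  lines <- c(
    "Band-limited resting tremor analysis",
    sprintf(
      "alpha = %g (main effects); Bonferroni-adjusted pairwise threshold %g/%d = %.3g",
      alpha, alpha, m, alpha / m
    ),
    ""
  )
  for (key in names(anovas)) {
    a <- anovas[[key]]
    lines <- c(lines, sprintf("== %s ==", key))
    for (r in seq_len(nrow(a))) {
      lines <- c(lines, sprintf(
        "  %s: F(%g, %g) = %.2f, %s, eta_p^2 = %.3f (%s), epsilon = %g (2 levels; sphericity not testable)",
        a$effect[r], a$df_num[r], a$df_den[r], a$F[r], fmt_p(a$p[r]),
        a$pes[r], a$cohen[r], a$epsilon[r]
      ))
    }
    pw <- pairwises[[key]]
    for (r in seq_len(nrow(pw))) {
      lines <- c(lines, if (isTRUE(pw$degenerate[r])) {
        sprintf("  pairwise %s: degenerate (zero-variance differences)", pw$contrast[r])
      } else {
        sprintf(
          "  pairwise %s: diff = %.3f, t(%g) = %.2f, p_adj = %.3f%s",
          pw$contrast[r], pw$mean_diff[r], pw$df[r], pw$t[r], pw$p_adj[r],
          ifelse(isTRUE(pw$significant[r]), " *", "")
        )
      })
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Descriptives (mean ± SD; * = significant within-limb PRE-POST change):")
  d <- descriptives
  for (key in unique(sprintf("%s(%s)", d$measure, d$band))) {
    dd <- d[sprintf("%s(%s)", d$measure, d$band) == key, ]
    lines <- c(lines, sprintf(
      "  %s: %s", key,
      paste(sprintf("%s %s", dd$cell, dd$mean_sd), collapse = " | ")
    ))
  }
  lines
}
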