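test_that("the SS decomposition matches a brute-force oracle on random tables", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    tab <- random_measure_table(n)
    a <- rm_anova_2x2(tab)
    bf <- brute_force_ss(tab)
    expect_equal(a$SS_effect, c(bf$time, bf$limb, bf$txl), tolerance = 1e-10)
    expect_equal(a$SS_error, c(bf$ts, bf$ls, bf$tls), tolerance = 1e-10)
  }
})

test_that("F and p agree with the classical aov error-stratum fit", {
  set.seed(21)
  n <- 10
  tab <- random_measure_table(n)
  mine <- rm_anova_2x2(tab)
  long <- data.frame(
    y = as.vector(tab),
    subj = factor(rep(seq_len(n), 4)),
    time = factor(rep(c("PRE", "POST", "PRE", "POST"), each = n)),
    limb = factor(rep(c("dom", "dom", "nd", "nd"), each = n))
  )
  av <- summary(stats::aov(y ~ time * limb + Error(subj / (time * limb)), data = long))
  f_aov <- c(
    av[["Error: subj:time"]][[1]]["time", "F value"],
    av[["Error: subj:limb"]][[1]]["limb", "F value"],
    av[["Error: subj:time:limb"]][[1]]["time:limb", "F value"]
  )
  expect_equal(mine$F, f_aov, tolerance = 1e-10)
})

test_that("F(time) equals the squared paired t on limb-averaged differences", {
  set.seed(22)
  for (i in 1:10) {
    tab <- random_measure_table(8)
    a <- rm_anova_2x2(tab)
    d <- rowMeans(tab[, c("POST.dominant", "POST.nondominant")]) -
      rowMeans(tab[, c("PRE.dominant", "PRE.nondominant")])
    tt <- t.test(d)
    expect_equal(a$F[a$effect == "time"], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p[a$effect == "time"], tt$p.value, tolerance = 1e-10)
  }
})

test_that("null and symmetric designs give zero F", {
  set.seed(23)
  base <- matrix(rnorm(12), 6, 2)
  # PRE cells identical to POST cells: F(time) = 0
  tab <- cbind(
    PRE.dominant = base[, 1], POST.dominant = base[, 1],
    PRE.nondominant = base[, 2], POST.nondominant = base[, 2]
  )
  a <- rm_anova_2x2(tab)
  expect_equal(a$F[a$effect == "time"], 0)
  # limb columns identical: F(limb) = 0 and F(interaction) = 0
  tab2 <- cbind(
    PRE.dominant = base[, 1], POST.dominant = base[, 2],
    PRE.nondominant = base[, 1], POST.nondominant = base[, 2]
  )
  a2 <- rm_anova_2x2(tab2)
  expect_equal(a2$F[a2$effect == "limb"], 0)
  expect_equal(a2$F[a2$effect == "time:limb"], 0)
})

test_that("Greenhouse-Geisser epsilon is 1 for 2 levels and general for k > 2", {
  set.seed(24)
  expect_equal(gg_epsilon(matrix(rnorm(40), 20, 2)), 1)
  # compound-symmetric 3-level covariance: epsilon near 1 (estimator is
  # downward biased in finite samples, so large n is used)
  eps <- replicate(500, {
    z <- rnorm(200)
    gg_epsilon(cbind(z + rnorm(200), z + rnorm(200), z + rnorm(200)))
  })
  expect_equal(mean(eps), 1, tolerance = 0.05)
  # maximally non-spherical: a single dominating difference contrast drives
  # epsilon to the lower bound 1/(k-1) = 0.5
  z <- rnorm(100)
  expect_equal(gg_epsilon(cbind(z, -z, rnorm(100, sd = 1e-6))), 0.5, tolerance = 1e-3)
})

test_that("partial eta squared reproduces published effect sizes from F", {
  expect_equal(round(partial_eta_squared_from_f(86.56, 1, 49), 3), 0.639)
  expect_equal(round(partial_eta_squared_from_f(3.91, 1, 49), 3), 0.074)
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(5, 0), 1)
  expect_error(partial_eta_squared(0, 0), "undefined")
  expect_equal(cohen_label(c(0.005, 0.03, 0.1, 0.5)),
               c("negligible", "small", "medium", "large"))
})

test_that("Bonferroni adjustment multiplies by m and caps at 1", {
  set.seed(25)
  tab <- random_measure_table(12)
  pw <- bonferroni_pairwise(tab, m = 6)
  expect_equal(nrow(pw), 6)
  expect_equal(pw$p_adj, pmin(1, 6 * pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
  # a large-p contrast caps at exactly 1.000
  tab_null <- random_measure_table(30)
  pw_null <- bonferroni_pairwise(tab_null, m = 6)
  expect_true(any(pw_null$p_adj == 1))
  # zero-variance difference scores are reported as degenerate, not dropped
  tab_deg <- tab
  tab_deg[, "POST.dominant"] <- tab_deg[, "PRE.dominant"]
  pw_deg <- bonferroni_pairwise(tab_deg)
  expect_equal(nrow(pw_deg), 6)
  expect_true(pw_deg$degenerate[pw_deg$contrast == "PRE.dominant - POST.dominant"])
})

test_that("a pure time effect yields the published contrast pattern", {
  # simulated at the measure-table level: subject offsets + cell noise,
  # post - pre shift of 3.79 log units on both limbs, no limb effect
  set.seed(26)
  ok_within <- 0
  ok_between <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    subj <- rnorm(50, 0, 0.98)
    noise <- function() rnorm(50, 0, 0.4)
    tab <- cbind(
      PRE.dominant = -8.66 + subj + noise(),
      POST.dominant = -4.87 + subj + noise(),
      PRE.nondominant = -8.66 + subj + noise(),
      POST.nondominant = -4.87 + subj + noise()
    )
    pw <- bonferroni_pairwise(tab)
    within <- pw$significant[pw$contrast %in% c(
      "PRE.dominant - POST.dominant", "PRE.nondominant - POST.nondominant"
    )]
    between <- pw$significant[pw$contrast %in% c(
      "PRE.dominant - PRE.nondominant", "POST.dominant - POST.nondominant"
    )]
    ok_within <- ok_within + all(within)
    ok_between <- ok_between + !any(between)
  }
  expect_gte(ok_within, 95)
  expect_gte(ok_between, 85)
})

test_that("the time effect holds its nominal size under a table-level null", {
  set.seed(27)
  rej <- replicate(500, {
    tab <- random_measure_table(50)
    a <- rm_anova_2x2(tab)
    a$p[a$effect == "time"] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Shapiro-Wilk screening flags non-normal and degenerate cells", {
  set.seed(28)
  q <- qnorm(ppoints(50))
  tab <- cbind(
    PRE.dominant = q, POST.dominant = q,
    PRE.nondominant = q, POST.nondominant = q
  )
  sw <- shapiro_screen(tab)
  expect_true(all(sw$W > 0.99))
  # one extreme outlier drives p below 0.01
  out <- c(rnorm(49), 50)
  tab2 <- tab
  tab2[, "PRE.dominant"] <- out
  sw2 <- shapiro_screen(tab2)
  expect_lt(sw2$p[sw2$sample == "PRE.dominant"], 0.01)
  # constant cell reported degenerate
  tab3 <- tab
  tab3[, "POST.dominant"] <- 1
  sw3 <- shapiro_screen(tab3)
  expect_true(sw3$degenerate[sw3$sample == "POST.dominant"])
  # difference-score screening covers the 6 pairs
  expect_equal(nrow(shapiro_screen(tab, on = "differences")), 6)
})

test_that("measure_table drops incomplete participants listwise with warning", {
  set.seed(29)
  coh_idx <- expand.grid(
    participant = c("A", "B", "C"), limb = c("dominant", "nondominant"),
    condition = c("PRE", "POST"), band = "2-4", stringsAsFactors = FALSE
  )
  coh_idx$L <- rnorm(12)
  coh_idx$F <- runif(12, 2, 4)
  incomplete <- coh_idx[!(coh_idx$participant == "C" & coh_idx$condition == "POST" &
    coh_idx$limb == "dominant"), ]
  expect_warning(tab <- measure_table(incomplete, "2-4", "L"), "C")
  expect_equal(nrow(tab), 2)
  expect_error(measure_table(coh_idx, "5-9", "L"), "no rows")
})
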