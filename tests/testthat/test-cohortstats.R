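test_that("identical groups compare as indistinguishable (tie-corrected Mann-Whitney)", {
  x <- c(1, 1, 1, 2, 2, 3, 5, 9, 20, 60)   # skewed: normality is rejected
  r <- compare_groups(x, x)
  expect_equal(r$method, "mann_whitney")
  expect_equal(r$p_raw, 1, tolerance = 1e-9)
})

test_that("normality decides between t and Mann-Whitney", {
  x <- withr::with_seed(1, rnorm(60)); y <- withr::with_seed(2, rnorm(60, 0.3))
  expect_equal(compare_groups(x, y)$method, "t")
  xe <- withr::with_seed(3, rexp(60)); ye <- withr::with_seed(4, rexp(60, 0.7))
  expect_equal(compare_groups(xe, ye)$method, "mann_whitney")
  expect_error(compare_groups(1:2, 1:5), "insufficient")
})

test_that("small-sample U statistic matches exhaustive enumeration", {
  x <- c(1.1, 3.4, 4.2, 6.8); y <- c(0.9, 2.2, 5.1, 2.8)
  r <- compare_groups(x, y, normality_alpha = 1)  # force the rank test
  u_hand <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(unname(r$statistic), u_hand)
  # exact permutation p over all C(8,4) group assignments
  pooled <- c(x, y)
  combs <- utils::combn(8, 4)
  u_all <- apply(combs, 2, function(ix)
    sum(outer(pooled[ix], pooled[-ix], ">")))
  p_exact <- mean(abs(u_all - 8) >= abs(u_hand - 8))
  expect_equal(p_exact, stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-9)
  expect_lt(abs(r$p_raw - p_exact), 0.08)   # asymptotic vs exact at n = 4
})

test_that("detection rate under a shifted alternative matches a Monte-Carlo oracle", {
  reps <- 300
  res <- vapply(1:reps, function(i) {
    withr::with_seed(10000 + i, {
      x <- rexp(200); y <- rexp(200) + 0.25
      mine <- compare_groups(x, y)$p_raw < 0.05
      oracle <- stats::wilcox.test(x, y, exact = FALSE)$p.value < 0.05
      c(mine, oracle)
    })
  }, logical(2))
  expect_lt(abs(mean(res[1, ]) - mean(res[2, ])), 0.05)
  expect_gt(mean(res[1, ]), 0.5)  # the shift is detectable
})

test_that("correlations behave on exact, monotone and degenerate inputs", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x, "pearson")$effect, 1)
  y <- exp(x / 5)   # monotone, nonlinear
  expect_equal(correlate(x, y, "spearman")$effect, 1)
  expect_lt(correlate(x, y, "pearson")$effect, 1)
  expect_warning(r <- correlate(x, rep(1, 20)), "constant")
  expect_true(is.na(r$effect))
})

test_that("generator rank correlation is recovered by the correlate operation", {
  co <- generate_cohort(cohort_spec(n_patients = 1000, seed = 17))
  r <- correlate(co$mri_pos_fap_fraction, co$mri_pos_cd8_fraction, "spearman")
  expect_gt(r$effect, 0.34)
  expect_lt(r$effect, 0.54)
  expect_lt(r$p_raw, 0.001)
})

test_that("dichotomization rules mark the documented patients", {
  d <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(d$cutoff, 2.5)
  expect_identical(d$high, c(FALSE, FALSE, TRUE, TRUE))
  f <- dichotomize(c(0.1, 0.19, 0.21, 0.5), "fixed", cutoff = 0.20)
  expect_identical(f$high, c(FALSE, FALSE, TRUE, TRUE))
  v280 <- withr::with_seed(5, runif(280))
  td <- dichotomize(v280, "top_decile")
  expect_equal(td$n_high, 28)
  bd <- dichotomize(v280, "bottom_decile")
  expect_equal(bd$n_low, 28)
  expect_error(dichotomize(rep(2, 10), "median"), "degenerate")
  na_in <- dichotomize(c(1, NA, 3), "median")
  expect_true(is.na(na_in$high[2]))
})

test_that("cross-tabulation reproduces printed row percentages and exact tests", {
  # PTEN (neg/pos) x FAP (low/high) counts as published
  pten <- rep(c("neg", "pos"), c(47, 255))
  fap <- c(rep(c("low", "high"), c(11, 36)), rep(c("low", "high"), c(140, 115)))
  ct <- crosstab(pten, fap)
  expect_equal(unname(ct$counts["neg", c("low", "high")]), c(11, 36))
  expect_equal(unname(ct$row_pct["neg", c("low", "high")]), c(23, 77))
  expect_equal(unname(ct$row_pct["pos", c("low", "high")]), c(55, 45))
  expect_lt(ct$p, 0.001)
  # Fisher p equals the hypergeometric enumeration oracle
  tab <- ct$counts
  ks <- 0:47
  probs <- dhyper(ks, 47, 255, tab["neg", "high"] + tab["pos", "high"])
  p_oracle <- sum(probs[probs <= dhyper(tab["neg", "high"], 47, 255,
                  tab["neg", "high"] + tab["pos", "high"]) * (1 + 1e-7)])
  p_fisher <- fisher.test(tab)$p.value
  expect_equal(p_fisher, p_oracle, tolerance = 1e-9)

  sym <- crosstab(rep(c("a", "b"), each = 10),
                  rep(c("x", "y", "x", "y"), each = 5))
  expect_equal(sym$test, "fisher")
  expect_equal(sym$p, 1)
})

test_that("Bonferroni correction is monotone and capped", {
  expect_equal(bonferroni(0.02, 53), 1)
  expect_equal(bonferroni(1, 53), 1)
  expect_equal(bonferroni(0.0005, 53), 0.0265)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 53)) >= 0))
})

test_that("univariable screen caps corrected p and flags degenerate fits", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 23))
  co$constant <- 1
  sc <- univariable_screen(co, c("age", "mri_pos_fap_fraction", "constant"),
                           family_size = 53)
  expect_true(all(sc$p_corrected <= 1, na.rm = TRUE))
  expect_true(all(sc$p_corrected >= sc$p_raw, na.rm = TRUE))
  expect_false(sc$converged[sc$variable == "constant"])
  age_row <- sc[sc$variable == "age", ]
  expect_equal(age_row$p_corrected, min(1, age_row$p_raw * 53))
})

test_that("Kaplan-Meier curves follow the product-limit hand computation", {
  # worked 3-subject example, duplicated into two identical groups
  time <- rep(c(1, 2, 3), 2); event <- rep(c(1, 1, 0), 2)
  grp <- rep(c("a", "b"), each = 3)
  km <- km_logrank(time, event, grp)
  a <- km$curves[km$curves$group == "a", ]
  expect_equal(a$surv[a$time == 0], 1)
  expect_equal(a$surv[a$time == 1], 2 / 3)
  expect_equal(a$surv[a$time == 2], 1 / 3)
  expect_true(all(diff(a$surv) <= 0))
  # identical groups: no separation
  expect_equal(km$logrank_chisq, 0, tolerance = 1e-9)
  expect_equal(km$p, 1, tolerance = 1e-9)
  expect_error(km_logrank(time, event, rep("a", 6)), "two non-empty groups")
})

test_that("KM with no censoring ends at the empirical survivor fraction", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8); event <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  km <- km_logrank(time, event, grp)
  a <- km$curves[km$curves$group == "a", ]
  expect_equal(min(a$surv), 0)
  expect_equal(a$surv[a$time == 2], 0.5)
})

test_that("Cox toy fit matches the hand-maximized partial likelihood", {
  # events at t=1 (x=1) and t=2 (x=0); censored at t=3 (one per group):
  # the partial likelihood maximum solves exp(beta) = sqrt(2)
  time <- c(1, 2, 3, 3); event <- c(1, 1, 0, 0); x <- c(1, 0, 1, 0)
  f <- cox_fit(time, event, data.frame(x = x))
  loglik <- function(b) b - log(2 * exp(b) + 2) - log(exp(b) + 2)
  b_oracle <- optimize(loglik, c(-3, 3), maximum = TRUE)$maximum
  expect_equal(f$table$beta, log(2) / 2, tolerance = 1e-4)
  expect_equal(f$table$beta, b_oracle, tolerance = 1e-4)
  expect_true(f$table$ci_lo <= f$table$hr && f$table$hr <= f$table$ci_hi)
  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(1, 0))), "events")
})

test_that("proportional-hazards diagnostics flag time-varying effects", {
  # crossing hazards: group effect reverses midway through follow-up
  rej <- vapply(1:20, function(i) {
    withr::with_seed(3000 + i, {
      n <- 300
      x <- rbinom(n, 1, 0.5)
      t1 <- rexp(n, 0.05 * exp(1.5 * x))          # early: x harmful
      tv <- t1 > 15
      t2 <- 15 + rexp(n, 0.05 * exp(-1.5 * x))    # late: x protective
      tt <- ifelse(tv, t2, t1)
      ev <- as.integer(tt < 60); tt <- pmin(tt, 60)
      ph <- ph_check(tt, ev, data.frame(x = x))
      ph$p_ph[1] < 0.05
    })
  }, logical(1))
  expect_gte(mean(rej), 0.5)
  # degenerate covariate is reported missing
  co <- generate_cohort(cohort_spec(n_patients = 100, seed = 31))
  ph <- ph_check(co$time_months, co$event,
                 data.frame(fap = co$mri_pos_fap_fraction, z = rep(1, 100)))
  expect_true(is.na(ph$p_ph[ph$covariate == "z"]))
  expect_false(is.na(ph$p_ph[ph$covariate == "fap"]))
})

test_that("DeLong AUCs equal the Mann-Whitney identity and match pROC", {
  withr::with_seed(41, {
    y <- rbinom(120, 1, 0.4)
    a <- rnorm(120) + y
    b <- 0.7 * a + rnorm(120, 0, 0.7)
  })
  r <- delong_compare(y, a, b)
  u <- sum(outer(a[y == 1], a[y == 0], ">")) +
    0.5 * sum(outer(a[y == 1], a[y == 0], "=="))
  expect_equal(r$auc_a, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(r$p_raw, ref$p.value, tolerance = 1e-9)
  same <- delong_compare(y, a, a)
  expect_equal(same$effect, 0)
  expect_equal(same$p_raw, 1)
  expect_error(delong_compare(rep(1, 10), rnorm(10), rnorm(10)), "classes")
})
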