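test_that("descriptives: interpolated quartiles, SE, and skew ordering", {
  co <- toy_cohort(5, 1, override = list(use_ratio = c(1, 2, 3, 4, 5)))
  d <- descriptives(co)
  r <- d[d$variable == "use_ratio", ]
  expect_equal(r$median, 3); expect_equal(r$q1, 2); expect_equal(r$q3, 4)
  expect_equal(r$se, sd(1:5) / sqrt(5))

  co2 <- toy_cohort(5, 1, override = list(d_time = rep(7, 5)))
  r2 <- descriptives(co2)
  r2 <- r2[r2$variable == "d_time", ]
  expect_equal(r2$sd, 0); expect_equal(r2$min, r2$max)

  set.seed(13)
  co3 <- toy_cohort(200, 1, override = list(d_magnitude = rlnorm(200, 0, 1)))
  r3 <- descriptives(co3)
  r3 <- r3[r3$variable == "d_magnitude", ]
  expect_gt(r3$mean, r3$median)
})

test_that("subject averaging is missing-aware", {
  co <- toy_cohort(2, 2, override = list(d_time = c(9, 11, 5, NA)))
  avg <- subject_average(co)
  expect_equal(avg$d_time[avg$subject_id == "S01"], 10)
  expect_equal(avg$d_time[avg$subject_id == "S02"], 5)
  expect_equal(nrow(avg), 2)
})

test_that("correlation screen: exact self-correlation and sign recovery", {
  set.seed(14)
  x <- rnorm(30)
  co <- toy_cohort(30, 1, override = list(d_time = x, nd_time = -x))
  scr <- correlation_screen(co)
  expect_true(all(diag(scr$r) == 1))
  expect_equal(scr$d_nd$r[scr$d_nd$dominant == "d_time"], -1)
  expect_equal(scr$alpha_adjusted, 0.002)
})

test_that("independent columns rarely exceed |r| = 0.2 at n = 222", {
  set.seed(15)
  hits <- replicate(40, {
    abs(cor(rnorm(222), rnorm(222))) < 0.2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("sex comparison uses the female-minus-male convention", {
  co <- toy_cohort(6, 1)
  co$sex <- rep(c("male", "female"), 3)
  co$d_time <- ifelse(co$sex == "male", c(10, 10.5, 11), c(8, 8.2, 8.4))
  sx <- sex_comparison(co, "d_time")
  expect_lt(sx$difference, 0)        # males higher -> negative

  co$d_time <- rep(c(1, 2, 3), each = 2)  # identical distributions
  sx2 <- sex_comparison(co, "d_time")
  expect_equal(sx2$difference, 0)
  expect_equal(sx2$p, 1)

  set.seed(16)
  n <- 200
  co3 <- toy_cohort(n, 1)
  delta <- 1.5
  co3$sex <- rep(c("male", "female"), n / 2)
  co3$nd_jerk <- rnorm(n, 10) + delta * (co3$sex == "female")
  sx3 <- sex_comparison(co3, "nd_jerk")
  se <- sqrt(2 / (n / 2))
  expect_lt(abs(sx3$difference - delta), 2.5 * se)

  co4 <- toy_cohort(4, 1); co4$sex <- "male"
  expect_error(sex_comparison(co4, "d_time"), "both sexes")
})

test_that("ICC(2,k) matches the ANOVA mean-squares oracle", {
  toy <- matrix(c(9, 10, 6, 8, 12, 12, 2, 4, 10, 9, 7, 7), nrow = 6,
                byrow = TRUE)
  expect_equal(icc2k(toy), icc2k_aov(toy), tolerance = 1e-10)
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(rnorm(8 * 3, 10, 2), 8, 3) + rnorm(8, 0, 3)
    expect_equal(icc2k(m), icc2k_aov(m), tolerance = 1e-10)
  }
  # perfect day agreement with differing subjects
  subj <- rnorm(6, 10, 2)
  expect_equal(icc2k(cbind(subj, subj, subj)), 1)
  # no between-subject signal
  set.seed(18)
  noise <- matrix(rnorm(200 * 2), 200, 2)
  expect_lt(abs(icc2k(noise)), 0.25)
  expect_error(icc2k(matrix(1:2, 1)), "2 subjects")
})

test_that("ICC is invariant to location and positive scale changes", {
  set.seed(19)
  m <- matrix(rnorm(10 * 3, 5, 1), 10, 3) + rnorm(10, 0, 2)
  i0 <- icc2k(m)
  expect_equal(icc2k(m + 7), i0, tolerance = 1e-12)
  expect_equal(icc2k(m * 3.2), i0, tolerance = 1e-12)
})

test_that("unbalanced cohorts truncate to the common day count", {
  set.seed(20)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    nd <- sample(2:4, 1)
    data.frame(subject_id = sprintf("S%02d", i), day_index = 1:nd,
               age = runif(1, 3, 17), sex = "male",
               y = rnorm(nd, 10 + i, 0.5))
  }))
  ic <- icc2k_cohort(rows, "y")
  expect_equal(ic$k, 2L)
  expect_equal(ic$n_subjects, 12)
  expect_gt(ic$icc2k, 0.8)           # strong subject separation planted
  expect_true(is.finite(ic$icc_vc))
  expect_gt(ic$icc_vc, 0.8)
})

test_that("mixed model recovers planted residual and subject variance", {
  set.seed(21)
  tab <- simulate_cohort_table(n_subjects = 200, days_per_subject = 3,
                               mean = 10, between_sd = 2, resid_sd = 1)
  dm <- day_variation_model(tab, "value")
  expect_lt(abs(dm$sigma_eps - 1) / 1, 0.1)

  # near-zero residual noise
  set.seed(22)
  tab0 <- simulate_cohort_table(n_subjects = 50, days_per_subject = 3,
                                between_sd = 2, resid_sd = 1e-4)
  dm0 <- suppressWarnings(day_variation_model(tab0, "value"))
  expect_lt(dm0$sigma_eps, 0.05)

  # no planted fixed effects: estimates near zero
  set.seed(23)
  tabn <- simulate_cohort_table(n_subjects = 150, days_per_subject = 3,
                                between_sd = 1, resid_sd = 1)
  dmn <- day_variation_model(tabn, "value")
  expect_lt(abs(dmn$fixed[["sexfemale"]]), 0.5)
  expect_lt(abs(dmn$fixed[["day"]]), 0.35)
})

test_that("mixed model recovers planted age and day fixed effects", {
  set.seed(24)
  tab <- simulate_cohort_table(n_subjects = 150, days_per_subject = 3,
                               mean = 10, between_sd = 1, resid_sd = 0.5,
                               age_slope = -0.3, sex_diff = 1, day_slope = 0.4)
  dm <- day_variation_model(tab, "value")
  expect_equal(dm$fixed[["day"]], 0.4, tolerance = 0.25)
  expect_equal(dm$fixed[["sexfemale"]], 1, tolerance = 0.4)
  # a planted negative age slope shows up as a negative age correlation
  avg <- do.call(rbind, lapply(split(tab, tab$subject_id), function(s)
    data.frame(age = s$age[1], v = mean(s$value))))
  expect_lt(cor(avg$age, avg$v), -0.5)
})

test_that("coefficient of variation across days", {
  co <- data.frame(subject_id = c("A", "A"), day_index = 1:2,
                   age = 8, sex = "male", y = c(9, 11))
  cv <- cov_across_days(co, "y")
  expect_equal(cv$mean_cov_pct, sd(c(9, 11)) / 10 * 100)
  co2 <- data.frame(subject_id = c("A", "A", "B", "B"), day_index = c(1, 2),
                    age = 8, sex = "male", y = c(5, 5, 7, 7))
  expect_equal(cov_across_days(co2, "y")$mean_cov_pct, 0)
  # scale invariance
  set.seed(25)
  y <- rlnorm(6, 1, 0.3)
  co3 <- data.frame(subject_id = rep(c("A", "B"), each = 3),
                    day_index = rep(1:3, 2), age = 8, sex = "male", y = y)
  co4 <- co3; co4$y <- co4$y * 13
  expect_equal(cov_across_days(co3, "y")$mean_cov_pct,
               cov_across_days(co4, "y")$mean_cov_pct, tolerance = 1e-12)
  # near-zero subject mean flagged and excluded
  co5 <- data.frame(subject_id = rep(c("A", "B"), each = 2),
                    day_index = c(1, 2), age = 8, sex = "male",
                    y = c(1e-12, -1e-12, 3, 4))
  expect_warning(res <- cov_across_days(co5, "y"), "zero")
  expect_equal(res$n_excluded, 1)
})

test_that("Bonferroni thresholds", {
  expect_identical(bonferroni_threshold(0.05, 25), 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(1.2, 5), "alpha")
})

test_that("the reliability report covers all 25 variables coherently", {
  set.seed(26)
  co <- toy_cohort(20, 3, seed = 26)
  # give the paired variables a correlated structure
  base <- rnorm(60, 10)
  co$d_time <- base + rnorm(60, 0, 0.2)
  co$nd_time <- base + rnorm(60, 0, 0.2)
  rep_ <- suppressWarnings(suppressMessages(reliability_report(co)))
  expect_s3_class(rep_, "limbwear_reliability")
  expect_equal(nrow(rep_), 25)
  expect_equal(attr(rep_, "alpha_adjusted"), 0.002)
  expect_true(all(abs(rep_$d_nd_correlation) <= 1, na.rm = TRUE))
  expect_true(all(rep_$mean_cov_pct >= 0, na.rm = TRUE))
  expect_gt(rep_$d_nd_correlation[rep_$variable == "d_time"], 0.9)
  expect_output(print(rep_), "Reliability report")
})
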