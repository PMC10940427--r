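test_that("duration variables are exact set arithmetic over moving seconds", {
  # both limbs moving all 7200 s
  d <- day_from_masks(rep(TRUE, 7200), rep(TRUE, 7200))
  v <- duration_variables(d)
  expect_equal(v$total_movement_time, 2)
  expect_equal(v$d_time, 2)
  expect_equal(v$nd_time, 2)
  expect_equal(v$simultaneous_time, 2)
  expect_equal(v$d_isolated_time, 0)
  expect_equal(v$nd_isolated_time, 0)

  # one limb only
  d2 <- day_from_masks(rep(TRUE, 3600), rep(FALSE, 3600))
  v2 <- duration_variables(d2)
  expect_equal(v2$d_time, 1)
  expect_equal(v2$total_movement_time, 1)
  expect_equal(v2$d_isolated_time, 1)
  expect_equal(v2$nd_time, 0)
  expect_equal(v2$simultaneous_time, 0)

  # overlapping windows, checked against brute-force index counting
  n <- 10000
  dm <- seq_len(n) - 1L; dmask <- dm %in% 0:5999; nmask <- dm %in% 3000:8999
  v3 <- duration_variables(day_from_masks(dmask, nmask))
  expect_equal(v3$simultaneous_time, length(intersect(0:5999, 3000:8999)) / 3600)
  expect_equal(v3$total_movement_time, length(union(0:5999, 3000:8999)) / 3600)
  expect_equal(v3$d_isolated_time, length(setdiff(0:5999, 3000:8999)) / 3600)
})

test_that("duration additivity holds for random masks", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(500:3000, 1)
    v <- duration_variables(day_from_masks(runif(n) < 0.4, runif(n) < 0.4))
    expect_equal(v$d_isolated_time + v$nd_isolated_time + v$simultaneous_time,
                 v$total_movement_time, tolerance = 1e-12)
    expect_equal(v$d_isolated_time + v$simultaneous_time, v$d_time,
                 tolerance = 1e-12)
    expect_gte(v$total_movement_time, max(v$d_time, v$nd_time))
  }
})

test_that("intensity: medians over moving seconds, peak over all valid", {
  k <- conversion_constants()$kappa
  # g_vm targets 0.1, 0.2, 0.3 on moving seconds
  cd <- c(0.1, 0.2, 0.3) / k
  d <- day_from_masks(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE),
                      d_counts = cd, nd_counts = cd)
  m <- intensity_variables(d)
  expect_equal(m$d_magnitude, 0.2)
  expect_equal(m$bilateral_magnitude, m$d_magnitude + m$nd_magnitude)

  # peak scans valid-but-still seconds too: plant a large value in a second
  # that the classifier is forced to treat as still
  es <- make_epochs(c(100, 120, 1.9 / k))
  es$moving <- c(TRUE, TRUE, FALSE)  # classified still despite large g_vm
  esn <- make_epochs(c(100, 120, 0), limb = "non_dominant")
  d3 <- align_bilateral(es, esn)
  m3 <- intensity_variables(d3)
  expect_equal(m3$d_peak_magnitude, 1.9)
  expect_equal(m3$d_magnitude, stats::median(c(100, 120) * k))
})

test_that("symmetry ratios equal 1 for symmetric limbs, guard zero division", {
  dur <- list(d_time = 6, nd_time = 6)
  mag <- list(d_magnitude = 0.2, nd_magnitude = 0.2)
  vv <- list(d_variance = 0.05, nd_variance = 0.05)
  r <- symmetry_ratios(dur, mag, vv)
  expect_equal(r$use_ratio, 1)
  expect_equal(r$magnitude_ratio, 1)
  expect_equal(r$variation_ratio, 1)

  r2 <- symmetry_ratios(list(d_time = 6, nd_time = 4.8), mag, vv)
  expect_equal(r2$use_ratio, 0.8)

  expect_error(symmetry_ratios(list(d_time = 0, nd_time = 1), mag, vv),
               "use_ratio")
})

test_that("jerk asymmetry index: zero at equality, antisymmetric, bounded", {
  expect_equal(jerk_asymmetry(1.5, 1.5), 0)
  expect_equal(jerk_asymmetry(3, 1), 0.5)
  expect_equal(jerk_asymmetry(1, 3), -0.5)
  expect_error(jerk_asymmetry(0, 0), "undefined")
  set.seed(7)
  for (i in 1:1000) {
    j <- runif(2, 0, 10)
    if (sum(j) == 0) next
    v <- jerk_asymmetry(j[1], j[2])
    expect_gte(v, -1); expect_lte(v, 1)
    expect_equal(jerk_asymmetry(j[2], j[1]), -v)
  }
})

test_that("variance variables: SD over moving seconds, lognormal check", {
  k <- conversion_constants()$kappa
  d <- day_from_masks(rep(TRUE, 10), rep(TRUE, 10),
                      d_counts = rep(60, 10), nd_counts = rep(60, 10))
  expect_equal(variance_variables(d)$d_variance, 0)

  d2 <- day_from_masks(c(TRUE, TRUE), c(TRUE, TRUE),
                       d_counts = c(0.1, 0.3) / k, nd_counts = c(0.1, 0.3) / k)
  expect_equal(variance_variables(d2)$d_variance, sd(c(0.1, 0.3)))

  set.seed(8)
  mu <- log(0.15); sg <- 0.4
  vals <- rlnorm(1000, mu, sg)
  d3 <- day_from_masks(rep(TRUE, 1000), rep(TRUE, 1000),
                       d_counts = vals / k, nd_counts = vals / k)
  analytic <- sqrt((exp(sg^2) - 1) * exp(2 * mu + sg^2))
  expect_equal(variance_variables(d3)$d_variance, analytic, tolerance = 0.1)
})

test_that("max activity hour slides in 1 s steps with earliest-start ties", {
  n <- 10000
  counts <- numeric(n)
  counts[5001:8600] <- 50          # seconds 5000..8599 (0-based)
  expect_equal(max_activity_hour(make_epochs(counts)), 5000)
  expect_equal(max_activity_hour(make_epochs(rep(7, n))), 0)
  two <- numeric(n); two[1001:4600] <- 10; two[6001:9600] <- 10
  expect_equal(max_activity_hour(make_epochs(two)), 1000)
  expect_error(max_activity_hour(make_epochs(rep(1, 1000))), "3600")
})

test_that("sample entropy equals direct pair counting and orders regularity", {
  p <- complexity_params()
  expect_equal(sample_entropy(rep(0.5, 300), p), 0)
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(200)
    expect_equal(sample_entropy(x, p),
                 sampen_brute(x, p$m, p$r * sd(x)), tolerance = 1e-14)
  }
  # strict period-2 square wave is more regular than white noise of equal SD
  sq <- rep(c(-1, 1), 250)
  wn <- rnorm(500, 0, sd(sq))
  expect_lt(sample_entropy(sq, p), sample_entropy(wn, p))
  # alternate parameters hit the same oracle
  p2 <- complexity_params(m = 3, r = 0.15)
  x <- rnorm(150)
  expect_equal(as.numeric(sample_entropy(x, p2)),
               sampen_brute(x, 3, 0.15 * sd(x)), tolerance = 1e-14)
})

test_that("average jerk is the mean absolute slope over moving pairs", {
  vm_const <- rep(0.4, 300)
  expect_equal(average_jerk(make_ms(vm_const), rep(TRUE, 10)), 0)
  vm_ramp <- 0.01 * seq_len(300)
  expect_equal(average_jerk(make_ms(vm_ramp), rep(TRUE, 10)), 0.3)
  set.seed(10)
  vm_rw <- cumsum(rnorm(600, 0, 0.01))
  expect_equal(average_jerk(make_ms(vm_rw), rep(TRUE, 20)),
               mean(abs(diff(vm_rw))) * 30)
  # only pairs inside moving epochs count
  mask <- c(TRUE, FALSE, rep(TRUE, 8))
  vm <- c(rep(0.1, 30), rep(0.5, 30), rep(0.1, 240))
  j_masked <- average_jerk(make_ms(vm), mask)
  expect_equal(j_masked, mean(abs(diff(vm[c(1:30, 61:300)][-30]))) * 30,
               tolerance = 0.2)
  expect_error(average_jerk(make_ms(vm), rep(FALSE, 10)), "no moving")
})

test_that("spectral moments recover planted line spectra", {
  fs <- 30
  t <- seq_len(fs * 240) / fs
  p <- complexity_params()
  s3 <- frequency_stats(make_ms(sin(2 * pi * 3 * t)), rep(TRUE, 240), p)
  expect_equal(s3$mean_freq, 3, tolerance = 0.05)
  expect_lt(s3$freq_variance, 0.2)

  two <- sin(2 * pi * 2 * t) + sin(2 * pi * 4 * t)
  s24 <- frequency_stats(make_ms(two), rep(TRUE, 240), p)
  expect_equal(s24$mean_freq, 3, tolerance = 0.1)

  # band-limited white noise on [1, 5] Hz: uniform spectral moments
  set.seed(11)
  long_t <- seq_len(fs * 1200) / fs
  wn <- rnorm(length(long_t))
  lo <- bandpass(wn, fs, c(1, 5), order = 8)
  sbl <- frequency_stats(make_ms(lo), rep(TRUE, 1200), p)
  expect_equal(sbl$mean_freq, 3, tolerance = 0.15)
  expect_equal(sbl$freq_variance, (5 - 1) / sqrt(12), tolerance = 0.15)
  expect_error(frequency_stats(make_ms(sin(t[1:300])), rep(TRUE, 10), p),
               "window")
})

test_that("identical limb streams give unit ratios and zero jerk asymmetry", {
  fix <- small_generated_day()
  gd <- fix$gd
  nd_copy <- gd$dom
  nd_copy$limb <- "non_dominant"
  day <- process_day(gd$dom, nd_copy)
  vs <- compute_variable_set(day)
  expect_identical(vs$use_ratio, 1)
  expect_identical(vs$magnitude_ratio, 1)
  expect_identical(vs$variation_ratio, 1)
  expect_identical(vs$jerk_asymmetry_index, 0)
  expect_identical(vs$d_isolated_time, 0)
  expect_identical(vs$nd_isolated_time, 0)
})

test_that("limb swap inverts the use ratio and negates jerk asymmetry", {
  fix <- small_generated_day()
  gd <- fix$gd
  swapped_d <- gd$nondom; swapped_d$limb <- "dominant"
  swapped_n <- gd$dom; swapped_n$limb <- "non_dominant"
  v1 <- compute_variable_set(fix$day)
  v2 <- compute_variable_set(process_day(swapped_d, swapped_n))
  expect_equal(v2$use_ratio, 1 / v1$use_ratio, tolerance = 1e-12)
  expect_equal(v2$jerk_asymmetry_index, -v1$jerk_asymmetry_index,
               tolerance = 1e-12)
  expect_equal(v2$d_time, v1$nd_time)
  expect_equal(v2$nd_magnitude, v1$d_magnitude)
  expect_equal(v2$d_variance, v1$nd_variance)
})

test_that("circular time shifts leave duration/intensity/variance unchanged", {
  set.seed(12)
  n <- 2000
  cd <- ifelse(runif(n) < 0.4, rpois(n, 80), 0)
  cn <- ifelse(runif(n) < 0.4, rpois(n, 70), 0)
  rot <- function(v, k) c(v[(k + 1):n], v[1:k])
  d1 <- day_from_masks(NULL, NULL, d_counts = cd, nd_counts = cn)
  d2 <- day_from_masks(NULL, NULL, d_counts = rot(cd, 137),
                       nd_counts = rot(cn, 137))
  for (f in c(duration_variables, intensity_variables, variance_variables)) {
    expect_equal(f(d1), f(d2))
  }
})

test_that("a day failing preconditions is flagged, not silently zeroed", {
  # a still day: no moving seconds anywhere
  d <- day_from_masks(rep(FALSE, 4000), rep(FALSE, 4000))
  vs <- compute_variable_set(d)
  expect_true(is.na(vs$d_magnitude))
  expect_true(is.na(vs$use_ratio))
  flags <- attr(vs, "flags")
  expect_true("d_magnitude" %in% names(flags))
  expect_equal(vs$total_movement_time, 0)
})
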