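#' Configuration of the synthetic bilateral cohort generator
#'
#' The defaults emulate a multi-day pediatric bilateral-wrist wearing
#' protocol: 2--4 recording days per subject, 24 h days, ages uniform on
#' 3--17 with a slight male excess, 94% right-handed, the dominant limb
#' moving about 42% of worn time in bouts of ~30 s, strong inter-limb
#' coupling (a shared bout with probability 0.79), a non-dominant duration
#' scale just below 1 and magnitude scale just above 1. Movement is emitted
#' as a quadrature sinusoid pair whose envelope is modulated at `mod_freq`,
#' so the bandpassed vector magnitude equals the envelope analytically and
#' every planted quantity (bout seconds, median envelope, modulation
#' frequency, envelope jerk) has a closed form recorded in the ground truth.
#'
#' @param n_subjects Number of subjects.
#' @param days_per_subject Day counts sampled uniformly per subject (scalar
#'   or vector, values in 2--4 for the emulated protocols).
#' @param seconds_per_day Length of each recording day in seconds.
#' @param age_range Uniform age range in years.
#' @param male_fraction,right_fraction Sex and handedness proportions.
#' @param move_frac Dominant-limb moving occupancy of the day.
#' @param bout_mean_s Mean movement-bout length in seconds.
#' @param coupling Probability that a dominant bout is shared by the
#'   non-dominant limb (controls simultaneous vs. isolated time).
#' @param nd_move_scale Planted ratio of non-dominant to dominant moving
#'   time (the expected use ratio).
#' @param amp_median Median bout envelope amplitude in g.
#' @param amp_log_sd Lognormal spread of per-bout amplitudes.
#' @param amp_floor Minimum bout amplitude in g (keeps every bout second
#'   above the count-chain dead-band, so the planted movement mask is exact).
#' @param nd_amp_scale Planted non-dominant amplitude scale (the expected
#'   magnitude ratio).
#' @param mod_freq Envelope modulation frequency in Hz (the planted
#'   movement frequency); `mod_depth` its relative depth.
#' @param carrier_freq Quadrature carrier frequency in Hz (inside the
#'   0.25--2.5 Hz count band so bouts always register counts).
#' @param noise_sd White sensor-noise SD in g (below the count dead-band,
#'   so quiescent seconds register zero counts).
#' @param sd_log_amp_subject,sd_log_amp_day Between-subject and day-level
#'   SDs of log amplitude.
#' @param sd_logit_move_subject,sd_logit_move_day The same for the logit
#'   moving occupancy.
#' @param sd_freq_subject,sd_freq_day The same for the modulation frequency
#'   (Hz).
#' @param age_slope_logit_move,age_slope_log_amp Linear age effects (per
#'   year, centered at 10 y) on occupancy and log amplitude; negative values
#'   emulate the gentle decline of activity with age.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10, days_per_subject = 2:4,
                         seconds_per_day = 86400,
                         age_range = c(3, 17), male_fraction = 0.52,
                         right_fraction = 0.94,
                         move_frac = 0.42, bout_mean_s = 30,
                         coupling = 0.79, nd_move_scale = 0.96,
                         amp_median = 0.25, amp_log_sd = 0.35,
                         amp_floor = 0.12, nd_amp_scale = 1.01,
                         mod_freq = 3.4, mod_depth = 0.8,
                         carrier_freq = 1.5, noise_sd = 0.005,
                         sd_log_amp_subject = 0.12, sd_log_amp_day = 0.06,
                         sd_logit_move_subject = 0.25,
                         sd_logit_move_day = 0.10,
                         sd_freq_subject = 0.25, sd_freq_day = 0.10,
                         age_slope_logit_move = -0.03,
                         age_slope_log_amp = -0.01) {
  cfg <- as.list(environment())
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop("synth_config: coupling must be in [0, 1]")
  if (cfg$bout_mean_s >= cfg$seconds_per_day)
    stop("synth_config: bout length exceeds the day")
  if (cfg$move_frac <= 0 || cfg$move_frac >= 1)
    stop("synth_config: move_frac must be in (0, 1)")
  structure(cfg, class = "synth_config")
}

# Alternating rest/bout schedule with shifted-geometric dwell times (minimum
# dwell 3 s in each state); returns a logical per-second mask of the
# requested length with expected occupancy p.
bout_mask <- function(n, p, bout_mean) {
  if (n <= 0L) return(logical(0))
  rest_mean <- bout_mean * (1 - p) / p
  min_dwell <- 3L
  mask <- logical(n)
  pos <- 1L
  state <- stats::runif(1) < p
  while (pos <= n) {
    mu <- if (state) bout_mean else rest_mean
    len <- min_dwell + stats::rgeom(1L, 1 / max(mu - min_dwell + 1, 1))
    end <- min(n, pos + len - 1L)
    if (state) mask[pos:end] <- TRUE
    pos <- end + 1L
    state <- !state
  }
  mask
}

# close sub-3 s still gaps between movement runs; overlapping filter
# ring-down from both neighbours would classify them as moving anyway, and
# the ground-truth tally is taken from the closed mask
close_short_gaps <- function(mask, min_gap = 3L) {
  r <- rle(mask)
  inner <- seq_along(r$values)[-c(1L, length(r$values))]
  short <- !r$values & r$lengths < min_gap
  short[setdiff(seq_along(short), inner)] <- FALSE
  r$values[short] <- TRUE
  inverse.rle(r)
}

# contiguous TRUE runs of a mask as (start, end) second pairs (1-based)
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Draw a synthetic subject
#'
#' Demographics plus the subject-level random effects of the three planted
#' drivers (log amplitude, logit occupancy, modulation frequency).
#'
#' @param config A [synth_config()].
#' @param id Subject identifier.
#' @return A list consumed by [generate_day()].
#' @export
generate_subject <- function(config, id) {
  age <- stats::runif(1, config$age_range[1], config$age_range[2])
  list(subject_id = as.character(id), age = age,
       sex = if (stats::runif(1) < config$male_fraction) "male" else "female",
       dominance = if (stats::runif(1) < config$right_fraction) "right" else "left",
       n_days = sample(rep(config$days_per_subject, 2L), 1L),
       eff_log_amp = stats::rnorm(1, 0, config$sd_log_amp_subject),
       eff_logit_move = stats::rnorm(1, 0, config$sd_logit_move_subject),
       eff_freq = stats::rnorm(1, 0, config$sd_freq_subject))
}

#' Generate one synthetic bilateral day
#'
#' Emits 30 Hz triaxial recordings for both limbs (quadrature sinusoid
#' carrier with modulated envelope during movement bouts, 1 g gravity offset
#' on the z axis, white sensor noise) together with the exact ground truth:
#' the per-second bout masks, their duration tallies, the day-level envelope
#' amplitudes and modulation frequency, and the analytic envelope jerk.
#'
#' @param config A [synth_config()].
#' @param subject A [generate_subject()] draw.
#' @param day_index Day number (1-based).
#' @return List with `dom` and `nondom` [triaxial_recording()]s and a
#'   `truth` list.
#' @export
generate_day <- function(config, subject, day_index) {
  n <- as.integer(config$seconds_per_day)
  # day-level driver values
  lm_day <- stats::qlogis(config$move_frac) +
    config$age_slope_logit_move * (subject$age - 10) +
    subject$eff_logit_move + stats::rnorm(1, 0, config$sd_logit_move_day)
  p_day <- stats::plogis(lm_day)
  amp_day <- exp(log(config$amp_median) +
                 config$age_slope_log_amp * (subject$age - 10) +
                 subject$eff_log_amp +
                 stats::rnorm(1, 0, config$sd_log_amp_day))
  fm_day <- max(0.5, config$mod_freq + subject$eff_freq +
                stats::rnorm(1, 0, config$sd_freq_day))

  # dominant-limb schedule; each bout shared with the other limb w.p. coupling
  d_mask <- bout_mask(n, p_day, config$bout_mean_s)
  d_runs <- mask_runs(d_mask)
  shared <- stats::runif(nrow(d_runs)) < config$coupling
  nd_mask <- logical(n)
  for (i in which(shared)) nd_mask[d_runs[i, 1]:d_runs[i, 2]] <- TRUE
  # isolated non-dominant bouts inside dominant rest, with occupancy q such
  # that E[nd time] = nd_move_scale * E[d time]
  q <- (config$nd_move_scale - config$coupling) * p_day / (1 - p_day)
  q <- min(max(q, 0), 0.95)
  if (q > 0) {
    rest_runs <- mask_runs(!d_mask)
    for (i in seq_len(nrow(rest_runs))) {
      len <- rest_runs[i, 2] - rest_runs[i, 1] + 1L
      sub <- bout_mask(len, q, min(config$bout_mean_s, max(3, len / 2)))
      nd_mask[rest_runs[i, 1]:rest_runs[i, 2]] <- sub
    }
  }
  d_mask <- close_short_gaps(d_mask)
  nd_mask <- close_short_gaps(nd_mask)

  emit_limb <- function(mask, amp, limb) {
    n30 <- n * 30L
    tt <- (seq_len(n30) - 1) / 30
    env <- numeric(n30)
    runs <- mask_runs(mask)
    for (i in seq_len(nrow(runs))) {
      s <- runs[i, 1]; e <- runs[i, 2]
      a_bout <- max(config$amp_floor,
                    stats::rlnorm(1, log(amp), config$amp_log_sd))
      i0 <- (s - 1L) * 30L + 1L; i1 <- e * 30L
      seg_t <- tt[i0:i1]
      phase <- stats::runif(1, 0, 2 * pi)
      env_seg <- a_bout * (1 + config$mod_depth * sin(2 * pi * fm_day * seg_t + phase))
      len <- length(env_seg)
      ramp <- rep(1, len)
      # raised-cosine onset/offset from zero: keeps count-filter ringing in
      # the adjacent rest seconds below the dead-band, so the planted mask
      # is recovered exactly by the count chain
      nr <- min(30L, len %/% 2L)
      if (nr > 0) {
        up <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
        ramp[seq_len(nr)] <- up
        ramp[(len - nr + 1L):len] <- rev(up)
      }
      env[i0:i1] <- env_seg * ramp
    }
    ph0 <- stats::runif(1, 0, 2 * pi)
    x <- env * cos(2 * pi * config$carrier_freq * tt + ph0) +
      stats::rnorm(n30, 0, config$noise_sd)
    y <- env * sin(2 * pi * config$carrier_freq * tt + ph0) +
      stats::rnorm(n30, 0, config$noise_sd)
    z <- 1 + stats::rnorm(n30, 0, config$noise_sd)
    q6 <- function(v) round(pmax(pmin(v, 8), -8) * 1e6) / 1e6
    triaxial_recording(q6(x), q6(y), q6(z),
                       fs = 30, subject_id = subject$subject_id, limb = limb,
                       day_index = day_index)
  }
  dom <- emit_limb(d_mask, amp_day, "dominant")
  nondom <- emit_limb(nd_mask, amp_day * config$nd_amp_scale, "non_dominant")

  truth <- list(subject_id = subject$subject_id, day_index = day_index,
                n_seconds = n,
                d_moving_s = sum(d_mask), nd_moving_s = sum(nd_mask),
                simultaneous_s = sum(d_mask & nd_mask),
                d_isolated_s = sum(d_mask & !nd_mask),
                nd_isolated_s = sum(nd_mask & !d_mask),
                d_mask = d_mask, nd_mask = nd_mask,
                amp_d = amp_day, amp_nd = amp_day * config$nd_amp_scale,
                nd_amp_scale = config$nd_amp_scale,
                nd_move_scale = config$nd_move_scale,
                mod_freq = fm_day,
                # mean |d env/dt| of the modulated envelope, mid-bout
                jerk_envelope = amp_day * config$mod_depth *
                  2 * pi * fm_day * 2 / pi)
  list(dom = dom, nondom = nondom, truth = truth)
}

#' Generate a synthetic cohort file tree
#'
#' Draws subjects and days from `config`, writes per-limb-day raw 30 Hz CSV
#' files, a cohort manifest consumable by [read_manifest()] with no special
#' casing, and a ground-truth table keyed by (subject, day). Refuses to
#' write into a non-empty directory.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created; must be empty if it exists).
#' @param seed Integer seed making the whole emission reproducible.
#' @return Invisibly, a list with `manifest` (data.frame),
#'   `ground_truth` (data.frame, mask columns dropped), and the two paths.
#' @export
generate_cohort <- function(config, out_dir, seed = 1L) {
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop("generate_cohort: output directory not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  manifest <- list()
  truths <- list()
  for (si in seq_len(config$n_subjects)) {
    subj <- generate_subject(config, sprintf("S%03d", si))
    for (di in seq_len(subj$n_days)) {
      gd <- generate_day(config, subj, di)
      df <- sprintf("%s_day%d_dom.csv", subj$subject_id, di)
      nf <- sprintf("%s_day%d_nondom.csv", subj$subject_id, di)
      write_raw(gd$dom, file.path(out_dir, df))
      write_raw(gd$nondom, file.path(out_dir, nf))
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = subj$subject_id, age = round(subj$age, 2),
        sex = subj$sex, dominance = subj$dominance, day_index = di,
        dom_file = df, nondom_file = nf, format = "raw",
        stringsAsFactors = FALSE)
      tr <- gd$truth
      tr$d_mask <- NULL; tr$nd_mask <- NULL
      truths[[length(truths) + 1L]] <- as.data.frame(tr)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truths)
  mpath <- file.path(out_dir, "manifest.csv")
  tpath <- file.path(out_dir, "ground_truth.csv")
  data.table::fwrite(manifest, mpath)
  data.table::fwrite(truth, tpath)
  invisible(list(manifest = manifest, ground_truth = truth,
                 manifest_path = mpath, truth_path = tpath))
}

#' Simulate a cohort table directly from the variance-component model
#'
#' Bypasses signal generation and draws one variable straight from the
#' mixed model the day-to-day analysis assumes: `y_ij = mu + b_age * age_i +
#' b_sex * female_i + b_day * j + gamma_i + eps_ij` with `gamma_i ~ N(0,
#' between_sd^2)` and `eps_ij ~ N(0, resid_sd^2)`. Used to validate
#' parameter recovery of [day_variation_model()], [icc2k_cohort()], and
#' [cov_across_days()] at cohort scale without synthesizing signals.
#'
#' @param n_subjects,days_per_subject Cohort dimensions.
#' @param mean Grand mean of the variable.
#' @param between_sd,resid_sd Between-subject and residual SDs.
#' @param age_slope,sex_diff,day_slope Fixed effects (age centered at 10 y;
#'   `sex_diff` is female minus male).
#' @param age_range,male_fraction Demographics.
#' @param variable Name for the simulated column.
#' @return Data.frame with `subject_id`, `day_index`, `age`, `sex`, and the
#'   simulated variable; the planted subject effects are in attribute
#'   `gamma`.
#' @export
simulate_cohort_table <- function(n_subjects = 200, days_per_subject = 3,
                                  mean = 10, between_sd = 2, resid_sd = 1,
                                  age_slope = 0, sex_diff = 0, day_slope = 0,
                                  age_range = c(3, 17), male_fraction = 0.52,
                                  variable = "value") {
  age <- stats::runif(n_subjects, age_range[1], age_range[2])
  sex <- ifelse(stats::runif(n_subjects) < male_fraction, "male", "female")
  gamma <- stats::rnorm(n_subjects, 0, between_sd)
  rows <- lapply(seq_len(n_subjects), function(i) {
    j <- seq_len(days_per_subject)
    data.frame(subject_id = sprintf("S%03d", i), day_index = j,
               age = age[i], sex = sex[i],
               y = mean + age_slope * (age[i] - 10) +
                 sex_diff * (sex[i] == "female") + day_slope * j +
                 gamma[i] + stats::rnorm(days_per_subject, 0, resid_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "y"] <- variable
  attr(out, "gamma") <- gamma
  out
}
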