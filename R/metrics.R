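#' Parameters for the complexity variables
#'
#' Sample-entropy embedding length `m` and tolerance fraction `r` (the
#' tolerance used is `r` times the SD of the analyzed segment), the Welch
#' window length for spectral estimation, and the frequency band over which
#' spectral moments are taken. `m = 2` and `r = 0.2` are the field-standard
#' defaults for physiological series.
#'
#' @param m Embedding length (integer >= 1).
#' @param r Tolerance as a fraction of the segment SD, in (0, 1).
#' @param welch_window Spectral window length in seconds.
#' @param freq_band Band in Hz over which spectral moments are computed.
#' @return A list of class `complexity_params`.
#' @export
complexity_params <- function(m = 2L, r = 0.2, welch_window = 60,
                              freq_band = c(0.2, 12)) {
  if (m < 1) stop("complexity_params: m must be >= 1")
  if (r <= 0 || r >= 1) stop("complexity_params: r must be in (0, 1)")
  structure(list(m = as.integer(m), r = r, welch_window = welch_window,
                 freq_band = freq_band),
            class = "complexity_params")
}

#' Duration variables (hours) from the bilateral movement masks
#'
#' Set arithmetic over per-second moving flags: total movement time is the
#' union of the two limbs' moving seconds, simultaneous time the
#' intersection, and each limb's isolated time its set difference, all
#' divided by 3600. The additivity identities
#' `d_time = d_isolated + simultaneous` and
#' `total = d_isolated + nd_isolated + simultaneous` hold exactly.
#'
#' @param day A [align_bilateral()] day.
#' @return Named list: `total_movement_time`, `d_time`, `nd_time`,
#'   `d_isolated_time`, `nd_isolated_time`, `simultaneous_time`, in hours.
#' @export
duration_variables <- function(day) {
  stopifnot(inherits(day, "bilateral_day"))
  if (!any(day$dom$valid & day$nondom$valid))
    stop("duration_variables: no valid seconds")
  d <- day$dom$moving
  nd <- day$nondom$moving
  list(total_movement_time = sum(d | nd) / 3600,
       d_time = sum(d) / 3600,
       nd_time = sum(nd) / 3600,
       d_isolated_time = sum(d & !nd) / 3600,
       nd_isolated_time = sum(nd & !d) / 3600,
       simultaneous_time = sum(d & nd) / 3600)
}

#' Intensity variables (g) from the per-second count magnitudes
#'
#' Per limb, magnitude is the median of the count-derived acceleration
#' magnitude (`g_vm`) over moving seconds; bilateral magnitude is the sum of
#' the two limb medians; peak magnitude is the maximum `g_vm` over all valid
#' seconds of the recording period (not only moving ones).
#'
#' @param day A [align_bilateral()] day.
#' @return Named list: `d_magnitude`, `nd_magnitude`, `bilateral_magnitude`,
#'   `d_peak_magnitude`, `nd_peak_magnitude`; limbs with no moving seconds
#'   yield `NA` medians (and an `NA` bilateral sum).
#' @export
intensity_variables <- function(day) {
  stopifnot(inherits(day, "bilateral_day"))
  limb_median <- function(es)
    if (any(es$moving)) stats::median(es$g_vm[es$moving]) else NA_real_
  limb_peak <- function(es)
    if (any(es$valid)) max(es$g_vm[es$valid]) else NA_real_
  dm <- limb_median(day$dom)
  nm <- limb_median(day$nondom)
  list(d_magnitude = dm, nd_magnitude = nm,
       bilateral_magnitude = dm + nm,
       d_peak_magnitude = limb_peak(day$dom),
       nd_peak_magnitude = limb_peak(day$nondom))
}

#' Symmetry ratios (non-dominant over dominant)
#'
#' `use_ratio = nd_time / d_time`, `magnitude_ratio = nd_magnitude /
#' d_magnitude`, `variation_ratio = nd_variance / d_variance`. Each ratio is
#' 1 when the limbs are active for the same amount of time, magnitude, and
#' variability respectively.
#'
#' @param durations,magnitudes,variances Outputs of [duration_variables()],
#'   [intensity_variables()], [variance_variables()].
#' @return Named list of the three ratios.
#' @export
symmetry_ratios <- function(durations, magnitudes, variances) {
  ratio <- function(num, den, what) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) stop("symmetry_ratios: zero dominant denominator for ", what)
    num / den
  }
  list(use_ratio = ratio(durations$nd_time, durations$d_time, "use_ratio"),
       magnitude_ratio = ratio(magnitudes$nd_magnitude,
                               magnitudes$d_magnitude, "magnitude_ratio"),
       variation_ratio = ratio(variances$nd_variance, variances$d_variance,
                               "variation_ratio"))
}

#' Jerk asymmetry index
#'
#' `(jerk_nd - jerk_d) / (jerk_nd + jerk_d)`: 0 means similar movement
#' smoothness on the two limbs; the index is bounded in \[-1, +1\] for
#' non-negative jerks and is antisymmetric under a limb swap.
#'
#' @param jerk_nd,jerk_d Average jerk magnitudes (g/s), non-negative.
#' @return The index.
#' @export
jerk_asymmetry <- function(jerk_nd, jerk_d) {
  if (is.na(jerk_nd) || is.na(jerk_d)) return(NA_real_)
  if (jerk_nd < 0 || jerk_d < 0)
    stop("jerk_asymmetry: jerks must be non-negative")
  if (jerk_nd + jerk_d == 0)
    stop("jerk_asymmetry: both jerks zero, index undefined")
  (jerk_nd - jerk_d) / (jerk_nd + jerk_d)
}

#' Movement-variability variables (g)
#'
#' Per limb, the sample standard deviation of the count-derived acceleration
#' magnitude over moving seconds.
#'
#' @param day A [align_bilateral()] day.
#' @return Named list `d_variance`, `nd_variance` (`NA` when a limb has
#'   fewer than 2 moving seconds).
#' @export
variance_variables <- function(day) {
  stopifnot(inherits(day, "bilateral_day"))
  limb_sd <- function(es)
    if (sum(es$moving) >= 2L) stats::sd(es$g_vm[es$moving]) else NA_real_
  list(d_variance = limb_sd(day$dom), nd_variance = limb_sd(day$nondom))
}

#' Start of the hour of maximum activity
#'
#' Slides a 3600 s window in 1 s steps over the epoch series and returns the
#' 0-based start second of the window maximizing summed vector-magnitude
#' counts (invalid seconds contribute zero). Ties break to the earliest
#' start.
#'
#' @param epochs An [epoch_series()].
#' @return Integer start second (0-based).
#' @export
max_activity_hour <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (sum(epochs$valid) < 3600L)
    stop("max_activity_hour: fewer than 3600 valid seconds")
  cv <- ifelse(epochs$valid, epochs$counts_vm, 0)
  n <- length(cv)
  cs <- cumsum(c(0, cv))
  wins <- cs[(3600 + 1):(n + 1)] - cs[1:(n - 3600 + 1)]
  as.integer(which.max(wins) - 1L)
}

#' Sample entropy of a 1 Hz magnitude segment
#'
#' Negative log conditional probability that template pairs matching for `m`
#' points (Chebyshev distance within `r` times the segment SD, self-matches
#' excluded) also match for `m + 1` points, counted directly over all pairs.
#' Constant segments have entropy 0 by convention; if no (m+1)-length match
#' exists the result is `Inf` with attribute `saturated = TRUE`.
#'
#' @param segment Numeric series (typically the 1 Hz `g_vm` of the
#'   hour of maximum activity).
#' @param params [complexity_params()] supplying `m` and `r`.
#' @return Sample entropy (>= 0).
#' @export
sample_entropy <- function(segment, params = complexity_params()) {
  s <- stats::sd(segment)
  if (!is.finite(s)) stop("sample_entropy: segment SD undefined")
  if (s == 0) return(0)
  cnt <- sampen_counts(as.numeric(segment), params$m, params$r * s)
  if (cnt$B == 0) {
    out <- Inf
    attr(out, "saturated") <- TRUE
    return(out)
  }
  if (cnt$A == 0) {
    out <- Inf
    attr(out, "saturated") <- TRUE
    return(out)
  }
  -log(cnt$A / cnt$B)
}

# Upsample a per-second logical mask to the 30 Hz sample grid of a
# magnitude series: a sample inherits the flag of its enclosing epoch.
mask_to_samples <- function(mask, ms) {
  idx <- ms$sec + 1L
  idx[idx > length(mask)] <- length(mask)
  mask[idx]
}

#' Average jerk (g/s) over moving epochs
#'
#' Mean absolute first difference of the 30 Hz bandpassed vector magnitude,
#' scaled by the sampling rate, over sample pairs whose enclosing epochs are
#' both classified moving. Lower values indicate smoother movement.
#'
#' @param mag30 A [magnitude_series()].
#' @param moving Per-second logical moving mask (aligned to the same clock).
#' @return Average jerk in g/s.
#' @export
average_jerk <- function(mag30, moving) {
  stopifnot(inherits(mag30, "magnitude_series"))
  mv <- mask_to_samples(moving, mag30)
  pair <- mv[-length(mv)] & mv[-1L]
  if (!any(pair)) stop("average_jerk: no moving sample pairs")
  dv <- abs(diff(mag30$vm))
  mean(dv[pair]) * mag30$fs
}

# Averaged modified periodogram (Welch) over the moving portion of a 30 Hz
# magnitude series: Hann-tapered, demeaned windows of welch_window seconds
# with 50% overlap, taken over concatenated moving samples.
welch_spectrum <- function(vm, fs, window_s) {
  nw <- as.integer(round(window_s * fs))
  if (length(vm) < nw) return(NULL)
  starts <- seq(1L, length(vm) - nw + 1L, by = max(1L, nw %/% 2L))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann taper
  acc <- numeric(nw %/% 2L)
  for (s in starts) {
    seg <- vm[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[2:(nw %/% 2L + 1L)]
  }
  list(freq = (seq_len(nw %/% 2L)) * fs / nw, power = acc / length(starts))
}

#' Spectral moments of the moving-time acceleration magnitude
#'
#' Estimates the power spectrum of the bandpassed 30 Hz vector magnitude
#' over moving epochs (concatenated moving samples, Hann-tapered demeaned
#' windows of `welch_window` seconds with 50% overlap, averaged), then
#' returns the power-weighted mean frequency and the power-weighted standard
#' deviation of frequency, restricted to `freq_band`.
#'
#' @param mag30 A [magnitude_series()].
#' @param moving Per-second logical moving mask.
#' @param params [complexity_params()].
#' @return Named list `mean_freq`, `freq_variance` (both Hz).
#' @export
frequency_stats <- function(mag30, moving, params = complexity_params()) {
  stopifnot(inherits(mag30, "magnitude_series"))
  mv <- mask_to_samples(moving, mag30)
  vm <- mag30$vm[mv]
  if (length(vm) < params$welch_window * mag30$fs)
    stop("frequency_stats: less than one spectral window of moving data")
  sp <- welch_spectrum(vm, mag30$fs, params$welch_window)
  sel <- sp$freq >= params$freq_band[1] & sp$freq <= params$freq_band[2]
  f <- sp$freq[sel]
  p <- sp$power[sel]
  if (sum(p) <= 0) stop("frequency_stats: zero in-band power")
  mu <- sum(f * p) / sum(p)
  list(mean_freq = mu,
       freq_variance = sqrt(sum((f - mu)^2 * p) / sum(p)))
}

#' Compute the full 25-variable set for one subject-day
#'
#' Runs every variable family on an aligned bilateral day: duration set
#' arithmetic, count-magnitude medians and peaks, symmetry ratios, moving
#' SDs, sample entropy of each limb's hour of maximum activity (1 Hz
#' `g_vm`), and -- when 30 Hz magnitude streams are attached -- average jerk,
#' jerk asymmetry, and spectral moments. Variables whose preconditions fail
#' are carried as `NA` with a reason in the `flags` attribute, never silently
#' zero.
#'
#' @param day A [align_bilateral()] day (should have passed
#'   [validate_wear()]; this is not re-enforced here).
#' @param params [complexity_params()].
#' @return A [variable_set()].
#' @export
compute_variable_set <- function(day, params = complexity_params()) {
  stopifnot(inherits(day, "bilateral_day"))
  flags <- character()
  note <- function(nms, why) {
    f <- stats::setNames(rep(why, length(nms)), nms)
    flags <<- c(flags, f)
  }
  try_or_na <- function(expr, nms) {
    tryCatch(expr, error = function(e) {
      note(nms, conditionMessage(e))
      NULL
    })
  }
  dur <- duration_variables(day)
  mag <- intensity_variables(day)
  vv <- variance_variables(day)
  for (nm in names(mag)) if (is.na(mag[[nm]])) note(nm, "no moving seconds")
  for (nm in names(vv)) if (is.na(vv[[nm]])) note(nm, "fewer than 2 moving seconds")
  ratios <- try_or_na(symmetry_ratios(dur, mag, vv),
                      c("use_ratio", "magnitude_ratio", "variation_ratio"))
  if (is.null(ratios))
    ratios <- list(use_ratio = NA_real_, magnitude_ratio = NA_real_,
                   variation_ratio = NA_real_)

  ent <- function(es, nm) {
    e <- try_or_na({
      start <- max_activity_hour(es)
      seg <- es$g_vm[(start + 1):(start + 3600)]
      sample_entropy(seg, params)
    }, nm)
    if (is.null(e)) NA_real_ else as.numeric(e)
  }
  d_ent <- ent(day$dom, "d_entropy")
  nd_ent <- ent(day$nondom, "nd_entropy")

  jerk_freq <- function(ms, mvmask, pre) {
    if (is.null(ms)) {
      note(paste0(pre, c("_jerk", "_mean_freq", "_freq_variance")),
           "no 30 Hz magnitude stream")
      return(list(jerk = NA_real_, mean_freq = NA_real_,
                  freq_variance = NA_real_))
    }
    j <- try_or_na(average_jerk(ms, mvmask), paste0(pre, "_jerk"))
    fsres <- try_or_na(frequency_stats(ms, mvmask, params),
                       paste0(pre, c("_mean_freq", "_freq_variance")))
    list(jerk = if (is.null(j)) NA_real_ else j,
         mean_freq = if (is.null(fsres)) NA_real_ else fsres$mean_freq,
         freq_variance = if (is.null(fsres)) NA_real_ else fsres$freq_variance)
  }
  djf <- jerk_freq(day$dom_vm30, day$dom$moving, "d")
  njf <- jerk_freq(day$nondom_vm30, day$nondom$moving, "nd")
  jai <- if (is.na(djf$jerk) || is.na(njf$jerk)) {
    if (!any(c("d_jerk", "nd_jerk") %in% names(flags)))
      note("jerk_asymmetry_index", "component jerk undefined")
    NA_real_
  } else {
    tryCatch(jerk_asymmetry(njf$jerk, djf$jerk), error = function(e) {
      note("jerk_asymmetry_index", conditionMessage(e))
      NA_real_
    })
  }

  variable_set(
    c(dur,
      mag,
      list(use_ratio = ratios$use_ratio,
           magnitude_ratio = ratios$magnitude_ratio,
           variation_ratio = ratios$variation_ratio,
           jerk_asymmetry_index = jai),
      vv,
      list(d_entropy = d_ent, nd_entropy = nd_ent,
           d_jerk = djf$jerk, nd_jerk = njf$jerk,
           d_mean_freq = djf$mean_freq, nd_mean_freq = njf$mean_freq,
           d_freq_variance = djf$freq_variance,
           nd_freq_variance = njf$freq_variance)),
    subject_id = day$subject_id, day_index = day$day_index,
    flags = flags, params = params)
}
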