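#' Signal-processing constants for the count chain
#'
#' Fixed defaults of the processing chain: the raw-signal analysis band
#' (0.2--12 Hz), the activity-count band (0.25--2.5 Hz), the count-to-g
#' reconversion factor kappa (0.001664 g per count, an approximation), and
#' the movement threshold tau (2 counts per second). The dead-band,
#' saturation, and quantization step belong to the open reconstruction of the
#' ActiGraph counting chain. Overriding any default emits a warning so that
#' non-standard settings are visible in logs.
#'
#' @param kappa g per activity count.
#' @param tau movement threshold in counts per second (moving iff
#'   `counts_vm >= tau`).
#' @param band_raw,band_counts Bandpass corners in Hz for the 30 Hz stream
#'   and the count chain.
#' @param filter_order Total Butterworth pole count (applied forward and
#'   backward, so the effective magnitude response is squared).
#' @param deadband,saturation,resolution Count-chain rectifier dead-band,
#'   clip level, and 8-bit quantization step, all in g.
#' @return A list of class `conversion_constants`.
#' @export
conversion_constants <- function(kappa = 0.001664, tau = 2,
                                 band_raw = c(0.2, 12),
                                 band_counts = c(0.25, 2.5),
                                 filter_order = 4,
                                 deadband = 0.068, saturation = 2.13,
                                 resolution = 2.13 / 128) {
  defaults <- list(kappa = 0.001664, tau = 2, band_raw = c(0.2, 12),
                   band_counts = c(0.25, 2.5), filter_order = 4,
                   deadband = 0.068, saturation = 2.13,
                   resolution = 2.13 / 128)
  out <- list(kappa = kappa, tau = tau, band_raw = band_raw,
              band_counts = band_counts, filter_order = filter_order,
              deadband = deadband, saturation = saturation,
              resolution = resolution)
  for (nm in names(defaults)) {
    if (!isTRUE(all.equal(out[[nm]], defaults[[nm]])))
      warning("conversion_constants: non-default ", nm, " = ",
              paste(format(out[[nm]]), collapse = ","), call. = FALSE)
  }
  structure(out, class = "conversion_constants")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Butterworth bandpass of `order` total poles applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift. With the default 4 poles the
#' passband gain for a mid-band sinusoid is within \[0.9, 1\] and DC is
#' attenuated far below -40 dB, which removes gravity and other constant
#' acceleration components.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz; must exceed twice the upper corner.
#' @param band Length-2 corner frequencies in Hz.
#' @param order Total pole count (even; default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, band = c(0.2, 12), order = 4) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("bandpass: band must be increasing positive corner frequencies")
  if (fs <= 2 * band[2])
    stop("bandpass: sampling rate must exceed twice the upper corner")
  if (order %% 2 != 0) stop("bandpass: order must be even")
  if (length(x) <= 3 * order)
    stop("bandpass: series shorter than the filter warm-up")
  bf <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  # odd-reflection padding suppresses start/end transients (a constant
  # signal pads to a constant, so gravity leaves no boundary artifact)
  n <- length(x)
  p <- min(n - 1L, as.integer(3 * fs))
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)]
}

#' Euclidean vector magnitude of a triaxial signal
#'
#' @param x,y,z Equal-length numeric sequences.
#' @return `sqrt(x^2 + y^2 + z^2)`, elementwise.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x))
    stop("vector_magnitude: inputs must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' Bandpassed 30 Hz vector-magnitude series
#'
#' Applies the raw-signal bandpass (default 0.2--12 Hz, removing gravity) to
#' each axis and collapses to the per-sample vector magnitude. Per-sample
#' validity is inherited from the enclosing epoch of the recording.
#'
#' @param rec A [triaxial_recording()].
#' @param constants [conversion_constants()].
#' @return An object of class `magnitude_series` with fields `vm`, `fs`,
#'   `t0`, `sec`, `valid`.
#' @export
magnitude_series <- function(rec, constants = conversion_constants()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  fx <- bandpass(rec$x, rec$fs, constants$band_raw, constants$filter_order)
  fy <- bandpass(rec$y, rec$fs, constants$band_raw, constants$filter_order)
  fz <- bandpass(rec$z, rec$fs, constants$band_raw, constants$filter_order)
  structure(
    list(vm = vector_magnitude(fx, fy, fz), fs = rec$fs, t0 = rec$t0,
         sec = rec$sec, valid = rec$valid_sec[rec$sec + 1L],
         subject_id = rec$subject_id, limb = rec$limb,
         day_index = rec$day_index),
    class = "magnitude_series")
}

#' Construct a per-second epoch series
#'
#' Holds per-second per-axis activity counts for one limb-day together with
#' the derived vector-magnitude counts, their reconversion to g, the
#' movement mask (`counts_vm >= tau`, on valid seconds), and the validity
#' mask. `counts_vm` and `g_vm` are always recomputed from the integer
#' per-axis counts, so they satisfy their defining identities exactly.
#'
#' @param counts_x,counts_y,counts_z Non-negative per-second counts.
#' @param valid Logical per-second validity mask (default all valid).
#' @param t0 Clock start of epoch 0, in seconds.
#' @param subject_id,limb,day_index Metadata.
#' @param constants [conversion_constants()] supplying kappa and tau.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(counts_x, counts_y, counts_z, valid = NULL, t0 = 0,
                         subject_id = "unknown",
                         limb = c("dominant", "non_dominant"), day_index = 1L,
                         constants = conversion_constants()) {
  limb <- match.arg(limb)
  n <- length(counts_x)
  if (length(counts_y) != n || length(counts_z) != n)
    stop("epoch_series: count vectors must have equal length")
  if (any(counts_x < 0 | counts_y < 0 | counts_z < 0))
    stop("epoch_series: counts must be non-negative")
  if (is.null(valid)) valid <- rep(TRUE, n)
  counts_vm <- vector_magnitude(counts_x, counts_y, counts_z)
  es <- structure(
    list(second_index = seq_len(n) - 1L,
         counts_x = counts_x, counts_y = counts_y, counts_z = counts_z,
         counts_vm = counts_vm, g_vm = constants$kappa * counts_vm,
         moving = logical(n), valid = as.logical(valid), t0 = t0,
         subject_id = as.character(subject_id), limb = limb,
         day_index = as.integer(day_index),
         kappa = constants$kappa, tau = constants$tau),
    class = "epoch_series")
  es$moving <- movement_mask(es, constants$tau)
  es
}

#' @exportS3Method base::print
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "epoch_series: subject %s, %s limb, day %d\n  %d epochs, %d valid, %d moving (tau = %g counts)\n",
    x$subject_id, x$limb, x$day_index, length(x$second_index),
    sum(x$valid), sum(x$moving), x$tau))
  invisible(x)
}

#' Per-second activity counts from a raw recording
#'
#' Open reconstruction of the ActiGraph counting chain, applied per axis:
#' resample to a uniform 30 Hz grid if needed, bandpass 0.25--2.5 Hz,
#' rectify, saturate at 2.13 g, zero below the 0.068 g dead-band, quantize at
#' the 8-bit step (2.13/128 g), decimate to 10 Hz, and accumulate per epoch
#' second. The resulting counts are approximately, not bit-exactly,
#' equivalent to the proprietary ActiLife output; the companion reconversion
#' kappa = 0.001664 g/count is likewise an approximation.
#'
#' @param rec A [triaxial_recording()].
#' @param constants [conversion_constants()].
#' @return An [epoch_series()] of length `rec$n_sec`.
#' @export
to_activity_counts <- function(rec, constants = conversion_constants()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (any(!is.finite(c(rec$x, rec$y, rec$z)))) {
    bad <- which(!is.finite(rec$x) | !is.finite(rec$y) | !is.finite(rec$z))[1L]
    stop("to_activity_counts: non-finite sample in epoch second ",
         rec$sec[bad])
  }
  fs <- rec$fs
  sec <- rec$sec
  axes <- list(x = rec$x, y = rec$y, z = rec$z)
  if (abs(fs - 30) > 1e-9) {
    # linear interpolation onto a uniform 30 Hz grid
    t_old <- (seq_along(rec$x) - 1) / fs
    t_new <- seq(0, max(t_old), by = 1 / 30)
    axes <- lapply(axes, function(a)
      stats::approx(t_old, a, xout = t_new, rule = 2)$y)
    sec <- as.integer(floor(t_new))
    fs <- 30
  }
  n_sec <- max(sec) + 1L
  one_axis <- function(a) {
    f <- bandpass(a, fs, constants$band_counts, constants$filter_order)
    f <- abs(f)
    f <- pmin(f, constants$saturation)
    f[f < constants$deadband] <- 0
    q <- floor(f / constants$resolution)
    keep <- seq(1L, length(q), by = 3L)     # 30 -> 10 Hz decimation
    agg <- rowsum(q[keep], sec[keep] + 1L)
    counts <- numeric(n_sec)
    counts[as.integer(rownames(agg))] <- agg[, 1L]
    counts
  }
  cx <- one_axis(axes$x); cy <- one_axis(axes$y); cz <- one_axis(axes$z)
  valid <- rec$valid_sec
  if (length(valid) < n_sec) valid <- c(valid, rep(FALSE, n_sec - length(valid)))
  epoch_series(cx, cy, cz, valid = valid[seq_len(n_sec)], t0 = rec$t0,
               subject_id = rec$subject_id, limb = rec$limb,
               day_index = rec$day_index, constants = constants)
}

#' Per-second movement classification
#'
#' A second is classified as moving when its vector-magnitude count reaches
#' the threshold (`counts_vm >= tau`; the boundary second counts as moving)
#' and the second is valid.
#'
#' @param epochs An [epoch_series()].
#' @param tau Threshold in counts (default 2).
#' @return Logical vector of per-second moving flags.
#' @export
movement_mask <- function(epochs, tau = 2) {
  stopifnot(inherits(epochs, "epoch_series"))
  epochs$counts_vm >= tau & epochs$valid
}

#' Write / read an epoch series as CSV
#'
#' Columns: `second_index, counts_x, counts_y, counts_z, counts_vm, g_vm,
#' moving, valid`. On read, `counts_vm` and `g_vm` are recomputed from the
#' integer per-axis counts so the derived columns always satisfy their
#' defining identities.
#'
#' @param epochs An [epoch_series()].
#' @param path CSV path.
#' @return `path` (write) or an [epoch_series()] (read).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_series"))
  data.table::fwrite(
    data.frame(second_index = epochs$second_index,
               counts_x = epochs$counts_x, counts_y = epochs$counts_y,
               counts_z = epochs$counts_z,
               counts_vm = epochs$counts_vm, g_vm = epochs$g_vm,
               moving = epochs$moving, valid = epochs$valid),
    path)
  invisible(path)
}

#' @rdname write_epochs
#' @param subject_id,limb,day_index,t0 Metadata for the read series.
#' @param constants [conversion_constants()].
#' @export
read_epochs <- function(path, subject_id = "unknown",
                        limb = c("dominant", "non_dominant"), day_index = 1L,
                        t0 = 0, constants = conversion_constants()) {
  limb <- match.arg(limb)
  if (!file.exists(path)) stop("read_epochs: file not found: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("second_index", "counts_x", "counts_y", "counts_z", "valid")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("read_epochs: missing columns: ", paste(miss, collapse = ", "))
  epoch_series(dt$counts_x, dt$counts_y, dt$counts_z,
               valid = as.logical(dt$valid), t0 = t0,
               subject_id = subject_id, limb = limb, day_index = day_index,
               constants = constants)
}
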