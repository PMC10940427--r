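#' Construct a one-limb-day triaxial recording
#'
#' Container for one limb-day of raw triaxial acceleration. Samples are in
#' gravitational units (g); the device dynamic range of +/- 8 g is enforced.
#' Each sample is assigned to a 0-based epoch second (`sec`), normally
#' `floor(i / fs)` for sample index `i` but derived from the timestamp column
#' when a file carries one, so that recording gaps map to empty (invalid)
#' epochs.
#'
#' @param x,y,z Equal-length numeric acceleration sequences in g.
#' @param fs Sampling frequency in Hz (nominally 30).
#' @param subject_id,limb,day_index Metadata; `limb` is `"dominant"` or
#'   `"non_dominant"`; `day_index >= 1`.
#' @param t0 Recording start time in seconds (clock origin for alignment).
#' @param time Optional per-sample timestamps (seconds); used to preserve the
#'   original time base across write/read round trips.
#' @param gaps Data frame logging inter-sample gaps longer than 1 s
#'   (columns `after_sample`, `from`, `to`, `duration`).
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(x, y, z, fs, subject_id = "unknown",
                               limb = c("dominant", "non_dominant"),
                               day_index = 1L, t0 = 0, time = NULL,
                               gaps = NULL) {
  limb <- match.arg(limb)
  n <- length(x)
  if (n == 0L) stop("triaxial_recording: empty signal")
  if (length(y) != n || length(z) != n)
    stop("triaxial_recording: x, y, z must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("triaxial_recording: fs must be a positive scalar")
  if (day_index < 1L) stop("triaxial_recording: day_index must be >= 1")
  samp <- c(x, y, z)
  if (any(!is.finite(samp)))
    stop("triaxial_recording: non-finite samples")
  if (any(abs(samp) > 8))
    stop("triaxial_recording: samples outside the +/- 8 g device range")
  if (is.null(time)) {
    sec <- as.integer((seq_len(n) - 1L) %/% fs)
  } else {
    if (length(time) != n) stop("triaxial_recording: time length mismatch")
    sec <- as.integer(floor(time - time[1L]))
    t0 <- time[1L]
  }
  n_sec <- max(sec) + 1L
  # epochs covered by fewer than half the nominal samples are invalid
  cover <- tabulate(sec + 1L, nbins = n_sec)
  structure(
    list(subject_id = as.character(subject_id), limb = limb,
         day_index = as.integer(day_index), fs = fs, t0 = t0,
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         time = time, sec = sec, n_sec = n_sec,
         valid_sec = cover >= fs / 2,
         gaps = if (is.null(gaps)) empty_gap_log() else gaps),
    class = "triaxial_recording")
}

empty_gap_log <- function() {
  data.frame(after_sample = integer(), from = numeric(), to = numeric(),
             duration = numeric())
}

#' @exportS3Method base::print
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "triaxial_recording: subject %s, %s limb, day %d\n  %d samples at %g Hz (%.2f h), %d/%d valid epochs, %d gap(s) > 1 s\n",
    x$subject_id, x$limb, x$day_index, length(x$x), x$fs,
    length(x$x) / x$fs / 3600, sum(x$valid_sec), x$n_sec, nrow(x$gaps)))
  invisible(x)
}

#' Read a raw triaxial acceleration file
#'
#' Reads a delimited text file with header columns `time,x,y,z` (time in
#' seconds) or `x,y,z` (requires `fs`). Timestamps must be strictly
#' increasing; inter-sample gaps longer than 1 s are recorded in the
#' recording's gap log and the uncovered epochs are flagged invalid.
#'
#' @param path File path.
#' @param subject_id,limb,day_index Metadata labels for the recording.
#' @param fs Sampling frequency in Hz; required when the file has no time
#'   column, otherwise inferred from the median timestamp step.
#' @param delim Field delimiter (default comma).
#' @return A [triaxial_recording()].
#' @export
read_raw <- function(path, subject_id = "unknown",
                     limb = c("dominant", "non_dominant"), day_index = 1L,
                     fs = NULL, delim = ",") {
  limb <- match.arg(limb)
  if (!file.exists(path)) stop("read_raw: file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = delim, header = TRUE, data.table = FALSE),
    error = function(e) stop("read_raw: parse error in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L) stop("read_raw: empty file: ", path)
  cols <- tolower(names(dt))
  names(dt) <- cols
  has_time <- all(c("time", "x", "y", "z") %in% cols)
  if (!has_time && !all(c("x", "y", "z") %in% cols))
    stop("read_raw: need columns time,x,y,z or x,y,z in ", path)
  for (cl in intersect(c("time", "x", "y", "z"), cols)) {
    if (!is.numeric(dt[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[cl]]))))[1L]
      stop(sprintf("read_raw: non-numeric value in column '%s' at data line %d of %s",
                   cl, if (is.na(bad)) 1L else bad, path))
    }
  }
  time <- NULL
  gaps <- empty_gap_log()
  if (has_time) {
    time <- dt$time
    dtt <- diff(time)
    if (any(dtt <= 0))
      stop("read_raw: non-monotonic timestamps at data line ",
           which(dtt <= 0)[1L] + 1L, " of ", path)
    if (is.null(fs)) {
      if (!length(dtt))
        stop("read_raw: fs not inferable from a single sample in ", path)
      fs <- 1 / stats::median(dtt)
      if (abs(fs - round(fs)) < 0.01) fs <- round(fs)
    }
    gi <- which(dtt > 1)
    if (length(gi)) {
      gaps <- data.frame(after_sample = gi, from = time[gi],
                         to = time[gi + 1L], duration = dtt[gi])
    }
  } else if (is.null(fs)) {
    stop("read_raw: fs not declared and no time column in ", path)
  }
  triaxial_recording(dt$x, dt$y, dt$z, fs = fs, subject_id = subject_id,
                     limb = limb, day_index = day_index, time = time,
                     gaps = gaps)
}

#' Canonical storage quantization for acceleration samples
#'
#' Snaps values to the 1e-6 g decimal grid as the text parser realizes it
#' (the double nearest each six-decimal string). 1e-6 g is far below the
#' ~0.004 g resolution of a 12-bit +/- 8 g device, and values on this grid
#' survive a CSV write/read round trip bit-identically.
#'
#' @param x Numeric vector in g.
#' @return `x` on the canonical grid.
#' @export
quantize_g <- function(x) as.numeric(sprintf("%.6f", x))

#' Write a raw triaxial recording to delimited text
#'
#' Samples and timestamps are stored on the canonical 1e-6 g / 1e-6 s grid
#' (see [quantize_g()]), which makes the write/read round trip
#' bit-identical.
#'
#' @param rec A [triaxial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  time <- if (!is.null(rec$time)) rec$time else
    rec$t0 + (seq_along(rec$x) - 1) / rec$fs
  data.table::fwrite(
    data.frame(time = quantize_g(time), x = quantize_g(rec$x),
               y = quantize_g(rec$y), z = quantize_g(rec$z)),
    path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per subject-day and columns
#' `subject_id, age, sex, dominance, day_index, dom_file, nondom_file`
#' (and optionally `format`, `"raw"` or `"epoch"`). File paths are resolved
#' relative to the manifest location. Ages must lie in [3, 17]; missing hand
#' dominance (`""` or `"missing"`) is treated as right-handed.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with normalized columns and absolute file paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("read_manifest: file not found: ", path)
  m <- data.table::fread(path, data.table = FALSE)
  need <- c("subject_id", "age", "sex", "dominance", "day_index",
            "dom_file", "nondom_file")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("read_manifest: missing columns: ", paste(miss, collapse = ", "))
  if (!"format" %in% names(m)) m$format <- "raw"
  if (any(!is.finite(m$age)) || any(m$age < 3 | m$age > 17))
    stop("read_manifest: ages must lie in [3, 17]")
  if (!all(m$sex %in% c("male", "female")))
    stop("read_manifest: sex must be 'male' or 'female'")
  m$dominance[is.na(m$dominance) | m$dominance %in% c("", "missing")] <- "right"
  if (!all(m$dominance %in% c("right", "left")))
    stop("read_manifest: dominance must be right/left/missing")
  for (s in unique(m$subject_id)) {
    sub <- m[m$subject_id == s, ]
    if (length(unique(sub$age)) > 1L || length(unique(sub$sex)) > 1L)
      stop("read_manifest: inconsistent age/sex for subject ", s)
  }
  root <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(grepl("^/", p), p, file.path(root, p))
  m$dom_file <- abspath(m$dom_file)
  m$nondom_file <- abspath(m$nondom_file)
  m$subject_id <- as.character(m$subject_id)
  m
}

#' Align two limbs' epoch series into a bilateral day
#'
#' Trims the dominant and non-dominant per-second epoch series (and, when
#' supplied, their 30 Hz magnitude series) to their common time overlap on
#' whole-second boundaries. Epochs are 0-based half-open 1 s bins anchored at
#' the trimmed common start.
#'
#' @param dom,nondom [epoch_series()] for the two limbs of one subject-day.
#' @param dom_vm30,nondom_vm30 Optional [magnitude_series()] (30 Hz bandpassed
#'   vector magnitude) for jerk and spectral variables.
#' @return An object of class `bilateral_day`.
#' @export
align_bilateral <- function(dom, nondom, dom_vm30 = NULL, nondom_vm30 = NULL) {
  stopifnot(inherits(dom, "epoch_series"), inherits(nondom, "epoch_series"))
  if (dom$subject_id != nondom$subject_id ||
      dom$day_index != nondom$day_index)
    stop("align_bilateral: limbs belong to different subject-days")
  s1 <- round(dom$t0); s2 <- round(nondom$t0)
  start <- max(s1, s2)
  end <- min(s1 + length(dom$second_index), s2 + length(nondom$second_index))
  if (end <= start)
    stop("align_bilateral: no temporal overlap between limbs")
  n <- as.integer(end - start)
  trim <- function(es, s0) {
    off <- as.integer(start - s0)
    idx <- seq_len(n) + off
    for (f in c("second_index", "counts_x", "counts_y", "counts_z",
                "counts_vm", "g_vm", "moving", "valid"))
      es[[f]] <- es[[f]][idx]
    es$second_index <- seq_len(n) - 1L
    es$t0 <- start
    es
  }
  trim30 <- function(ms, s0) {
    if (is.null(ms)) return(NULL)
    off <- as.integer(round((start - round(ms$t0)) * ms$fs))
    idx <- seq_len(n * ms$fs) + off
    ms$vm <- ms$vm[idx]
    ms$valid <- ms$valid[idx]
    ms$t0 <- start
    ms
  }
  structure(
    list(subject_id = dom$subject_id, day_index = dom$day_index,
         n_epochs = n,
         dom = trim(dom, s1), nondom = trim(nondom, s2),
         dom_vm30 = trim30(dom_vm30, if (is.null(dom_vm30)) NA else dom_vm30$t0),
         nondom_vm30 = trim30(nondom_vm30,
                              if (is.null(nondom_vm30)) NA else nondom_vm30$t0)),
    class = "bilateral_day")
}

#' @exportS3Method base::print
print.bilateral_day <- function(x, ...) {
  cat(sprintf(
    "bilateral_day: subject %s, day %d, %d aligned epochs (%.2f h)%s\n",
    x$subject_id, x$day_index, x$n_epochs, x$n_epochs / 3600,
    if (is.null(x$dom_vm30)) "" else ", with 30 Hz magnitude streams"))
  invisible(x)
}

#' Wear-time report for a bilateral day
#'
#' Hours worn are counted as valid epoch-seconds on the shorter limb divided
#' by 3600; a day is included when it exceeds `min_hours` (strictly).
#' Sleep periods are not excluded.
#'
#' @param day A [align_bilateral()] day.
#' @param min_hours Inclusion threshold in hours (default 10).
#' @return A list with `hours_worn` and logical `included`.
#' @export
validate_wear <- function(day, min_hours = 10) {
  stopifnot(inherits(day, "bilateral_day"))
  hours <- min(sum(day$dom$valid), sum(day$nondom$valid)) / 3600
  list(hours_worn = hours, included = hours > min_hours)
}
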