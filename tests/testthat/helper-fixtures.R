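# Fixtures built in code: small epoch series, bilateral days, and magnitude
# streams used across the unit tests.

# epoch series with prescribed vector-magnitude counts on the x axis
make_epochs <- function(counts, valid = NULL, limb = "dominant",
                        subject = "T1", day = 1L, t0 = 0) {
  epoch_series(counts_x = counts, counts_y = numeric(length(counts)),
               counts_z = numeric(length(counts)), valid = valid, t0 = t0,
               subject_id = subject, limb = limb, day_index = day)
}

# bilateral day from two per-second moving masks: moving seconds get counts
# well above the 2-count threshold (scaled so g_vm varies across seconds)
day_from_masks <- function(d_mask, nd_mask, d_counts = NULL,
                           nd_counts = NULL, subject = "T1", day = 1L) {
  mk <- function(mask, counts, limb) {
    if (is.null(counts)) counts <- ifelse(mask, 100, 0)
    make_epochs(counts, limb = limb, subject = subject, day = day)
  }
  align_bilateral(mk(d_mask, d_counts, "dominant"),
                  mk(nd_mask, nd_counts, "non_dominant"))
}

# magnitude_series wrapper around a bare 30 Hz vm vector
make_ms <- function(vm, fs = 30, t0 = 0, limb = "dominant") {
  n_sec <- as.integer(ceiling(length(vm) / fs))
  structure(
    list(vm = vm, fs = fs, t0 = t0,
         sec = as.integer((seq_along(vm) - 1L) %/% fs),
         valid = rep(TRUE, length(vm)),
         subject_id = "T1", limb = limb, day_index = 1L),
    class = "magnitude_series")
}

# one small generated bilateral day (cached per session; several tests
# reuse it read-only)
small_generated_day <- local({
  cache <- NULL
  function(seconds = 3000, seed = 42, ...) {
    key <- paste(seconds, seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$val)
    set.seed(seed)
    cfg <- synth_config(n_subjects = 1, days_per_subject = 1,
                        seconds_per_day = seconds, ...)
    subj <- generate_subject(cfg, "S1")
    gd <- generate_day(cfg, subj, 1)
    val <- list(gd = gd, day = process_day(gd$dom, gd$nondom))
    cache <<- list(key = key, val = val)
    val
  }
})

# independent brute-force sample entropy: embedding matrices and explicit
# Chebyshev distances, no shared code with the package kernel
sampen_brute <- function(x, m, r_abs) {
  n <- length(x)
  nt <- n - m
  emb <- function(len)
    sapply(0:(len - 1), function(k) x[seq_len(nt) + k])  # nt x len
  Em <- emb(m); Em1 <- emb(m + 1)
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(Em[i, ] - Em[j, ])) <= r_abs) {
        B <- B + 1
        if (max(abs(Em1[i, ] - Em1[j, ])) <= r_abs) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(Inf)
  -log(A / B)
}

# hand-computed ICC(2,k) via the standard two-way ANOVA table from aov()
icc2k_aov <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   day = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- summary(stats::aov(y ~ subj + day, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["day", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / nrow(mat))
}

# cohort table with all 25 variables drawn from mild noise, optionally
# overriding chosen columns
toy_cohort <- function(n_subjects = 8, days = 2, seed = 1, override = list()) {
  set.seed(seed)
  reg <- limbwear_variables()
  n <- n_subjects * days
  df <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = days),
    day_index = rep(seq_len(days), n_subjects),
    age = rep(round(runif(n_subjects, 3, 17), 1), each = days),
    sex = rep(ifelse(runif(n_subjects) < 0.5, "male", "female"), each = days),
    dominance = "right", stringsAsFactors = FALSE)
  for (nm in reg$name) df[[nm]] <- rnorm(n, 10, 1)
  for (nm in names(override)) df[[nm]] <- override[[nm]]
  cohort_table(df)
}
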