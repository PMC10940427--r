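#' Assemble a cohort table of subject-day variable rows
#'
#' Validates and classes a data.frame with one row per subject-day:
#' identifier columns `subject_id`, `day_index`, demographics `age` (years),
#' `sex` (`"male"`/`"female"`), `dominance`, and the 25 variable columns
#' named as in [limbwear_variables()]. Each subject must have a single
#' age/sex; any number of days (>= 1) is accepted.
#'
#' @param df The subject-day data.frame.
#' @return `df` with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  need <- c("subject_id", "day_index", "age", "sex",
            limbwear_variables()$name)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort_table: missing columns: ", paste(miss, collapse = ", "))
  ag <- tapply(df$age, df$subject_id, function(a) length(unique(a)))
  sx <- tapply(df$sex, df$subject_id, function(a) length(unique(a)))
  if (any(ag > 1) || any(sx > 1))
    stop("cohort_table: age and sex must be constant within subject")
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("cohort_table", class(df)[class(df) != "cohort_table"])
  df
}

#' Per-variable descriptive statistics over subject-days
#'
#' Mean, SD, SE (= SD / sqrt(n)), minimum, quartiles (linear interpolation),
#' and maximum for each variable, over all subject-day rows with a defined
#' value. Variables with no defined values are omitted with a message.
#'
#' @param cohort A [cohort_table()].
#' @return Data.frame with one row per variable.
#' @export
descriptives <- function(cohort) {
  if (nrow(cohort) < 2L) stop("descriptives: need at least 2 rows")
  vars <- limbwear_variables()$name
  rows <- lapply(vars, function(nm) {
    v <- cohort[[nm]]
    v <- v[is.finite(v)]
    if (!length(v)) {
      message("descriptives: variable ", nm, " has no defined values; omitted")
      return(NULL)
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = nm, n = length(v), mean = mean(v),
               sd = stats::sd(v), se = stats::sd(v) / sqrt(length(v)),
               min = min(v), q1 = q[1], median = q[2], q3 = q[3],
               max = max(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average each subject's days into one row per subject
#'
#' Means are taken over available (non-missing) days per variable, so a day
#' with one flagged-undefined variable still contributes its other
#' variables.
#'
#' @param cohort A [cohort_table()].
#' @return Data.frame with one row per subject (demographics preserved).
#' @export
subject_average <- function(cohort) {
  vars <- intersect(limbwear_variables()$name, names(cohort))
  ids <- unique(cohort$subject_id)
  rows <- lapply(ids, function(s) {
    sub <- cohort[cohort$subject_id == s, , drop = FALSE]
    out <- data.frame(subject_id = s, age = sub$age[1L], sex = sub$sex[1L],
                      n_days = nrow(sub), stringsAsFactors = FALSE)
    if ("dominance" %in% names(sub)) out$dominance <- sub$dominance[1L]
    for (nm in vars) {
      v <- sub[[nm]]
      out[[nm]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  })
  do.call(rbind, rows)
}

cor_or_na <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson correlation screen over subject-averaged variables
#'
#' Three products, all on the subject-averaged table (one observation per
#' participant): the dominant vs. non-dominant correlation for each paired
#' variable, the correlation of each variable with age, and the full
#' inter-variable correlation matrix, each with two-sided p-values and
#' significance flags at the Bonferroni-adjusted threshold `alpha / 25`.
#' Zero-variance variables yield `NA` correlations.
#'
#' @param cohort A [cohort_table()] (averaged internally) or an already
#'   subject-averaged table.
#' @param alpha Family-wise level before correction (default 0.05).
#' @return List with data.frames `d_nd` and `age`, matrices `r` and `p`,
#'   and the adjusted threshold `alpha_adjusted`.
#' @export
correlation_screen <- function(cohort, alpha = 0.05) {
  avg <- if (anyDuplicated(cohort$subject_id)) subject_average(cohort)
         else cohort
  reg <- limbwear_variables()
  thr <- bonferroni_threshold(alpha, nrow(reg))
  paired <- reg[!is.na(reg$paired), ]
  d_nd <- do.call(rbind, lapply(seq_len(nrow(paired)), function(i) {
    ct <- cor_or_na(avg[[paired$name[i]]], avg[[paired$paired[i]]])
    data.frame(dominant = paired$name[i], non_dominant = paired$paired[i],
               r = ct$r, p = ct$p, n = ct$n,
               significant = !is.na(ct$p) & ct$p < thr,
               stringsAsFactors = FALSE)
  }))
  age <- do.call(rbind, lapply(reg$name, function(nm) {
    ct <- cor_or_na(avg[[nm]], avg$age)
    data.frame(variable = nm, r = ct$r, p = ct$p, n = ct$n,
               significant = !is.na(ct$p) & ct$p < thr,
               stringsAsFactors = FALSE)
  }))
  k <- nrow(reg)
  rmat <- matrix(NA_real_, k, k, dimnames = list(reg$name, reg$name))
  pmat <- rmat
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        v <- avg[[reg$name[i]]]
        rmat[i, j] <- if (any(is.finite(v))) 1 else NA_real_
        pmat[i, j] <- 0
      } else if (j < i) {
        rmat[i, j] <- rmat[j, i]; pmat[i, j] <- pmat[j, i]
      } else {
        ct <- cor_or_na(avg[[reg$name[i]]], avg[[reg$name[j]]])
        rmat[i, j] <- ct$r; pmat[i, j] <- ct$p
      }
    }
  }
  list(d_nd = d_nd, age = age, r = rmat, p = pmat, alpha_adjusted = thr)
}

#' Sex comparison of a subject-averaged variable
#'
#' Welch two-sample t test on subject-averaged values; the reported
#' difference is female mean minus male mean, so negative values indicate
#' higher values in males.
#'
#' @param cohort A [cohort_table()] (averaged internally).
#' @param variable Variable name.
#' @return List `difference`, `t`, `df`, `p`.
#' @export
sex_comparison <- function(cohort, variable) {
  avg <- if (anyDuplicated(cohort$subject_id)) subject_average(cohort)
         else cohort
  f <- avg[[variable]][avg$sex == "female"]
  m <- avg[[variable]][avg$sex == "male"]
  f <- f[is.finite(f)]; m <- m[is.finite(m)]
  if (length(f) < 2L || length(m) < 2L)
    stop("sex_comparison: both sexes must be present with >= 2 subjects")
  tt <- stats::t.test(f, m, var.equal = FALSE)
  list(difference = mean(f) - mean(m), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Closed-form mean-squares estimator on a complete subjects-by-days matrix:
#' `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)` with `MS_R` the between-row
#' (subject) mean square, `MS_C` the between-column (day) mean square, `MS_E`
#' the residual mean square, and `n` the number of subjects.
#'
#' @param mat Numeric matrix, subjects in rows, the k repeated days in
#'   columns; complete (no `NA`), `>= 2` rows and `>= 2` columns.
#' @return The ICC(2,k) estimate.
#' @export
icc2k <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("icc2k: matrix must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L) stop("icc2k: need at least 2 subjects")
  if (k < 2L) stop("icc2k: need at least 2 days")
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  mse <- sum((mat - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

#' ICC(2,k) for one variable of an unbalanced cohort
#'
#' Subjects contribute unequal day counts (2--4 in the wearing protocols the
#' package targets). For the closed-form ICC each subject is truncated to
#' the minimum common day count k (earliest days first) and subjects with a
#' missing value among those days are dropped; alongside, a
#' variance-components ICC is estimated from all available data via a
#' crossed random-effects model, `sigma_s^2 / (sigma_s^2 + (sigma_d^2 +
#' sigma_e^2) / k)`.
#'
#' @param cohort A [cohort_table()].
#' @param variable Variable name.
#' @return List `icc2k`, `k`, `n_subjects`, `icc_vc`.
#' @export
icc2k_cohort <- function(cohort, variable) {
  v <- cohort[[variable]]
  keep <- is.finite(v)
  dat <- data.frame(subject_id = cohort$subject_id[keep],
                    day_index = cohort$day_index[keep], y = v[keep])
  counts <- table(dat$subject_id)
  counts <- counts[counts >= 2L]
  if (length(counts) < 2L)
    stop("icc2k_cohort: need >= 2 subjects with >= 2 days for ", variable)
  k <- min(counts)
  ids <- names(counts)
  mat <- t(vapply(ids, function(s) {
    d <- dat[dat$subject_id == s, ]
    d <- d[order(d$day_index), ]
    d$y[seq_len(k)]
  }, numeric(k)))
  vc <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | subject_id) + (1 | day_index), data = dat)))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    sg <- function(g) {
      i <- vcs$grp == g
      if (any(i)) vcs$vcov[i] else 0
    }
    s2s <- sg("subject_id"); s2d <- sg("day_index"); s2e <- sg("Residual")
    s2s / (s2s + (s2d + s2e) / k)
  }, error = function(e) NA_real_)
  list(icc2k = icc2k(mat), k = as.integer(k), n_subjects = length(ids),
       icc_vc = vc)
}

#' Mixed-model decomposition of day-to-day variation
#'
#' Fits, by REML, `y ~ age + age^2 + age^3 + sex + day + (1 | subject)` with
#' an orthogonal cubic age polynomial (degree reduced when the cohort has
#' too few distinct ages), sex, a linear day effect, and a random subject
#' intercept. The residual standard deviation is the unexplained day-to-day
#' variation in the variable's own units after the systematic sources are
#' removed.
#'
#' @param cohort A [cohort_table()].
#' @param variable Variable name.
#' @return List `sigma_eps`, `fixed` (named fixed-effect estimates),
#'   `n_obs`, `singular` (boundary-fit flag), and the `lme4` `fit`.
#' @export
day_variation_model <- function(cohort, variable) {
  v <- cohort[[variable]]
  keep <- is.finite(v)
  dat <- data.frame(y = v[keep], age = cohort$age[keep],
                    sex = factor(cohort$sex[keep],
                                 levels = c("male", "female")),
                    day = as.numeric(cohort$day_index[keep]),
                    subject_id = cohort$subject_id[keep])
  if (!any(table(dat$subject_id) >= 2L))
    stop("day_variation_model: no subject has repeated days for ", variable)
  deg <- min(3L, length(unique(dat$age)) - 1L)
  if (deg < 1L) stop("day_variation_model: age has no variation")
  form <- stats::as.formula(
    sprintf("y ~ poly(age, %d) + sex + day + (1 | subject_id)", deg))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = dat, REML = TRUE)),
    error = function(e)
      stop("day_variation_model: fit failed for ", variable, ": ",
           conditionMessage(e)))
  list(sigma_eps = stats::sigma(fit),
       fixed = lme4::fixef(fit),
       n_obs = nrow(dat),
       singular = lme4::isSingular(fit),
       fit = fit)
}

#' Mean per-subject coefficient of variation across days
#'
#' For each subject with at least two defined days, the sample SD across
#' days divided by the subject's mean; returned as the mean of these
#' per-subject values, expressed as a percentage. Subjects whose mean is
#' numerically indistinguishable from zero are excluded with a warning
#' (a near-zero mean makes the ratio uninformatively large).
#'
#' @param cohort A [cohort_table()].
#' @param variable Variable name.
#' @return List `mean_cov_pct`, `n_subjects`, `n_excluded`.
#' @export
cov_across_days <- function(cohort, variable) {
  v <- cohort[[variable]]
  keep <- is.finite(v)
  sp <- split(v[keep], cohort$subject_id[keep])
  sp <- sp[vapply(sp, length, 1L) >= 2L]
  if (!length(sp)) stop("cov_across_days: no subject has >= 2 days")
  means <- vapply(sp, mean, 1)
  sds <- vapply(sp, stats::sd, 1)
  bad <- abs(means) < 1e-8
  if (any(bad))
    warning("cov_across_days: ", sum(bad), " subject(s) excluded for ",
            variable, ": mean indistinguishable from zero", call. = FALSE)
  covs <- sds[!bad] / means[!bad]
  list(mean_cov_pct = mean(covs) * 100, n_subjects = sum(!bad),
       n_excluded = sum(bad))
}

#' Bonferroni-adjusted per-test threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 25)  # 0.002
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("bonferroni_threshold: alpha must be in (0, 1)")
  if (m < 1) stop("bonferroni_threshold: m must be >= 1")
  alpha / m
}

#' Full reliability and cohort-analysis report
#'
#' Runs the complete statistical battery for every variable: the dominant
#' vs. non-dominant correlation (for paired variables), the correlation with
#' age, the sex comparison (female minus male), ICC(2,k) agreement across
#' days, the mixed-model residual SD (typical day-to-day variation in the
#' variable's units), and the mean per-subject coefficient of variation.
#' Significance flags use the Bonferroni threshold `alpha / 25`.
#'
#' @param cohort A [cohort_table()].
#' @param alpha Family-wise level (default 0.05).
#' @return A data.frame of class `limbwear_reliability`, one row per
#'   variable, with the adjusted threshold in attribute `alpha_adjusted`.
#' @export
reliability_report <- function(cohort, alpha = 0.05) {
  reg <- limbwear_variables()
  thr <- bonferroni_threshold(alpha, nrow(reg))
  scr <- correlation_screen(cohort, alpha)
  safe <- function(expr) tryCatch(expr, error = function(e) NULL,
                                  warning = function(w) {
                                    tryCatch(suppressWarnings(expr),
                                             error = function(e) NULL)
                                  })
  rows <- lapply(reg$name, function(nm) {
    pr <- reg$paired[reg$name == nm]
    dn <- if (!is.na(pr)) scr$d_nd[scr$d_nd$dominant == nm, ] else NULL
    agerow <- scr$age[scr$age$variable == nm, ]
    sx <- safe(sex_comparison(cohort, nm))
    ic <- safe(icc2k_cohort(cohort, nm))
    dm <- safe(day_variation_model(cohort, nm))
    cv <- safe(cov_across_days(cohort, nm))
    data.frame(
      variable = nm,
      d_nd_correlation = if (!is.null(dn)) dn$r else NA_real_,
      d_nd_p = if (!is.null(dn)) dn$p else NA_real_,
      age_correlation = agerow$r,
      age_p = agerow$p,
      sex_difference = if (!is.null(sx)) sx$difference else NA_real_,
      sex_p = if (!is.null(sx)) sx$p else NA_real_,
      icc2k = if (!is.null(ic)) ic$icc2k else NA_real_,
      residual_sd = if (!is.null(dm)) dm$sigma_eps else NA_real_,
      mean_cov_pct = if (!is.null(cv)) cv$mean_cov_pct else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$age_significant <- !is.na(out$age_p) & out$age_p < thr
  out$sex_significant <- !is.na(out$sex_p) & out$sex_p < thr
  out$d_nd_significant <- !is.na(out$d_nd_p) & out$d_nd_p < thr
  structure(out, class = c("limbwear_reliability", "data.frame"),
            alpha_adjusted = thr, n_subjects = length(unique(cohort$subject_id)),
            n_days = nrow(cohort))
}

#' @exportS3Method base::print
print.limbwear_reliability <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Reliability report: %d subjects, %d subject-days, adjusted threshold p < %g\n\n",
    attr(x, "n_subjects"), attr(x, "n_days"), attr(x, "alpha_adjusted")))
  show <- data.frame(
    variable = x$variable,
    `D-ND r` = round(x$d_nd_correlation, digits),
    `age r` = round(x$age_correlation, digits),
    `sex diff` = signif(x$sex_difference, digits),
    `ICC(2,k)` = round(x$icc2k, digits),
    `day-to-day SD` = signif(x$residual_sd, digits),
    `CoV %` = round(x$mean_cov_pct, 1),
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method base::summary
summary.limbwear_reliability <- function(object, ...) {
  cat(sprintf("ICC(2,k) range: %.2f-%.2f\n",
              min(object$icc2k, na.rm = TRUE),
              max(object$icc2k, na.rm = TRUE)))
  cv <- object$mean_cov_pct[object$variable != "jerk_asymmetry_index"]
  cat(sprintf("Coefficient of variation range (excluding jerk asymmetry): %.1f%%-%.1f%%\n",
              min(cv, na.rm = TRUE), max(cv, na.rm = TRUE)))
  cat(sprintf("Variables with a significant age correlation: %d\n",
              sum(object$age_significant, na.rm = TRUE)))
  cat(sprintf("Variables with a significant sex difference: %d\n",
              sum(object$sex_significant, na.rm = TRUE)))
  invisible(object)
}
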