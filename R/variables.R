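#' Registry of the 25 upper-limb accelerometry variables
#'
#' One row per variable, in canonical reporting order: the six duration
#' variables (hours), five intensity variables (g), four symmetry variables
#' (unitless), and ten complexity variables (g, unitless, g/s, Hz). The
#' `column` field gives the unit-suffixed CSV column name used by
#' [cmd_extract()] and expected by [cmd_cohort_stats()]; `paired` links each
#' dominant-limb variable to its non-dominant counterpart for the side-to-side
#' correlation screen.
#'
#' @return A data.frame with columns `name`, `unit`, `column`, `category`,
#'   and `paired` (the non-dominant partner of a dominant variable, or `NA`).
#' @examples
#' limbwear_variables()$name
#' @export
limbwear_variables <- function() {
  v <- rbind(
    c("total_movement_time", "hrs", "duration", NA),
    c("d_time",              "hrs", "duration", "nd_time"),
    c("nd_time",             "hrs", "duration", NA),
    c("d_isolated_time",     "hrs", "duration", "nd_isolated_time"),
    c("nd_isolated_time",    "hrs", "duration", NA),
    c("simultaneous_time",   "hrs", "duration", NA),
    c("d_magnitude",         "g",   "intensity", "nd_magnitude"),
    c("nd_magnitude",        "g",   "intensity", NA),
    c("bilateral_magnitude", "g",   "intensity", NA),
    c("d_peak_magnitude",    "g",   "intensity", "nd_peak_magnitude"),
    c("nd_peak_magnitude",   "g",   "intensity", NA),
    c("use_ratio",           "",    "symmetry", NA),
    c("magnitude_ratio",     "",    "symmetry", NA),
    c("variation_ratio",     "",    "symmetry", NA),
    c("jerk_asymmetry_index", "",   "symmetry", NA),
    c("d_variance",          "g",   "complexity", "nd_variance"),
    c("nd_variance",         "g",   "complexity", NA),
    c("d_entropy",           "",    "complexity", "nd_entropy"),
    c("nd_entropy",          "",    "complexity", NA),
    c("d_jerk",              "g_per_s", "complexity", "nd_jerk"),
    c("nd_jerk",             "g_per_s", "complexity", NA),
    c("d_mean_freq",         "hz",  "complexity", "nd_mean_freq"),
    c("nd_mean_freq",        "hz",  "complexity", NA),
    c("d_freq_variance",     "hz",  "complexity", "nd_freq_variance"),
    c("nd_freq_variance",    "hz",  "complexity", NA)
  )
  out <- data.frame(
    name = v[, 1], unit = v[, 2], category = v[, 3], paired = v[, 4],
    stringsAsFactors = FALSE
  )
  out$column <- ifelse(out$unit == "", out$name,
                       paste(out$name, out$unit, sep = "_"))
  out[, c("name", "unit", "column", "category", "paired")]
}

#' Construct a variable set for one subject-day
#'
#' Bundles the 25 variable values with the identifying metadata and the
#' parameter provenance for one subject-day. Normally produced by
#' [compute_variable_set()]; exposed so that externally computed rows can be
#' assembled into a cohort table.
#'
#' @param values Named list or vector covering the 25 names in
#'   [limbwear_variables()]; `NA` marks a value flagged undefined.
#' @param subject_id,day_index Identifiers for the subject-day.
#' @param flags Named character vector of reasons for undefined values.
#' @param params The [complexity_params()] used, for provenance.
#' @return An object of class `variable_set`: a named list with attributes.
#' @export
variable_set <- function(values, subject_id = NA_character_,
                         day_index = NA_integer_, flags = character(),
                         params = complexity_params()) {
  reg <- limbwear_variables()
  missing_vars <- setdiff(reg$name, names(values))
  if (length(missing_vars)) {
    stop("variable_set: missing variables: ",
         paste(missing_vars, collapse = ", "))
  }
  vals <- as.list(values)[reg$name]
  structure(vals,
            class = "variable_set",
            subject_id = as.character(subject_id),
            day_index = as.integer(day_index),
            flags = flags,
            params = params)
}

#' @exportS3Method base::print
print.variable_set <- function(x, ...) {
  reg <- limbwear_variables()
  cat(sprintf("Upper-limb accelerometry variables: subject %s, day %s\n",
              attr(x, "subject_id"), attr(x, "day_index")))
  for (cat_name in unique(reg$category)) {
    cat(sprintf("  %s:\n", cat_name))
    for (nm in reg$name[reg$category == cat_name]) {
      u <- reg$unit[reg$name == nm]
      val <- x[[nm]]
      cat(sprintf("    %-22s %s %s\n", nm,
                  if (is.na(val)) "NA" else formatC(val, digits = 4, format = "fg"),
                  u))
    }
  }
  fl <- attr(x, "flags")
  if (length(fl)) {
    cat("  flagged undefined:\n")
    for (nm in names(fl)) cat(sprintf("    %s: %s\n", nm, fl[[nm]]))
  }
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.variable_set <- function(x, ...) {
  df <- data.frame(subject_id = attr(x, "subject_id"),
                   day_index = attr(x, "day_index"),
                   stringsAsFactors = FALSE)
  for (nm in names(x)) df[[nm]] <- as.numeric(x[[nm]])
  df
}
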