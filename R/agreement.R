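#' Pearson correlation with confidence interval
#'
#' Product-moment correlation between two aligned speed series, with a 95%
#' Fisher-z confidence interval and a two-sided p-value from the t
#' distribution on n - 2 degrees of freedom (via [stats::cor.test()]). The
#' Fisher-z interval is undefined at n = 3 and reported as `NA` there.
#'
#' @param a,b Equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return List with `r`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
pearson_r <- function(a, b) {
  check_paired(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    sv_stop_validation("degenerate series: zero variance")
  }
  ct <- stats::cor.test(a, b, method = "pearson", conf.level = 0.95)
  ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_) else
    as.numeric(ct$conf.int)
  list(r = unname(ct$estimate), ci_low = ci[1], ci_high = ci[2],
       p_value = ct$p.value, n = length(a))
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) {
    sv_stop_validation("paired series differ in length: ", length(a),
                       " vs ", length(b))
  }
  if (length(a) < 3) {
    sv_stop_validation("need at least 3 paired observations, got ", length(a))
  }
  if (anyNA(a) || anyNA(b)) {
    sv_stop_validation("paired series must not contain missing values")
  }
  invisible(TRUE)
}

#' Label the strength of agreement implied by a correlation
#'
#' Conventional bands on `|r|`: below 0.50 low; 0.50 to below 0.70 moderate;
#' 0.70 to below 0.90 high; 0.90 and above very high. The magnitude is used
#' because agreement strength is a magnitude; the bands partition `[-1, 1]`
#' with no gaps or overlaps.
#'
#' @param r Correlation in `[-1, 1]`.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very high"`.
#' @export
categorize_agreement <- function(r) {
  if (!is.finite(r) || r < -1 || r > 1) {
    sv_stop_validation("r must lie in [-1, 1], got ", r)
  }
  a <- abs(r)
  if (a < 0.50) "low"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "high"
  else "very high"
}

#' Bland-Altman limits of agreement
#'
#' Differences are `a - b`; the limits of agreement are
#' `mean(diff) +/- 1.96 * sd(diff)` with the sample (n - 1) standard
#' deviation and the conventional fixed 1.96 multiplier. About 95% of
#' differences are expected inside the limits when disagreement is normal.
#'
#' @param a,b Equal-length numeric vectors, `n >= 3`.
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n_outside` (differences strictly outside the limits), and the per-pair
#'   `means` and `diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b)
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - 1.96 * s, m + 1.96 * s)
  list(mean_diff = m, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
       n_outside = sum(d < loa[1] | d > loa[2]),
       means = (a + b) / 2, diffs = d)
}

#' Full agreement report for one paired series
#'
#' Combines [pearson_r()], [categorize_agreement()] and [bland_altman()]
#' into one result, the per-subtask record of a concurrent-validity study.
#'
#' @param a,b Equal-length numeric speed vectors.
#' @return List of class `AgreementResult` with fields `r`, `r_ci_low`,
#'   `r_ci_high`, `p_value`, `category`, `mean_diff`, `loa_low`, `loa_high`,
#'   `n_outside_loa`, `n`.
#' @export
agreement_result <- function(a, b) {
  pr <- pearson_r(a, b)
  ba <- bland_altman(a, b)
  structure(
    list(r = pr$r, r_ci_low = pr$ci_low, r_ci_high = pr$ci_high,
         p_value = pr$p_value, category = categorize_agreement(pr$r),
         mean_diff = ba$mean_diff, loa_low = ba$loa_low,
         loa_high = ba$loa_high, n_outside_loa = ba$n_outside, n = pr$n),
    class = "AgreementResult"
  )
}

#' @export
print.AgreementResult <- function(x, ...) {
  cat(sprintf(
    "r = %.3f [%.3f, %.3f], p = %.3g (%s agreement)\n",
    x$r, x$r_ci_low, x$r_ci_high, x$p_value, x$category))
  cat(sprintf("bias = %.4f m/s, 95%% LOA [%.4f, %.4f], %d/%d outside\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n_outside_loa, x$n))
  invisible(x)
}

#' Cohort summary of 100-m trial performance
#'
#' Per-trial mean and sample (n - 1) standard deviation of run time and of
#' run speed, plus means and SDs of the demographic columns. Each
#' participant's speed is `distance / time` rounded to 3 decimals before
#' averaging, matching how published split-time tables are assembled
#' (speeds are tabulated per athlete at report precision, then summarized).
#' With a single participant the SDs are reported missing.
#'
#' @param rows Data frame with one row per participant: any of the
#'   demographic columns `age_yr`, `height_cm`, `weight_kg`, `bmi`, and one
#'   or more time columns named `time_<trial>` (seconds).
#' @param distance_m Run distance (default 100).
#' @return List with `trials` (data frame: trial, mean_time_s, sd_time_s,
#'   mean_speed_m_per_s, sd_speed_m_per_s) and `demographics` (data frame:
#'   variable, mean, sd), plus `n`.
#' @export
summarize_cohort <- function(rows, distance_m = 100) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  time_cols <- grep("^time_", names(rows), value = TRUE)
  if (length(time_cols) == 0) {
    sv_stop_validation("no time_<trial> columns found")
  }
  sd_or_na <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
  trials <- do.call(rbind, lapply(time_cols, function(cl) {
    t <- rows[[cl]]
    if (any(!is.finite(t)) || any(t <= 0)) {
      sv_stop_validation("nonpositive time in column ", cl)
    }
    sp <- format_speed(average_speed(distance_m, t))
    data.frame(trial = sub("^time_", "", cl),
               mean_time_s = mean(t), sd_time_s = sd_or_na(t),
               mean_speed_m_per_s = mean(sp),
               sd_speed_m_per_s = sd_or_na(sp))
  }))
  demo_cols <- intersect(c("age_yr", "height_cm", "weight_kg", "bmi"),
                         names(rows))
  demographics <- do.call(rbind, lapply(demo_cols, function(cl) {
    data.frame(variable = cl, mean = mean(rows[[cl]]),
               sd = sd_or_na(rows[[cl]]))
  }))
  list(trials = trials, demographics = demographics, n = nrow(rows))
}

#' Example sprint cohort
#'
#' A bundled example cohort of five collegiate sprinters (three male, two
#' female) who each ran two timed 100-m trials, in the format expected by
#' [summarize_cohort()]. Useful for demonstrating cohort summaries and the
#' time-to-speed computation without collecting data.
#'
#' @return Data frame with columns `participant`, `gender`, `age_yr`,
#'   `height_cm`, `weight_kg`, `bmi`, `time_trial1`, `time_trial2`.
#' @export
example_cohort <- function() {
  data.frame(
    participant = paste0("S", 1:5),
    gender = c("M", "M", "M", "F", "F"),
    age_yr = c(20, 20, 22, 22, 22),
    height_cm = c(168, 171, 180, 151, 160),
    weight_kg = c(68, 72, 73, 43, 48),
    bmi = c(24.1, 24.6, 22.5, 18.9, 18.8),
    time_trial1 = c(14.211, 14.317, 16.724, 21.219, 16.937),
    time_trial2 = c(13.955, 17.680, 16.876, 20.143, 17.470)
  )
}
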