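#' Sex-specific physical-activity thresholds
#'
#' Computes the median daily physical activity (MET-hours/day) separately for
#' men and women. "Physically active" is defined as a level at or above the
#' sex-specific median (inclusive).
#'
#' @param cohort A data frame with columns `sex` ("male"/"female") and
#'   `activity_met_h` (MET-hours/day).
#' @return Named numeric vector with elements `male` and `female`.
#' @export
activity_threshold <- function(cohort) {
  .require_columns(cohort, c("sex", "activity_met_h"), "activity_threshold")
  .fail_on_missing(cohort, c("sex", "activity_met_h"))
  out <- vapply(c("male", "female"), function(s) {
    v <- cohort$activity_met_h[cohort$sex == s]
    if (length(v) == 0L) {
      stop(sprintf("activity_threshold: no participants with sex '%s'", s),
           call. = FALSE)
    }
    stats::median(v)
  }, numeric(1))
  out
}

#' Three-level alcohol consumption classification
#'
#' Heavy use is daily drinking of at least 30 g of pure alcohol per day
#' (boundary inclusive); moderate use is weekly-but-not-daily drinking, or
#' daily drinking of less than 30 g; anything else (never/occasional drinking)
#' is non-regular use.
#'
#' @param alcohol_freq Character vector: one of "never", "monthly",
#'   "weekly", "daily".
#' @param alcohol_g_day Numeric vector, grams of pure alcohol on a typical
#'   drinking day (ignored unless frequency is "daily").
#' @return Character vector with levels "non_regular", "moderate", "heavy".
#' @export
alcohol_three_group <- function(alcohol_freq, alcohol_g_day) {
  stopifnot(length(alcohol_freq) == length(alcohol_g_day))
  ok <- c("never", "monthly", "weekly", "daily")
  if (!all(alcohol_freq %in% ok)) {
    stop("alcohol_three_group: alcohol_freq must be one of ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  out <- rep("non_regular", length(alcohol_freq))
  out[alcohol_freq == "weekly"] <- "moderate"
  daily <- alcohol_freq == "daily"
  out[daily & alcohol_g_day < 30] <- "moderate"
  out[daily & alcohol_g_day >= 30] <- "heavy"
  out
}

# Diet score over the six healthy food-frequency components.
.diet_score <- function(data) {
  comps <- c("veg_daily", "fruit_daily", "red_meat_lt7", "soybean_ge4",
             "fish_ge1", "coarse_grain_ge4")
  .require_columns(data, comps, "diet score")
  .fail_on_missing(data, comps)
  Reduce(`+`, lapply(comps, function(cl) as.integer(data[[cl]])))
}

# Adiposity flag under the standard or strict (sensitivity) rule.
.adiposity_flag <- function(bmi, wc, sex, rule = c("standard", "strict")) {
  rule <- match.arg(rule)
  bmi_hi <- if (rule == "standard") 27.9 else 24.9
  wc_lim <- ifelse(sex == "male", 90,
                   if (rule == "standard") 85 else 80)
  bmi >= 18.5 & bmi <= bmi_hi & wc < wc_lim
}

#' Classify healthy lifestyle factors
#'
#' Derives the five binary healthy-lifestyle-factor (HLF) indicators from raw
#' lifestyle fields, their count (0-5), and the categorical grouping used in
#' downstream models:
#' \enumerate{
#'   \item never smoking;
#'   \item moderate alcohol consumption: weekly but not daily drinking, or
#'     daily drinking of less than 30 g of pure alcohol;
#'   \item healthy diet: at least 4 of 6 components (fresh vegetables daily,
#'     fresh fruit daily, red meat fewer than 7 days/week, soybean products
#'     on 4+ days/week, fish on 1+ day/week, coarse grains on 4+ days/week);
#'   \item physically active: daily MET-hours at or above the sex-specific
#'     median;
#'   \item healthy adiposity: BMI in \[18.5, 27.9\] kg/m^2 and waist
#'     circumference below 90 cm (men) / 85 cm (women); the strict
#'     sensitivity rule uses BMI in \[18.5, 24.9\] and WC below 90/80.
#' }
#' Missing raw fields are hard errors naming the field and participant.
#'
#' @param raw Data frame of raw per-participant fields: `sex`,
#'   `smoking_status` ("never"/"former"/"current"), `alcohol_freq`,
#'   `alcohol_g_day`, the six diet component flags, `activity_met_h`, `bmi`,
#'   `wc`.
#' @param activity_thresholds Named vector (`male`, `female`) of MET-h/day
#'   cutoffs; default: sex-specific medians of `raw` itself.
#' @param adiposity_rule "standard" or "strict".
#' @return Data frame (one row per participant): the five flags,
#'   `diet_score`, `alcohol_class`, `hlf_count`, `hlf_group`
#'   (factor "0-1" < "2-3" < "4-5"), and `hlf_group2` (factor "0-2" < "3-5",
#'   used in joint genetic-score analyses).
#' @export
classify_hlf <- function(raw, activity_thresholds = NULL,
                         adiposity_rule = c("standard", "strict")) {
  adiposity_rule <- match.arg(adiposity_rule)
  need <- c("sex", "smoking_status", "alcohol_freq", "alcohol_g_day",
            "activity_met_h", "bmi", "wc")
  .require_columns(raw, need, "classify_hlf")
  .fail_on_missing(raw, need)
  if (!all(raw$smoking_status %in% c("never", "former", "current"))) {
    stop("classify_hlf: smoking_status must be never/former/current",
         call. = FALSE)
  }
  if (is.null(activity_thresholds)) activity_thresholds <- activity_threshold(raw)

  alcohol_class <- alcohol_three_group(raw$alcohol_freq, raw$alcohol_g_day)
  diet_score <- .diet_score(raw)
  profile <- data.frame(
    never_smoking = raw$smoking_status == "never",
    moderate_alcohol = alcohol_class == "moderate",
    healthy_diet = diet_score >= 4L,
    physically_active =
      raw$activity_met_h >= activity_thresholds[match(raw$sex, c("male", "female"))],
    healthy_adiposity = .adiposity_flag(raw$bmi, raw$wc, raw$sex, adiposity_rule),
    diet_score = diet_score,
    alcohol_class = alcohol_class
  )
  profile$hlf_count <- profile$never_smoking + profile$moderate_alcohol +
    profile$healthy_diet + profile$physically_active + profile$healthy_adiposity
  profile$hlf_group <- hlf_group(profile$hlf_count)
  profile$hlf_group2 <- hlf_group2(profile$hlf_count)
  if ("participant_id" %in% names(raw)) {
    profile <- cbind(participant_id = raw$participant_id, profile)
  }
  profile
}

#' Three-level grouping of the HLF count
#' @param hlf_count Integer vector in 0..5.
#' @return Ordered factor with levels "0-1" < "2-3" < "4-5".
#' @export
hlf_group <- function(hlf_count) {
  stopifnot(all(hlf_count %in% 0:5))
  cut(hlf_count, breaks = c(-0.5, 1.5, 3.5, 5.5),
      labels = c("0-1", "2-3", "4-5"), ordered_result = TRUE)
}

#' Two-level grouping of the HLF count (joint genetic-score analyses)
#' @param hlf_count Integer vector in 0..5.
#' @return Ordered factor with levels "0-2" < "3-5".
#' @export
hlf_group2 <- function(hlf_count) {
  stopifnot(all(hlf_count %in% 0:5))
  cut(hlf_count, breaks = c(-0.5, 2.5, 5.5),
      labels = c("0-2", "3-5"), ordered_result = TRUE)
}

#' Sensitivity-analysis variants of the HLF profile
#'
#' Two pre-specified sensitivity definitions: `drop_alcohol` removes moderate
#' alcohol consumption from the score (count over the remaining four factors;
#' groups re-derived on the 0-4 count with the same breakpoints), and
#' `strict_adiposity` recomputes the adiposity flag with BMI 18.5-24.9 and
#' WC below 90 cm (men) / 80 cm (women).
#'
#' @param raw Raw fields as in [classify_hlf()].
#' @param mode "drop_alcohol" or "strict_adiposity".
#' @param activity_thresholds Optional thresholds passed through.
#' @return A profile data frame as from [classify_hlf()]; under
#'   `drop_alcohol` the `moderate_alcohol` column is kept for reference but
#'   excluded from `hlf_count`.
#' @export
hlf_sensitivity_variants <- function(raw, mode = c("drop_alcohol", "strict_adiposity"),
                                     activity_thresholds = NULL) {
  mode <- match.arg(mode)
  if (mode == "strict_adiposity") {
    return(classify_hlf(raw, activity_thresholds, adiposity_rule = "strict"))
  }
  profile <- classify_hlf(raw, activity_thresholds)
  profile$hlf_count <- profile$never_smoking + profile$healthy_diet +
    profile$physically_active + profile$healthy_adiposity
  profile$hlf_group <- cut(profile$hlf_count, breaks = c(-0.5, 1.5, 3.5, 5.5),
                           labels = c("0-1", "2-3", "4-5"), ordered_result = TRUE)
  profile$hlf_group2 <- cut(profile$hlf_count, breaks = c(-0.5, 2.5, 5.5),
                            labels = c("0-2", "3-5"), ordered_result = TRUE)
  profile
}

#' Summarise an HLF-count distribution
#'
#' Given counts of participants by number of HLFs adopted (as printed in a
#' baseline-characteristics table), computes the percentage of participants
#' with at least `k` factors for each threshold.
#'
#' @param counts Named or unnamed integer vector of participant counts; the
#'   i-th element is the number of participants with `i - 1` HLFs (the last
#'   element may pool the top categories, e.g. "4-5").
#' @return Data frame with columns `at_least`, `n`, and `pct` (percentage of
#'   the total, full precision; round to taste for presentation).
#' @export
hlf_distribution_summary <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0), length(counts) >= 2L)
  total <- sum(counts)
  ks <- seq_along(counts) - 1L
  data.frame(
    at_least = ks,
    n = rev(cumsum(rev(counts))),
    pct = 100 * rev(cumsum(rev(counts))) / total
  )
}
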