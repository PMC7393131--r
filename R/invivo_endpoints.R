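#' @title In-vivo and clinical endpoint derivation
#' @description Caliper tumor volumes, day-1 normalization, last-observation-
#'   carried-forward imputation for bioluminescence series, tumor tripling
#'   time as a time-to-event endpoint, per-arm Kaplan-Meier analysis with
#'   pairwise log-rank tests, and median-split survival analysis of
#'   expression-annotated cohorts.
#' @name invivo_endpoints
NULL

#' Caliper tumor volume
#'
#' Volume = (pi/6) * Length * Width^2, in mm^3.  Length must be the larger
#' dimension; reversed inputs are swapped with a warning.
#'
#' @param length,width caliper measurements in mm, both >= 0 (vectorized).
#' @return volume(s) in mm^3.
#' @export
caliper_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) {
    stop("validation error: caliper measurements must be >= 0")
  }
  rev <- width > length
  if (any(rev)) {
    warning("caliper_volume: width > length; dimensions swapped")
    tmp <- length[rev]; length[rev] <- width[rev]; width[rev] <- tmp
  }
  (pi / 6) * length * width^2
}

#' Normalize a growth series to its first measured day
#'
#' Each measurement is divided by the day-1 (first measured day) value and
#' expressed in percent, so every series starts at 100%.
#'
#' @param days measurement days, strictly increasing.
#' @param values measurements (mm^3 or photons/s), baseline > 0.
#' @return values in percent of baseline.
#' @export
normalize_to_baseline <- function(days, values) {
  if (length(days) != length(values)) stop("normalize_to_baseline: lengths differ")
  if (is.unsorted(days, strictly = TRUE)) {
    stop("validation error: days must be strictly increasing")
  }
  if (!is.finite(values[1]) || values[1] <= 0) {
    stop("normalization error: baseline measurement must be > 0")
  }
  100 * values / values[1]
}

#' Last-observation-carried-forward imputation
#'
#' Fills missing scheduled measurements (e.g. bioluminescence time points after
#' euthanization) with the most recent observed value.  Observed values are
#' never changed; imputed points are flagged.
#'
#' @param days scheduled measurement days, strictly increasing.
#' @param values measurements with NA at missing time points.
#' @return data.frame (day, value, imputed).
#' @export
locf_impute <- function(days, values) {
  if (length(days) != length(values)) stop("locf_impute: lengths differ")
  if (is.unsorted(days, strictly = TRUE)) {
    stop("validation error: days must be strictly increasing")
  }
  if (is.na(values[1])) {
    stop("imputation error: missing value with no prior observation")
  }
  imputed <- is.na(values)
  for (i in seq_along(values)[-1]) {
    if (is.na(values[i])) values[i] <- values[i - 1]
  }
  data.frame(day = days, value = values, imputed = imputed)
}

#' Tumor tripling time
#'
#' The earliest measured day on which the tumor is at least three times as
#' large as on the first day of treatment (the first measured day).  The
#' crossing is evaluated only at measured days — no interpolation.  Animals
#' that never reach tripling are censored at their last measured day.
#'
#' @param days measurement days, strictly increasing, >= 2 values.
#' @param values measurements, baseline > 0.
#' @return list with `tripling_day` (NA when censored), `censored`,
#'   `last_day`, `time` (tripling day, or last day when censored) and `event`
#'   (1 = tripled, 0 = censored) ready for time-to-event analysis.
#' @export
tripling_time <- function(days, values) {
  if (length(days) != length(values) || length(days) < 2) {
    stop("tripling_time: need >= 2 matched (day, value) pairs")
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("validation error: days must be strictly increasing")
  }
  baseline <- values[1]
  if (!is.finite(baseline) || baseline <= 0) {
    stop("validation error: baseline measurement must be > 0")
  }
  hit <- which(values >= 3 * baseline)
  if (length(hit)) {
    d <- days[hit[1]]
    list(tripling_day = d, censored = FALSE, last_day = days[length(days)],
         time = d, event = 1L)
  } else {
    list(tripling_day = NA_real_, censored = TRUE,
         last_day = days[length(days)],
         time = days[length(days)], event = 0L)
  }
}

#' Tripling records for a growth cohort
#'
#' Applies [tripling_time()] per animal of a long growth table.
#'
#' @param growth data.frame (animal, arm, day, volume_mm3 or flux).
#' @return data.frame (animal, arm, tripling_day, censored, last_day, time,
#'   event).
#' @export
tripling_records <- function(growth) {
  growth <- validate_table(growth, "growth",
                           source = attr(growth, "source") %||% "in-memory")
  mcol <- intersect(c("volume_mm3", "flux"), names(growth))[1]
  animals <- unique(growth$animal)
  rows <- lapply(animals, function(a) {
    sub <- growth[growth$animal == a, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    tr <- tripling_time(sub$day, sub[[mcol]])
    data.frame(animal = a, arm = sub$arm[1],
               tripling_day = tr$tripling_day, censored = tr$censored,
               last_day = tr$last_day, time = tr$time, event = tr$event,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-arm Kaplan-Meier endpoints with pairwise log-rank tests
#'
#' For a time-to-event table with >= 2 arms (tripling records or survival
#' data): per-arm Kaplan-Meier median, and the log-rank p-value for every
#' arm pair.
#'
#' @param time,event,arm vectors of times (> 0), event indicators (1/0) and
#'   arm labels.
#' @return list with `summary` (data.frame: arm, n, events, median),
#'   `pairwise` (data.frame: comparison, statistic, df_or_n, p), and `curves`
#'   (named list of `km_curve` objects).
#' @export
arm_endpoint_analysis <- function(time, event, arm) {
  arm <- as.character(arm)
  arms <- sort(unique(arm))
  if (length(arms) < 2) stop("arm_endpoint_analysis: need >= 2 arms")
  curves <- lapply(arms, function(a) km_curve(time[arm == a], event[arm == a]))
  names(curves) <- arms
  summary <- data.frame(
    arm = arms,
    n = vapply(arms, function(a) sum(arm == a), numeric(1)),
    events = vapply(arms, function(a) sum(event[arm == a]), numeric(1)),
    median = vapply(curves, function(k) k$median, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    sel <- arm %in% pr
    lr <- logrank_test(time[sel], event[sel], arm[sel])
    data.frame(comparison = paste(pr, collapse = " vs "),
               statistic = lr$statistic, df_or_n = lr$df, p = lr$p_value,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  rownames(pw) <- NULL
  list(summary = summary, pairwise = pw, curves = curves)
}

#' Median-split survival analysis
#'
#' Stratifies subjects into high (expression strictly above the median) and
#' low (at or below the median; ties go low, matching a ">median" rule) groups,
#' then compares overall survival: Kaplan-Meier curves and medians, log-rank
#' test, and univariate Cox hazard ratio (high vs low) with a Wald 95% CI.
#'
#' @param expression numeric expression values, >= 4 subjects, not constant.
#' @param os_time,os_event overall-survival times (> 0) and event flags.
#' @return list with `group` (character vector "high"/"low"), `median_cutoff`,
#'   `km` (named list of curves), `medians`, `logrank` and `cox` results.
#' @export
median_split_survival <- function(expression, os_time, os_event) {
  n <- length(expression)
  if (n < 4) stop("split error: need >= 4 subjects")
  if (length(os_time) != n || length(os_event) != n) {
    stop("median_split_survival: lengths differ")
  }
  med <- stats::median(expression)
  group <- ifelse(expression > med, "high", "low")
  if (length(unique(group)) < 2) {
    stop("split error: constant expression or empty group after median split")
  }
  km <- list(high = km_curve(os_time[group == "high"], os_event[group == "high"]),
             low = km_curve(os_time[group == "low"], os_event[group == "low"]))
  lr <- logrank_test(os_time, os_event, group)
  # covariate coded 1 = high, 0 = low so HR is high vs low
  cox <- cox_univariate(os_time, os_event, as.numeric(group == "high"))
  list(group = group, median_cutoff = med,
       km = km,
       medians = c(high = km$high$median, low = km$low$median),
       logrank = lr, cox = cox)
}
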