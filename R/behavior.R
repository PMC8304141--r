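#' Aggregate one day's escape-latency trials
#'
#' In a three-day Barnes-maze protocol each rat runs two trials per day; the
#' day-level escape latency (ESL) is the aggregate of that day's trials. The
#' default aggregate is the arithmetic mean; `min` and `median` are offered
#' because protocols differ on whether the best or the typical trial
#' represents the day.
#'
#' @param latencies numeric vector of trial escape latencies (seconds) for one
#'   rat on one day; must be nonempty.
#' @param method aggregation rule, one of `"mean"`, `"min"`, `"median"`.
#' @return day-level ESL in seconds.
#' @export
day_esl <- function(latencies, method = c("mean", "min", "median")) {
  method <- match.arg(method)
  if (length(latencies) == 0 || all(is.na(latencies))) {
    stop("no trials available for this day")
  }
  stopifnot(is.numeric(latencies), all(latencies >= 0, na.rm = TRUE))
  latencies <- latencies[!is.na(latencies)]
  switch(method,
         mean = mean(latencies),
         min = min(latencies),
         median = stats::median(latencies))
}

#' Relative escape latency (REL3)
#'
#' REL3 expresses a rat's day-3 ESL as a fraction of its day-1 ESL. Values
#' below 1 indicate learning (faster escape by day 3); values at or above 1
#' indicate failure to improve. The ratio is invariant under rescaling of the
#' latency units.
#'
#' @param day1_esl day-1 ESL in seconds, must be > 0.
#' @param day3_esl day-3 ESL in seconds, nonnegative.
#' @return dimensionless ratio day3/day1.
#' @export
compute_rel3 <- function(day1_esl, day3_esl) {
  stopifnot(is.numeric(day1_esl), is.numeric(day3_esl))
  if (any(day1_esl <= 0)) stop("day-1 ESL must be positive to form the REL3 ratio")
  if (any(day3_esl < 0)) stop("day-3 ESL must be nonnegative")
  day3_esl / day1_esl
}

#' Classify spatial-memory phenotype from REL3
#'
#' A rat is called IMPAIRED when its REL3 strictly exceeds the threshold
#' (default 0.7); a rat sitting exactly at the threshold is FUNCTIONAL.
#'
#' @param rel3 numeric vector of REL3 ratios, all > 0.
#' @param threshold classification threshold (default 0.7).
#' @return character vector, `"FUNCTIONAL"` or `"IMPAIRED"`.
#' @export
classify_phenotype <- function(rel3, threshold = 0.7) {
  stopifnot(is.numeric(rel3), is.numeric(threshold), threshold > 0)
  if (any(rel3 <= 0)) stop("REL3 must be positive")
  ifelse(rel3 > threshold, "IMPAIRED", "FUNCTIONAL")
}

#' Per-rat REL3 table from a behavioral trial table
#'
#' Aggregates day-1 and day-3 trials per rat, forms REL3, and classifies the
#' phenotype. Day-2 trials may be present in the input but do not enter REL3.
#' Rats missing day-1 or day-3 data raise an error.
#'
#' @param behavior data.frame with columns `rat_id`, `cohort`, `day`, `trial`,
#'   `escape_latency_s`.
#' @param day_aggregation how to collapse a day's trials, see [day_esl()].
#' @param threshold phenotype threshold for [classify_phenotype()].
#' @return data.frame with one row per rat: `rat_id`, `cohort`, `day1_esl`,
#'   `day3_esl`, `rel3`, `phenotype`.
#' @export
rel3_table <- function(behavior, day_aggregation = "mean", threshold = 0.7) {
  validate_behavior(behavior)
  rats <- unique(behavior[, c("rat_id", "cohort")])
  if (anyDuplicated(rats$rat_id)) stop("a rat_id appears in more than one cohort")
  esl_for <- function(rid, day) {
    lat <- behavior$escape_latency_s[behavior$rat_id == rid & behavior$day == day]
    if (length(lat) == 0) {
      stop("rat ", rid, " has no trials for day ", day)
    }
    day_esl(lat, day_aggregation)
  }
  d1 <- vapply(rats$rat_id, esl_for, numeric(1), day = 1)
  d3 <- vapply(rats$rat_id, esl_for, numeric(1), day = 3)
  rel3 <- compute_rel3(d1, d3)
  data.frame(rat_id = rats$rat_id, cohort = rats$cohort,
             day1_esl = unname(d1), day3_esl = unname(d3),
             rel3 = unname(rel3),
             phenotype = classify_phenotype(rel3, threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Shared Mann-Whitney engine. Exact enumeration when both groups are small
# (<= exact_max each) and tie-free; otherwise the normal approximation with
# the tie correction. The small-sample cutoff keeps 8/4/4 cohort designs on
# the exact path.
mw_engine <- function(x, y, exact_max = 8) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = !use_exact)
  )
  list(U = unname(ht$statistic), p_value = ht$p.value,
       exact = use_exact, ties = ties)
}

#' Compare REL3 distributions of two cohorts
#'
#' Two-sided Wilcoxon-Mann-Whitney test. The test is exact (full
#' enumeration) whenever both groups have at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie correction is
#' used.
#'
#' @param rel3_a,rel3_b numeric vectors of REL3 values, both nonempty.
#' @return list with elements `U` (Mann-Whitney U for the first sample),
#'   `p_value` (two-sided), `exact` (logical), `ties` (logical).
#' @export
compare_cohorts <- function(rel3_a, rel3_b) {
  mw_engine(rel3_a, rel3_b)
}

#' Summary statistics for a cohort's REL3 values
#'
#' @param rel3 numeric vector, n >= 1.
#' @return list with `mean`, `sem` (sample sd over sqrt(n); `NA` when n = 1),
#'   `median`, `n`.
#' @export
cohort_summary <- function(rel3) {
  stopifnot(is.numeric(rel3), length(rel3) >= 1)
  n <- length(rel3)
  list(mean = mean(rel3),
       sem = if (n > 1) stats::sd(rel3) / sqrt(n) else NA_real_,
       median = stats::median(rel3),
       n = n)
}
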