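#' Annual (12-month) prevalence at one age
#'
#' Share of persons occupying a matching ED state during year `age`, among
#' persons alive at the start of that year.
#'
#' @param cohort an `ed_cohort`.
#' @param ed_filter `"ANY"` or an ED label.
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param age integer age 0..40 (or vector).
#' @return proportion(s).
#' @export
annual_prevalence <- function(cohort, ed_filter = "ANY", sex = "both",
                              age = 0:N_AGES) {
  codes <- ed_filter_codes(ed_filter)
  sx <- if (identical(sex, "both")) 1:2 else sex_index(sex)
  num <- den <- numeric(length(age))
  for (k in seq_along(age)) {
    a <- age[k] + 1L
    num[k] <- sum(cohort$state_counts[codes, sx, a])
    den[k] <- sum(cohort$n_by_sex[sx]) -
      sum(cohort$state_counts[STATE_DECEASED, sx, a])
  }
  if (any(den == 0)) stop("no persons alive at the requested age")
  num / den
}

#' Lifetime (cumulative) prevalence by one age
#'
#' Share of the birth cohort with a first matching-ED onset at or before
#' `age`. By default deaths remain in the denominator (cumulative
#' incidence, so the curve is nondecreasing in age); the
#' survivor-conditioned variant — closer to what a cross-sectional survey
#' of living respondents measures — divides by persons alive at the start
#' of year `age` instead.
#'
#' @inheritParams annual_prevalence
#' @param surviving_only condition the denominator on being alive at `age`.
#' @return proportion(s).
#' @export
lifetime_prevalence <- function(cohort, ed_filter = "ANY", sex = "both",
                                age = N_AGES, surviving_only = FALSE) {
  sx <- if (identical(sex, "both")) 1:2 else sex_index(sex)
  if (length(ed_filter) == 1L && toupper(ed_filter) == "ANY") {
    byage <- colSums(cohort$onset_counts[sx, , drop = FALSE])
  } else {
    e <- ed_index(ed_filter)
    byage <- colSums(cohort$first_ed_counts[e, sx, , drop = FALSE])
  }
  cum <- cumsum(byage)
  out <- numeric(length(age))
  for (k in seq_along(age)) {
    a <- age[k] + 1L
    den <- if (surviving_only)
      sum(cohort$n_by_sex[sx]) - sum(cohort$state_counts[STATE_DECEASED, sx, a])
    else sum(cohort$n_by_sex[sx])
    if (den == 0) stop("empty denominator at age ", age[k])
    out[k] <- cum[a] / den
  }
  out
}

#' Cumulative distribution of first-ever onset age
#'
#' `F(a)` is the share of all first-ever (naive) onsets occurring at or
#' before age `a`, among persons with any onset; `F(40) = 1`.
#'
#' @inheritParams annual_prevalence
#' @return numeric vector over ages 0..40.
#' @export
naive_incidence_cdf <- function(cohort, sex = "both") {
  sx <- if (identical(sex, "both")) 1:2 else sex_index(sex)
  onsets <- colSums(cohort$onset_counts[sx, , drop = FALSE])
  tot <- sum(onsets)
  if (tot == 0) stop("no first-ever onsets in the cohort")
  stats::setNames(cumsum(onsets) / tot, 0:N_AGES)
}

#' Distribution of episode counts among affected persons
#'
#' Shares of persons with exactly 1, 2, 3, 4, and 5 or more episodes by age
#' 40, conditional on having at least one. For `ed_filter = "ANY"` an
#' episode is a maximal contiguous run of ages in any ED state (diagnostic
#' crossover does not end an episode); for a specific ED it is a maximal
#' contiguous run in that state.
#'
#' @inheritParams annual_prevalence
#' @return named numeric vector over `c("1", "2", "3", "4", "5+")`, summing
#'   to 1.
#' @export
episode_distribution <- function(cohort, sex = "both", ed_filter = "ANY") {
  sx <- if (identical(sex, "both")) 1:2 else sex_index(sex)
  if (length(ed_filter) == 1L && toupper(ed_filter) == "ANY") {
    counts <- rowSums(cohort$episodes_any[, sx, drop = FALSE])
  } else {
    e <- ed_index(ed_filter)
    counts <- apply(cohort$episodes_ed[e, , sx, drop = FALSE], 2, sum)
  }
  affected <- counts[-1]  # drop the zero-episode bin
  if (sum(affected) == 0) stop("no affected persons in the conditioning set")
  stats::setNames(affected / sum(affected), c("1", "2", "3", "4", "5+"))
}

#' Cumulative deaths by age 40
#'
#' @inheritParams annual_prevalence
#' @return number of deaths (count).
#' @export
deaths_by_40 <- function(cohort, sex = "both") {
  sx <- if (identical(sex, "both")) 1:2 else sex_index(sex)
  sum(cohort$state_counts[STATE_DECEASED, sx, N_AGES + 1L])
}

#' Deaths averted between two paired scenario runs
#'
#' For two cohorts simulated under common random numbers (same seed and
#' size), `(deaths(a) - deaths(b)) * scale / n`: positive when scenario `b`
#' averts deaths relative to scenario `a`.
#'
#' @param cohort_a,cohort_b paired `ed_cohort` runs of equal size.
#' @param scale population scale for the rate (default per 100 000).
#' @return deaths averted per `scale` persons.
#' @export
deaths_averted <- function(cohort_a, cohort_b, scale = 1e5) {
  if (cohort_a$n != cohort_b$n)
    stop("paired cohorts must have equal size")
  (deaths_by_40(cohort_a) - deaths_by_40(cohort_b)) * scale / cohort_a$n
}

#' Mean, median and 95% uncertainty interval of per-run statistics
#'
#' Uncertainty intervals are the empirical 2.5th and 97.5th percentiles
#' (linear interpolation) of the per-run values.
#'
#' @param per_run_values numeric vector of one statistic across simulation
#'   runs.
#' @return named vector `mean`, `median`, `ui_lo`, `ui_hi`.
#' @export
ensemble_statistics <- function(per_run_values) {
  if (!length(per_run_values)) stop("no runs supplied")
  q <- stats::quantile(per_run_values, c(0.025, 0.975), names = FALSE,
                       type = 7)
  c(mean = mean(per_run_values), median = stats::median(per_run_values),
    ui_lo = q[1], ui_hi = q[2])
}

#' Evaluate calibration-target statistics on a simulated cohort
#'
#' For each target row, extracts the matching prevalence statistic:
#' annual or lifetime prevalence for the given ED (or ANY) and sex,
#' averaged over the target's age range. Lifetime targets use the
#' survivor-conditioned denominator, matching what prevalence surveys of
#' living respondents measure.
#'
#' @param cohort an `ed_cohort`.
#' @param targets a data.frame with columns `kind, ed, sex, age_lo,
#'   age_hi`.
#' @return numeric vector of per-target simulated estimates.
#' @export
extract_target_estimates <- function(cohort, targets) {
  vapply(seq_len(nrow(targets)), function(k) {
    ages <- targets$age_lo[k]:min(targets$age_hi[k], N_AGES)
    kind <- targets$kind[k]
    if (kind == "annual_prevalence")
      mean(annual_prevalence(cohort, targets$ed[k], targets$sex[k], ages))
    else if (kind == "lifetime_prevalence")
      mean(lifetime_prevalence(cohort, targets$ed[k], targets$sex[k], ages,
                               surviving_only = TRUE))
    else stop("unknown target kind: ", kind)
  }, numeric(1))
}
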