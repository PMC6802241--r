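#' Design object for synthetic model inputs
#'
#' Bundles the parameters of the synthetic input generators: a
#' Gompertz-Makeham background life table, log-Gaussian (in log-age)
#' incidence shapes peaking in adolescence, and a calibration-target design
#' (which prevalence statistics are observed and at what survey size, which
#' determines the binomial standard errors).
#'
#' Defaults emulate US-style under-40 mortality (cumulative mortality to
#' age 40 of about 2.3% for women and 4.0% for men) and first-onset curves
#' concentrated in adolescence, peaking between ages 16 (AN) and 19 (BED)
#' with the bulk of onset mass before age 25.
#'
#' @param makeham,gompertz_a,gompertz_b Gompertz-Makeham parameters of the
#'   female annual death probability `q(age) = makeham +
#'   gompertz_a * exp(gompertz_b * age)`.
#' @param male_mult rate-scale mortality multiplier for men (> 1).
#' @param peak_age named numeric vector (AN, BN, BED, OSFED): modal age of
#'   first onset, within 12..25.
#' @param log_sd named numeric vector: width of each incidence shape on the
#'   log-age axis.
#' @param targets data.frame describing observed calibration targets
#'   (columns `kind`, `ed`, `sex`, `age_lo`, `age_hi`, `n_survey`); the
#'   default observes, per sex, 12-month prevalence of AN, BN and BED at
#'   ages 16, 21 and 26, lifetime OSFED prevalence at 20 and lifetime
#'   AN/BN/BED prevalence at 35 (26 targets in all), each at survey size
#'   2000 — an effective sample size typical of sex-specific national
#'   survey cells after design effects.
#' @param n_cohort cohort size used to simulate the ground truth when
#'   generating targets.
#' @return an object of class `ed_synthetic_design`.
#' @export
synthetic_design <- function(makeham = 1e-4, gompertz_a = 7.8e-5,
                             gompertz_b = 0.075, male_mult = 1.75,
                             peak_age = c(AN = 16, BN = 18, BED = 19,
                                          OSFED = 17),
                             log_sd = c(AN = 0.18, BN = 0.18, BED = 0.17,
                                        OSFED = 0.19),
                             targets = default_target_design(),
                             n_cohort = 100000L) {
  stopifnot(all(peak_age >= 12 & peak_age <= 25), all(log_sd > 0))
  structure(list(makeham = makeham, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, male_mult = male_mult,
                 peak_age = peak_age[ED_TYPES], log_sd = log_sd[ED_TYPES],
                 targets = targets, n_cohort = as.integer(n_cohort)),
            class = "ed_synthetic_design")
}

#' Default calibration-target design for recovery experiments
#'
#' @param n_survey survey size per target (sets the binomial SE); may be
#'   `Inf` for noise-free targets.
#' @return data.frame with one row per observed target.
#' @export
default_target_design <- function(n_survey = 2000L) {
  # mirrors the emulated study's target structure: 12-month prevalence of
  # AN, BN and BED at several ages, lifetime OSFED at 20, and lifetime
  # AN/BN/BED in the 30s, per sex (13 targets per sex vs 4 free incidence
  # multipliers, so the disorder mix is identified)
  expand <- function(sex) data.frame(
    kind = c(rep("annual_prevalence", 9L), rep("lifetime_prevalence", 4L)),
    ed = c(rep(c("AN", "BN", "BED"), each = 3L), "OSFED", "AN", "BN", "BED"),
    sex = sex,
    age_lo = c(rep(c(16L, 21L, 26L), 3L), 20L, 35L, 35L, 35L),
    age_hi = c(rep(c(16L, 21L, 26L), 3L), 20L, 35L, 35L, 35L),
    n_survey = n_survey)
  rbind(expand("male"), expand("female"))
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' @param design an [synthetic_design()].
#' @return a `[2 sex, 40 age]` life-table matrix of annual death
#'   probabilities; an error is raised if any probability reaches 0.02
#'   before age 40 (implausible pre-40 background mortality).
#' @export
synthetic_life_table <- function(design = synthetic_design()) {
  ages <- 0:(N_AGES - 1L)
  q_f <- design$makeham + design$gompertz_a * exp(design$gompertz_b * ages)
  q_m <- 1 - (1 - q_f)^design$male_mult
  q <- rbind(male = q_m, female = q_f)
  if (any(q <= 0) || any(q >= 0.02))
    stop("synthetic life-table q outside (0, 0.02) before age 40; ",
         "adjust the Gompertz-Makeham parameters")
  colnames(q) <- ages
  q
}

#' Generate a unimodal incidence-by-age shape
#'
#' Returns a curve over ages 0..39 that is Gaussian on the log-age axis
#' (hence symmetric in log age around the peak), normalised so the maximum,
#' attained at the integer age nearest `peak_age`, equals 1. Emulates
#' published incidence-by-age curves that peak in adolescence.
#'
#' @param peak_age modal age, within 12..25.
#' @param log_sd width on the log-age axis.
#' @return numeric vector of length 40 (ages 0..39), maximum exactly 1.
#' @export
synthetic_incidence_shape <- function(peak_age, log_sd = 0.2) {
  if (peak_age < 12 || peak_age > 25) stop("peak_age must lie in [12, 25]")
  ages <- 0:(N_AGES - 1L)
  s <- numeric(N_AGES)
  pos <- ages >= 1
  s[pos] <- exp(-(log(ages[pos]) - log(peak_age))^2 / (2 * log_sd^2))
  s / max(s)
}

#' Default incidence shapes for all EDs and sexes
#'
#' @param design an [synthetic_design()].
#' @return a `[4 ED, 2 sex, 40 age]` shape array (same shape per sex).
#' @export
synthetic_shapes <- function(design = synthetic_design()) {
  sh <- array(0, dim = c(4L, 2L, N_AGES),
              dimnames = list(ED_TYPES, SEXES, 0:(N_AGES - 1L)))
  for (i in 1:4) {
    v <- synthetic_incidence_shape(design$peak_age[i], design$log_sd[i])
    sh[i, 1, ] <- v
    sh[i, 2, ] <- v
  }
  sh
}

#' Default model frame built from synthetic inputs
#'
#' @param design an [synthetic_design()].
#' @return an [ed_model_frame()] with synthetic shapes and life table.
#' @export
synthetic_frame <- function(design = synthetic_design()) {
  ed_model_frame(synthetic_shapes(design), synthetic_life_table(design))
}

#' Generate noisy calibration targets from a known parameter set
#'
#' Simulates a large baseline cohort under `ps_true`, extracts each target
#' statistic, and perturbs it with binomial sampling noise at the design's
#' survey sizes, with `se = sqrt(p * (1 - p) / n_survey)`. An infinite
#' survey size yields the noise-free simulated truth (with `se = 0`).
#'
#' @param ps_true a valid [ed_parameter_set()].
#' @param design an [synthetic_design()].
#' @param seed integer seed controlling both the truth simulation and the
#'   noise draws.
#' @return an `ed_targets` data.frame (columns `kind, ed, sex, age_lo,
#'   age_hi, value, se`) with the noise-free truth attached as attribute
#'   `"truth"`.
#' @export
generate_targets <- function(ps_true, design = synthetic_design(),
                             seed = 1L) {
  td <- design$targets
  hist <- simulate_cohort(ps_true, scenario_spec("baseline"),
                          n_persons = design$n_cohort,
                          master_seed = seed)
  truth <- extract_target_estimates(hist, td)
  set.seed(seed)
  value <- se <- numeric(nrow(td))
  for (k in seq_len(nrow(td))) {
    n <- td$n_survey[k]
    if (is.finite(n)) {
      value[k] <- stats::rbinom(1L, n, truth[k]) / n
      se[k] <- sqrt(value[k] * (1 - value[k]) / n)
      if (se[k] == 0) se[k] <- sqrt(0.5 * (n - 0.5) / n^3)  # continuity floor
    } else {
      value[k] <- truth[k]
      se[k] <- 0
    }
  }
  out <- data.frame(kind = td$kind, ed = td$ed, sex = td$sex,
                    age_lo = td$age_lo, age_hi = td$age_hi,
                    value = value, se = se)
  class(out) <- c("ed_targets", "data.frame")
  attr(out, "truth") <- truth
  out
}

#' End-to-end parameter-recovery experiment
#'
#' Samples (or accepts) a ground-truth parameter set, generates noisy
#' targets from it, calibrates against them, and compares the
#' ensemble-mean fitted prevalence statistics with the noise-free truth,
#' reporting the standardized deviation per target.
#'
#' @param design an [synthetic_design()].
#' @param config an [anneal_config()]; use a desk-scale profile.
#' @param seed master seed.
#' @param bounds search bounds; the default frees the eight incidence
#'   multipliers and pins every other parameter at its published
#'   calibrated mean, mirroring how the calibration is used, so the
#'   over-determined default target set (16 targets vs 8 free scalars)
#'   gives a genuine test of the optimizer rather than of the noise draw.
#' @param truth_theta optional named truth vector; when `NULL` a valid set
#'   is sampled from the bounds.
#' @return a list of class `ed_recovery_report`: `fit` (the [ed_fit]
#'   object), `targets`, `truth` (noise-free target values), `fitted`
#'   (ensemble-mean simulated values), `z` (standardized deviations,
#'   `(fitted - truth) / se`), `max_abs_z`, `truth_in_bounds` flag, and the
#'   initial/final best scores.
#' @export
recovery_experiment <- function(design = synthetic_design(),
                                config = anneal_config("test"),
                                seed = 1L, bounds = NULL,
                                truth_theta = NULL) {
  if (is.null(bounds)) {
    tab <- read_param_table()
    bounds <- fix_bounds(param_bounds(tab), param_means(tab))
  }
  frame <- synthetic_frame(design)
  if (is.null(truth_theta)) {
    set.seed(seed)
    truth_theta <- sample_valid_parameter_set(bounds, frame)$theta
  }
  in_bounds <- all(truth_theta >= bounds$lower[match(names(truth_theta),
                                                    bounds$param)] &
                   truth_theta <= bounds$upper[match(names(truth_theta),
                                                    bounds$param)])
  ps_true <- params_from_theta(truth_theta, frame)
  targets <- generate_targets(ps_true, design, seed = seed + 1L)
  fit <- ed_calibrate(targets, bounds, frame, config,
                      master_seed = seed + 2L)
  fitted <- ensemble_mean_estimates(fit)
  truth <- attr(targets, "truth")
  z <- (fitted - truth) / targets$se
  structure(list(fit = fit, targets = targets, truth = truth,
                 fitted = fitted, z = z, max_abs_z = max(abs(z)),
                 truth_in_bounds = in_bounds,
                 initial_score = fit$initial_score,
                 best_score = min(fit$scores)),
            class = "ed_recovery_report")
}

#' @export
print.ed_recovery_report <- function(x, ...) {
  cat("Parameter-recovery experiment\n")
  cat(sprintf("  truth inside search bounds: %s\n", x$truth_in_bounds))
  cat(sprintf("  best score %.4g (initial %.4g)\n",
              x$best_score, x$initial_score))
  cat(sprintf("  max |z| of fitted vs truth across %d targets: %.2f\n",
              length(x$z), x$max_abs_z))
  invisible(x)
}
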