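#' Counterfactual scenario specification
#'
#' A scenario toggles the intervention switches of the simulation:
#' `treatment_mode` (`"current"`: annual Bernoulli(coverage) treatment
#' assignment; `"none"`: nobody treated; `"full"`: every prevalent case
#' treated) and `incidence_on` (`FALSE` zeroes naive incidence, the
#' prevention counterfactual). The baseline is `("current", TRUE)`.
#'
#' @param name scenario label.
#' @param treatment_mode one of `"current"`, `"none"`, `"full"`.
#' @param incidence_on logical.
#' @return an object of class `ed_scenario`.
#' @export
scenario_spec <- function(name, treatment_mode = "current",
                          incidence_on = TRUE) {
  treatment_mode <- match.arg(treatment_mode, c("current", "none", "full"))
  structure(list(name = name, treatment_mode = treatment_mode,
                 incidence_on = isTRUE(incidence_on)),
            class = "ed_scenario")
}

#' The four standard scenarios
#'
#' Baseline (current treatment), no treatment, full treatment, and no
#' incidence (prevention of all ED cases).
#'
#' @return named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  list(baseline = scenario_spec("baseline", "current", TRUE),
       no_treatment = scenario_spec("no_treatment", "none", TRUE),
       full_treatment = scenario_spec("full_treatment", "full", TRUE),
       no_incidence = scenario_spec("no_incidence", "current", FALSE))
}

treatment_mode_code <- function(mode) {
  match(mode, c("current", "none", "full")) - 1L
}

# ---- closed-form per-cycle transforms --------------------------------------

#' Annual relapse probability with exponential decay
#'
#' Relapse risk is highest in the first year after remission and declines
#' exponentially: `p_first * exp(-decay * (years_since_remission - 1))`.
#'
#' @param p_first probability of relapse in the first year after remission.
#' @param decay nonnegative decay parameter in `[0, 1]`.
#' @param years_since_remission integer >= 1 (1 = first year after
#'   remission).
#' @return relapse probability; equals `p_first` in year 1 and is
#'   nonincreasing in years since remission.
#' @export
relapse_probability <- function(p_first, decay, years_since_remission) {
  if (any(years_since_remission < 1))
    stop("years_since_remission must be >= 1")
  p_first * exp(-decay * (years_since_remission - 1))
}

#' Remission probability under treatment
#'
#' The treatment effect is a rate ratio on the remission rate: the annual
#' probability is converted to a rate, scaled, and converted back, giving
#' `1 - (1 - p_base)^rr`.
#'
#' @param p_base annual untreated remission probability in `[0, 1]`.
#' @param efficacy_rr rate ratio >= 1.
#' @return treated remission probability (always >= `p_base`, <= 1).
#' @export
treated_remission_probability <- function(p_base, efficacy_rr) {
  if (any(efficacy_rr < 1)) stop("efficacy rate ratio must be >= 1")
  1 - (1 - p_base)^efficacy_rr
}

#' Annual death probability in an ED state
#'
#' Excess mortality is a standardized mortality ratio applied to the
#' background mortality rate (rate-scale multiplication):
#' `1 - (1 - q_bg)^smr`.
#'
#' @param q_bg background annual death probability in `[0, 1)`.
#' @param smr standardized mortality ratio >= 1.
#' @return annual death probability, strictly below 1.
#' @export
ed_mortality_probability <- function(q_bg, smr) {
  if (any(q_bg < 0 | q_bg >= 1)) stop("q_bg must lie in [0, 1)")
  if (any(smr < 1)) stop("SMR must be >= 1")
  1 - (1 - q_bg)^smr
}

# ---- single-cycle outcome distribution (arithmetic oracle) -----------------

#' Distribution over next-year states for one person-year
#'
#' Computes, in closed form, the categorical distribution over next states
#' for a person in a given state, marginalising over the annual treatment
#' draw. Death is resolved first from the start-of-year state; survivors
#' resolve a single multinomial over remission, crossovers and persistence
#' (ED states) or onset/relapse (healthy). This is the exact arithmetic the
#' simulation engine draws from, computed independently in R; it is used
#' for validation and for exhaustive small-model enumeration.
#'
#' @param state integer state code (not deceased).
#' @param sex `"male"`/`"female"` or 1/2.
#' @param age integer age 0..39.
#' @param history list with `has_history` (logical), `last_ed` (ED label or
#'   index, required when `has_history`), `years_since_remission`.
#' @param ps a valid [ed_parameter_set()].
#' @param scenario a [scenario_spec()].
#' @return named numeric vector of length 6 over [STATE_LABELS], summing
#'   to 1.
#' @export
annual_outcome_distribution <- function(state, sex, age, history, ps,
                                        scenario = scenario_spec("baseline")) {
  if (state == STATE_DECEASED) stop("no transitions out of the deceased state")
  s <- sex_index(sex)
  a <- age + 1L
  out <- stats::setNames(numeric(6), STATE_LABELS)
  if (is_ed_state(state)) {
    e <- state - 1L
    p_die <- ed_mortality_probability(ps$life_table[s, a], ps$smr[e, s])
    cov <- switch(scenario$treatment_mode,
                  current = ps$treat_coverage[e, s], none = 0, full = 1)
    prem <- cov * treated_remission_probability(ps$remission[e, s],
                                                ps$treat_rr[e, s]) +
      (1 - cov) * ps$remission[e, s]
    cross <- ps$crossover[e, , s]
    out[STATE_DECEASED] <- p_die
    out[STATE_HEALTHY] <- (1 - p_die) * prem
    out[ED_STATE_CODES] <- (1 - p_die) * cross
    out[state] <- out[state] + (1 - p_die) * (1 - prem - sum(cross))
  } else {
    q <- ps$life_table[s, a]
    out[STATE_DECEASED] <- q
    if (isTRUE(history$has_history)) {
      e <- if (is.character(history$last_ed)) ed_index(history$last_ed)
           else as.integer(history$last_ed)
      pr <- relapse_probability(ps$relapse_first[e, s], ps$relapse_decay[e, s],
                                history$years_since_remission)
      out[e + 1L] <- (1 - q) * pr
      out[STATE_HEALTHY] <- (1 - q) * (1 - pr)
    } else {
      inc <- if (scenario$incidence_on) ps$incidence[, s, a] else rep(0, 4)
      out[ED_STATE_CODES] <- (1 - q) * inc
      out[STATE_HEALTHY] <- (1 - q) * (1 - sum(inc))
    }
  }
  out
}

# ---- cohort simulation ------------------------------------------------------

#' Pregenerate death and incidence/relapse uniform streams
#'
#' The two per-person-year decision channels consulted for nearly every
#' person-year can be generated once and reused across repeated evaluations
#' under the same master seed (as simulated annealing does). Passing the
#' result to [simulate_cohort()] changes nothing numerically.
#'
#' @param n_persons cohort size.
#' @param master_seed integer seed.
#' @return list of two `[40, n]` matrices (`u0` death, `u1`
#'   incidence/relapse).
#' @export
ed_streams <- function(n_persons, master_seed) {
  ed_streams_cpp(as.integer(n_persons), as.numeric(master_seed))
}

#' Simulate a birth cohort through age 40
#'
#' Advances `n_persons` individuals (first half male, second half female)
#' through annual cycles from birth to age 40 under a scenario. Within each
#' cycle, death is resolved first from the start-of-year state; survivors
#' in an ED state resolve one multinomial over remission (treated or not),
#' crossover to another ED, and persistence; healthy survivors face naive
#' incidence (if no ED history) or relapse into their most recent ED.
#' All randomness is counter-based on (seed, person, age, channel), so runs
#' with the same seed are identical and scenarios share common random
#' numbers.
#'
#' @param ps a valid [ed_parameter_set()]; invalid sets raise an error
#'   before any simulation.
#' @param scenario a [scenario_spec()].
#' @param n_persons even cohort size (50/50 sex split).
#' @param master_seed integer seed.
#' @param record_full keep the per-person annual state matrix and treatment
#'   log (needed for history export; aggregate statistics are always
#'   recorded).
#' @param streams optional pregenerated [ed_streams()] for this
#'   `(n_persons, master_seed)`.
#' @return an object of class `ed_cohort`; see [cohort_from_states()] for
#'   the aggregate components.
#' @export
simulate_cohort <- function(ps, scenario = scenario_spec("baseline"),
                            n_persons = 1000L, master_seed = 1L,
                            record_full = TRUE, streams = NULL) {
  stopifnot(inherits(ps, "ed_parameter_set"), inherits(scenario, "ed_scenario"))
  n_persons <- as.integer(n_persons)
  if (n_persons < 2L || n_persons %% 2L != 0L)
    stop("n_persons must be even (50/50 sex split)")
  v <- validate_parameter_set(ps)
  if (nrow(v) > 0L)
    stop("invalid parameter set: ", paste(v$kind, v$ed, v$sex, collapse = "; "))
  res <- sim_cohort_cpp(as.numeric(ps$incidence), ps$relapse_first,
                        ps$relapse_decay, ps$remission, ps$treat_coverage,
                        ps$treat_rr, as.numeric(ps$crossover), ps$smr,
                        ps$life_table,
                        treatment_mode_code(scenario$treatment_mode),
                        scenario$incidence_on, n_persons,
                        as.numeric(master_seed), isTRUE(record_full),
                        if (is.null(streams)) NULL else streams$u0,
                        if (is.null(streams)) NULL else streams$u1)
  res$n <- n_persons
  res$n_by_sex <- c(male = n_persons %/% 2L, n_persons - n_persons %/% 2L)
  names(res$n_by_sex) <- SEXES
  res$sex <- rep(1:2, res$n_by_sex)
  res$scenario <- scenario
  res$master_seed <- master_seed
  class(res) <- "ed_cohort"
  res
}

#' @export
print.ed_cohort <- function(x, ...) {
  dead <- sum(x$state_counts[STATE_DECEASED, , N_AGES + 1L])
  ever <- sum(x$onset_counts)
  cat(sprintf("Simulated cohort: %d persons, scenario '%s', seed %s\n",
              x$n, x$scenario$name, format(x$master_seed)))
  cat(sprintf("  ever-ED by 40: %d (%.1f%%); deaths by 40: %d (%.2f%%)\n",
              ever, 100 * ever / x$n, dead, 100 * dead / x$n))
  invisible(x)
}

#' Build a cohort object from an explicit state matrix
#'
#' Computes, in R, the aggregate statistics the engine accumulates
#' (state occupancy counts, first-onset counts, first per-ED onset counts,
#' and episode-count distributions) from a per-person annual state matrix.
#' An overall episode is a maximal contiguous run of ages in any ED state
#' (crossover does not end it); a per-ED episode is a maximal contiguous
#' run in that specific state. Useful for hand-built cohorts in analyses
#' and as a cross-check of the engine's bookkeeping.
#'
#' @param states integer matrix `[n, 41]` of state codes, ages 0..40.
#' @param sex integer vector (1 male, 2 female) of length `n`.
#' @return an `ed_cohort` object.
#' @export
cohort_from_states <- function(states, sex) {
  states <- as.matrix(states)
  n <- nrow(states)
  stopifnot(ncol(states) == N_AGES + 1L, length(sex) == n)
  sex <- sex_index(sex)
  state_counts <- array(0L, dim = c(6, 2, N_AGES + 1L))
  for (st in 1:6) for (s in 1:2)
    state_counts[st, s, ] <-
      as.integer(colSums(states[sex == s, , drop = FALSE] == st))
  ed <- is_ed_state(states)
  onset_age <- apply(ed, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] - 1L else -1L
  })
  onset_counts <- array(0L, dim = c(2, N_AGES + 1L))
  first_ed_counts <- array(0L, dim = c(4, 2, N_AGES + 1L))
  for (s in 1:2) {
    oa <- onset_age[sex == s & onset_age >= 0]
    if (length(oa)) onset_counts[s, ] <- tabulate(oa + 1L, N_AGES + 1L)
    for (e in 1:4) {
      fe <- apply(states[sex == s, , drop = FALSE] == e + 1L, 1, function(r) {
        w <- which(r)
        if (length(w)) w[1] else NA_integer_
      })
      fe <- fe[!is.na(fe)]
      if (length(fe)) first_ed_counts[e, s, ] <- tabulate(fe, N_AGES + 1L)
    }
  }
  run_starts <- function(m) {
    # counts of maximal TRUE runs per row
    starts <- m & !cbind(FALSE, m[, -ncol(m), drop = FALSE])
    rowSums(starts)
  }
  epi_bin <- function(k) pmin(k, 5L) + 1L
  n_any <- run_starts(ed)
  epi_any <- array(0L, dim = c(6, 2))
  epi_ed <- array(0L, dim = c(4, 6, 2))
  for (s in 1:2) {
    epi_any[, s] <- tabulate(epi_bin(n_any[sex == s]), 6L)
    for (e in 1:4) {
      k <- run_starts(states[sex == s, , drop = FALSE] == e + 1L)
      epi_ed[e, , s] <- tabulate(epi_bin(k), 6L)
    }
  }
  structure(list(state_counts = state_counts, onset_counts = onset_counts,
                 first_ed_counts = first_ed_counts, episodes_any = epi_any,
                 episodes_ed = epi_ed, states = states,
                 onset_age = onset_age, n = n,
                 n_by_sex = stats::setNames(tabulate(sex, 2L), SEXES),
                 sex = sex,
                 scenario = scenario_spec("handmade"), master_seed = NA),
            class = "ed_cohort")
}

#' Run several scenarios under common random numbers
#'
#' All scenarios share the same master seed (hence the same per-channel
#' draws), so paired person-level outputs are aligned by person id and
#' differences between scenarios reflect only the intervention.
#'
#' @param ps a valid [ed_parameter_set()].
#' @param scenarios named list of [scenario_spec()]; names must be unique.
#' @param n_persons even cohort size.
#' @param master_seed integer seed shared by all scenarios.
#' @param record_full see [simulate_cohort()].
#' @return named list of `ed_cohort` objects.
#' @export
run_counterfactuals <- function(ps, scenarios, n_persons, master_seed,
                                record_full = FALSE) {
  if (length(scenarios) < 2L) stop("need at least two scenarios")
  nm <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate scenario names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  streams <- ed_streams(n_persons, master_seed)
  out <- lapply(scenarios, function(sc)
    simulate_cohort(ps, sc, n_persons, master_seed,
                    record_full = record_full, streams = streams))
  names(out) <- nm
  out
}

#' Export simulated histories as long-format and per-person CSV
#'
#' @param cohort an `ed_cohort` simulated with `record_full = TRUE`.
#' @param path long-format CSV path (columns `id, sex, age, state,
#'   treated`).
#' @param summary_path optional per-person summary CSV (columns `id, sex,
#'   age_first_onset, n_episodes, age_at_death`).
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(cohort, path, summary_path = NULL) {
  if (is.null(cohort$states))
    stop("cohort was simulated without record_full = TRUE")
  n <- cohort$n
  ages <- 0:N_AGES
  long <- data.frame(
    id = rep(seq_len(n), each = length(ages)),
    sex = SEXES[rep(cohort$sex, each = length(ages))],
    age = rep(ages, n),
    state = STATE_LABELS[t(cohort$states)])
  tr <- cbind(cohort$treated, 0L)
  long$treated = as.integer(t(tr))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    dead <- cohort$states == STATE_DECEASED
    aad <- apply(dead, 1, function(r) {
      w <- which(r)
      if (length(w)) w[1] - 1L else NA_integer_
    })
    ed <- is_ed_state(cohort$states)
    starts <- ed & !cbind(FALSE, ed[, -ncol(ed), drop = FALSE])
    summ <- data.frame(
      id = seq_len(n), sex = SEXES[cohort$sex],
      age_first_onset = ifelse(cohort$onset_age >= 0, cohort$onset_age, NA),
      n_episodes = rowSums(starts),
      age_at_death = aad)
    utils::write.csv(summ, summary_path, row.names = FALSE)
  }
  invisible(path)
}
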