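# Shared fixtures: all inputs are generated in code.

fixture_frame <- function() synthetic_frame()

fixture_table <- function() read_param_table()

# published calibrated means plus mid-bound incidence multipliers
fixture_means_theta <- function(tab = fixture_table()) {
  th <- param_means(tab)
  b <- param_bounds(tab, "incidence_multiplier")
  mult <- stats::setNames((b$lower + b$upper) / 2, b$param)
  c(th, mult)
}

fixture_means_ps <- function() {
  params_from_theta(fixture_means_theta(), fixture_frame())
}

# reduced two-ED parameter set with rates constant in age, both sexes equal
fixture_two_ed_ps <- function(q = 0.005) {
  m2 <- function(an, bn) matrix(c(an, bn, 0, 0), 4, 2,
                                dimnames = list(ED_TYPES, SEXES))
  inc <- array(0, dim = c(4, 2, 40))
  inc[1, , ] <- 0.05
  inc[2, , ] <- 0.04
  cross <- array(0, dim = c(4, 4, 2))
  cross[1, 2, ] <- 0.03  # AN -> BN
  cross[2, 1, ] <- 0.02  # BN -> AN
  ed_parameter_set(
    incidence = inc,
    relapse_first = m2(0.25, 0.20),
    relapse_decay = m2(0.40, 0.30),
    remission = m2(0.20, 0.25),
    treat_coverage = m2(0.30, 0.30),
    treat_rr = matrix(c(2, 1.5, 1, 1), 4, 2),
    crossover = cross,
    smr = matrix(c(3, 2, 1, 1), 4, 2),
    life_table = matrix(q, 2, 40))
}

# Exhaustive path enumeration of the annual-cycle chain: an independent
# reimplementation of the bookkeeping rules (relapse clock, most-recent ED,
# absorbing death) on top of the closed-form one-cycle distribution.
enumerate_occupancy <- function(ps, sex, n_steps,
                                scenario = scenario_spec("baseline")) {
  occ <- matrix(0, 6, n_steps + 1)
  recurse <- function(age, state, hist, prob) {
    occ[state, age + 1] <<- occ[state, age + 1] + prob
    if (state == STATE_DECEASED) {
      if (age < n_steps)
        for (b in (age + 1):n_steps)
          occ[state, b + 1] <<- occ[state, b + 1] + prob
      return(invisible(NULL))
    }
    if (age == n_steps) return(invisible(NULL))
    d <- annual_outcome_distribution(state, sex, age, hist, ps, scenario)
    for (ns in which(d > 0)) {
      h2 <- hist
      if (is_ed_state(state) && ns == STATE_HEALTHY) {
        h2$last_ed <- state - 1L
        h2$years_since_remission <- 1L
      } else if (state == STATE_HEALTHY && ns == STATE_HEALTHY &&
                 isTRUE(hist$has_history)) {
        h2$years_since_remission <- hist$years_since_remission + 1L
      }
      if (is_ed_state(ns)) {
        h2$has_history <- TRUE
        h2$last_ed <- ns - 1L
      }
      recurse(age + 1L, ns, h2, prob * d[[ns]])
    }
  }
  recurse(0L, STATE_HEALTHY,
          list(has_history = FALSE, last_ed = NA, years_since_remission = NA),
          1)
  occ
}

# state matrix -> long data.frame, for group-by oracles
states_long <- function(states, sex) {
  data.frame(id = rep(seq_len(nrow(states)), ncol(states)),
             sex = rep(sex, ncol(states)),
             age = rep(0:(ncol(states) - 1L), each = nrow(states)),
             state = as.vector(states))
}
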