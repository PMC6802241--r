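test_that("per-cycle probability transforms match their closed forms", {
  # relapse hazard declines exponentially from the first-year value
  expect_equal(relapse_probability(0.213, 0.52, 1), 0.213)
  expect_equal(relapse_probability(0.213, 0.52, 2), 0.213 * exp(-0.52))
  expect_equal(relapse_probability(0.4, 0, 17), 0.4)
  yrs <- 1:30
  expect_true(all(diff(relapse_probability(0.3, 0.7, yrs)) <= 0))
  expect_error(relapse_probability(0.2, 0.5, 0), ">= 1")

  # treatment scales the remission rate, not the probability
  expect_equal(treated_remission_probability(0.085, 8), 1 - 0.915^8)
  expect_equal(treated_remission_probability(0.3, 1), 0.3)
  expect_equal(treated_remission_probability(0, 5), 0)
  expect_equal(treated_remission_probability(1, 3), 1)
  expect_true(all(treated_remission_probability(seq(0, 0.9, 0.1), 4) >=
                    seq(0, 0.9, 0.1)))

  # SMR acts on the mortality rate scale
  expect_equal(ed_mortality_probability(0.001, 6.71), 1 - 0.999^6.71)
  expect_equal(ed_mortality_probability(0.002, 1), 0.002)
  expect_equal(ed_mortality_probability(0, 8), 0)
  expect_error(ed_mortality_probability(1, 2), "q_bg")
})

test_that("one-cycle outcome distribution matches hand arithmetic and edge cases", {
  ps <- fixture_means_ps()
  # AN male at age 30 under current treatment, hand-computed marginals
  q <- ps$life_table["male", 31]
  d <- annual_outcome_distribution(2, "male", 30,
                                   list(has_history = TRUE, last_ed = 1,
                                        years_since_remission = 1), ps)
  p_die <- 1 - (1 - q)^6.71
  prem <- 0.282 * (1 - (1 - 0.078)^7.59) + (1 - 0.282) * 0.078
  expect_equal(unname(d[["DECEASED"]]), p_die)
  expect_equal(unname(d[["HEALTHY"]]), (1 - p_die) * prem)
  expect_equal(unname(d[["BN"]]), (1 - p_die) * 0.000)
  expect_equal(unname(d[["BED"]]), (1 - p_die) * 0.012)
  expect_equal(unname(d[["OSFED"]]), (1 - p_die) * 0.040)
  expect_equal(sum(d), 1, tolerance = 1e-14)

  # healthy person, incidence switched off: stay or die only
  d2 <- annual_outcome_distribution(STATE_HEALTHY, "female", 15,
                                    list(has_history = FALSE), ps,
                                    scenario_spec("prev", incidence_on = FALSE))
  q15 <- ps$life_table["female", 16]
  expect_equal(unname(d2[["HEALTHY"]]), 1 - q15)
  expect_equal(sum(d2[ED_TYPES]), 0)

  # everything zeroed: persistence is certain
  zero <- fixture_means_theta()
  zero[] <- 0
  zero[grepl("^(treat_rr|smr)", names(zero))] <- 1
  ps0 <- params_from_theta(zero, fixture_frame())
  ps0$life_table[] <- 0
  d3 <- annual_outcome_distribution(3, "male", 10,
                                    list(has_history = TRUE, last_ed = 2,
                                         years_since_remission = 1), ps0)
  expect_equal(unname(d3[["BN"]]), 1)
  expect_error(annual_outcome_distribution(STATE_DECEASED, "male", 5,
                                           list(), ps), "deceased")
})

test_that("simulation is deterministic and stream caching changes nothing", {
  ps <- fixture_means_ps()
  a <- simulate_cohort(ps, scenario_spec("baseline"), 2000, 99)
  b <- simulate_cohort(ps, scenario_spec("baseline"), 2000, 99)
  expect_identical(a$states, b$states)
  st <- ed_streams(2000, 99)
  c3 <- simulate_cohort(ps, scenario_spec("baseline"), 2000, 99, streams = st)
  expect_identical(a$states, c3$states)
  d <- simulate_cohort(ps, scenario_spec("baseline"), 2000, 100)
  expect_false(identical(a$states, d$states))
  expect_error(simulate_cohort(ps, scenario_spec("baseline"), 1001, 1), "even")
})

test_that("histories are legal: absorbing death, crossover-only ED jumps, relapse returns to the last ED", {
  ps <- fixture_two_ed_ps()
  co <- simulate_cohort(ps, scenario_spec("baseline"), 6000, 17)
  st <- co$states
  # deceased is absorbing
  dead <- st == STATE_DECEASED
  expect_true(all(dead[, -1] >= dead[, -ncol(st)]))
  # no transitions from healthy into an ED differing from the most recent
  # ED except first onset; relapse destination equals the most recent ED
  for (p in which(rowSums(is_ed_state(st)) > 0)) {
    r <- st[p, ]
    last <- NA
    for (a in 2:41) {
      if (is_ed_state(r[a]) && r[a - 1] == STATE_HEALTHY) {
        if (!is.na(last)) expect_identical(r[a], last)  # relapse
      }
      if (is_ed_state(r[a])) last <- r[a]
    }
  }
  # the engine's aggregate bookkeeping equals a recount from the matrix
  rebuilt <- cohort_from_states(co$states, co$sex)
  expect_identical(rebuilt$state_counts, array(co$state_counts, dim = c(6, 2, 41)))
  expect_identical(rebuilt$onset_counts, array(co$onset_counts, dim = c(2, 41)))
  expect_identical(rebuilt$first_ed_counts,
                   array(co$first_ed_counts, dim = c(4, 2, 41)))
  expect_identical(rebuilt$episodes_any, array(co$episodes_any, dim = c(6, 2)))
  expect_identical(rebuilt$episodes_ed, array(co$episodes_ed, dim = c(4, 6, 2)))
  expect_identical(unname(rebuilt$onset_age), as.integer(co$onset_age))
})

test_that("with incidence zeroed the cohort reduces to the background life table", {
  th <- fixture_means_theta()
  th[grepl("incidence_multiplier", names(th))] <- 0
  ps <- params_from_theta(th, fixture_frame())
  co <- simulate_cohort(ps, scenario_spec("baseline"), 20000, 31,
                        record_full = FALSE)
  expect_equal(sum(co$state_counts[2:5, , ]), 0)
  for (s in 1:2) {
    q <- ps$life_table[s, ]
    expect_gt(stats::binom.test(co$state_counts[STATE_DECEASED, s, 41],
                                10000, 1 - prod(1 - q))$p.value, 0.005)
  }
})

test_that("common random numbers leave never-affected persons untouched across scenarios", {
  ps <- fixture_means_ps()
  runs <- run_counterfactuals(ps, default_scenarios(), 4000, 53,
                              record_full = TRUE)
  base_ed <- rowSums(is_ed_state(runs$baseline$states)) > 0
  for (nm in c("no_treatment", "full_treatment", "no_incidence")) {
    other <- runs[[nm]]$states[!base_ed, ]
    expect_identical(other, runs$baseline$states[!base_ed, ])
  }
  expect_error(run_counterfactuals(ps, list(scenario_spec("x"),
                                            scenario_spec("x")), 100, 1),
               "duplicate")
  same <- run_counterfactuals(ps, list(a = scenario_spec("b1"),
                                       b = scenario_spec("b2")), 1000, 5,
                              record_full = TRUE)
  expect_identical(same$a$states, same$b$states)
})

test_that("treatment and prevention reduce deaths in expectation across seeds", {
  ps <- fixture_means_ps()
  d_none <- d_full <- d_base <- d_prev <- numeric(20)
  for (i in 1:20) {
    runs <- run_counterfactuals(ps, default_scenarios(), 4000, 1000 + i)
    d_base[i] <- deaths_by_40(runs$baseline)
    d_none[i] <- deaths_by_40(runs$no_treatment)
    d_full[i] <- deaths_by_40(runs$full_treatment)
    d_prev[i] <- deaths_by_40(runs$no_incidence)
  }
  expect_lt(mean(d_full), mean(d_none))
  expect_lt(mean(d_prev), mean(d_base))
  expect_lte(mean(d_base), mean(d_none))
})

test_that("simulated occupancy matches exhaustive enumeration of the reduced chain", {
  ps <- fixture_two_ed_ps()
  n <- 200000
  co <- simulate_cohort(ps, scenario_spec("baseline"), n, 2024,
                        record_full = FALSE)
  for (s in 1:2) {
    exact <- enumerate_occupancy(ps, s, 3)
    sim <- array(co$state_counts, dim = c(6, 2, 41))[, s, 1:4] / (n / 2)
    se <- sqrt(exact * (1 - exact) / (n / 2))
    expect_true(all(abs(sim - exact) <= 3 * se + 1e-12))
  }
})
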