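test_that("incidence curves scale a fixed shape and invert cumulative anchors", {
  shape <- rep(0, 40)
  expect_equal(build_incidence_curve(shape, 0.7), rep(0, 40))
  shape[19] <- 1  # age 18
  curve <- build_incidence_curve(shape, 0.004)
  expect_equal(curve[19], 0.004)
  expect_equal(sum(curve), 0.004)
  expect_error(build_incidence_curve(c(-0.1, rep(0, 39)), 1), "nonnegative")
  expect_error(build_incidence_curve(shape, -1), "nonnegative")

  # flat shape over an 8-year window: closed form m = 1 - (1 - target)^(1/8)
  flat <- c(rep(1, 8), rep(0, 32))
  for (target in c(0.026, 0.242)) {
    m <- calibrate_multiplier_to_cumulative(flat, c(0, 7), target)
    expect_equal(m, 1 - (1 - target)^(1 / 8), tolerance = 1e-8)
    cum <- 1 - prod(1 - build_incidence_curve(flat, m)[1:8])
    expect_equal(cum, target, tolerance = 1e-8)
  }
  expect_equal(calibrate_multiplier_to_cumulative(flat, c(0, 7), 0), 0)
  expect_error(calibrate_multiplier_to_cumulative(rep(0, 40), c(0, 7), 0.1),
               "unreachable")
  # a window far from the peak cannot reach a high cumulative target
  # without pushing the peak's annual probability above 1
  tail_shape <- synthetic_incidence_shape(16, 0.2)
  expect_error(calibrate_multiplier_to_cumulative(tail_shape, c(33, 39), 0.5),
               "unreachable")
})

test_that("multiplier calibration round-trips random unimodal shapes", {
  set.seed(101)
  for (rep in 1:20) {
    peak <- runif(1, 12, 25)
    shape <- synthetic_incidence_shape(peak, runif(1, 0.15, 0.5))
    win <- sort(sample(10:30, 2))
    idx <- (win[1]:win[2]) + 1L
    # keep the target inside the reachable range for this window
    cum_max <- 1 - prod(1 - shape[idx] / max(shape))
    target <- runif(1, 0.05, 0.9) * cum_max
    m <- calibrate_multiplier_to_cumulative(shape, win, target)
    cum <- 1 - prod(1 - build_incidence_curve(shape, m)[idx])
    expect_equal(cum, target, tolerance = 1e-8)
  }
})

test_that("the parameter table fixture loads with unit conversion intact", {
  tab <- fixture_table()
  expect_s3_class(tab, "ed_param_table")
  # 8 cells for each of 7 scalar blocks + 24 crossovers + 8 multipliers
  expect_equal(nrow(tab), 7 * 8 + 24)
  expect_equal(sum(tab$block == "crossover"), 24)
  b <- param_bounds(tab)
  expect_true(all(b$lower <= b$upper))
  # percent rows land on the probability scale
  an_m <- tab[tab$param == "relapse_first.AN.male", ]
  expect_equal(an_m$lower, 0.05)
  expect_equal(an_m$mean, 0.213)
  expect_equal(tab[tab$param == "smr.AN.male", "mean"], 6.71)
  means <- param_means(tab)
  expect_false(any(grepl("incidence_multiplier", names(means))))
})

test_that("uniform sampling respects bounds and is reproducible", {
  tab <- fixture_table()
  bounds <- param_bounds(tab)
  set.seed(7)
  draws <- replicate(200, sample_theta(bounds))
  expect_true(all(draws >= bounds$lower & draws <= bounds$upper))
  smr_row <- which(bounds$param == "smr.AN.male")
  expect_true(all(draws[smr_row, ] >= 4.17 & draws[smr_row, ] <= 8.26))
  set.seed(42)
  th1 <- sample_theta(bounds)
  set.seed(42)
  th2 <- sample_theta(bounds)
  expect_identical(th1, th2)
  degenerate <- bounds
  degenerate$lower <- degenerate$upper
  expect_identical(unname(sample_theta(degenerate)), degenerate$upper)
})

test_that("validity checking flags probability sums above one", {
  frame <- fixture_frame()
  th <- fixture_means_theta()
  zero <- th
  zero[grepl("^(relapse_first|remission|treat_coverage|crossover|incidence_multiplier)",
             names(zero))] <- 0
  zero[grepl("^(treat_rr|smr)", names(zero))] <- 1
  expect_equal(nrow(validate_parameter_set(params_from_theta(zero, frame))), 0)

  bad <- th
  bad[c("crossover.BN.AN.female", "crossover.BN.BED.female",
        "crossover.BN.OSFED.female")] <- 0.40
  v <- validate_parameter_set(params_from_theta(bad, frame))
  expect_true(any(v$kind == "ed_row" & v$ed == "BN" & v$sex == "female"))

  # hand-summed oracle for the flagged excess
  ps_bad <- params_from_theta(bad, frame)
  p_die <- 1 - (1 - max(frame$life_table["female", ]))^ps_bad$smr[2, 2]
  p_rem <- 1 - (1 - ps_bad$remission[2, 2])^ps_bad$treat_rr[2, 2]
  by_hand <- p_die + p_rem + 3 * 0.40 - 1
  expect_equal(v$excess[v$ed == "BN" & v$sex == "female"], by_hand,
               tolerance = 1e-12)
})

test_that("bound repair lowers the implicated lower bounds until sampling succeeds", {
  frame <- fixture_frame()
  tab <- fixture_table()
  bounds <- param_bounds(tab)
  # force an impossible row: BN female crossovers must sum near 1.2
  hot <- bounds$block == "crossover" & bounds$ed == "BN" &
    bounds$sex == "female"
  bounds$lower[hot] <- 0.40
  bounds$upper[hot] <- 0.45
  v <- data.frame(kind = "ed_row", ed = "BN", sex = "female", excess = 0.3)
  b1 <- repair_bounds(bounds, v[1, ])
  expect_equal(b1$lower[hot], rep(0.9 * 0.40, sum(hot)))
  expect_identical(b1$upper, bounds$upper)
  expect_identical(b1[!hot & b1$block == "crossover", "lower"],
                   bounds[!hot & bounds$block == "crossover", "lower"])

  set.seed(11)
  fixed <- fix_bounds(bounds, fixture_means_theta())
  fixed$lower[hot] <- 0.40
  fixed$upper[hot] <- 0.45
  res <- sample_valid_parameter_set(fixed, frame)
  expect_equal(nrow(validate_parameter_set(res$ps)), 0)
  expect_true(all(res$bounds$lower[hot] < 0.40))
})

test_that("valid parameter sets give unit-sum outcome distributions everywhere", {
  frame <- fixture_frame()
  set.seed(5)
  res <- sample_valid_parameter_set(param_bounds(fixture_table()), frame)
  ps <- res$ps
  worst <- 0
  for (state in c(STATE_HEALTHY, 2:5)) for (s in 1:2) for (a in c(0, 15, 39)) {
    for (hist in list(list(has_history = FALSE),
                      list(has_history = TRUE, last_ed = 3,
                           years_since_remission = 2))) {
      if (is_ed_state(state) && !isTRUE(hist$has_history)) next
      d <- annual_outcome_distribution(state, s, a, hist, ps)
      expect_true(all(d >= 0))
      worst <- max(worst, abs(sum(d) - 1))
    }
  }
  expect_lt(worst, 1e-12)
})
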