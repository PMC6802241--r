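toy_targets <- function(values, se) {
  structure(data.frame(kind = "annual_prevalence", ed = "ANY", sex = "male",
                       age_lo = 21, age_hi = 21, value = values, se = se),
            class = c("ed_targets", "data.frame"))
}

test_that("the weighted quadratic loss behaves as specified", {
  tg <- toy_targets(c(0.10, 0.2), c(0.01, 0.05))
  expect_equal(goodness_of_fit(tg$value, tg), 0)
  expect_equal(goodness_of_fit(c(0.12, 0.2), tg), (1 / 0.01) * 0.02^2)
  # halving one SE doubles that term's contribution
  tg2 <- tg
  tg2$se[1] <- 0.005
  expect_equal(goodness_of_fit(c(0.12, 0.2), tg2),
               2 * goodness_of_fit(c(0.12, 0.2), tg))
  # order invariance
  perm <- c(2, 1)
  expect_equal(goodness_of_fit(c(0.12, 0.25), tg),
               goodness_of_fit(c(0.25, 0.12), tg[perm, ]))
  # inverse-variance option
  expect_equal(goodness_of_fit(c(0.12, 0.2), tg, weight = "inv_var"),
               (1 / 0.01^2) * 0.02^2)
  tg$se[1] <- 0
  expect_error(goodness_of_fit(c(0.1, 0.2), tg), "positive")
})

test_that("target simulation is deterministic and order-independent", {
  th <- fixture_means_theta()
  frame <- fixture_frame()
  targets <- read_targets()
  th0 <- th
  th0[grepl("incidence_multiplier", names(th0))] <- 0
  expect_equal(simulate_targets(params_from_theta(th0, frame), targets,
                                4000, 3),
               rep(0, nrow(targets)))
  ps <- params_from_theta(th, frame)
  est <- simulate_targets(ps, targets, 4000, 3)
  perm <- c(3, 1, 4, 2)
  expect_equal(simulate_targets(ps, targets[perm, ], 4000, 3), est[perm])
  expect_equal(simulate_targets(ps, targets, 4000, 3), est)
})

test_that("annealing solves a one-parameter convex problem to proposal resolution", {
  bounds <- structure(data.frame(param = "x", block = "toy", ed = NA,
                                 ed2 = NA, sex = NA, lower = 0, upper = 1),
                      class = c("ed_search_bounds", "data.frame"))
  obj <- function(theta) (theta[["x"]] - 0.371)^2
  cfg <- anneal_config("test", n_searches = 1, n_iterations = 300,
                       keep_k = 1, proposal_scale = 0.05, t0 = NULL)
  res <- anneal_search(bounds, NULL, cfg, search_seed = 8, objective = obj)
  grid <- seq(0, 1, by = 1e-4)
  x_star <- grid[which.min((grid - 0.371)^2)]
  expect_lt(abs(res$theta[["x"]] - x_star), 0.05)
  # best-so-far trace never increases
  expect_true(all(diff(res$trace$best) <= 0))
  expect_equal(min(res$trace$best), res$score)

  # degenerate start at the optimum: zero score at iteration 0
  b0 <- bounds
  b0$lower <- b0$upper <- 0.371
  res0 <- anneal_search(b0, NULL, cfg, search_seed = 9, objective = obj)
  expect_equal(res0$initial_score, 0)
  expect_equal(res0$score, 0)

  # at vanishing temperature the search is greedy: accepted scores descend
  cfg_greedy <- anneal_config("test", n_searches = 1, n_iterations = 200,
                              keep_k = 1, t0 = 1e-300)
  resg <- anneal_search(bounds, NULL, cfg_greedy, search_seed = 10,
                        objective = obj)
  acc <- resg$trace$score[resg$trace$accepted]
  expect_true(all(diff(acc) <= 1e-12))
})

test_that("ensemble selection keeps the lowest scores with deterministic ties", {
  mk <- function(score, seed) list(theta = c(x = score), score = score,
                                   initial_score = 1, trace = NULL,
                                   search_seed = seed)
  res <- list(mk(3, 1), mk(1, 2), mk(2, 3))
  kept <- select_ensemble(res, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "score"), c(1, 2))
  expect_length(select_ensemble(res, 3), 3)
  expect_error(select_ensemble(res, 0), "positive")
  expect_error(select_ensemble(res, 4), "fewer")
  ties <- list(mk(1, 5), mk(1, 2), mk(1, 9))
  expect_equal(vapply(select_ensemble(ties, 2), `[[`, numeric(1),
                      "search_seed"), c(2, 5))
})

test_that("ensemble summaries use mean and interpolated 2.5/97.5 percentiles", {
  one <- summarize_ensemble(matrix(0.4, 1, 1, dimnames = list(NULL, "p")))
  expect_equal(one$mean, 0.4)
  expect_equal(one$ui_lo, 0.4)
  expect_equal(one$ui_hi, 0.4)
  m <- matrix(1:100, 100, 1, dimnames = list(NULL, "p"))
  s <- summarize_ensemble(m)
  expect_equal(s$mean, 50.5)
  expect_equal(s$ui_lo, unname(quantile(1:100, 0.025, type = 7)))
  expect_equal(s$ui_hi, unname(quantile(1:100, 0.975, type = 7)))
  expect_error(summarize_ensemble(matrix(numeric(), 0, 1)), "empty")
})

test_that("a small calibration run pulls the simulated targets toward the anchors", {
  frame <- fixture_frame()
  tab <- fixture_table()
  bounds <- fix_bounds(param_bounds(tab), param_means(tab))
  targets <- read_targets()
  cfg <- anneal_config("test", n_searches = 6, n_iterations = 120,
                       sim_size = 6000, keep_k = 3)
  fit <- ed_calibrate(targets, bounds, frame, cfg, master_seed = 12)
  expect_s3_class(fit, "ed_fit")
  expect_equal(nrow(fit$ensemble), 3)
  expect_lt(min(fit$scores), mean(fit$initial_scores))
  # fitted estimates should be much closer than a random draw, in loss units
  expect_lt(goodness_of_fit(fit$fitted, targets),
            0.25 * mean(fit$initial_scores))
  # methods
  expect_length(coef(fit), nrow(param_bounds(tab)))
  expect_length(residuals(fit), nrow(targets))
  s <- summary(fit)
  expect_equal(nrow(s$parameters), 8)  # only free multipliers reported
  expect_identical(colnames(s$targets)[8], "fitted")
})
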