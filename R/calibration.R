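#' Annealing configuration profiles
#'
#' Controls the restart simulated-annealing search. The `"paper"` profile
#' is the full-scale design (10 000 independent searches of 1000 iterations
#' each, 100 000-person evaluations, keeping the best 100 sets); `"desk"`
#' is a workstation-scale profile (200 searches x 500 iterations,
#' 20 000-person evaluations) and `"test"` a minutes-scale profile for
#' examples and tests.
#'
#' @param profile `"desk"`, `"paper"`, or `"test"`; sets defaults that the
#'   other arguments override.
#' @param n_searches number of independent annealing restarts.
#' @param n_iterations proposals per search.
#' @param sim_size cohort size per objective evaluation.
#' @param keep_k ensemble size (best-scoring sets kept).
#' @param t0 initial temperature; `NULL` sets it to each search's initial
#'   score so the first uphill moves are accepted with probability ~exp(-1).
#' @param cooling geometric cooling factor per iteration; `NULL` (default)
#'   sets it so the temperature falls four orders of magnitude over a
#'   search, `10^(-4/n_iterations)`, keeping the late phase effectively
#'   greedy regardless of search length.
#' @param proposal_scale jitter half-width as a fraction of each bound
#'   width.
#' @param perturb_prob probability each free parameter is included in a
#'   proposal (at least one always is).
#' @param weight `"inv_se"` weights each squared deviation by 1/SE;
#'   `"inv_var"` by 1/SE^2.
#' @return list of class `ed_anneal_config`.
#' @export
anneal_config <- function(profile = c("desk", "paper", "test"),
                          n_searches = NULL, n_iterations = NULL,
                          sim_size = NULL, keep_k = NULL, t0 = NULL,
                          cooling = NULL, proposal_scale = 0.05,
                          perturb_prob = 0.25, weight = c("inv_se", "inv_var")) {
  profile <- match.arg(profile)
  def <- switch(profile,
                paper = list(n_searches = 10000L, n_iterations = 1000L,
                             sim_size = 100000L, keep_k = 100L),
                desk = list(n_searches = 200L, n_iterations = 500L,
                            sim_size = 20000L, keep_k = 100L),
                test = list(n_searches = 30L, n_iterations = 120L,
                            sim_size = 4000L, keep_k = 10L))
  cfg <- list(profile = profile,
              n_searches = as.integer(n_searches %||% def$n_searches),
              n_iterations = as.integer(n_iterations %||% def$n_iterations),
              sim_size = as.integer(sim_size %||% def$sim_size),
              keep_k = as.integer(keep_k %||% def$keep_k),
              t0 = t0,
              cooling = cooling %||% 10^(-4 / (n_iterations %||% def$n_iterations)),
              proposal_scale = proposal_scale,
              perturb_prob = perturb_prob,
              weight = match.arg(weight))
  stopifnot(cfg$n_searches >= cfg$keep_k, cfg$keep_k > 0L,
            cfg$cooling > 0, cfg$cooling <= 1)
  class(cfg) <- "ed_anneal_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted quadratic calibration loss
#'
#' `sum_i w_i * (target_i - sim_i)^2` with `w_i = 1/se_i` (or `1/se_i^2`
#' for inverse-variance weighting); zero iff every estimate matches its
#' target exactly. More precise targets (smaller SE) carry more weight.
#'
#' @param sim_estimates per-target simulated proportions.
#' @param targets an `ed_targets` data.frame (columns `value`, `se`).
#' @param weight `"inv_se"` (default) or `"inv_var"`.
#' @return nonnegative score.
#' @export
goodness_of_fit <- function(sim_estimates, targets,
                            weight = c("inv_se", "inv_var")) {
  weight <- match.arg(weight)
  if (length(sim_estimates) != nrow(targets))
    stop("need one simulated estimate per target")
  if (any(targets$se <= 0)) stop("target standard errors must be positive")
  w <- if (weight == "inv_se") 1 / targets$se else 1 / targets$se^2
  sum(w * (targets$value - sim_estimates)^2)
}

#' Simulate the calibration-target statistics for one parameter set
#'
#' Runs one baseline cohort and extracts each target's matching statistic;
#' deterministic given the seed.
#'
#' @param ps a valid [ed_parameter_set()].
#' @param targets target data.frame (see [read_targets()]).
#' @param sim_size cohort size.
#' @param seed evaluation seed.
#' @param streams optional pregenerated [ed_streams()] for `(sim_size,
#'   seed)`.
#' @return per-target estimates.
#' @export
simulate_targets <- function(ps, targets, sim_size = 20000L, seed = 1L,
                             streams = NULL) {
  cohort <- simulate_cohort(ps, scenario_spec("baseline"), sim_size, seed,
                            record_full = FALSE, streams = streams)
  extract_target_estimates(cohort, targets)
}

#' Read / write calibration-target CSV files
#'
#' Targets are CSV with columns `kind` (`annual_prevalence` or
#' `lifetime_prevalence`), `ed` (label or `ANY`), `sex`, `age_lo`,
#' `age_hi`, `value`, `se` (proportions).
#'
#' @param path CSV path; the default reads the shipped target set built
#'   from published headline prevalence anchors.
#' @return an `ed_targets` data.frame.
#' @export
read_targets <- function(path = system.file("extdata", "default_targets.csv",
                                            package = "edmicrosim")) {
  if (!file.exists(path)) stop("targets file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "ed", "sex", "age_lo", "age_hi", "value", "se")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed targets file ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  if (any(df$value < 0 | df$value > 1)) stop("target values must be in [0, 1]")
  if (any(df$se <= 0)) stop("target SEs must be positive")
  class(df) <- c("ed_targets", "data.frame")
  df
}

#' @rdname read_targets
#' @param targets an `ed_targets` data.frame.
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets)[, c("kind", "ed", "sex", "age_lo",
                                              "age_hi", "value", "se")],
                   path, row.names = FALSE)
  invisible(path)
}

# lean evaluation used inside the annealing loop: the proposal has already
# passed validate_parameter_set, so skip the wrapper re-validation
eval_targets_fast <- function(ps, targets, sim_size, seed, streams, n_by_sex) {
  res <- sim_cohort_cpp(as.numeric(ps$incidence), ps$relapse_first,
                        ps$relapse_decay, ps$remission, ps$treat_coverage,
                        ps$treat_rr, as.numeric(ps$crossover), ps$smr,
                        ps$life_table, 0L, TRUE, sim_size,
                        as.numeric(seed), FALSE, streams$u0, streams$u1)
  res$n <- sim_size
  res$n_by_sex <- n_by_sex
  class(res) <- "ed_cohort"
  extract_target_estimates(res, targets)
}

#' One simulated-annealing search
#'
#' Starts from a valid uniform draw within the bounds and proposes, each
#' iteration, a uniform jitter (half-width `proposal_scale` times the bound
#' width) on a random subset of the free parameters, clipped to the bounds;
#' proposals yielding invalid probability sums are repaired by shrinking
#' the jitter toward the (valid) current point. Downhill moves are always
#' accepted, uphill moves with probability `exp(-delta/T)` under geometric
#' cooling `T_k = T0 * cooling^k`. Objective evaluations share a fixed
#' evaluation seed (common random numbers across iterations) so the search
#' sees a fixed realisation of the stochastic loss surface.
#'
#' @param bounds an `ed_search_bounds` data.frame.
#' @param targets target data.frame (ignored when `objective` is given).
#' @param config an [anneal_config()].
#' @param search_seed integer seed for this restart (also the evaluation
#'   seed).
#' @param frame an [ed_model_frame()].
#' @param objective optional function `theta -> score` replacing the
#'   default simulate-and-score objective (used for algorithm tests).
#' @return list: `theta` (best-ever), `score`, `initial_score`, `trace`
#'   (data.frame `iter, score, best, accepted`), `search_seed`.
#' @export
anneal_search <- function(bounds, targets, config, search_seed, frame = NULL,
                          objective = NULL) {
  set.seed(search_seed)
  last_ps <- NULL  # parameter set built during the validity check
  if (is.null(objective)) {
    streams <- ed_streams(config$sim_size, search_seed)
    build <- make_params_builder(bounds$param, frame)
    nhalf <- config$sim_size %/% 2L
    n_by_sex <- stats::setNames(c(nhalf, config$sim_size - nhalf), SEXES)
    w <- if (config$weight == "inv_se") 1 / targets$se else 1 / targets$se^2
    if (any(targets$se <= 0)) stop("target standard errors must be positive")
    objective <- function(theta) {
      ps <- last_ps %||% build(theta)
      est <- eval_targets_fast(ps, targets, config$sim_size,
                               search_seed, streams, n_by_sex)
      sum(w * (targets$value - est)^2)
    }
    valid <- function(theta) {
      last_ps <<- build(theta)
      nrow(validate_parameter_set(last_ps)) == 0L
    }
    draw <- function() {
      r <- sample_valid_parameter_set(bounds, frame)
      bounds <<- r$bounds
      last_ps <<- NULL
      r$theta
    }
  } else {
    valid <- function(theta) TRUE
    draw <- function() sample_theta(bounds)
  }

  cur <- draw()
  cur_score <- objective(cur)
  best <- cur
  best_score <- initial_score <- cur_score
  t0 <- config$t0 %||% max(cur_score, .Machine$double.eps)
  free <- which(bounds$upper > bounds$lower)
  width <- bounds$upper - bounds$lower
  n_it <- config$n_iterations
  trace <- data.frame(iter = seq_len(n_it), score = NA_real_,
                      best = NA_real_, accepted = NA)

  for (k in seq_len(n_it)) {
    if (length(free)) {
      pick <- free[stats::runif(length(free)) < config$perturb_prob]
      if (!length(pick)) pick <- sample(free, 1L)
      delta <- stats::runif(length(pick), -1, 1) *
        config$proposal_scale * width[pick]
      prop <- cur
      ok <- FALSE
      for (r in 0:20) {  # jitter-shrink repair: cur is valid, so this ends
        prop[pick] <- pmin(pmax(cur[pick] + delta, bounds$lower[pick]),
                           bounds$upper[pick])
        if (valid(prop)) { ok <- TRUE; break }
        delta <- delta / 2
      }
      if (!ok) { prop <- cur; last_ps <- NULL }
    } else prop <- cur
    s <- objective(prop)
    temp <- t0 * config$cooling^k
    d <- s - cur_score
    acc <- d < 0 || stats::runif(1) < exp(-d / max(temp, 1e-300))
    if (acc) {
      cur <- prop
      cur_score <- s
      if (s < best_score) {
        best <- prop
        best_score <- s
      }
    }
    trace$score[k] <- s
    trace$best[k] <- best_score
    trace$accepted[k] <- acc
  }
  list(theta = best, score = best_score, initial_score = initial_score,
       trace = trace, search_seed = search_seed)
}

#' Keep the best-scoring parameter sets
#'
#' @param search_results list of [anneal_search()] results.
#' @param keep_k how many to keep; ties broken by search seed (lower
#'   first).
#' @return the selected subset of `search_results`, best first.
#' @export
select_ensemble <- function(search_results, keep_k) {
  if (keep_k <= 0) stop("keep_k must be positive")
  if (length(search_results) < keep_k)
    stop("fewer search results than keep_k")
  scores <- vapply(search_results, `[[`, numeric(1), "score")
  seeds <- vapply(search_results, `[[`, numeric(1), "search_seed")
  search_results[order(scores, seeds)[seq_len(keep_k)]]
}

#' Parameter means and 95% uncertainty intervals over an ensemble
#'
#' @param ensemble matrix (sets x parameters) or list of named theta
#'   vectors.
#' @return data.frame `param, mean, ui_lo, ui_hi` (empirical 2.5th/97.5th
#'   percentiles, linear interpolation).
#' @export
summarize_ensemble <- function(ensemble) {
  if (is.list(ensemble)) ensemble <- do.call(rbind, ensemble)
  if (!nrow(ensemble)) stop("empty ensemble")
  qs <- apply(ensemble, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  data.frame(param = colnames(ensemble), mean = colMeans(ensemble),
             ui_lo = qs[1, ], ui_hi = qs[2, ], row.names = NULL)
}

#' Calibrate the model to prevalence targets
#'
#' The model-fitting entry point: runs `n_searches` independent simulated-
#' annealing restarts of the inverse-SE-weighted quadratic loss between
#' simulated and target prevalences, keeps the best `keep_k` parameter
#' sets as an ensemble, and returns a fitted-model object with
#' `print`, `summary`, `coef`, `residuals`, `plot` and `simulate` methods.
#'
#' @param targets an `ed_targets` data.frame ([read_targets()],
#'   [generate_targets()]).
#' @param bounds search bounds ([param_bounds()]); pin parameters with
#'   [fix_bounds()] to calibrate a subset.
#' @param frame an [ed_model_frame()].
#' @param config an [anneal_config()].
#' @param master_seed integer master seed; search seeds are derived from
#'   it.
#' @return an object of class `ed_fit`.
#' @export
ed_calibrate <- function(targets, bounds, frame,
                         config = anneal_config("desk"), master_seed = 1L) {
  stopifnot(nrow(targets) > 0)
  seeds <- (as.numeric(master_seed) + 104729 * seq_len(config$n_searches)) %%
    2147483647
  results <- vector("list", config$n_searches)
  for (i in seq_len(config$n_searches))
    results[[i]] <- anneal_search(bounds, targets, config, seeds[i], frame)
  kept <- select_ensemble(results, config$keep_k)
  ensemble <- do.call(rbind, lapply(kept, `[[`, "theta"))
  fit <- structure(list(
    ensemble = ensemble,
    scores = vapply(kept, `[[`, numeric(1), "score"),
    search_seeds = vapply(kept, `[[`, numeric(1), "search_seed"),
    initial_scores = vapply(results, `[[`, numeric(1), "initial_score"),
    initial_score = mean(vapply(results, `[[`, numeric(1), "initial_score")),
    summary = summarize_ensemble(do.call(rbind,
                                         lapply(kept, `[[`, "theta"))),
    targets = targets, bounds = bounds, frame = frame, config = config,
    master_seed = master_seed), class = "ed_fit")
  fit$fitted <- ensemble_mean_estimates(fit)
  fit
}

#' Ensemble-mean simulated target estimates
#'
#' Averages, over the kept parameter sets, the simulated value of each
#' calibration target, using fresh evaluation seeds (independent of the
#' seeds used during the search).
#'
#' @param fit an `ed_fit`.
#' @param sim_size evaluation cohort size (defaults to the fit's).
#' @return per-target ensemble-mean estimates.
#' @export
ensemble_mean_estimates <- function(fit, sim_size = NULL) {
  sim_size <- sim_size %||% fit$config$sim_size
  est <- matrix(NA_real_, nrow(fit$ensemble), nrow(fit$targets))
  for (i in seq_len(nrow(fit$ensemble))) {
    ps <- params_from_theta(fit$ensemble[i, ], fit$frame)
    seed <- (as.numeric(fit$master_seed) + 15485863 + 977 * i) %% 2147483647
    est[i, ] <- simulate_targets(ps, fit$targets, sim_size, seed)
  }
  colMeans(est)
}
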