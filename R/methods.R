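#' @export
print.ed_fit <- function(x, ...) {
  cat("Calibrated eating-disorder microsimulation (simulated annealing)\n")
  cat(sprintf("  %d searches x %d iterations, %d-person evaluations; kept %d sets\n",
              x$config$n_searches, x$config$n_iterations, x$config$sim_size,
              nrow(x$ensemble)))
  cat(sprintf("  best score %.4g; kept-score range %.4g-%.4g (initial mean %.4g)\n",
              min(x$scores), min(x$scores), max(x$scores), x$initial_score))
  cat(sprintf("  %d free parameter(s), %d target(s)\n",
              sum(x$bounds$upper > x$bounds$lower), nrow(x$targets)))
  invisible(x)
}

#' @export
coef.ed_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$param)
}

#' @export
summary.ed_fit <- function(object, ...) {
  free <- object$bounds$param[object$bounds$upper > object$bounds$lower]
  tab <- object$summary[object$summary$param %in% free, ]
  fit_tab <- cbind(as.data.frame(object$targets)[, c("kind", "ed", "sex",
                                                     "age_lo", "age_hi",
                                                     "value", "se")],
                   fitted = object$fitted)
  fit_tab$z <- (fit_tab$fitted - fit_tab$value) / fit_tab$se
  out <- list(parameters = tab, targets = fit_tab, scores = object$scores,
              config = object$config)
  class(out) <- "summary.ed_fit"
  out
}

#' @export
print.summary.ed_fit <- function(x, ...) {
  cat("Calibrated parameters (ensemble mean and 95% UI):\n")
  print(format(x$parameters, digits = 4), row.names = FALSE)
  cat("\nTarget fit (ensemble-mean simulated vs target):\n")
  print(format(x$targets, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
residuals.ed_fit <- function(object, ...) {
  (object$fitted - object$targets$value) / object$targets$se
}

#' @export
plot.ed_fit <- function(x, ...) {
  tg <- x$targets
  lab <- paste(substr(tg$kind, 1, 1), tg$ed, substr(tg$sex, 1, 1), tg$age_lo)
  ord <- seq_len(nrow(tg))
  ylim <- range(c(tg$value - 2 * tg$se, tg$value + 2 * tg$se, x$fitted))
  plot(ord, tg$value, pch = 19, ylim = ylim, xaxt = "n",
       xlab = "", ylab = "prevalence",
       main = "Calibration targets (dots, +/-2 SE) vs ensemble-mean fit (x)",
       ...)
  graphics::axis(1, at = ord, labels = lab, las = 2, cex.axis = 0.7)
  graphics::arrows(ord, tg$value - 2 * tg$se, ord, tg$value + 2 * tg$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::points(ord, x$fitted, pch = 4, col = 2, cex = 1.2)
  invisible(x)
}

#' Simulate an outcome ensemble from a calibrated fit
#'
#' Runs `nsim` simulations, each sampling one parameter set uniformly (with
#' replacement) from the calibrated ensemble and running all scenarios
#' under common random numbers, so parameter (second-order) and stochastic
#' (first-order) uncertainty both propagate into the 95% uncertainty
#' intervals.
#'
#' @param object an `ed_fit`.
#' @param nsim number of simulation runs.
#' @param seed integer seed.
#' @param n_persons cohort size per run.
#' @param scenarios named list of [scenario_spec()]; the default four
#'   standard scenarios.
#' @param ... unused.
#' @return an object of class `ed_ensemble` holding per-run prevalence
#'   curves, onset CDF, episode distributions and deaths by scenario.
#' @export
simulate.ed_fit <- function(object, nsim = 100L, seed = 1L,
                            n_persons = 20000L,
                            scenarios = default_scenarios(), ...) {
  set.seed(seed)
  picks <- sample.int(nrow(object$ensemble), nsim, replace = TRUE)
  nm <- names(scenarios)
  ages <- 0:N_AGES
  annual <- lifetime <- array(NA_real_, c(2, length(ages), nsim))
  cdf <- array(NA_real_, c(length(ages), nsim))
  episodes <- array(NA_real_, c(5, 2, nsim))
  deaths <- matrix(NA_real_, length(nm), nsim, dimnames = list(nm, NULL))
  for (r in seq_len(nsim)) {
    ps <- params_from_theta(object$ensemble[picks[r], ], object$frame)
    run_seed <- (as.numeric(seed) + 7919 * r) %% 2147483647
    runs <- run_counterfactuals(ps, scenarios, n_persons, run_seed)
    base <- runs[[if ("baseline" %in% nm) "baseline" else nm[1]]]
    for (s in 1:2) {
      annual[s, , r] <- annual_prevalence(base, "ANY", SEXES[s], ages)
      lifetime[s, , r] <- lifetime_prevalence(base, "ANY", SEXES[s], ages)
      episodes[, s, r] <- episode_distribution(base, SEXES[s], "ANY")
    }
    cdf[, r] <- naive_incidence_cdf(base, "both")
    for (j in seq_along(nm)) deaths[j, r] <- deaths_by_40(runs[[j]])
  }
  structure(list(annual = annual, lifetime = lifetime, cdf = cdf,
                 episodes = episodes, deaths = deaths, picks = picks,
                 n_persons = n_persons, nsim = nsim, seed = seed,
                 scenario_names = nm),
            class = "ed_ensemble")
}

# per-run deaths averted (per 100 000) between two named scenarios
averted_runs <- function(ens, from, to, scale = 1e5) {
  if (!all(c(from, to) %in% rownames(ens$deaths)))
    stop("ensemble lacks scenarios ", from, " / ", to)
  (ens$deaths[from, ] - ens$deaths[to, ]) * scale / ens$n_persons
}

#' Headline statistics of a simulated ensemble
#'
#' @param object an `ed_ensemble` from [simulate.ed_fit()].
#' @param ... unused.
#' @return list of class `summary.ed_ensemble`: per-sex lifetime
#'   prevalence at 40 and peak of the mean annual prevalence curve (with
#'   peak age), first-onset CDF at age 25, single-episode shares, and
#'   deaths averted per 100 000 for the three standard comparisons, each
#'   with ensemble mean/median/95% UI where per-run values exist.
#' @export
summary.ed_ensemble <- function(object, ...) {
  x <- object
  lt40 <- lapply(1:2, function(s) ensemble_statistics(x$lifetime[s, N_AGES + 1L, ]))
  names(lt40) <- SEXES
  mean_annual <- apply(x$annual, c(1, 2), mean)
  peak <- lapply(1:2, function(s) {
    i <- which.max(mean_annual[s, ])
    c(peak = unname(mean_annual[s, i]), age = i - 1L,
      ui_lo = unname(stats::quantile(x$annual[s, i, ], 0.025, type = 7)),
      ui_hi = unname(stats::quantile(x$annual[s, i, ], 0.975, type = 7)))
  })
  names(peak) <- SEXES
  cdf25 <- ensemble_statistics(x$cdf[26, ])
  single <- lapply(1:2, function(s) ensemble_statistics(x$episodes[1, s, ]))
  names(single) <- SEXES
  averted <- list()
  if (all(c("baseline", "no_treatment") %in% x$scenario_names))
    averted$current_vs_none <-
      ensemble_statistics(averted_runs(x, "no_treatment", "baseline"))
  if (all(c("full_treatment", "no_treatment") %in% x$scenario_names))
    averted$full_vs_none <-
      ensemble_statistics(averted_runs(x, "no_treatment", "full_treatment"))
  if (all(c("baseline", "no_incidence") %in% x$scenario_names))
    averted$prevention_vs_baseline <-
      ensemble_statistics(averted_runs(x, "baseline", "no_incidence"))
  out <- list(lifetime_40 = lt40, peak_annual = peak, cdf25 = cdf25,
              single_episode = single, deaths_averted = averted,
              nsim = x$nsim, n_persons = x$n_persons)
  class(out) <- "summary.ed_ensemble"
  out
}

#' @export
print.summary.ed_ensemble <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%% (95%% UI %.1f-%.1f)",
                             100 * v[["mean"]], 100 * v[["ui_lo"]],
                             100 * v[["ui_hi"]])
  cat(sprintf("Outcome ensemble: %d runs x %d persons\n", x$nsim, x$n_persons))
  cat("  lifetime ED prevalence by 40:\n")
  for (s in SEXES) cat(sprintf("    %-7s %s\n", s, pct(x$lifetime_40[[s]])))
  cat("  peak annual ED prevalence (mean curve):\n")
  for (s in SEXES)
    cat(sprintf("    %-7s %.1f%% at age %d\n", s,
                100 * x$peak_annual[[s]][["peak"]],
                as.integer(x$peak_annual[[s]][["age"]])))
  cat(sprintf("  first onsets by age 25: %s\n", pct(x$cdf25)))
  cat("  share of affected with a single episode:\n")
  for (s in SEXES) cat(sprintf("    %-7s %s\n", s, pct(x$single_episode[[s]])))
  if (length(x$deaths_averted)) {
    cat("  deaths averted by 40 per 100 000:\n")
    for (nm in names(x$deaths_averted)) {
      v <- x$deaths_averted[[nm]]
      cat(sprintf("    %-24s %.1f (95%% UI %.1f-%.1f)\n", nm, v[["mean"]],
                  v[["ui_lo"]], v[["ui_hi"]]))
    }
  }
  invisible(x)
}

#' @export
print.ed_ensemble <- function(x, ...) {
  cat(sprintf("ed_ensemble: %d runs x %d persons, scenarios: %s\n",
              x$nsim, x$n_persons, paste(x$scenario_names, collapse = ", ")))
  invisible(x)
}

#' Plot ensemble prevalence curves, episode distributions or deaths averted
#'
#' @param x an `ed_ensemble`.
#' @param type `"prevalence"`, `"episodes"` or `"deaths"`.
#' @param ... unused.
#' @export
plot.ed_ensemble <- function(x, type = c("prevalence", "episodes", "deaths"),
                             ...) {
  type <- match.arg(type)
  ages <- 0:N_AGES
  if (type == "prevalence") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    for (what in c("annual", "lifetime")) {
      arr <- x[[what]]
      mn <- apply(arr, c(1, 2), mean)
      lo <- apply(arr, c(1, 2), stats::quantile, 0.025, type = 7)
      hi <- apply(arr, c(1, 2), stats::quantile, 0.975, type = 7)
      plot(ages, 100 * mn[2, ], type = "n", ylim = c(0, 100 * max(hi)),
           xlab = "age", ylab = "prevalence (%)", main = what)
      for (s in 1:2) {
        graphics::polygon(c(ages, rev(ages)), 100 * c(lo[s, ], rev(hi[s, ])),
                          col = grDevices::adjustcolor(s + 1, 0.2),
                          border = NA)
        graphics::lines(ages, 100 * mn[s, ], col = s + 1, lwd = 2)
      }
      graphics::legend("topleft", SEXES, col = 2:3, lwd = 2, bty = "n")
    }
  } else if (type == "episodes") {
    mn <- apply(x$episodes, c(1, 2), mean)
    graphics::barplot(100 * t(mn), beside = TRUE,
                      names.arg = c("1", "2", "3", "4", "5+"),
                      legend.text = SEXES, xlab = "episodes by age 40",
                      ylab = "share of affected (%)")
  } else {
    comps <- names(summary(x)$deaths_averted)
    v <- vapply(comps, function(nm) {
      s <- summary(x)$deaths_averted[[nm]]
      c(s[["mean"]], s[["ui_lo"]], s[["ui_hi"]])
    }, numeric(3))
    bp <- graphics::barplot(v[1, ], names.arg = comps,
                            ylim = c(0, max(v) * 1.1),
                            ylab = "deaths averted by 40 per 100 000")
    graphics::arrows(bp, v[2, ], bp, v[3, ], angle = 90, code = 3,
                     length = 0.05)
  }
  invisible(x)
}
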