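#' Structural model inputs: incidence shapes and a life table
#'
#' A model frame bundles the fixed structural inputs of the microsimulation
#' that are not searched over during calibration: the age shape of
#' first-onset (naive) incidence for each ED and sex (normalised to peak 1),
#' and the background life table. Scalar parameters sampled from search
#' bounds are combined with a frame by [params_from_theta()].
#'
#' @param shapes numeric array `[4 ED, 2 sex, 40 ages]` of nonnegative
#'   incidence shapes, each `(ed, sex)` slice normalised so its maximum is 1.
#'   A `[4, 40]` matrix is accepted and recycled across sexes.
#' @param life_table a life table as returned by [synthetic_life_table()] or
#'   [read_life_table()]: numeric matrix `[2 sex, 40 ages]` of annual death
#'   probabilities.
#' @return an object of class `ed_model_frame`.
#' @export
ed_model_frame <- function(shapes, life_table) {
  if (length(dim(shapes)) == 2L) {
    shapes <- array(rep(shapes, 2L), dim = c(4L, 40L, 2L))
    shapes <- aperm(shapes, c(1L, 3L, 2L))
  }
  stopifnot(identical(dim(shapes), c(4L, 2L, 40L)))
  if (any(shapes < 0)) stop("incidence shapes must be nonnegative")
  q <- as_life_table_matrix(life_table)
  structure(list(shapes = shapes, life_table = q), class = "ed_model_frame")
}

as_life_table_matrix <- function(life_table) {
  if (is.data.frame(life_table)) life_table <- life_table_matrix(life_table)
  q <- as.matrix(life_table)
  if (nrow(q) != 2L || ncol(q) < N_AGES)
    stop("life table must cover both sexes and ages 0..39")
  q <- q[, seq_len(N_AGES), drop = FALSE]
  if (any(q < 0) || any(q >= 1)) stop("life-table q must lie in [0, 1)")
  rownames(q) <- SEXES
  q
}

#' Assemble a complete parameter set
#'
#' A parameter set holds every per-(ED, sex) scalar of the transition model
#' together with the structural incidence curves and life table. All
#' probabilities are on the probability scale (not percent).
#'
#' @param incidence numeric array `[4, 2, 40]`: annual probability of
#'   first-ever onset of each ED by sex and age.
#' @param relapse_first,relapse_decay,remission,treat_coverage,treat_rr,smr
#'   numeric `[4, 2]` matrices (ED by sex): first-year relapse probability,
#'   relapse decay parameter, annual untreated remission probability, annual
#'   treatment proportion, treatment rate ratio on remission, and
#'   standardized mortality ratio.
#' @param crossover numeric array `[4, 4, 2]`: annual probability of direct
#'   transition from one ED (first index) to another (second index), by sex;
#'   the diagonal must be zero.
#' @param life_table background mortality, see [ed_model_frame()].
#' @return an object of class `ed_parameter_set`.
#' @export
ed_parameter_set <- function(incidence, relapse_first, relapse_decay,
                             remission, treat_coverage, treat_rr,
                             crossover, smr, life_table) {
  stopifnot(identical(dim(incidence), c(4L, 2L, 40L)),
            identical(dim(crossover), c(4L, 4L, 2L)))
  for (m in list(relapse_first, relapse_decay, remission,
                 treat_coverage, treat_rr, smr))
    stopifnot(identical(dim(m), c(4L, 2L)))
  if (any(diag_crossover(crossover) != 0))
    stop("crossover diagonal (self-transition) must be zero")
  rng01 <- function(x) any(x < 0 | x > 1)
  if (rng01(incidence)) stop("incidence probabilities must lie in [0, 1]")
  if (rng01(relapse_first) || rng01(relapse_decay) || rng01(remission) ||
      rng01(treat_coverage) || rng01(crossover))
    stop("probabilities must lie in [0, 1]")
  if (any(treat_rr < 1)) stop("treatment rate ratio must be >= 1")
  if (any(smr < 1)) stop("SMR must be >= 1")
  q <- as_life_table_matrix(life_table)
  structure(list(incidence = incidence, relapse_first = relapse_first,
                 relapse_decay = relapse_decay, remission = remission,
                 treat_coverage = treat_coverage, treat_rr = treat_rr,
                 crossover = crossover, smr = smr, life_table = q),
            class = "ed_parameter_set")
}

diag_crossover <- function(crossover) {
  c(crossover[cbind(rep(1:4, 2), rep(1:4, 2), rep(1:2, each = 4))])
}

#' @export
print.ed_parameter_set <- function(x, ...) {
  cat("Eating-disorder microsimulation parameter set\n")
  cat("  peak annual naive incidence by ED (male / female):\n")
  for (i in 1:4)
    cat(sprintf("    %-6s %.5f / %.5f\n", ED_TYPES[i],
                max(x$incidence[i, 1, ]), max(x$incidence[i, 2, ])))
  cat(sprintf("  untreated remission (male, AN..OSFED): %s\n",
              paste(sprintf("%.3f", x$remission[, 1]), collapse = " ")))
  cat(sprintf("  SMR range: %.2f-%.2f\n", min(x$smr), max(x$smr)))
  invisible(x)
}

# ---- incidence curves -------------------------------------------------------

#' Build a naive-incidence curve from an age shape and a scalar multiplier
#'
#' The age pattern of first onset is a fixed shape (peak normalised to 1,
#' emulating unimodal adolescent-peak incidence curves) and the level is a
#' single calibrated multiplier, so each `(ED, sex)` incidence curve
#' contributes one scalar to the calibration search space.
#'
#' @param shape nonnegative numeric vector over ages 0..39, peak value 1.
#' @param multiplier nonnegative scalar level.
#' @return numeric vector of annual onset probabilities, clipped to `[0, 1]`.
#' @export
build_incidence_curve <- function(shape, multiplier) {
  if (any(shape < 0)) stop("shape entries must be nonnegative")
  if (length(multiplier) != 1L || multiplier < 0)
    stop("multiplier must be a nonnegative scalar")
  pmin(multiplier * shape, 1)
}

#' Solve for the multiplier matching a cumulative-incidence anchor
#'
#' Finds `m` such that the cumulative incidence over an age window,
#' `1 - prod(1 - m * shape[a])`, equals a target proportion. Used to anchor
#' incidence levels to published multi-year cumulative incidence (for
#' example an 8-year cumulative incidence over an adolescent window).
#'
#' @param shape nonnegative shape vector over ages 0..39 (peak 1).
#' @param age_window integer `c(a0, a1)`, inclusive window of ages (0-based).
#' @param cumulative_target target cumulative incidence in `[0, 1)`.
#' @param tol convergence tolerance on the cumulative incidence.
#' @return the scalar multiplier.
#' @export
calibrate_multiplier_to_cumulative <- function(shape, age_window,
                                               cumulative_target,
                                               tol = 1e-10) {
  if (any(shape < 0)) stop("shape entries must be nonnegative")
  if (cumulative_target < 0 || cumulative_target >= 1)
    stop("cumulative target must lie in [0, 1)")
  idx <- (age_window[1]:age_window[2]) + 1L
  s <- shape[idx]
  if (cumulative_target == 0) return(0)
  if (all(s == 0)) stop("shape is zero over the age window; target unreachable")
  cum <- function(m) 1 - prod(1 - m * s)
  # largest admissible multiplier keeps every annual probability (including
  # at the curve's peak, possibly outside the window) at or below 1
  m_hi <- 1 / max(shape)
  if (cum(m_hi) < cumulative_target - tol)
    stop("cumulative target unreachable: would require m * shape > 1")
  r <- stats::uniroot(function(m) cum(m) - cumulative_target,
                      lower = 0, upper = m_hi, tol = tol / 10)
  r$root
}

# ---- Table-style parameter fixture -----------------------------------------

#' Read a parameter table of search bounds and calibrated values
#'
#' Reads the structured text fixture shipped with the package (one row per
#' scalar parameter: `block, ed, ed2, sex, lower, upper, mean, ui_lo, ui_hi,
#' unit`), converting percent-scale rows to probabilities. `ed2` is only
#' used for crossover rows (destination ED). Incidence-multiplier rows have
#' no published calibrated value and carry `NA` means.
#'
#' @param path path to the CSV; default is the shipped fixture mirroring the
#'   published search bounds and calibrated means.
#' @return a data.frame of class `ed_param_table` on the probability scale,
#'   with a `param` id column.
#' @export
read_param_table <- function(path = system.file("extdata",
                                                "table1_parameters.csv",
                                                package = "edmicrosim")) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "ed", "ed2", "sex", "lower", "upper",
            "mean", "ui_lo", "ui_hi", "unit")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed parameter table ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  pc <- tab$unit == "percent"
  for (col in c("lower", "upper", "mean", "ui_lo", "ui_hi"))
    tab[[col]][pc] <- tab[[col]][pc] / 100
  tab$param <- param_id(tab$block, tab$ed, tab$ed2, tab$sex)
  class(tab) <- c("ed_param_table", "data.frame")
  tab
}

param_id <- function(block, ed, ed2, sex) {
  ed2 <- ifelse(is.na(ed2) | ed2 == "", "", paste0(".", ed2))
  paste0(block, ".", ed, ed2, ".", sex)
}

#' Extract search bounds or calibrated means from a parameter table
#'
#' @param tab an `ed_param_table` from [read_param_table()].
#' @param blocks optional character vector restricting to parameter blocks
#'   (e.g. `"incidence_multiplier"`).
#' @return `param_bounds()`: a data.frame of class `ed_search_bounds` with
#'   one row per scalar parameter; `param_means()`: a named vector of
#'   calibrated means (`NA` dropped).
#' @export
param_bounds <- function(tab, blocks = NULL) {
  if (!is.null(blocks)) tab <- tab[tab$block %in% blocks, , drop = FALSE]
  b <- tab[, c("param", "block", "ed", "ed2", "sex", "lower", "upper")]
  if (any(b$lower > b$upper)) stop("invalid bounds: lower > upper")
  rownames(b) <- NULL
  class(b) <- c("ed_search_bounds", "data.frame")
  b
}

#' @rdname param_bounds
#' @export
param_means <- function(tab, blocks = NULL) {
  if (!is.null(blocks)) tab <- tab[tab$block %in% blocks, , drop = FALSE]
  m <- tab$mean
  names(m) <- tab$param
  m[!is.na(m)]
}

#' Collapse search bounds to fixed values
#'
#' Returns bounds in which the listed parameters are pinned
#' (`lower = upper = value`), so that sampling and annealing leave them
#' untouched. Used to calibrate a subset of parameters (e.g. only the
#' incidence multipliers) with the rest held at published means.
#'
#' @param bounds an `ed_search_bounds` data.frame.
#' @param values named vector of fixed values (names are `param` ids).
#' @return modified bounds.
#' @export
fix_bounds <- function(bounds, values) {
  i <- match(names(values), bounds$param)
  if (anyNA(i)) stop("unknown parameter ids: ",
                     paste(names(values)[is.na(i)], collapse = ", "))
  bounds$lower[i] <- bounds$upper[i] <- unname(values)
  bounds
}

# ---- theta <-> parameter set -----------------------------------------------

#' Map a parameter vector to a full parameter set
#'
#' `theta` is the flat vector of scalars the calibration searches over, with
#' names matching the `param` ids of the bounds table. Incidence multipliers
#' are combined with the frame's fixed shapes via [build_incidence_curve()].
#'
#' @param theta named numeric vector covering every parameter block.
#' @param frame an [ed_model_frame()].
#' @return an [ed_parameter_set()].
#' @export
params_from_theta <- function(theta, frame) {
  get2 <- function(block) {
    m <- matrix(NA_real_, 4, 2, dimnames = list(ED_TYPES, SEXES))
    for (i in 1:4) for (s in 1:2) {
      id <- param_id(block, ED_TYPES[i], NA, SEXES[s])
      if (!id %in% names(theta)) stop("theta is missing ", id)
      m[i, s] <- theta[[id]]
    }
    m
  }
  cross <- array(0, dim = c(4, 4, 2),
                 dimnames = list(ED_TYPES, ED_TYPES, SEXES))
  for (i in 1:4) for (j in 1:4) for (s in 1:2) {
    if (i == j) next
    id <- param_id("crossover", ED_TYPES[i], ED_TYPES[j], SEXES[s])
    if (!id %in% names(theta)) stop("theta is missing ", id)
    cross[i, j, s] <- theta[[id]]
  }
  mult <- get2("incidence_multiplier")
  inc <- array(0, dim = c(4, 2, 40))
  for (i in 1:4) for (s in 1:2)
    inc[i, s, ] <- build_incidence_curve(frame$shapes[i, s, ], mult[i, s])
  ed_parameter_set(incidence = inc,
                   relapse_first = get2("relapse_first"),
                   relapse_decay = get2("relapse_decay"),
                   remission = get2("remission"),
                   treat_coverage = get2("treat_coverage"),
                   treat_rr = get2("treat_rr"),
                   crossover = cross, smr = get2("smr"),
                   life_table = frame$life_table)
}

# Precompiled theta -> parameter-set assembler for hot loops: resolves the
# name -> position mapping once so repeated assembly is pure indexing.
make_params_builder <- function(param_names, frame) {
  pos2 <- function(block) {
    ids <- param_id(block, rep(ED_TYPES, 2), NA, rep(SEXES, each = 4))
    i <- match(ids, param_names)
    if (anyNA(i)) stop("theta is missing ", paste(ids[is.na(i)], collapse = ", "))
    i
  }
  i_rf <- pos2("relapse_first"); i_rd <- pos2("relapse_decay")
  i_rm <- pos2("remission"); i_tc <- pos2("treat_coverage")
  i_tr <- pos2("treat_rr"); i_sm <- pos2("smr")
  i_mu <- pos2("incidence_multiplier")
  cr <- expand.grid(from = 1:4, to = 1:4, sex = 1:2)
  cr <- cr[cr$from != cr$to, ]
  ids <- param_id("crossover", ED_TYPES[cr$from], ED_TYPES[cr$to],
                  SEXES[cr$sex])
  i_cr <- match(ids, param_names)
  if (anyNA(i_cr)) stop("theta is missing ", paste(ids[is.na(i_cr)], collapse = ", "))
  cross_idx <- cbind(cr$from, cr$to, cr$sex)
  shapes <- frame$shapes
  q <- frame$life_table
  function(theta) {
    cross <- array(0, dim = c(4, 4, 2))
    cross[cross_idx] <- theta[i_cr]
    inc <- pmin(shapes * c(theta[i_mu]), 1)  # mult recycles over age slices
    structure(list(
      incidence = inc,
      relapse_first = matrix(theta[i_rf], 4, 2),
      relapse_decay = matrix(theta[i_rd], 4, 2),
      remission = matrix(theta[i_rm], 4, 2),
      treat_coverage = matrix(theta[i_tc], 4, 2),
      treat_rr = matrix(theta[i_tr], 4, 2),
      crossover = cross,
      smr = matrix(theta[i_sm], 4, 2),
      life_table = q), class = "ed_parameter_set")
  }
}

#' Draw a parameter vector or parameter set from uniform search bounds
#'
#' Each scalar is drawn independently from `Uniform(lower, upper)` using the
#' current R random-number stream (set a seed for reproducibility).
#'
#' @param bounds an `ed_search_bounds` data.frame.
#' @param frame an [ed_model_frame()]; if supplied,
#'   `sample_parameter_set()` returns the assembled [ed_parameter_set()],
#'   otherwise use `sample_theta()` for the raw vector.
#' @return a named theta vector, or a parameter set.
#' @export
sample_theta <- function(bounds) {
  th <- stats::runif(nrow(bounds), bounds$lower, bounds$upper)
  names(th) <- bounds$param
  th
}

#' @rdname sample_theta
#' @export
sample_parameter_set <- function(bounds, frame) {
  params_from_theta(sample_theta(bounds), frame)
}

# ---- validation and bound repair -------------------------------------------

#' Check a parameter set for valid per-cycle transition probabilities
#'
#' For every occupied ED state, sex and age, the annual probabilities of
#' death, (treated) remission and all crossovers must admit a valid
#' multinomial (sum at most 1), with remission taken at its treated maximum.
#' For healthy person-years, total naive incidence plus background mortality
#' must not exceed 1 at any age.
#'
#' @param ps an [ed_parameter_set()].
#' @return a data.frame of violations (zero rows if valid) with columns
#'   `kind` (`"ed_row"` or `"incidence"`), `ed` (`NA` for incidence rows),
#'   `sex`, and `excess` (amount by which the worst age exceeds 1).
#' @export
validate_parameter_set <- function(ps) {
  # worst age is the one with the largest q (death prob is monotone in q)
  qmax <- c(max(ps$life_table[1, ]), max(ps$life_table[2, ]))
  p_die_max <- 1 - (1 - rep(qmax, each = 4))^ps$smr          # [4, 2]
  p_rem_max <- 1 - (1 - ps$remission)^ps$treat_rr
  cross_sum <- ps$crossover[, 1, ] + ps$crossover[, 2, ] +
    ps$crossover[, 3, ] + ps$crossover[, 4, ]
  tot_ed <- p_die_max + p_rem_max + cross_sum
  inc_tot <- vapply(1:2, function(s)
    max(.colSums(ps$incidence[, s, ], 4L, N_AGES) + ps$life_table[s, ]),
    numeric(1))
  out <- list()
  bad <- which(tot_ed > 1, arr.ind = TRUE)
  if (nrow(bad))
    out[[1L]] <- data.frame(kind = "ed_row", ed = ED_TYPES[bad[, 1]],
                            sex = SEXES[bad[, 2]],
                            excess = tot_ed[bad] - 1)
  bad_inc <- which(inc_tot > 1)
  if (length(bad_inc))
    out[[length(out) + 1L]] <- data.frame(
      kind = "incidence", ed = NA_character_, sex = SEXES[bad_inc],
      excess = inc_tot[bad_inc] - 1)
  if (!length(out))
    return(data.frame(kind = character(), ed = character(),
                      sex = character(), excess = numeric()))
  do.call(rbind, out)
}

# parameters entering the probability sum for one violation row
violation_params <- function(bounds, violation) {
  if (violation$kind == "ed_row") {
    hit <- (bounds$block %in% c("remission", "treat_rr", "smr") &
              bounds$ed == violation$ed & bounds$sex == violation$sex) |
      (bounds$block == "crossover" & bounds$ed == violation$ed &
         bounds$sex == violation$sex)
  } else {
    hit <- bounds$block == "incidence_multiplier" & bounds$sex == violation$sex
  }
  which(hit)
}

#' Lower the search bounds implicated in a validity violation
#'
#' When a sampled parameter set has transition probabilities summing above 1,
#' the lower bounds of the parameters entering the offending sum are
#' multiplicatively reduced (by `factor` per call) so that a fresh uniform
#' draw can be valid. Upper bounds are never touched.
#'
#' @param bounds an `ed_search_bounds` data.frame.
#' @param violation one row of the data.frame from
#'   [validate_parameter_set()].
#' @param factor multiplicative shrink applied to the implicated lower
#'   bounds.
#' @return the repaired bounds.
#' @export
repair_bounds <- function(bounds, violation, factor = 0.9) {
  idx <- violation_params(bounds, violation)
  if (!length(idx)) stop("violation matches no bound rows")
  bounds$lower[idx] <- bounds$lower[idx] * factor
  bounds$upper[idx] <- pmax(bounds$upper[idx], bounds$lower[idx])
  bounds
}

#' Sample until a valid parameter set is drawn, repairing bounds as needed
#'
#' Repeatedly draws from the bounds; on an invalid draw the implicated lower
#' bounds are lowered via [repair_bounds()] and sampling retried.
#'
#' @inheritParams sample_theta
#' @param frame an [ed_model_frame()].
#' @param max_iter maximum sample-repair iterations before giving up.
#' @return list with elements `ps` (valid parameter set), `theta`, and
#'   `bounds` (possibly repaired).
#' @export
sample_valid_parameter_set <- function(bounds, frame, max_iter = 100L) {
  for (k in seq_len(max_iter)) {
    theta <- sample_theta(bounds)
    ps <- params_from_theta(theta, frame)
    v <- validate_parameter_set(ps)
    if (nrow(v) == 0L)
      return(list(ps = ps, theta = theta, bounds = bounds))
    for (r in seq_len(nrow(v)))
      bounds <- repair_bounds(bounds, v[r, ])
  }
  stop("no valid parameter set after ", max_iter,
       " sample-repair iterations (degenerate bounds?)")
}
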