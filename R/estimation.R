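# Subject-specific parameter estimation: normalized least-squares cost over
# sparse timed measurements, bounded multi-start global search (seeded Latin
# hypercube starts + Levenberg-Marquardt local refinement), sensitivity-based
# reduction of the free parameter set, and the agreement metrics used to
# summarize goodness of fit.

measurement_vars <- c("uo", "hct", "co", "map", "cvp", "na")

# Map measurement variable -> trajectory column and units.
meas_column <- c(uo = "j_uo", hct = "hct", co = "co", map = "map",
                 cvp = "cvp", na = "na_plasma")

# Shared observation operator: urine output is observed as the trailing-hour
# collected volume (mean rate from the cumulative-urine state), everything
# else as the instantaneous value, linearly interpolated from the dense
# trajectory. Used identically by observe(), the estimation cost and the
# fit metrics so that model predictions and synthetic observations are
# commensurate.
predict_obs <- function(tr, variable, times) {
  if (variable == "uo") {
    c1 <- stats::approx(tr$time_h, tr$cum_UO, xout = times, rule = 2)$y
    c0 <- stats::approx(tr$time_h, tr$cum_UO, xout = pmax(times - 1, 0),
                        rule = 2)$y
    (c1 - c0) / pmin(times, 1)
  } else {
    stats::approx(tr$time_h, tr[[meas_column[[variable]]]], xout = times,
                  rule = 2)$y
  }
}

#' Measurement set
#'
#' Sparse timed observations of the fitted observables. `variable` must be
#' one of `uo` (mL/h), `hct` (fraction), `co` (L/min), `map` (mmHg), `cvp`
#' (mmHg), `na` (mEq/L).
#'
#' @param data data frame with columns `time_h`, `variable`, `value`.
#' @param normalization optional named vector of per-variable normalization
#'   factors `Y_j`; defaults to the subject's baseline value of each
#'   variable (see [default_normalization()]).
#' @param subject_id optional identifier.
#' @return tibble of class `burn_measurements`.
#' @export
measurement_set <- function(data, normalization = NULL, subject_id = NA) {
  stopifnot(all(c("time_h", "variable", "value") %in% names(data)))
  bad <- setdiff(unique(data$variable), measurement_vars)
  if (length(bad)) stop("unknown measurement variable(s): ",
                        paste(bad, collapse = ", "))
  out <- tibble::as_tibble(data[c("time_h", "variable", "value")])
  attr(out, "normalization") <- normalization
  attr(out, "subject_id") <- subject_id
  class(out) <- c("burn_measurements", class(out))
  out
}

#' Default Eq.-style normalization factors
#'
#' The per-variable normalization factor is the subject's baseline value of
#' that variable at the pre-injury operating point; for urine output the
#' species target-band midpoint (in absolute mL/h) is used instead, since
#' post-burn urine output is managed toward the band rather than baseline.
#'
#' @param profile a [burn_profile()]; `params` completed registry.
#' @return named numeric vector over the six measurement variables.
#' @export
default_normalization <- function(profile, params = NULL) {
  op <- baseline_operating_point(profile, params)
  band <- switch(profile$species,
                 pig = c(1, 1.5) * profile$weight,
                 sheep = c(1, 2) * profile$weight,
                 human = c(30, 50))
  c(uo = mean(band), hct = op$hct, co = op$co, map = op$map,
    cvp = op$cvp, na = op$na_plasma)
}

#' Normalized least-squares cost
#'
#' `J(theta) = sum_j sum_k ((y_jk^meas - y_j(t_k; theta)) / Y_j)^2` over all
#' measured variables and time points, with model predictions linearly
#' interpolated from the dense trajectory to the measurement times. A failed
#' simulation yields `Inf` with the failure attached as an attribute.
#'
#' @param theta named vector of candidate values for the free parameters.
#' @param profile,params subject and completed base registry.
#' @param schedule infusion schedule driving the simulation.
#' @param measurements a [measurement_set()].
#' @param horizon simulation horizon (h), defaulting to the last measurement.
#' @param engine integrator engine passed to [simulate_burn()].
#' @return scalar cost (sum of squared normalized residuals).
#' @export
cost_function <- function(theta, profile, params, schedule, measurements,
                          horizon = NULL, engine = "compiled") {
  r <- fit_residuals(theta, profile, params, schedule, measurements,
                     horizon, engine)
  if (anyNA(r)) return(structure(Inf, failure = attr(r, "failure")))
  sum(r^2)
}

# Residual vector (one entry per measurement) shared by cost and optimizer.
fit_residuals <- function(theta, profile, params, schedule, measurements,
                          horizon = NULL, engine = "compiled") {
  params2 <- apply_theta(params, theta)
  params2 <- tryCatch(derive_constrained_parameters(profile, params2),
                      error = function(e) e)
  if (inherits(params2, "error")) {
    return(structure(rep(NA_real_, nrow(measurements)),
                     failure = conditionMessage(params2)))
  }
  horizon <- horizon %||% max(measurements$time_h)
  sim <- tryCatch(
    simulate_burn(profile, params2, schedule = schedule, horizon = horizon,
                  dt_out = 0.25, engine = engine),
    error = function(e) e)
  if (inherits(sim, "error")) {
    return(structure(rep(NA_real_, nrow(measurements)),
                     failure = conditionMessage(sim)))
  }
  yfac <- attr(measurements, "normalization") %||%
    default_normalization(profile, params2)
  tr <- sim$trajectory
  res <- numeric(nrow(measurements))
  for (v in unique(measurements$variable)) {
    idx <- measurements$variable == v
    pred <- predict_obs(tr, v, measurements$time_h[idx])
    res[idx] <- (measurements$value[idx] - pred) / yfac[[v]]
  }
  res
}

# Overwrite the free parameters with candidate values (bounds are enforced
# by the optimizer; out-of-bound candidates are an error upstream).
apply_theta <- function(params, theta) {
  set_pv(params, names(theta), unname(theta))
}

#' Fit configuration
#'
#' @param free_params names of the subject-specific registry parameters to
#'   estimate; must all carry class `subject_specific`.
#' @param starts number of Latin-hypercube multi-starts (>= 1).
#' @param seed integer seed fixing the start points.
#' @param maxiter Levenberg-Marquardt iteration cap for the final polish of
#'   the best start.
#' @param explore_maxiter iteration cap during the exploration phase (each
#'   start gets a short refinement; only the winner is polished fully).
#' @param ftol relative cost-reduction tolerance.
#' @return list of class `burn_fit_config`.
#' @export
fit_config <- function(free_params, starts = 20, seed = 1, maxiter = 30,
                       explore_maxiter = 6, ftol = 1e-8) {
  stopifnot(starts >= 1)
  structure(list(free_params = free_params, starts = starts, seed = seed,
                 maxiter = maxiter, explore_maxiter = explore_maxiter,
                 ftol = ftol), class = "burn_fit_config")
}

#' Subject-specific parameter estimation
#'
#' Bounded multi-start global search: `starts` Latin-hypercube points over
#' the registered bounds of the free parameters (seeded, deterministic), each
#' refined by bounded Levenberg-Marquardt on the normalized residual vector;
#' the lowest-cost solution wins (ties broken by first found).
#'
#' @param config a [fit_config()].
#' @param profile,params subject and completed base registry (preset default).
#' @param schedule infusion schedule used during the measurements.
#' @param measurements a [measurement_set()].
#' @param horizon simulation horizon (h).
#' @return object of class `burn_fit` with elements `theta` (named estimate),
#'   `cost`, `starts` (per-start tibble), `config`, plus the fit inputs.
#' @export
fit_subject <- function(config, profile, params = NULL, schedule,
                        measurements, horizon = NULL) {
  if (is.null(params)) {
    params <- derive_constrained_parameters(profile, param_registry(profile$species))
  }
  free <- config$free_params
  cls <- params$class[match(free, params$name)]
  if (anyNA(cls)) stop("unknown free parameter(s)")
  if (any(cls != "subject_specific")) {
    stop("free parameters must be subject_specific: ",
         paste(free[cls != "subject_specific"], collapse = ", "))
  }
  lower <- params$lower[match(free, params$name)]
  upper <- params$upper[match(free, params$name)]
  # keep LM away from exact bound edges where derived constraints may fail
  eps <- 1e-6 * (upper - lower)
  yfac <- attr(measurements, "normalization") %||%
    default_normalization(profile, params)
  attr(measurements, "normalization") <- yfac

  set.seed(config$seed)
  # first start at the population (preset) values, the rest Latin hypercube
  starts <- rbind(par_values(params)[free],
                  if (config$starts > 1) {
                    u <- lhs::randomLHS(config$starts - 1, length(free))
                    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
                  })
  colnames(starts) <- free

  fn <- function(th) fit_residuals(stats::setNames(th, free), profile, params,
                                   schedule, measurements, horizon)
  fn_safe <- function(th) {
    r <- fn(th)
    if (anyNA(r)) rep(1e6, length(r)) else r
  }
  run_lm <- function(par0, iters) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower + eps, upper = upper - eps,
                         fn = fn_safe,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iters, ftol = config$ftol)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      list(theta = par0, cost = Inf, message = conditionMessage(fit))
    } else {
      list(theta = stats::setNames(coef(fit), free),
           cost = sum(residuals(fit)^2), message = fit$message)
    }
  }
  runs <- lapply(seq_len(config$starts), function(s)
    run_lm(starts[s, ], config$explore_maxiter))
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  if (all(!is.finite(costs))) {
    stop("all multi-starts failed: ",
         paste(unique(vapply(runs, `[[`, character(1), "message")),
               collapse = "; "))
  }
  best <- which.min(costs)  # first minimum wins ties
  polish <- run_lm(runs[[best]]$theta, config$maxiter)
  theta_hat <- if (is.finite(polish$cost) &&
                   polish$cost <= runs[[best]]$cost) {
    polish$theta
  } else {
    runs[[best]]$theta
  }
  out <- list(
    theta = theta_hat,
    cost = cost_function(theta_hat, profile, params, schedule, measurements,
                         horizon),
    starts = tibble::tibble(
      start = seq_len(config$starts), cost = costs,
      message = vapply(runs, `[[`, character(1), "message")),
    config = config, profile = profile, params = params,
    schedule = schedule, measurements = measurements, horizon = horizon
  )
  class(out) <- "burn_fit"
  out
}

#' @export
print.burn_fit <- function(x, ...) {
  cat(sprintf("<burn_fit> %d free parameters, %d starts, best cost %.4g\n",
              length(x$theta), nrow(x$starts), x$cost))
  print(round(x$theta, 4))
  invisible(x)
}

#' Sensitivity ranking and free-set reduction
#'
#' Ranks candidate subject-specific parameters by the normalized local
#' sensitivity of the pooled cost around a population-average parameter
#' vector (central finite differences of the cost summed over subjects,
#' scaled by the parameter's bound width), and returns the `m` most
#' sensitive as the reduced free set, fixing the rest at population values.
#' With a single measured variable (the clinical situation) this prevents
#' overfitting.
#'
#' @param subjects list of lists, each with `profile`, `schedule`,
#'   `measurements` (>= 2 subjects).
#' @param candidate_params character vector of subject-specific parameter
#'   names to rank.
#' @param params population-average registry (preset default, optionally
#'   pre-fitted).
#' @param m size of the reduced free set.
#' @param rel_step finite-difference step as a fraction of bound width.
#' @return tibble ranked by decreasing sensitivity, with `selected` flags.
#' @export
sensitivity_rank <- function(subjects, candidate_params, params = NULL,
                             m = 10, rel_step = 0.05) {
  if (length(subjects) < 2) stop("need at least 2 subjects")
  if (is.null(params)) {
    params <- derive_constrained_parameters(subjects[[1]]$profile,
                                            param_registry(subjects[[1]]$profile$species))
  }
  lower <- params$lower[match(candidate_params, params$name)]
  upper <- params$upper[match(candidate_params, params$name)]
  base <- par_values(params)[candidate_params]

  pooled_cost <- function(theta) {
    sum(vapply(subjects, function(s) {
      cost_function(theta, s$profile, params, s$schedule, s$measurements)
    }, numeric(1)))
  }
  sens <- vapply(seq_along(candidate_params), function(i) {
    h <- rel_step * (upper[i] - lower[i])
    up <- base; up[i] <- min(base[i] + h, upper[i])
    dn <- base; dn[i] <- max(base[i] - h, lower[i])
    abs(pooled_cost(up) - pooled_cost(dn)) / (up[i] - dn[i]) *
      (upper[i] - lower[i])
  }, numeric(1))
  ord <- order(sens, decreasing = TRUE)
  tibble::tibble(
    name = candidate_params[ord],
    sensitivity = sens[ord],
    rank = seq_along(ord),
    selected = seq_along(ord) <= m
  )
}

## ---- agreement metrics ----------------------------------------------------

#' Normalized mean absolute error
#'
#' `100 * mean(|pred - meas|) / Y` with `Y` the same normalization factor
#' used in the estimation cost.
#'
#' @param pred,meas paired numeric vectors; `y` normalization factor.
#' @return percent NMAE.
#' @export
nmae <- function(pred, meas, y) {
  stopifnot(length(pred) == length(meas), y > 0)
  100 * mean(abs(pred - meas)) / y
}

#' Pearson correlation on pooled prediction/measurement pairs
#' @param pred,meas paired numeric vectors (n >= 2).
#' @return correlation coefficient.
#' @export
pearson_r <- function(pred, meas) {
  if (length(pred) < 2) stop("need at least 2 pairs")
  stats::cor(pred, meas)
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean prediction-minus-measurement difference; the limits are
#' `bias +/- 2 * SD` with the sample (n-1) standard deviation.
#'
#' @param pred,meas paired numeric vectors (n >= 2).
#' @return named vector `bias, loa_low, loa_high, sd`.
#' @export
bland_altman <- function(pred, meas) {
  if (length(pred) < 2) stop("need at least 2 pairs")
  d <- pred - meas
  s <- stats::sd(d)
  c(bias = mean(d), loa_low = mean(d) - 2 * s, loa_high = mean(d) + 2 * s,
    sd = s)
}

#' Urine-output operational-range agreement
#'
#' Percent of paired points falling in the same clinical urine-output bin:
#' pigs `<1, 1-1.5, >1.5` mL/kg/h; sheep `<0.5, 0.5-1.0, >1.0` mL/kg/h
#' (rates must already be per kg).
#'
#' @param pred,meas paired urine-output rates (mL/kg/h).
#' @param species `"pig"` or `"sheep"`.
#' @return percent agreement.
#' @export
uo_range_agreement <- function(pred, meas, species = c("pig", "sheep")) {
  species <- match.arg(species)
  cuts <- switch(species, pig = c(1, 1.5), sheep = c(0.5, 1.0))
  bin <- function(x) findInterval(x, cuts)
  100 * mean(bin(pred) == bin(meas))
}

#' Per-variable fit metrics for a completed fit
#'
#' @param fit a `burn_fit`.
#' @return tibble with one row per measured variable: NMAE, Pearson r,
#'   Bland-Altman bias and limits.
#' @export
fit_metrics <- function(fit) {
  params2 <- derive_constrained_parameters(
    fit$profile, apply_theta(fit$params, fit$theta))
  horizon <- fit$horizon %||% max(fit$measurements$time_h)
  sim <- simulate_burn(fit$profile, params2, schedule = fit$schedule,
                       horizon = horizon, dt_out = 0.25)
  tr <- sim$trajectory
  yfac <- attr(fit$measurements, "normalization")
  purrr::map_dfr(unique(fit$measurements$variable), function(v) {
    idx <- fit$measurements$variable == v
    meas <- fit$measurements$value[idx]
    pred <- predict_obs(tr, v, fit$measurements$time_h[idx])
    ba <- if (sum(idx) >= 2) bland_altman(pred, meas) else
      c(bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_, sd = NA_real_)
    r <- if (sum(idx) >= 2 && stats::sd(meas) > 0 && stats::sd(pred) > 0)
      pearson_r(pred, meas) else NA_real_
    tibble::tibble(variable = v, n = sum(idx),
                   nmae = nmae(pred, meas, yfac[[v]]), r = r,
                   bias = ba[["bias"]], loa_low = ba[["loa_low"]],
                   loa_high = ba[["loa_high"]])
  })
}
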