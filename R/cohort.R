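# Synthetic virtual-patient cohorts: species-typical subject sampling,
# the species measurement schedules, and a noisy observation operator --
# everything needed to exercise simulation and estimation with no external
# data.

#' Cohort specification
#'
#' Species distributions mirror the study cohorts: pigs 31.7 +/- 4.2 kg at a
#' fixed 40% TBSA; sheep 40 kg at 40% TBSA; humans 85 +/- 18 kg with TBSA
#' 42 +/- 18%. Subject-specific parameters are drawn uniformly within their
#' registered bounds (optionally shrunk toward the preset by
#' `param_spread`), and observations carry per-variable multiplicative
#' Gaussian noise.
#'
#' @param species cohort species.
#' @param n number of subjects.
#' @param paradigms protocol names cycled across subjects.
#' @param noise_cv named per-variable coefficients of variation.
#' @param param_spread fraction of each bound interval (centered on the
#'   preset value) within which subject-specific parameters are sampled.
#' @param sample_params names of subject-specific parameters to randomize;
#'   default all of them.
#' @param seed integer seed fixing the whole cohort.
#' @return list of class `burn_cohort_spec`.
#' @export
cohort_spec <- function(species = c("pig", "sheep", "human"), n = 10,
                        paradigms = NULL,
                        noise_cv = c(uo = 0.10, hct = 0.02, co = 0.05,
                                     map = 0.05, cvp = 0.10, na = 0.01),
                        param_spread = 0.3, sample_params = NULL, seed = 1) {
  species <- match.arg(species)
  if (is.null(paradigms)) {
    paradigms <- switch(species, pig = c("P1", "P2", "P3"),
                        sheep = "sheep", human = "human")
  }
  structure(list(species = species, n = n, paradigms = paradigms,
                 noise_cv = noise_cv, param_spread = param_spread,
                 sample_params = sample_params, seed = seed),
            class = "burn_cohort_spec")
}

#' Sample one virtual subject
#'
#' Deterministic given `(spec$seed, index)`. Returns both the profile and
#' the ground-truth parameter registry (subject-specific entries perturbed
#' within bounds, constraint-derived entries re-solved).
#'
#' @param spec a [cohort_spec()].
#' @param index subject index (1-based).
#' @return list `profile`, `params` (ground truth), `paradigm`.
#' @export
sample_subject <- function(spec, index) {
  set.seed(combine_seed(spec$seed, index))
  prof <- switch(spec$species,
    pig = burn_profile("pig", weight = truncnorm1(31.7, 4.2, 20, 50),
                       tbsa = 0.40),
    sheep = burn_profile("sheep", weight = 40, tbsa = 0.40),
    human = burn_profile("human",
                         weight = truncnorm1(85, 18, 40, 160),
                         tbsa = min(max(stats::rnorm(1, 0.42, 0.18), 0.10), 0.90))
  )
  params <- param_registry(spec$species)
  ss <- spec$sample_params %||% params$name[params$class == "subject_specific"]
  i <- match(ss, params$name)
  ctr <- params$value[i]
  half <- 0.5 * spec$param_spread * (params$upper[i] - params$lower[i])
  lo <- pmax(params$lower[i], ctr - half)
  hi <- pmin(params$upper[i], ctr + half)
  params$value[i] <- lo + stats::runif(length(i)) * (hi - lo)
  params <- derive_constrained_parameters(prof, params)
  paradigm <- spec$paradigms[((index - 1) %% length(spec$paradigms)) + 1]
  list(profile = prof, params = params, paradigm = paradigm)
}

# Combine a user seed and subject index into a valid 32-bit seed.
combine_seed <- function(seed, index, salt = 0) {
  as.integer((as.numeric(seed) * 10007 + index * 101 + salt) %% 2147483629)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

#' Species measurement schedules
#'
#' Pig: hourly urine output over 24 h, the other variables at hours
#' 0, 1, 2, 3, 5, 9, 12, 18, 24 (hematocrit generated but flagged excluded:
#' the study pigs were not splenectomized). Sheep: 48 h, hourly urine
#' output, sparse HCT/CVP/MAP/CO. Human: hourly urine output only.
#'
#' @param species species name.
#' @return tibble `variable`, `time_h`, `excluded`.
#' @export
measurement_schedule <- function(species = c("pig", "sheep", "human")) {
  species <- match.arg(species)
  pig_sparse <- c(0, 1, 2, 3, 5, 9, 12, 18, 24)
  sheep_sparse <- seq(0, 48, by = 6)
  grid <- switch(species,
    pig = dplyr::bind_rows(
      tibble::tibble(variable = "uo", time_h = 1:24, excluded = FALSE),
      purrr::map_dfr(c("hct", "co", "map", "cvp", "na"), function(v)
        tibble::tibble(variable = v, time_h = pig_sparse,
                       excluded = v == "hct"))),
    sheep = dplyr::bind_rows(
      tibble::tibble(variable = "uo", time_h = 1:48, excluded = FALSE),
      purrr::map_dfr(c("hct", "co", "map", "cvp"), function(v)
        tibble::tibble(variable = v, time_h = sheep_sparse, excluded = FALSE))),
    human = tibble::tibble(variable = "uo", time_h = 1:24, excluded = FALSE)
  )
  grid
}

#' Observe a simulation through a measurement schedule
#'
#' Samples the trajectory at the scheduled times (urine output as the
#' trailing-hour mean rate from the cumulative urine state; other variables
#' as instantaneous values), then applies multiplicative Gaussian noise with
#' the per-variable CV and floors at zero. Deterministic given `seed`.
#'
#' @param sim a `burn_sim`.
#' @param schedule tibble from [measurement_schedule()].
#' @param noise_cv named per-variable CV; 0 gives exact samples.
#' @param seed integer seed.
#' @param include_excluded keep variables flagged `excluded` in the output.
#' @return a [measurement_set()].
#' @export
observe <- function(sim, schedule, noise_cv = NULL, seed = 1,
                    include_excluded = FALSE) {
  tr <- sim$trajectory
  if (max(schedule$time_h) > max(tr$time_h) + 1e-9) {
    stop("measurement schedule extends beyond the simulated horizon")
  }
  if (!include_excluded) schedule <- schedule[!schedule$excluded, ]
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    v <- schedule$variable[i]; tk <- schedule$time_h[i]
    tibble::tibble(time_h = tk, variable = v,
                   value = predict_obs(tr, v, tk))
  })
  cv <- noise_cv %||% stats::setNames(rep(0, length(measurement_vars)),
                                      measurement_vars)
  mult <- stats::rnorm(nrow(out), 1, unname(cv[out$variable]))
  out$value <- pmax(out$value * mult, 0)
  measurement_set(out)
}

#' Generate a full synthetic cohort
#'
#' For each subject: sample profile and ground-truth parameters, simulate
#' under the assigned resuscitation paradigm, and observe through the
#' species schedule with noise.
#'
#' @param spec a [cohort_spec()].
#' @param horizon simulation horizon; default from species (24 h, sheep 48 h).
#' @return list of per-subject lists `profile, params, paradigm, sim,
#'   measurements, schedule_realized`.
#' @export
generate_cohort <- function(spec, horizon = NULL) {
  horizon <- horizon %||% if (spec$species == "sheep") 48 else 24
  lapply(seq_len(spec$n), function(i) {
    subj <- sample_subject(spec, i)
    sim <- simulate_burn(subj$profile, subj$params,
                         protocol = protocol_preset(subj$paradigm),
                         horizon = horizon)
    sched <- measurement_schedule(spec$species)
    sched <- sched[sched$time_h <= horizon, ]
    meas <- observe(sim, sched, noise_cv = spec$noise_cv,
                    seed = combine_seed(spec$seed, i, salt = 5000))
    c(subj, list(sim = sim, measurements = meas,
                 schedule_realized = sim$schedule))
  })
}
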