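# Small shared fit fixture: one synthetic pig subject under P2.
fit_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      free <- c("amp_kf_bt", "k_msp")
      spec <- cohort_spec("pig", n = 1, paradigms = "P2",
                         sample_params = free, seed = 5)
      subj <- sample_subject(spec, 1)
      sim <- simulate_burn(subj$profile, subj$params,
                           protocol = protocol_preset("P2"), horizon = 24)
      meas <- observe(sim, measurement_schedule("pig"), seed = 1)
      val <<- list(free = free, subj = subj, sim = sim, meas = meas,
                   truth = burnsim:::par_values(subj$params)[free])
    }
    val
  }
})

test_that("the cost is zero at the generating parameters and matches the
          hand-computed single-point value", {
  fx <- fit_fixture()
  c0 <- cost_function(fx$truth, fx$subj$profile, fx$subj$params,
                      fx$sim$schedule, fx$meas)
  expect_lt(c0, 1e-10)
  # single variable, one point: y_meas 10, y_pred 8, Y 10 -> 0.04
  m1 <- measurement_set(tibble::tibble(time_h = 5, variable = "cvp",
                                       value = 10),
                        normalization = c(cvp = 10))
  pred <- burnsim:::predict_obs(fx$sim$trajectory, "cvp", 5)
  manual <- ((10 - pred) / 10)^2
  expect_equal(cost_function(fx$truth, fx$subj$profile, fx$subj$params,
                             fx$sim$schedule, m1, horizon = 24),
               manual, tolerance = 1e-6)
})

test_that("the cost is invariant to measurement ordering", {
  fx <- fit_fixture()
  shuf <- fx$meas[sample.int(nrow(fx$meas)), ]
  attr(shuf, "normalization") <- attr(fx$meas, "normalization")
  th <- fx$truth * 1.1
  expect_equal(
    cost_function(th, fx$subj$profile, fx$subj$params, fx$sim$schedule, fx$meas),
    cost_function(th, fx$subj$profile, fx$subj$params, fx$sim$schedule, shuf),
    tolerance = 1e-12)
})

test_that("fit recovers a two-parameter subject and re-evaluates its own
          cost consistently", {
  fx <- fit_fixture()
  cfg <- fit_config(fx$free, starts = 3, seed = 2, maxiter = 20)
  fit <- suppressWarnings(
    fit_subject(cfg, fx$subj$profile, schedule = fx$sim$schedule,
                measurements = fx$meas))
  err <- abs(fit$theta - fx$truth) / abs(fx$truth)
  expect_lt(max(err), 0.05)
  re <- cost_function(fit$theta, fx$subj$profile, fit$params,
                      fx$sim$schedule, fx$meas)
  expect_equal(unname(re), fit$cost, tolerance = 1e-12)
  # bounds respected
  i <- match(fx$free, fit$params$name)
  expect_true(all(fit$theta >= fit$params$lower[i] &
                  fit$theta <= fit$params$upper[i]))
})

test_that("more multi-starts never worsen the best cost (nested starts)", {
  fx <- fit_fixture()
  f1 <- suppressWarnings(fit_subject(fit_config(fx$free, starts = 1, seed = 3,
                                                maxiter = 8),
                                     fx$subj$profile,
                                     schedule = fx$sim$schedule,
                                     measurements = fx$meas))
  f3 <- suppressWarnings(fit_subject(fit_config(fx$free, starts = 3, seed = 3,
                                                maxiter = 8),
                                     fx$subj$profile,
                                     schedule = fx$sim$schedule,
                                     measurements = fx$meas))
  expect_lte(f3$cost, f1$cost + 1e-12)
})

test_that("seeded fits are deterministic", {
  fx <- fit_fixture()
  cfg <- fit_config(fx$free, starts = 2, seed = 4, maxiter = 5)
  a <- suppressWarnings(fit_subject(cfg, fx$subj$profile,
                                    schedule = fx$sim$schedule,
                                    measurements = fx$meas))
  b <- suppressWarnings(fit_subject(cfg, fx$subj$profile,
                                    schedule = fx$sim$schedule,
                                    measurements = fx$meas))
  expect_identical(a$theta, b$theta)
  expect_identical(a$cost, b$cost)
})

test_that("non-subject-specific parameters are rejected from the free set", {
  expect_error(
    fit_subject(fit_config(c("p_k"), starts = 1), pig_profile(),
                schedule = infusion_schedule(0, 0),
                measurements = fit_fixture()$meas),
    "subject_specific")
})

test_that("sensitivity ranking is permutation-invariant and returns the
          requested reduced set size", {
  free <- c("amp_kf_bt", "k_msp")
  spec <- cohort_spec("human", n = 2, paradigms = "human",
                      sample_params = free, seed = 9)
  subjects <- lapply(1:2, function(i) {
    subj <- sample_subject(spec, i)
    sim <- simulate_burn(subj$profile, subj$params,
                         protocol = protocol_preset("human"), horizon = 24)
    list(profile = subj$profile, schedule = sim$schedule,
         measurements = observe(sim, measurement_schedule("human"), seed = i))
  })
  cand <- c("amp_kf_bt", "k_msp", "amp_constrict", "w_v")
  r1 <- sensitivity_rank(subjects, cand, m = 2)
  r2 <- sensitivity_rank(subjects, rev(cand), m = 2)
  expect_setequal(r1$name[r1$selected], r2$name[r2$selected])
  expect_equal(sum(r1$selected), 2)
  expect_true(all(diff(r1$sensitivity) <= 1e-12))
  expect_error(sensitivity_rank(subjects[1], cand), "2 subjects")
})

test_that("agreement metrics match their definitions", {
  pred <- c(1, 2, 3, 4); meas <- c(1, 2, 3, 4)
  expect_equal(nmae(pred, meas, 2), 0)
  expect_equal(pearson_r(pred, meas), 1)
  ba <- bland_altman(pred, meas)
  expect_equal(unname(ba[c("bias", "loa_low", "loa_high")]), c(0, 0, 0))
  expect_equal(uo_range_agreement(c(1.2), c(1.4), "pig"), 100)

  # diffs +1/-1: bias 0, limits at +/- 2 * sample SD = 2 * sqrt(2)
  ba2 <- bland_altman(c(11, 9), c(10, 10))
  expect_equal(unname(ba2[["bias"]]), 0)
  expect_equal(unname(ba2[["loa_high"]]), 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(nmae(c(11, 9), c(10, 10), 10), 10)
  expect_equal(uo_range_agreement(c(0.5, 1.2, 2), c(0.9, 1.3, 1.6), "pig"), 100)
  expect_equal(uo_range_agreement(c(0.5, 1.2), c(1.2, 1.2), "pig"), 50)
  expect_error(pearson_r(1, 1), "2 pairs")
})

test_that("fit metrics table summarizes every measured variable", {
  fx <- fit_fixture()
  cfg <- fit_config(fx$free, starts = 1, maxiter = 4)
  fit <- suppressWarnings(
    fit_subject(cfg, fx$subj$profile, schedule = fx$sim$schedule,
                measurements = fx$meas))
  m <- fit_metrics(fit)
  expect_setequal(m$variable, unique(fx$meas$variable))
  expect_true(all(is.finite(m$nmae)))
  td <- tidy.burn_fit(fit)
  expect_setequal(td$term, fx$free)
  g <- glance.burn_fit(fit)
  expect_equal(g$n_obs, nrow(fx$meas))
})
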