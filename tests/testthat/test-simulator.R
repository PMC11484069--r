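test_that("reference R right-hand side and compiled core agree to machine
          precision on perturbed states", {
  prof <- human_profile(); par <- human_params()
  rt <- burnsim:::runtime_constants(prof, par, perturb_on = TRUE)
  rt[["j_inf"]] <- 250
  y0 <- initialize_state(prof, par)
  set.seed(99)
  for (tt in c(0.25, 1.5, 6, 18)) {
    y <- y0 * exp(rnorm(length(y0), 0, 0.05))
    y[13:17] <- abs(y[13:17])
    names(y) <- names(y0)
    r <- model_rhs(tt, y, rt)
    cc <- deSolve::DLLfunc(y = y, times = tt, func = "burnmod_derivs",
                           parms = unname(rt), dllname = "burnsim",
                           initfunc = "burnmod_init",
                           nout = length(burnsim:::output_names),
                           outnames = burnsim:::output_names)
    expect_equal(unname(cc$dy), unname(unlist(r[[1]])), tolerance = 1e-8)
    expect_equal(unname(cc$var), unname(r[[2]]), tolerance = 1e-8)
  }
})

test_that("baseline state with maintenance gives a null derivative and a
          circulatory equilibrium residual below 1e-6", {
  rt <- human_rt(maintenance = TRUE, perturb_on = FALSE)
  y <- initialize_state(human_profile(), human_params())
  r <- model_rhs(0.5, y, rt)
  d <- unlist(r[[1]])[1:12]
  expect_lt(max(abs(d) / pmax(abs(y[1:12]), 1)), 1e-8)
  expect_lt(abs(r[[2]][["co"]] - r[[2]][["vr"]]), 1e-6)
})

test_that("a fresh burn with no fluid loses plasma volume immediately", {
  rt <- human_rt(perturb_on = TRUE)
  y <- initialize_state(human_profile(), human_params())
  r <- model_rhs(0.25, y, rt)
  expect_lt(unlist(r[[1]])[["V_P"]], 0)
})

test_that("steady-state hold: maintenance-balanced baseline drifts less than
          0.1% over 48 h", {
  sim <- simulate_burn(human_profile(), human_params(), horizon = 48,
                       maintenance = TRUE, perturb = FALSE)
  tr <- sim$trajectory
  for (v in vk_state_names()) {
    expect_lt(max(abs(tr[[v]] / tr[[v]][1] - 1)), 1e-3)
  }
})

test_that("water, albumin and sodium ledgers balance over a resuscitated run", {
  sim <- simulate_burn(pig_profile(), pig_params(),
                       protocol = protocol_preset("P2"), horizon = 24)
  tr <- sim$trajectory
  infus <- cum_infusion(sim$schedule, tr$time_h, 24)
  totw <- tr$V_P + tr$V_BT + tr$V_IT
  water_err <- (totw - totw[1]) -
    (infus - tr$cum_UO - tr$cum_evap - tr$cum_exud)
  expect_lt(max(abs(water_err)) / totw[1], 1e-6)
  tota <- tr$A_P + tr$A_BT + tr$A_IT
  expect_lt(max(abs((tota - tota[1]) + tr$cum_denat)) / tota[1], 1e-6)
  na_err <- (tr$Na_ECF - tr$Na_ECF[1]) - (infus * 0.130 - tr$cum_FUO)
  expect_lt(max(abs(na_err)) / tr$Na_ECF[1], 1e-6)
})

test_that("identical inputs give bit-identical trajectories and schedules", {
  a <- simulate_burn(pig_profile(), pig_params(),
                     protocol = protocol_preset("P2"), horizon = 12)
  b <- simulate_burn(pig_profile(), pig_params(),
                     protocol = protocol_preset("P2"), horizon = 12)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$schedule, b$schedule)
})

test_that("halving integrator tolerances changes 24-h outputs by less than
          0.1%", {
  base <- simulate_burn(human_profile(), human_params(),
                        protocol = protocol_preset("P1"), horizon = 24)
  tight <- simulate_burn(human_profile(), human_params(),
                         protocol = protocol_preset("P1"), horizon = 24,
                         rtol = 5e-7, atol_scale = 5e-9)
  for (v in c("hct", "cvp", "co", "map", "na_plasma")) {
    a <- tail(base$trajectory[[v]], 1)
    b <- tail(tight$trajectory[[v]], 1)
    expect_lt(abs(a - b) / max(abs(b), 1e-6), 1e-3)
  }
})

test_that("controller arithmetic follows the multiplicative titration rule", {
  p2 <- protocol_preset("P2")
  w <- 30
  # below band for three consecutive reviews: 200 * 1.25^3
  r <- 200
  for (i in 1:3) r <- run_protocol_controller(p2, r, uo_last = 0.5 * w, w)
  expect_equal(r, 200 * 1.25^3)
  # inside the band: hold
  expect_equal(run_protocol_controller(p2, 300, uo_last = 1.2 * w, w), 300)
  # above: down-step
  expect_equal(run_protocol_controller(p2, 300, uo_last = 2 * w, w), 240)
  expect_equal(run_protocol_controller(protocol_preset("P1"), 300, 0, w), 0)
  expect_equal(run_protocol_controller(protocol_preset("P3"), 300, 0, w), 500)
})

test_that("the human protocol starts at the Parkland-style rate and sheep
          resuscitation starts at 1 h", {
  expect_equal(parkland_initial_rate(70, 0.4), 4 * 70 * 40 / 16)
  sim <- simulate_burn(burn_profile("sheep", 40, 0.4),
                       derive_constrained_parameters(
                         burn_profile("sheep", 40, 0.4),
                         param_registry("sheep")),
                       protocol = protocol_preset("sheep"), horizon = 6)
  sch <- sim$schedule
  expect_equal(sch$rate_mL_per_h[sch$time_h == 0], 0)
  expect_equal(sch$rate_mL_per_h[sch$time_h == 1], parkland_initial_rate(40, 0.4))
})

test_that("paradigm separation: 24-h mean hematocrit orders P1 > P2 > P3", {
  means <- vapply(c("P1", "P2", "P3"), function(k) {
    mean(simulate_burn(pig_profile(), pig_params(),
                       protocol = protocol_preset(k),
                       horizon = 24)$trajectory$hct)
  }, numeric(1))
  expect_gt(means[["P1"]], means[["P2"]])
  expect_gt(means[["P2"]], means[["P3"]])
})

test_that("unresuscitated hematocrit stays above baseline while heavy fixed
          rate dilutes below it by 24 h", {
  p1 <- simulate_burn(pig_profile(), pig_params(),
                      protocol = protocol_preset("P1"), horizon = 24)
  expect_true(all(p1$trajectory$hct[p1$trajectory$time_h > 0.5] >
                  pig_profile()$hct0))
  p3 <- simulate_burn(pig_profile(), pig_params(),
                      protocol = protocol_preset("P3"), horizon = 24)
  expect_lt(tail(p3$trajectory$hct, 1), pig_profile()$hct0)
})

test_that("schedule validation rejects malformed inputs", {
  expect_error(infusion_schedule(c(0, 0), c(1, 1)), "increasing")
  expect_error(infusion_schedule(c(0, 1), c(-1, 1)), "non-negative")
  expect_error(simulate_burn(human_profile(), human_params(),
                             schedule = infusion_schedule(0, 100),
                             protocol = protocol_preset("P1")),
               "not both")
})

test_that("tidiers and autoplot produce well-formed objects", {
  sim <- simulate_burn(human_profile(), human_params(),
                       protocol = protocol_preset("P1"), horizon = 2)
  long <- tidy.burn_sim(sim)
  expect_setequal(unique(long$variable),
                  c("hct", "cvp", "co", "map", "j_uo", "na_plasma"))
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
})
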