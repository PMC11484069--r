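test_that("Starling filtration evaluates the force balance", {
  expect_equal(starling_filtration(1, 10, 0, 1, 25, 15), 0)
  expect_equal(starling_filtration(0.5, 20, -2, 0.9, 25, 10),
               0.5 * (22 - 0.9 * 15))
  expect_equal(starling_filtration(2, 5, 5, 0, 30, 2), 0)
  expect_error(starling_filtration(-1, 10, 0, 1, 25, 15), "kf")
  # zero crossing exactly where hydrostatic equals scaled oncotic gradient
  sig <- 0.8; dpi <- 12
  expect_equal(starling_filtration(1.3, sig * dpi, 0, sig, dpi, 0), 0)
})

test_that("lymphatic flow is a bounded increasing sigmoid with midpoint", {
  q <- burnsim:::logit(0.5)
  jl <- function(p) lymphatic_flow(p, jl_max = 10, gain = 0.5, p_ref = -2, q = q)
  expect_equal(jl(-2), 5)            # midpoint: half the upper bound
  expect_lt(jl(-60), 1e-6)           # lower asymptote at 0
  expect_gt(jl(60), 10 - 1e-6)       # upper asymptote
  ps <- seq(-20, 20, by = 0.1)
  expect_true(all(diff(jl(ps)) > 0))
  slopes <- diff(jl(ps)) / 0.1
  expect_equal(ps[which.max(slopes)], -2, tolerance = 0.11)
})

test_that("Patlak albumin flux has the diffusion and convection limits", {
  expect_equal(albumin_flux(0, 0.03, 0.03, 0.9, 2), 0)
  expect_equal(albumin_flux(0, 0.04, 0.02, 0.9, 2), 2 * 0.02)  # 0.04 g/h
  # convection-dominated: flux / J_C -> (1 - sigma_a) * C_P
  big <- albumin_flux(1e6, 0.04, 0.02, 0.85, 2)
  expect_equal(big / 1e6, (1 - 0.85) * 0.04, tolerance = 1e-9)
  # continuity through J_C = 0
  eps <- albumin_flux(1e-10, 0.04, 0.02, 0.85, 2)
  expect_equal(eps, albumin_flux(0, 0.04, 0.02, 0.85, 2), tolerance = 1e-8)
})

test_that("tissue pressure-volume curve is continuous, monotone, with the
          configured compliance break", {
  tp <- function(v) burnsim:::tissue_pressure(v, p_t0 = -2, g_above = 4,
                                              g_below = 60, blend_w = 0.01)
  expect_equal(tp(1), -2, tolerance = 1e-12)
  vs <- seq(0.6, 1.6, by = 0.001)
  p <- tp(vs)
  expect_true(all(diff(p) > 0))
  slope_below <- (tp(0.9) - tp(0.8)) / 0.1
  slope_above <- (tp(1.3) - tp(1.2)) / 0.1
  expect_equal(slope_below / slope_above, 60 / 4, tolerance = 0.01)
  # strongly negative pressures when dehydrated
  expect_lt(tp(0.7), -15)
})

test_that("compartment pressures anchor oncotic pressure and reject zero volume", {
  rt <- human_rt(perturb_on = FALSE)
  y <- initialize_state(human_profile(), human_params())
  pr <- compartment_pressures(y, rt, apply_perturbations(-1, rt))
  expect_equal(pr$pi_c, 25, tolerance = 1e-12)
  expect_equal(pr$p_c, rt[["p_c0"]])
  y2 <- y; y2[["A_P"]] <- y[["A_P"]] / 2
  pr2 <- compartment_pressures(y2, rt, apply_perturbations(-1, rt))
  expect_equal(pr2$pi_c, 12.5, tolerance = 1e-12)  # linear oncotic model
  y3 <- y; y3[["V_BT"]] <- 0
  expect_error(compartment_pressures(y3, rt, apply_perturbations(-1, rt)),
               "positive")
})

test_that("hematocrit observation inverts red-cell dilution", {
  rt <- human_rt()
  y <- initialize_state(human_profile(), human_params())
  expect_equal(hematocrit(y, rt), 0.40, tolerance = 1e-12)
  rt2 <- rt; rt2[["rcv"]] <- 2000
  y2 <- y; y2[["V_P"]] <- 1500
  expect_equal(hematocrit(y2, rt2), 2000 / 3500, tolerance = 1e-12)
  y3 <- y; y3[["V_P"]] <- 1e12
  expect_lt(hematocrit(y3, rt), 1e-6)
})

test_that("plasma sodium is content over extracellular water", {
  y <- initialize_state(human_profile(), human_params())
  expect_equal(plasma_sodium(y), 140, tolerance = 1e-12)
  # pure-water gain dilutes
  y2 <- y
  y2[["V_IT"]] <- y2[["V_IT"]] + 0.1 * (y[["V_P"]] + y[["V_BT"]] + y[["V_IT"]])
  expect_equal(plasma_sodium(y2), 140 / 1.1, tolerance = 1e-12)
  # isotonic gain leaves concentration unchanged
  y3 <- y
  y3[["V_P"]] <- y3[["V_P"]] * 1.2
  y3[["Na_ECF"]] <- y3[["Na_ECF"]] +
    0.140 * 0.2 * y[["V_P"]]
  expect_equal(plasma_sodium(y3), 140, tolerance = 1e-12)
})

test_that("dermal losses are gated, proportional, and vanish at baseline", {
  rt <- human_rt(perturb_on = TRUE)
  y <- initialize_state(human_profile(), human_params())
  pk <- apply_perturbations(6, rt)
  dl <- dermal_loss(y, rt, pk)
  expect_equal(dl$j_exud, 0)            # no excess burnt-tissue volume
  expect_gt(dl$j_evap, 0)
  # evaporation doubles with TBSA at fixed weight
  prof2 <- burn_profile("human", 70, tbsa = 0.8)
  par2 <- derive_constrained_parameters(prof2, param_registry("human"))
  rt2 <- burnsim:::runtime_constants(prof2, par2, perturb_on = TRUE)
  dl2 <- dermal_loss(initialize_state(prof2, par2), rt2, pk)
  expect_equal(dl2$j_evap / dl$j_evap, 2, tolerance = 1e-12)
  # swollen burnt tissue exudes
  y2 <- y; y2[["V_BT"]] <- y2[["V_BT"]] + 500
  expect_equal(dermal_loss(y2, rt, pk)$j_exud,
               rt[["k_exud"]] * 500 * pk$wound_gate)
})

test_that("vk derivative assembly conserves water, albumin and sodium", {
  rt <- human_rt(perturb_on = TRUE)
  y <- initialize_state(human_profile(), human_params())
  y[["V_P"]] <- y[["V_P"]] * 0.9
  y[["A_BT"]] <- y[["A_BT"]] * 1.1
  pk <- apply_perturbations(3, rt)
  out <- vk_rhs(y, rt, pk, j_i = 500, q_i = 0, f_i = 500 * 0.130,
                j_uo = 50, f_uo = 50 * 0.100)
  water <- out$dV_P + out$dV_BT + out$dV_IT
  expect_equal(water, 500 - 50 - out$fluxes$j_evap - out$fluxes$j_exud,
               tolerance = 1e-9)
  alb <- out$dA_P + out$dA_BT + out$dA_IT
  expect_equal(alb, -out$fluxes$denat, tolerance = 1e-12)
  # LR at 500 mL/h against urine at 100 mEq/L: net sodium gain 60 mEq/h
  expect_equal(out$dNa_ECF, 500 * 0.130 - 50 * 0.100)
})
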