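test_that("renin secretion is inverse-linear in macula-densa sodium with a
          floor", {
  rt <- human_rt()
  base <- renin_rhs(rt[["na_md0"]], 1, rt)
  expect_equal(base$dC, 0)
  expect_equal(base$secretion, 1)
  # a rise in MD sodium suppresses release
  expect_lt(renin_rhs(1.1 * rt[["na_md0"]], 1, rt)$secretion, 1)
  # steady-state algebra: at Na_MD = 0.9 * baseline and gain 2 the new steady
  # concentration is 1.2 (secretion equals clearance there)
  rt2 <- rt; rt2[["g_renin"]] <- 2
  expect_equal(renin_rhs(0.9 * rt2[["na_md0"]], 1.2, rt2)$dC, 0,
               tolerance = 1e-12)
  # floored secretion
  expect_equal(renin_rhs(10 * rt[["na_md0"]], 0.5, rt)$secretion, 0)
})

test_that("angiotensin II follows lagged renin with unit steady-state gain", {
  rt <- human_rt()
  expect_equal(angii_rhs(1, 1, 1, rt)$dC, 0)
  expect_equal(angii_rhs(1, 1, 1, rt)$dL, 0)
  # steady renin 1.5 with unit gain gives steady Ang II 1.5
  expect_equal(angii_rhs(1.5, 1.5, 1.5, rt)$dC, 0, tolerance = 1e-12)
  expect_equal(angii_rhs(1.5, 1.5, 1.5, rt)$dL, 0, tolerance = 1e-12)
})

test_that("the first-order lag approximates an explicit delayed-argument
          response to a renin step", {
  rt <- human_rt()
  tau_d <- rt[["tau_d"]]; k <- rt[["k_angii"]]
  renin_t <- function(t) ifelse(t < 0, 1, 1.5)
  # lag-chain model (as implemented)
  f_lag <- function(t, y, p) {
    a <- angii_rhs(renin_t(t), y[1], y[2], rt)
    list(c(a$dL, a$dC))
  }
  # reference: true delayed argument renin(t - tau_d), no lag state
  f_delay <- function(t, y, p) {
    s <- max(0, 1 + rt[["g_angii"]] * (renin_t(t - tau_d) - 1))
    list(k * (s - y))
  }
  ts <- seq(0, 10, by = 0.01)
  lag <- deSolve::ode(c(1, 1), ts, f_lag, NULL)[, 3]
  del <- deSolve::ode(1, ts, f_delay, NULL)[, 2]
  expect_equal(tail(lag, 1), 1.5, tolerance = 1e-4)
  expect_equal(tail(del, 1), 1.5, tolerance = 1e-4)
  expect_lt(sqrt(mean((lag - del)^2)), 0.05)
  # both responses are delayed relative to an undelayed first-order rise
  undel <- 1 + 0.5 * (1 - exp(-k * ts))
  expect_gt(sum(undel - lag) * 0.01, 0)
})

test_that("aldosterone secretion is exponential in its weighted drives", {
  rt <- human_rt()
  expect_equal(aldosterone_rhs(rt[["na_plasma0"]], 1, 1, rt)$dC, 0)
  # Ang II drive alone: +0.5 with unit weight multiplies secretion by e^0.5
  rt2 <- rt; rt2[["w_a"]] <- 1
  expect_equal(aldosterone_rhs(rt2[["na_plasma0"]], 1.5, 1, rt2)$secretion,
               exp(0.5), tolerance = 1e-12)
  # low sodium stimulates secretion (retention drive)
  expect_gt(aldosterone_rhs(0.95 * rt[["na_plasma0"]], 1, 1, rt)$secretion, 1)
})

test_that("ADH responds to volume and osmolarity with osmoreceptor dominance", {
  rt <- human_rt()
  v0 <- rt[["v_p0"]]; na0 <- rt[["na_plasma0"]]
  expect_equal(adh_rhs(v0, na0, 1, rt)$dC, 0)
  expect_gt(adh_rhs(0.9 * v0, na0, 1, rt)$secretion, 1)
  # equal-magnitude fractional changes: the sodium term dominates (w_s > w_v)
  s_na <- adh_rhs(v0, 1.05 * na0, 1, rt)$secretion
  s_vol <- adh_rhs(0.95 * v0, na0, 1, rt)$secretion
  expect_gt(s_na, s_vol)
  expect_gt(rt[["w_s"]], rt[["w_v"]])
})

test_that("hormone subsystem holds the normalized baseline indefinitely", {
  sim <- simulate_burn(human_profile(), human_params(), horizon = 48,
                       maintenance = TRUE, perturb = FALSE)
  tr <- sim$trajectory
  for (h in c("C_renin", "C_angII", "C_ald", "C_adh", "L_angII")) {
    expect_lt(max(abs(tr[[h]] - 1)), 1e-7)
  }
})

test_that("hypovolemic burn drives all four hormones above baseline", {
  sim <- simulate_burn(pig_profile(), pig_params(),
                       protocol = protocol_preset("P1"), horizon = 24)
  tr <- sim$trajectory
  for (h in c("C_renin", "C_angII", "C_ald", "C_adh")) {
    expect_gt(max(tr[[h]]), 1.02)
  }
  # and concentrations never become non-positive
  expect_true(all(tr[burnsim:::hormone_state_names()] > 0))
})
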