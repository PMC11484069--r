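test_that("renal pressures are anchored linear maps of MAP and CVP", {
  rt <- human_rt()
  pr <- renal_pressures(93, 4, rt)
  expect_equal(pr$p_ra, 85)     # a1 = 1, a0 = -8 at the human preset
  expect_equal(pr$p_rv, 6)
  expect_gt(renal_pressures(100, 4, rt)$p_ra, pr$p_ra)
})

test_that("renal plasma flow follows Poiseuille's law", {
  expect_equal(renal_plasma_flow(80, 0, 40 / 37500, 30 / 37500, 10 / 37500),
               37500)
  expect_equal(renal_plasma_flow(5, 5, 1, 1, 1), 0)
  expect_equal(renal_plasma_flow(80, 0, 2 * 40 / 37500, 2 * 30 / 37500,
                                 2 * 10 / 37500), 37500 / 2)
  expect_error(renal_plasma_flow(80, 0, -1, 1, 1), "positive")
})

test_that("glomerular pressure and oncotic linearization evaluate directly", {
  expect_equal(glomerular_pressure(0, 1e-3, 1e-4, 6), 6)
  expect_equal(glomerular_pressure(2000, 1e-3, 1e-4, 6),
               6 + 2 * glomerular_pressure(1000, 1e-3, 1e-4, 6) - 12)
  expect_equal(glomerular_oncotic(58, 18, 25, 1, 0.25), 35)
  expect_equal(glomerular_oncotic(58, 18, 25, 1, 0), 25)
  expect_gt(glomerular_oncotic(60, 18, 25, 1, 0.25),
            glomerular_oncotic(58, 18, 25, 1, 0.25))
})

test_that("GFR is floored Starling filtration with albumin-dilution gain", {
  expect_lt(gfr(43, 18, 25, 1000), 0.1)        # filtration equilibrium
  expect_equal(gfr(60, 18, 35.5, 1154), 1154 * 6.5, tolerance = 1e-3)
  # albumin dilution (lower pi_C hence pi_G) raises GFR at fixed pressures
  expect_gt(gfr(60, 18, 30, 1154), gfr(60, 18, 35.5, 1154))
  expect_error(gfr(60, 18, 30, -5), "kfg")
})

test_that("human preset reproduces the baseline renal anchors", {
  rep <- baseline_fraction_report(human_profile(), human_params())
  expect_equal(rep$filtration_fraction, 0.20, tolerance = 1e-6)
  expect_equal(rep$uo_fraction_of_rpf, 0.01, tolerance = 1e-6)
  expect_gte(rep$r_p0, 0.65)
  expect_lte(rep$r_p0, 0.75)
  expect_equal(rep$p_k, 0.60)
  expect_equal(rep$j_gfr, 0.20 * rep$j_rpf, tolerance = 1e-6)
})

test_that("autoregulation resistances vanish at baseline and saturate", {
  rt <- human_rt()
  expect_equal(myogenic_resistance(85, rt), 0, tolerance = 1e-12)
  expect_equal(myogenic_resistance(1e4, rt),
               rt[["f_mm"]] * rt[["r_aff0"]], tolerance = 1e-9)
  ps <- seq(40, 160, by = 1)
  expect_true(all(diff(myogenic_resistance(ps, rt)) > 0))
  expect_equal(tgf_resistance(rt[["na_md0"]], rt), 0, tolerance = 1e-12)
  expect_lt(tgf_resistance(2 * rt[["na_md0"]], rt),
            rt[["f_tgf"]] * rt[["r_aff0"]])
  expect_gt(tgf_resistance(2 * rt[["na_md0"]], rt), 0)
  expect_error(tgf_resistance(-1, rt), "positive")
})

test_that("efferent resistance is anchored and dilates below baseline Ang II", {
  rt <- human_rt()
  expect_equal(efferent_resistance(1, rt), rt[["r_eff0"]], tolerance = 1e-12)
  expect_lt(efferent_resistance(0.5, rt), rt[["r_eff0"]])
  expect_gt(efferent_resistance(2, rt), rt[["r_eff0"]])
})

test_that("raising Ang II raises glomerular pressure and GFR in the coupled
          renal solve", {
  rt <- human_rt()
  lo <- burnsim:::renal_solve(93, 4, 25, 0.140, 0.7, 1, 1, rt)
  hi <- burnsim:::renal_solve(93, 4, 25, 0.140, 1.3, 1, 1, rt)
  expect_gt(hi$p_g, lo$p_g)
  expect_gt(hi$j_gfr, lo$j_gfr)
})

test_that("higher macula-densa sodium lowers plasma flow through TGF", {
  rt <- human_rt()
  r1 <- burnsim:::afferent_resistance(85, rt[["na_md0"]], rt)
  r2 <- burnsim:::afferent_resistance(85, 1.5 * rt[["na_md0"]], rt)
  expect_gt(r2, r1)
})

test_that("proximal node reabsorbs water and sodium at the same fraction", {
  rt <- human_rt()
  p <- proximal_node(7500, 1050, 1, rt)
  expect_equal(p$r_p, rt[["r_p0"]], tolerance = 1e-12)
  # sodium concentration preserved across the node for any aldosterone
  for (ald in c(0.3, 1, 2.5)) {
    p2 <- proximal_node(7500, 1050, ald, rt)
    expect_equal(p2$f_pn / p2$j_pn, 1050 / 7500, tolerance = 1e-12)
  }
  # glomerulotubular balance: absolute reabsorption doubles with inflow
  p3 <- proximal_node(15000, 2100, 1, rt)
  expect_equal(p3$j_pv, 2 * p$j_pv, tolerance = 1e-12)
})

test_that("descending limb is sodium-impermeable with inverse flow dependence", {
  rt <- human_rt()
  n <- descending_limb_node(rt[["j_pn0"]], 315, rt)
  expect_equal(n$r_n, 0.5, tolerance = 1e-12)   # anchored midpoint value
  expect_equal(n$f_nk, 315)                     # sodium untouched
  n_fast <- descending_limb_node(2 * rt[["j_pn0"]], 630, rt)
  expect_lt(n_fast$r_n, n$r_n)
  # faster flow leaves the outflow more dilute
  expect_lt(n_fast$f_nk / n_fast$j_nk, n$f_nk / n$j_nk)
})

test_that("ascending limb removes a fixed 60% of sodium at any inflow", {
  rt <- human_rt()
  for (f in c(10, 126, 4000)) {
    k <- ascending_limb_node(1000, f, rt)
    expect_equal(k$f_ke / f, 0.40, tolerance = 1e-12)
    expect_equal(k$j_ke, 1000)                  # water impermeable
  }
})

test_that("early distal node defines macula-densa sodium", {
  rt <- human_rt()
  e <- early_distal_node(1125, 126, rt)
  expect_equal(e$j_ec, 1125)
  expect_equal(e$na_md, 126 * (1 - e$p_e) / 1125, tolerance = 1e-12)
  # faster sodium inflow -> less reabsorption -> higher MD sodium
  e2 <- early_distal_node(1125, 200, rt)
  expect_lt(e2$p_e, e$p_e)
  expect_gt(e2$na_md, e$na_md)
  expect_error(early_distal_node(0, 10, rt), "zero water flow")
})

test_that("collecting duct implements hormonal water and sodium control", {
  rt <- human_rt()
  cd <- collecting_duct_node(1125, 37.8, 1, 1, rt)
  expect_equal(cd$j_uo / 1125, 1 - rt[["r_c0"]], tolerance = 1e-12)
  # more ADH: less urine, more concentrated
  cd2 <- collecting_duct_node(1125, 37.8, 3, 1, rt)
  expect_lt(cd2$j_uo, cd$j_uo)
  expect_gt(cd2$na_uo, cd$na_uo)
  # bounded dose-response: urine never vanishes
  cd3 <- collecting_duct_node(1125, 37.8, 1e6, 1, rt)
  expect_gt(cd3$j_uo, 1125 * (1 - rt[["r_c_hi"]]) * 0.999)
})

test_that("nephron chain conserves water and sodium node-wise and overall", {
  rt <- human_rt()
  for (gfr_in in c(2000, 7500, 12000)) {
    ch <- nephron_chain(gfr_in, 0.140, 1.2, 0.8, rt)
    expect_equal(ch$j_pv + ch$j_nv + (ch$j_ec - ch$j_uo) + ch$j_uo, gfr_in,
                 tolerance = 1e-10 * gfr_in)
    f_cv <- ch$f_ec - ch$f_uo
    expect_equal(ch$f_pv + ch$f_kv + ch$f_ev + f_cv + ch$f_uo, ch$f_gfr,
                 tolerance = 1e-10 * ch$f_gfr)
  }
})

test_that("all fractions stay in [0,1] over a wide renal pressure sweep", {
  rt <- human_rt()
  rt[["renal_mode"]] <- 1
  for (p_ra in seq(40, 160, by = 5)) {
    rt[["pra_forced"]] <- p_ra
    sol <- burnsim:::renal_solve(NA, NA, 25, 0.140, 1, 1, 1, rt)
    fr <- c(sol$r_p, sol$r_n, sol$p_k, sol$p_e, sol$r_c, sol$p_c)
    expect_true(all(fr >= 0 & fr <= 1))
    # fixed point of the TGF loop is self-consistent
    expect_equal(sol$na_md, sol$na_md_fp, tolerance = 1e-9)
  }
})
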