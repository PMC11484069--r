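# Algebraic circulatory-equilibrium block: mean systemic pressure from blood
# volume, angiotensin-driven total peripheral resistance, Guyton-style linear
# venous return versus a logistic cardiac function curve, cardiac output at
# their intersection, and mean arterial pressure. Re-solved at every
# right-hand-side evaluation (the circulation is quasi-steady relative to
# hourly fluid shifts), so no cardiovascular state variables exist.

#' Mean systemic (filling) pressure
#'
#' Exponential in fractional blood volume:
#' `MSP = MSP0 * exp(k_msp * (V_B - V_B0) / V_B0)`.
#'
#' @param v_b blood volume (mL).
#' @param msp0 baseline MSP (mmHg); `v_b0` baseline blood volume (mL);
#'   `k_msp` volume sensitivity.
#' @return MSP (mmHg).
#' @export
mean_systemic_pressure <- function(v_b, msp0, v_b0, k_msp) {
  if (any(v_b <= 0)) stop("blood volume must be positive")
  msp0 * exp(k_msp * (v_b - v_b0) / v_b0)
}

#' Total peripheral resistance from relative angiotensin II
#'
#' Bounded increasing logistic anchored so `TPR(1) = TPR0`.
#'
#' @param c_angii relative plasma Ang II concentration (baseline 1).
#' @param rt runtime constant block.
#' @return TPR (mmHg.min/L).
#' @export
total_peripheral_resistance <- function(c_angii, rt) {
  rt[["tpr_min"]] + (rt[["tpr_max"]] - rt[["tpr_min"]]) *
    sigmoid(rt[["s_tpr"]] * (c_angii - 1) + rt[["q_tpr"]])
}

#' Venous return line
#'
#' `VR = (MSP - CVP) / (kappa_v * TPR)`: linear in CVP, zero where CVP equals
#' the filling pressure, slope set by MSP-independent resistance
#' proportional to TPR.
#'
#' @param cvp central venous pressure (mmHg).
#' @param msp mean systemic pressure (mmHg).
#' @param tpr total peripheral resistance (mmHg.min/L).
#' @param kappa_v venous-return resistance as a fraction of TPR.
#' @return venous return (L/min).
#' @export
venous_return <- function(cvp, msp, tpr, kappa_v) {
  (msp - cvp) / (kappa_v * tpr)
}

#' Cardiac function (Frank-Starling) curve
#'
#' Saturating logistic dose-response of CVP anchored through the baseline
#' operating point `(CVP0, CO0)` with plateau `CO_max`.
#'
#' @param cvp central venous pressure (mmHg).
#' @param rt runtime constant block.
#' @return cardiac output (L/min).
#' @export
cardiac_function_curve <- function(cvp, rt) {
  rt[["co_max"]] / (1 + exp(-(cvp - rt[["co_mid"]]) / rt[["s_co"]]))
}

#' Circulatory equilibrium (CO-VR intersection)
#'
#' Bracketed bisection on CVP in `[cvp_floor, MSP]` for the unique point
#' where the cardiac function curve meets the venous-return line; the
#' residual `|CO - VR|` at the returned point is below 1e-6 L/min.
#'
#' @param msp mean systemic pressure (mmHg).
#' @param tpr total peripheral resistance (mmHg.min/L).
#' @param rt runtime constant block.
#' @return list `cvp`, `co` (equal to VR at equilibrium).
#' @export
circulatory_equilibrium <- function(msp, tpr, rt) {
  kv <- rt[["kappa_v"]]
  lo <- rt[["cvp_floor"]]; hi <- msp
  if (hi <= lo) stop("circulatory equilibrium: MSP ", signif(msp, 4),
                     " below the CVP bracket floor ", lo)
  f <- function(cvp) cardiac_function_curve(cvp, rt) - venous_return(cvp, msp, tpr, kv)
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop(sprintf(
      "circulatory equilibrium: no sign change in bracket [%g, %g] (f: %g, %g)",
      lo, hi, flo, fhi))
  }
  for (i in 1:100) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if (fm > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  cvp <- 0.5 * (lo + hi)
  list(cvp = cvp, co = cardiac_function_curve(cvp, rt))
}

#' Mean arterial pressure
#'
#' `MAP = CO * TPR * M_MAP + CVP`, with `M_MAP` the net vasomotor multiplier
#' from the burn-perturbation block.
#'
#' @param co cardiac output (L/min); `tpr` (mmHg.min/L); `m_map`
#'   dimensionless multiplier; `cvp` (mmHg).
#' @return MAP (mmHg).
#' @export
mean_arterial_pressure <- function(co, tpr, m_map, cvp) {
  co * tpr * m_map + cvp
}

#' Evaluate the full cardiovascular block
#'
#' @param v_b blood volume (mL); `c_angii` relative Ang II; `m_map`
#'   vasomotor multiplier; `rt` runtime block.
#' @return list `msp, tpr, cvp, co, vr, map`.
#' @export
cv_block <- function(v_b, c_angii, m_map, rt) {
  msp <- mean_systemic_pressure(v_b, rt[["msp0"]], rt[["v_b0"]], rt[["k_msp"]])
  tpr <- total_peripheral_resistance(c_angii, rt)
  eq <- circulatory_equilibrium(msp, tpr, rt)
  list(msp = msp, tpr = tpr, cvp = eq$cvp, co = eq$co, vr = eq$co,
       map = mean_arterial_pressure(eq$co, tpr, m_map, eq$cvp))
}
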