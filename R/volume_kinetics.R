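# Three-compartment water/albumin/sodium kinetics: Starling filtration,
# sigmoidal lymphatic return, Patlak albumin transport, dermal losses, and
# assembly of the 7 volume-kinetic state derivatives.

#' Starling transcapillary filtration
#'
#' `J = kf * ((P_C - P_T) - sigma * (pi_C - pi_T))`. Negative values mean
#' reabsorption from tissue into plasma.
#'
#' @param kf filtration conductance (mL/h/mmHg), must be >= 0.
#' @param p_c,p_t capillary and tissue hydrostatic pressures (mmHg).
#' @param sigma osmotic reflection coefficient in \[0, 1\].
#' @param pi_c,pi_t capillary and tissue colloid oncotic pressures (mmHg).
#' @return filtration rate (mL/h).
#' @export
starling_filtration <- function(kf, p_c, p_t, sigma, pi_c, pi_t) {
  if (any(kf < 0)) stop("kf must be non-negative")
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  kf * ((p_c - p_t) - sigma * (pi_c - pi_t))
}

#' Lymphatic flow as a sigmoid of tissue pressure
#'
#' Bounded in `[0, jl_max]`, monotone non-decreasing in tissue hydrostatic
#' pressure. At the baseline tissue pressure the anchored logit offset makes
#' lymph flow equal baseline capillary filtration, so each tissue is in water
#' balance pre-injury.
#'
#' @param p_t tissue hydrostatic pressure (mmHg).
#' @param jl_max upper lymph-flow asymptote (mL/h).
#' @param gain logistic slope (1/mmHg).
#' @param p_ref pressure at which the logit offset `q` applies (mmHg).
#' @param q logit offset; `sigmoid(q)` is the fraction of `jl_max` at `p_ref`.
#' @return lymph flow (mL/h).
#' @export
lymphatic_flow <- function(p_t, jl_max, gain, p_ref, q) {
  jl_max * sigmoid(gain * (p_t - p_ref) + q)
}

#' Coupled convection-diffusion (Patlak) albumin flux
#'
#' `flux = J_C (1 - sigma_a) (C_P - C_T e^{-Pe}) / (1 - e^{-Pe})` with Peclet
#' number `Pe = J_C (1 - sigma_a) / PS`. Reduces to pure diffusion
#' `PS (C_P - C_T)` as `J_C -> 0` and to convection `J_C (1 - sigma_a) C_P`
#' as `J_C -> Inf`.
#'
#' @param j_c water filtration rate (mL/h); may be negative.
#' @param c_p,c_t plasma and tissue albumin concentrations (g/mL).
#' @param sigma_a albumin reflection coefficient.
#' @param ps permeability-surface-area product (mL/h).
#' @return albumin flux plasma -> tissue (g/h).
#' @export
albumin_flux <- function(j_c, c_p, c_t, sigma_a, ps) {
  jconv <- j_c * (1 - sigma_a)
  pe <- jconv / ps
  small <- abs(pe) < 1e-8
  out <- numeric(length(pe))
  # series limit at Pe ~ 0 keeps the flux continuous through J_C = 0
  out[small] <- ps * (c_p - c_t) + 0.5 * jconv[small] * (c_p + c_t)
  if (any(!small)) {
    e <- exp(-pe[!small])
    out[!small] <- jconv[!small] * (c_p - c_t * e) / (1 - e)
  }
  out
}

# Continuous piecewise-linear tissue pressure-volume curve with a softplus
# blend of width `blend_w` (fractional volume): low compliance (steep slope
# g_below) under baseline volume, high compliance (shallow g_above) above.
tissue_pressure <- function(v_rel, p_t0, g_above, g_below, blend_w) {
  sp <- function(x) {
    # softplus with width blend_w, overflow-safe
    z <- x / blend_w
    ifelse(z > 30, x, blend_w * log1p(exp(pmin(z, 30))))
  }
  off <- (g_above - g_below) * blend_w * log(2)  # re-anchor P(v_rel = 1) = p_t0
  p_t0 + g_above * sp(v_rel - 1) - g_below * sp(1 - v_rel) - off
}

#' Compartment hydrostatic and oncotic pressures
#'
#' Capillary pressure is linear in plasma volume; tissue pressures follow the
#' blended piecewise-linear compliance curve (steep below baseline volume,
#' shallow above), with the transient burn negative-pressure offset applied
#' to the burnt tissue. Oncotic pressures are linear in albumin
#' concentration, `pi = k_pi * A / V`.
#'
#' @param state model state vector (see [initialize_state()]).
#' @param rt runtime constant block from [runtime_constants()].
#' @param perturb perturbation signals from [apply_perturbations()].
#' @return named list `p_c, p_bt, p_it, pi_c, pi_bt, pi_it` (mmHg).
#' @export
compartment_pressures <- function(state, rt, perturb) {
  if (any(state[c("V_P", "V_BT", "V_IT")] <= 0)) {
    stop("compartment volumes must be strictly positive")
  }
  p_c <- rt[["p_c0"]] + rt[["g_pc"]] * (state[["V_P"]] / rt[["v_p0"]] - 1)
  p_bt <- tissue_pressure(state[["V_BT"]] / rt[["v_bt0"]], rt[["p_t0"]],
                          rt[["g_t_above"]], rt[["g_t_below"]],
                          rt[["blend_w"]]) - perturb$pbt_offset
  p_it <- tissue_pressure(state[["V_IT"]] / rt[["v_it0"]], rt[["p_t0"]],
                          rt[["g_t_above"]], rt[["g_t_below"]],
                          rt[["blend_w"]])
  list(p_c = p_c, p_bt = p_bt, p_it = p_it,
       pi_c = rt[["k_pi"]] * state[["A_P"]] / state[["V_P"]],
       pi_bt = rt[["k_pi"]] * state[["A_BT"]] / state[["V_BT"]],
       pi_it = rt[["k_pi"]] * state[["A_IT"]] / state[["V_IT"]])
}

#' Dermal fluid losses
#'
#' Evaporation is proportional to burned surface (TBSA x weight) and gated by
#' the transient wound signal; exudation is proportional to burnt-tissue
#' water excess above baseline and gated by the same signal. Both are drawn
#' from the burnt-tissue compartment and are always non-negative.
#'
#' @inheritParams compartment_pressures
#' @return list `j_evap, j_exud` (mL/h).
#' @export
dermal_loss <- function(state, rt, perturb) {
  gate <- perturb$wound_gate
  list(j_evap = rt[["k_evap_tot"]] * gate,
       j_exud = rt[["k_exud"]] * max(0, state[["V_BT"]] - rt[["v_bt0"]]) * gate)
}

#' Hematocrit observation
#'
#' `HCT = RCV / (RCV + V_P)` with the red-cell volume fixed post-injury at
#' its baseline value derived from baseline hematocrit.
#'
#' @inheritParams compartment_pressures
#' @return hematocrit fraction.
#' @export
hematocrit <- function(state, rt) {
  if (state[["V_P"]] <= 0) stop("plasma volume must be positive")
  rt[["rcv"]] / (rt[["rcv"]] + state[["V_P"]])
}

#' Plasma sodium concentration
#'
#' Extracellular sodium content divided by extracellular water
#' (plasma + both tissue compartments), reported in mEq/L.
#'
#' @inheritParams compartment_pressures
#' @return plasma sodium (mEq/L).
#' @export
plasma_sodium <- function(state) {
  v_ecf <- state[["V_P"]] + state[["V_BT"]] + state[["V_IT"]]
  if (v_ecf <= 0) stop("extracellular volume must be positive")
  1000 * state[["Na_ECF"]] / v_ecf
}

#' Volume-kinetic state derivatives
#'
#' Assembles the 7 water/albumin/sodium derivatives from the fluxes:
#' plasma volume gains infusion and lymph and loses urine and filtration;
#' tissue volumes gain filtration and lose lymph and dermal losses (burnt
#' tissue only); albumin follows Patlak capillary flux, lymphatic return at
#' tissue concentration, infused albumin, and the burnt-tissue denaturation
#' sink; extracellular sodium changes only through infusion and urine
#' (capillary and lymphatic exchange are isotonic and cancel).
#'
#' @inheritParams compartment_pressures
#' @param j_i total water input rate (mL/h), `q_i` infused albumin (g/h),
#'   `f_i` sodium input (mEq/h).
#' @param j_uo urinary output (mL/h), `f_uo` urinary sodium output (mEq/h).
#' @return named list with the 7 derivatives plus the fluxes used.
#' @export
vk_rhs <- function(state, rt, perturb, j_i, q_i, f_i, j_uo, f_uo) {
  pr <- compartment_pressures(state, rt, perturb)
  kf_bt <- rt[["kf_bt0"]] * (1 + perturb$kf_bt + perturb$kf_sys)
  kf_it <- rt[["kf_it0"]] * (1 + perturb$kf_sys)
  sig <- min(1, max(0, rt[["sigma0"]] * (1 - perturb$sigma_drop)))
  sig_a <- min(1, max(0, rt[["sigma_a0"]] * (1 - perturb$sigma_drop)))

  j_c_bt <- starling_filtration(kf_bt, pr$p_c, pr$p_bt, sig, pr$pi_c, pr$pi_bt)
  j_c_it <- starling_filtration(kf_it, pr$p_c, pr$p_it, sig, pr$pi_c, pr$pi_it)
  j_l_bt <- lymphatic_flow(pr$p_bt, rt[["jl_max_bt"]], rt[["lymph_gain"]],
                           rt[["p_t0"]], rt[["q_lymph"]])
  j_l_it <- lymphatic_flow(pr$p_it, rt[["jl_max_it"]], rt[["lymph_gain"]],
                           rt[["p_t0"]], rt[["q_lymph"]])

  c_p <- state[["A_P"]] / state[["V_P"]]
  c_bt <- state[["A_BT"]] / state[["V_BT"]]
  c_it <- state[["A_IT"]] / state[["V_IT"]]
  q_bt <- albumin_flux(j_c_bt, c_p, c_bt, sig_a, rt[["ps_bt"]])
  q_it <- albumin_flux(j_c_it, c_p, c_it, sig_a, rt[["ps_it"]])
  denat <- perturb$denat_rate * state[["A_BT"]]

  dl <- dermal_loss(state, rt, perturb)

  list(
    dV_P = j_i - j_uo - j_c_bt - j_c_it + j_l_bt + j_l_it,
    dA_P = q_i - q_bt - q_it + j_l_bt * c_bt + j_l_it * c_it,
    dV_BT = j_c_bt - j_l_bt - dl$j_evap - dl$j_exud,
    dV_IT = j_c_it - j_l_it,
    dA_BT = q_bt - j_l_bt * c_bt - denat,
    dA_IT = q_it - j_l_it * c_it,
    dNa_ECF = f_i - f_uo,
    fluxes = list(j_c_bt = j_c_bt, j_c_it = j_c_it, j_l_bt = j_l_bt,
                  j_l_it = j_l_it, q_bt = q_bt, q_it = q_it,
                  denat = denat, j_evap = dl$j_evap, j_exud = dl$j_exud),
    pressures = pr
  )
}
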