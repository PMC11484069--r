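# Runtime constant block: everything the right-hand side needs, precomputed
# once per (profile, params) so both the R reference implementation and the
# compiled model index the same quantities. The vector layout is the contract
# with src/burnmod.c -- do not reorder.

rt_layout <- c(
  "w", "tbsa", "rcv",
  "v_p0", "v_bt0", "v_it0", "k_pi", "p_c0", "g_pc", "p_t0",
  "g_t_above", "g_t_below", "blend_w",
  "kf_bt0", "kf_it0", "sigma0", "sigma_a0", "ps_bt", "ps_it",
  "lymph_gain", "q_lymph", "jl_max_bt", "jl_max_it",
  "k_evap_tot", "k_exud",
  "na_maint", "j_maint", "j_inf", "na_inf", "q_inf",
  "amp_kf_bt", "amp_kf_sys", "amp_sigma", "amp_pbt", "amp_den",
  "amp_constrict", "amp_dilate",
  "tau1_fast", "tau2_fast", "tau1_slow", "tau2_slow", "perturb_on",
  "msp0", "k_msp", "v_b0", "kappa_v", "tpr0", "tpr_min", "tpr_max",
  "s_tpr", "q_tpr", "co_max", "s_co", "co_mid", "cvp_floor",
  "a1", "a0", "b1", "b0", "r_aff0", "r_eff0", "r_rv", "kfg", "p_b",
  "lambda_c", "lambda_p", "f_mm", "s_mm", "pra0", "f_tgf", "s_tgf",
  "na_md0", "eff_min", "eff_max", "s_eff",
  "r_p_lo", "r_p_hi", "r_p0", "g_rp",
  "r_n_lo", "r_n_hi", "r_n0", "g_rn", "j_pn0",
  "p_k",
  "p_e_lo", "p_e_hi", "p_e0", "g_pe", "f_ke0",
  "r_c_lo", "r_c_hi", "r_c0", "g_rc",
  "p_c_lo", "p_c_hi", "p_c0n", "g_pc_ald",
  "k_renin", "g_renin", "tau_d", "k_angii", "g_angii",
  "k_ald", "w_na", "w_a", "k_adh", "w_v", "w_s",
  "na_plasma0", "gfr_soft_w",
  "renal_mode", "pra_forced", "vk_frozen", "prv0", "pi_c0"
)

logit <- function(p) log(p / (1 - p))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Assemble the runtime constant block
#'
#' Flattens a completed parameter registry plus subject profile into the
#' named numeric vector consumed by the model right-hand side (both the R
#' reference implementation and the compiled integrator core). Includes every
#' derived baseline anchor: red-cell volume from baseline hematocrit,
#' per-tissue filtration conductances and lymph scales, dose-response logit
#' offsets, baseline nephron flows and the macula-densa sodium anchor, and
#' the constraint-derived maintenance intake (rate equal to baseline urinary
#' output, sodium matching baseline urinary sodium).
#'
#' @param profile a [burn_profile()].
#' @param params completed registry.
#' @param maintenance logical; include the baseline maintenance intake.
#' @param perturb_on logical; enable the burn perturbation signals.
#' @return named numeric vector (layout `burnsim:::rt_layout`).
#' @keywords internal
runtime_constants <- function(profile, params, maintenance = FALSE,
                              perturb_on = TRUE) {
  v <- par_values(params)
  if (anyNA(v)) {
    stop("registry has underived entries; call derive_constrained_parameters()")
  }
  w <- profile$weight; tbsa <- profile$tbsa; hct0 <- profile$hct0

  v_p0 <- v[["v_plasma_perkg"]] * w
  v_bt0 <- v[["v_tissue_perkg"]] * w * tbsa
  v_it0 <- v[["v_tissue_perkg"]] * w * (1 - tbsa)
  rcv <- v_p0 * hct0 / (1 - hct0)

  pi_t0 <- v[["k_pi"]] * v[["c_alb_t0"]]
  grad0 <- (v[["p_c0"]] - v[["p_t0"]]) - v[["sigma0"]] * (v[["pi_c0"]] - pi_t0)
  if (grad0 <= 0) {
    stop("infeasible baseline: net Starling filtration gradient must be > 0")
  }
  kf_bt0 <- v[["kf_perkg"]] * w * tbsa
  kf_it0 <- v[["kf_perkg"]] * w * (1 - tbsa)
  jc_bt0 <- kf_bt0 * grad0
  jc_it0 <- kf_it0 * grad0
  jl_max_bt <- v[["lymph_max_mult"]] * jc_bt0
  jl_max_it <- v[["lymph_max_mult"]] * jc_it0
  q_lymph <- logit(1 / v[["lymph_max_mult"]])
  ps_bt <- v[["ps_ratio"]] * jc_bt0
  ps_it <- v[["ps_ratio"]] * jc_it0

  co0 <- v[["co0_perkg"]] * w
  tpr_min <- v[["tpr_min_frac"]] * v[["tpr0"]]
  tpr_max <- v[["tpr_max_frac"]] * v[["tpr0"]]
  q_tpr <- logit((v[["tpr0"]] - tpr_min) / (tpr_max - tpr_min))
  co_max <- v[["co_max_frac"]] * co0
  v_b0 <- v_p0 + rcv

  rpf0 <- v[["rpf0_perkg"]] * w
  gfr0 <- v[["ff0"]] * rpf0
  j_pn0 <- gfr0 * (1 - v[["r_p0"]])
  f_ke0 <- gfr0 * v[["na_plasma0"]] * (1 - v[["r_p0"]]) * (1 - v[["p_k"]])
  j_ec0 <- j_pn0 * (1 - v[["r_n0"]])
  f_ec0 <- f_ke0 * (1 - v[["p_e0"]])
  na_md0 <- f_ec0 / j_ec0
  j_uo0 <- j_ec0 * (1 - v[["r_c0"]])
  f_uo0 <- f_ec0 * (1 - v[["p_c0n"]])
  na_uo0 <- f_uo0 / j_uo0

  out <- c(
    w, tbsa, rcv,
    v_p0, v_bt0, v_it0, v[["k_pi"]], v[["p_c0"]], v[["g_pc"]], v[["p_t0"]],
    v[["g_t_above"]], v[["g_t_below"]], v[["blend_w"]],
    kf_bt0, kf_it0, v[["sigma0"]], v[["sigma_a0"]], ps_bt, ps_it,
    v[["lymph_gain"]], q_lymph, jl_max_bt, jl_max_it,
    v[["k_evap_perkg"]] * w * tbsa, v[["k_exud"]],
    na_uo0, if (maintenance) j_uo0 else 0, 0, v[["na_lr"]], 0,
    v[["amp_kf_bt"]], v[["amp_kf_sys"]], v[["amp_sigma"]], v[["amp_pbt"]],
    v[["amp_den"]], v[["amp_constrict"]], v[["amp_dilate"]],
    v[["tau1_fast"]], v[["tau2_fast"]], v[["tau1_slow"]], v[["tau2_slow"]],
    as.numeric(perturb_on),
    v[["msp0"]], v[["k_msp"]], v_b0, v[["kappa_v"]], v[["tpr0"]],
    tpr_min, tpr_max, v[["s_tpr"]], q_tpr, co_max, v[["s_co"]],
    v[["co_mid"]], v[["cvp_floor"]],
    v[["a1"]], v[["a0"]], v[["b1"]], v[["b0"]],
    v[["r_aff0"]], v[["r_eff0"]], v[["r_rv"]], v[["kfg"]], v[["p_b"]],
    v[["lambda_c"]], v[["lambda_p"]], v[["f_mm"]], v[["s_mm"]], v[["pra0"]],
    v[["f_tgf"]], v[["s_tgf"]], na_md0,
    v[["eff_min"]], v[["eff_max"]], v[["s_eff"]],
    v[["r_p_lo"]], v[["r_p_hi"]], v[["r_p0"]], v[["g_rp"]],
    v[["r_n_lo"]], v[["r_n_hi"]], v[["r_n0"]], v[["g_rn"]], j_pn0,
    v[["p_k"]],
    v[["p_e_lo"]], v[["p_e_hi"]], v[["p_e0"]], v[["g_pe"]], f_ke0,
    v[["r_c_lo"]], v[["r_c_hi"]], v[["r_c0"]], v[["g_rc"]],
    v[["p_c_lo"]], v[["p_c_hi"]], v[["p_c0n"]], v[["g_pc_ald"]],
    v[["k_renin"]], v[["g_renin"]], v[["tau_d"]], v[["k_angii"]],
    v[["g_angii"]], v[["k_ald"]], v[["w_na"]], v[["w_a"]], v[["k_adh"]],
    v[["w_v"]], v[["w_s"]],
    v[["na_plasma0"]], v[["gfr_soft_w"]],
    0, v[["pra0"]], 0, v[["prv0"]], v[["pi_c0"]]
  )
  stats::setNames(out, rt_layout)
}

# Algebraic output names written by the right-hand side (order shared with C).
output_names <- c(
  "hct", "v_b", "pi_c", "p_c", "msp", "tpr", "cvp", "co", "vr", "map",
  "m_map", "p_ra", "p_rv", "p_g", "pi_g", "j_rpf", "j_gfr",
  "r_aff", "r_eff", "r_mm", "r_tgf", "na_md",
  "r_p", "r_n", "p_e", "r_c", "p_cn",
  "j_uo", "f_uo", "na_uo", "j_pn", "j_ec", "na_plasma",
  "j_c_bt", "j_c_it", "j_l_bt", "j_l_it", "j_evap", "j_exud",
  "j_i_total", "f_i", "s_renin"
)
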