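# Kidney model: renal pressures, Poiseuille plasma flow, glomerular Starling
# filtration with myogenic + tubuloglomerular-feedback (TGF) autoregulation,
# and the four-node nephron chain (proximal P, thin descending limb N, thick
# ascending limb K folded into the early distal node E, collecting duct C)
# producing urinary output and urinary sodium.

# Anchored four-parameter logistic: bounded in (lo, hi), passes through y0 at
# x = 1 (relative input), slope sign given by `gain`. All renal dose-response
# and flow-dependence curves use this one form.
anchored_logistic <- function(x_rel, lo, hi, y0, gain) {
  lo + (hi - lo) * sigmoid(gain * (x_rel - 1) + logit((y0 - lo) / (hi - lo)))
}

#' Renal arterial and venous pressures
#'
#' Linear maps of MAP and CVP, anchored so the baseline MAP of the preset
#' maps to the 85 mmHg renal arterial operating point.
#'
#' @param map,cvp systemic pressures (mmHg).
#' @param rt runtime constant block.
#' @return list `p_ra, p_rv` (mmHg).
#' @export
renal_pressures <- function(map, cvp, rt) {
  list(p_ra = rt[["a1"]] * map + rt[["a0"]],
       p_rv = rt[["b1"]] * cvp + rt[["b0"]])
}

#' Renal plasma flow by Poiseuille's law
#'
#' @param p_ra,p_rv renal arterial/venous pressures (mmHg).
#' @param r_aff,r_eff,r_rv afferent, efferent and venous resistances
#'   (mmHg.h/mL), all positive.
#' @return plasma flow (mL/h).
#' @export
renal_plasma_flow <- function(p_ra, p_rv, r_aff, r_eff, r_rv) {
  if (any(c(r_aff, r_eff, r_rv) <= 0)) stop("renal resistances must be positive")
  (p_ra - p_rv) / (r_aff + r_eff + r_rv)
}

#' Glomerular capillary pressure
#'
#' Proportional to plasma flow and downstream (efferent + venous)
#' resistance: `P_G = J_RPF * (R_Eff + R_RV) + P_RV`.
#'
#' @param j_rpf renal plasma flow (mL/h); `r_eff`, `r_rv` resistances;
#'   `p_rv` renal venous pressure (mmHg).
#' @return P_G (mmHg).
#' @export
glomerular_pressure <- function(j_rpf, r_eff, r_rv, p_rv) {
  j_rpf * (r_eff + r_rv) + p_rv
}

#' Mean glomerular oncotic pressure
#'
#' Filtration-equilibrium linearization:
#' `pi_G = lambda_c * pi_C + lambda_p * (P_G - P_B)`.
#'
#' @param p_g,p_b glomerular and Bowman pressures (mmHg); `pi_c` plasma
#'   oncotic pressure (mmHg); `lambda_c`, `lambda_p` coefficients.
#' @return pi_G (mmHg).
#' @export
glomerular_oncotic <- function(p_g, p_b, pi_c, lambda_c, lambda_p) {
  lambda_c * pi_c + lambda_p * (p_g - p_b)
}

#' Glomerular filtration rate
#'
#' Starling filtration `K_fG * ((P_G - P_B) - pi_G)`, floored at zero through
#' a softplus of width `soft_w` (mL/h) so the right-hand side stays
#' continuously differentiable at filtration equilibrium.
#'
#' @param p_g,p_b,pi_g pressures (mmHg); `kfg` ultrafiltration coefficient
#'   (mL/h/mmHg); `soft_w` smoothing width (mL/h).
#' @return GFR (mL/h), non-negative.
#' @export
gfr <- function(p_g, p_b, pi_g, kfg, soft_w = 0.1) {
  if (any(kfg <= 0)) stop("kfg must be positive")
  x <- kfg * ((p_g - p_b) - pi_g)
  z <- x / soft_w
  # tiny positive floor keeps downstream concentrations defined
  pmax(ifelse(z > 30, x, soft_w * log1p(exp(pmin(z, 30)))), 1e-9)
}

#' Myogenic afferent resistance contribution
#'
#' Bounded odd-symmetric sigmoid of renal arterial pressure: zero at the
#' 85 mmHg baseline, saturating at `+/- f_mm * R_Aff0`.
#'
#' @param p_ra renal arterial pressure (mmHg); `rt` runtime block.
#' @return resistance contribution (mmHg.h/mL).
#' @export
myogenic_resistance <- function(p_ra, rt) {
  rt[["f_mm"]] * rt[["r_aff0"]] *
    (2 * sigmoid((p_ra - rt[["pra0"]]) / rt[["s_mm"]]) - 1)
}

#' TGF afferent resistance contribution
#'
#' Bounded sigmoid of fractional macula-densa sodium deviation, zero at the
#' baseline macula-densa sodium concentration.
#'
#' @param na_md macula-densa sodium concentration (mEq/mL); `rt` runtime.
#' @return resistance contribution (mmHg.h/mL).
#' @export
tgf_resistance <- function(na_md, rt) {
  if (any(na_md <= 0)) stop("macula-densa sodium must be positive")
  rt[["f_tgf"]] * rt[["r_aff0"]] *
    (2 * sigmoid((na_md / rt[["na_md0"]] - 1) / rt[["s_tgf"]]) - 1)
}

#' Angiotensin-modulated efferent resistance
#'
#' Bounded increasing function of relative Ang II anchored at baseline:
#' dilation (resistance below baseline) when Ang II falls below 1.
#'
#' @param c_angii relative Ang II; `rt` runtime block.
#' @return efferent resistance (mmHg.h/mL).
#' @export
efferent_resistance <- function(c_angii, rt) {
  # tolerates transient integrator undershoot below 0: the logistic is
  # defined and bounded for any real argument
  rt[["r_eff0"]] * anchored_logistic(c_angii, rt[["eff_min"]], rt[["eff_max"]],
                                     1, rt[["s_eff"]])
}

# Total afferent resistance: additive composition floored softly at 5% of
# baseline so saturated dilation cannot drive it non-positive.
afferent_resistance <- function(p_ra, na_md, rt) {
  raw <- rt[["r_aff0"]] + myogenic_resistance(p_ra, rt) + tgf_resistance(na_md, rt)
  floor_r <- 0.05 * rt[["r_aff0"]]
  w <- 0.02 * rt[["r_aff0"]]
  z <- (raw - floor_r) / w
  floor_r + ifelse(z > 30, raw - floor_r, w * log1p(exp(pmax(pmin(z, 30), -30))))
}

#' Proximal tubule node
#'
#' Water and sodium reabsorbed together at the aldosterone-regulated
#' fraction `r_P = p_P` (glomerulotubular balance: the fraction, not the
#' absolute rate, is controlled); outflow sodium concentration equals
#' inflow concentration.
#'
#' @param j_gfr,f_gfr water (mL/h) and sodium (mEq/h) inflows.
#' @param c_ald relative aldosterone concentration.
#' @param rt runtime block.
#' @return list `r_p, j_pn, f_pn, j_pv, f_pv`.
#' @export
proximal_node <- function(j_gfr, f_gfr, c_ald, rt) {
  r_p <- anchored_logistic(c_ald, rt[["r_p_lo"]], rt[["r_p_hi"]],
                           rt[["r_p0"]], rt[["g_rp"]])
  list(r_p = r_p, j_pn = j_gfr * (1 - r_p), f_pn = f_gfr * (1 - r_p),
       j_pv = j_gfr * r_p, f_pv = f_gfr * r_p)
}

#' Thin descending limb node
#'
#' Sodium-impermeable; water reabsorption fraction is an inverse sigmoid of
#' the relative water inflow (slower flow, more reabsorption) -- the main
#' flow-dependence behind pressure diuresis.
#'
#' @param j_pn,f_pn inflows; `rt` runtime block.
#' @return list `r_n, j_nk, f_nk, j_nv`.
#' @export
descending_limb_node <- function(j_pn, f_pn, rt) {
  r_n <- anchored_logistic(j_pn / rt[["j_pn0"]], rt[["r_n_lo"]], rt[["r_n_hi"]],
                           rt[["r_n0"]], -rt[["g_rn"]])
  list(r_n = r_n, j_nk = j_pn * (1 - r_n), f_nk = f_pn, j_nv = j_pn * r_n)
}

#' Thick ascending limb node
#'
#' Water-impermeable; actively reabsorbs the fixed fraction `p_K`
#' (approximately 60%) of sodium inflow at any flow rate.
#'
#' @param j_nk,f_nk inflows; `rt` runtime block.
#' @return list `p_k, j_ke, f_ke, f_kv`.
#' @export
ascending_limb_node <- function(j_nk, f_nk, rt) {
  p_k <- rt[["p_k"]]
  list(p_k = p_k, j_ke = j_nk, f_ke = f_nk * (1 - p_k), f_kv = f_nk * p_k)
}

#' Early distal tubule node (macula densa)
#'
#' Water-impermeable; passive sodium reabsorption fraction is an inverse
#' sigmoid of relative sodium inflow. The outflow concentration is the
#' macula-densa sodium concentration driving TGF and renin release.
#'
#' @param j_ke,f_ke inflows; `rt` runtime block.
#' @return list `p_e, j_ec, f_ec, f_ev, na_md` (`na_md` in mEq/mL).
#' @export
early_distal_node <- function(j_ke, f_ke, rt) {
  if (j_ke <= 0) stop("early distal node: zero water flow, concentration undefined")
  p_e <- anchored_logistic(f_ke / rt[["f_ke0"]], rt[["p_e_lo"]], rt[["p_e_hi"]],
                           rt[["p_e0"]], -rt[["g_pe"]])
  f_ec <- f_ke * (1 - p_e)
  list(p_e = p_e, j_ec = j_ke, f_ec = f_ec, f_ev = f_ke * p_e,
       na_md = f_ec / j_ke)
}

#' Collecting duct node
#'
#' Hormonal control of the final fractions: ADH sets the pure-water
#' reabsorption fraction `r_C`, aldosterone the sodium fraction `p_C`; the
#' remainders are urinary output and urinary sodium.
#'
#' @param j_ec,f_ec inflows; `c_adh`, `c_ald` relative hormone
#'   concentrations; `rt` runtime block.
#' @return list `r_c, p_c, j_uo, f_uo, na_uo` (`na_uo` in mEq/mL).
#' @export
collecting_duct_node <- function(j_ec, f_ec, c_adh, c_ald, rt) {
  r_c <- anchored_logistic(c_adh, rt[["r_c_lo"]], rt[["r_c_hi"]],
                           rt[["r_c0"]], rt[["g_rc"]])
  p_c <- anchored_logistic(c_ald, rt[["p_c_lo"]], rt[["p_c_hi"]],
                           rt[["p_c0n"]], rt[["g_pc_ald"]])
  j_uo <- j_ec * (1 - r_c)
  if (j_uo <= 0) stop("collecting duct: zero urinary output, concentration undefined")
  f_uo <- f_ec * (1 - p_c)
  list(r_c = r_c, p_c = p_c, j_uo = j_uo, f_uo = f_uo, na_uo = f_uo / j_uo)
}

#' Compose the nephron chain
#'
#' Runs the four nodes in order starting from `F_GFR = J_GFR * Na_plasma`
#' and returns every flow, fraction, the macula-densa sodium and the urine
#' composition. Node-wise and chain-wise water/sodium balance hold by
#' construction.
#'
#' @param j_gfr GFR (mL/h); `na_plasma` plasma sodium (mEq/mL);
#'   `c_ald`, `c_adh` relative hormones; `rt` runtime block.
#' @return named list of all chain quantities.
#' @export
nephron_chain <- function(j_gfr, na_plasma, c_ald, c_adh, rt) {
  f_gfr <- j_gfr * na_plasma
  p <- proximal_node(j_gfr, f_gfr, c_ald, rt)
  n <- descending_limb_node(p$j_pn, p$f_pn, rt)
  k <- ascending_limb_node(n$j_nk, n$f_nk, rt)
  e <- early_distal_node(k$j_ke, k$f_ke, rt)
  cd <- collecting_duct_node(e$j_ec, e$f_ec, c_adh, c_ald, rt)
  c(list(j_gfr = j_gfr, f_gfr = f_gfr), p, n, k, e, cd)
}

# Coupled renal solve: the TGF loop makes macula-densa sodium an implicit
# quantity (Na_MD -> R_TGF -> RPF/GFR -> chain -> Na_MD). The composed map is
# strictly decreasing in Na_MD, so bracketed bisection finds the unique fixed
# point. `pi_c` and `na_plasma` come from volume kinetics, hormones from the
# hormone states; with `renal_mode = 1` the arterial pressure is forced
# (verification sweeps) instead of taken from the cardiovascular block.
renal_solve <- function(map, cvp, pi_c, na_plasma, c_angii, c_ald, c_adh, rt) {
  if (rt[["renal_mode"]] == 1) {
    p_ra <- rt[["pra_forced"]]; p_rv <- rt[["prv0"]]
  } else {
    pr <- renal_pressures(map, cvp, rt)
    p_ra <- pr$p_ra; p_rv <- pr$p_rv
  }
  r_eff <- efferent_resistance(c_angii, rt)
  eval_chain <- function(na_md) {
    r_aff <- afferent_resistance(p_ra, na_md, rt)
    j_rpf <- max((p_ra - p_rv), 0) / (r_aff + r_eff + rt[["r_rv"]])
    p_g <- glomerular_pressure(j_rpf, r_eff, rt[["r_rv"]], p_rv)
    pi_g <- glomerular_oncotic(p_g, rt[["p_b"]], pi_c,
                               rt[["lambda_c"]], rt[["lambda_p"]])
    j_gfr <- gfr(p_g, rt[["p_b"]], pi_g, rt[["kfg"]], rt[["gfr_soft_w"]])
    ch <- nephron_chain(j_gfr, na_plasma, c_ald, c_adh, rt)
    c(ch, list(r_aff = r_aff, j_rpf = j_rpf, p_g = p_g, pi_g = pi_g,
               p_ra = p_ra, p_rv = p_rv, r_eff = r_eff))
  }
  lo <- 1e-5; hi <- 1.0  # mEq/mL bracket: residual is + at lo, - at hi
  g <- function(x) eval_chain(x)$na_md - x
  for (i in 1:80) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  na_md <- 0.5 * (lo + hi)
  out <- eval_chain(na_md)
  out$na_md_fp <- na_md
  out$r_mm <- myogenic_resistance(p_ra, rt)
  out$r_tgf <- tgf_resistance(na_md, rt)
  out
}
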