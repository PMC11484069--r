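# RAAS (renin -> angiotensin II -> aldosterone) and ADH dynamics as
# normalized first-order secretion/clearance ODEs. Concentrations are
# relative to their pre-injury baselines (baseline = 1), so every law is of
# the form dC/dt = k * (S(inputs) - C) with S = 1 at baseline inputs;
# secretion drives are floored at zero so no concentration can be driven
# non-positive.

#' Renin dynamics
#'
#' Secretion is inverse-linear in the fractional macula-densa sodium
#' deviation (macula densa cells inhibit renin release when their sodium
#' load rises); clearance is first-order.
#'
#' @param na_md macula-densa sodium (mEq/mL); `c_renin` relative renin;
#'   `rt` runtime block.
#' @return list `dC` (derivative) and `secretion` (relative release rate).
#' @export
renin_rhs <- function(na_md, c_renin, rt) {
  s <- max(0, 1 - rt[["g_renin"]] * (na_md / rt[["na_md0"]] - 1))
  list(dC = rt[["k_renin"]] * (s - c_renin), secretion = s)
}

#' Angiotensin II dynamics with secretion delay
#'
#' The renin signal passes through a first-order lag of time constant
#' `tau_d` (the release delay), then drives secretion linearly in the
#' fractional lagged-renin change; clearance is first-order (hepatic).
#'
#' @param c_renin,l_angii,c_angii states; `rt` runtime block.
#' @return list `dL`, `dC`.
#' @export
angii_rhs <- function(c_renin, l_angii, c_angii, rt) {
  s <- max(0, 1 + rt[["g_angii"]] * (l_angii - 1))
  list(dL = (c_renin - l_angii) / rt[["tau_d"]],
       dC = rt[["k_angii"]] * (s - c_angii))
}

#' Aldosterone dynamics
#'
#' Secretion is an exponential of the weighted sum of the two drives:
#' negative-linear in fractional plasma sodium deviation and positive in the
#' Ang II deviation; clearance is first-order (hepatic + renal).
#'
#' @param na_plasma plasma sodium (mEq/mL); `c_angii`, `c_ald` states;
#'   `rt` runtime block.
#' @return list `dC`, `secretion`.
#' @export
aldosterone_rhs <- function(na_plasma, c_angii, c_ald, rt) {
  dna <- na_plasma / rt[["na_plasma0"]] - 1
  s <- exp(-rt[["w_na"]] * dna + rt[["w_a"]] * (c_angii - 1))
  list(dC = rt[["k_ald"]] * (s - c_ald), secretion = s)
}

#' ADH dynamics
#'
#' Secretion is an exponential of the weighted sum of fractional changes in
#' plasma volume (baroreceptor, negative) and plasma sodium (osmoreceptor,
#' positive, with the larger sensitivity `w_s > w_v`); clearance is
#' first-order (hepatic + renal).
#'
#' @param v_p plasma volume (mL); `na_plasma` plasma sodium (mEq/mL);
#'   `c_adh` state; `rt` runtime block.
#' @return list `dC`, `secretion`.
#' @export
adh_rhs <- function(v_p, na_plasma, c_adh, rt) {
  dv <- v_p / rt[["v_p0"]] - 1
  dna <- na_plasma / rt[["na_plasma0"]] - 1
  s <- exp(-rt[["w_v"]] * dv + rt[["w_s"]] * dna)
  list(dC = rt[["k_adh"]] * (s - c_adh), secretion = s)
}

# All five hormone derivatives at once.
hormone_rhs <- function(state, na_md, na_plasma, rt) {
  r <- renin_rhs(na_md, state[["C_renin"]], rt)
  a <- angii_rhs(state[["C_renin"]], state[["L_angII"]], state[["C_angII"]], rt)
  al <- aldosterone_rhs(na_plasma, state[["C_angII"]], state[["C_ald"]], rt)
  ad <- adh_rhs(state[["V_P"]], na_plasma, state[["C_adh"]], rt)
  list(dC_renin = r$dC, dL_angII = a$dL, dC_angII = a$dC,
       dC_ald = al$dC, dC_adh = ad$dC, s_renin = r$secretion)
}
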