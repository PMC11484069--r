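# Transient burn-injury perturbation signals. Each channel is a
# double-exponential pulse: zero before injury, amplitude-normalized peak,
# decaying back to baseline -- the "transient and disappearing" disturbance
# contract. Fast channels (capillary destruction, pore-size increase,
# burnt-tissue negative pressure, protein denaturation, wound gate onset)
# share one (tau1, tau2) pair; the slower vasomotor channels share another.

#' Double-exponential perturbation time course
#'
#' `A * (exp(-t/tau2) - exp(-t/tau1)) / n` for `t >= 0`, 0 before injury,
#' with `n` chosen so the peak equals `A` exactly (analytic maximum at
#' `t* = tau1 tau2 / (tau2 - tau1) * log(tau2/tau1)`).
#'
#' @param t time, hours post-burn (vectorized).
#' @param amplitude peak value `A >= 0`.
#' @param tau1 onset time constant (h), must be `< tau2`.
#' @param tau2 decay time constant (h).
#' @return signal value(s).
#' @export
perturbation_timecourse <- function(t, amplitude, tau1, tau2) {
  if (tau1 >= tau2) stop("tau1 must be strictly less than tau2")
  tpk <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  norm <- exp(-tpk / tau2) - exp(-tpk / tau1)
  ifelse(t < 0, 0, amplitude * (exp(-t / tau2) - exp(-t / tau1)) / norm)
}

#' Peak time of the double-exponential pulse
#' @inheritParams perturbation_timecourse
#' @return hours post-burn at which the pulse attains its amplitude.
#' @export
perturbation_peak_time <- function(tau1, tau2) {
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' Evaluate all perturbation channels at time t
#'
#' Maps the per-channel pulses onto the model quantities they drive:
#' multiplicative increases of burnt-tissue and systemic capillary
#' conductance, a fractional drop of the reflection coefficients (clipped so
#' sigma never leaves \[0, 1\]), a negative hydrostatic offset in burnt
#' tissue, a first-order albumin denaturation rate, the wound gate for
#' dermal losses, and the net vasomotor multiplier
#' `M_MAP = 1 + constrict - dilate` (floored at 0.1).
#'
#' @param t hours post-burn.
#' @param rt runtime constant block ([runtime_constants()]); set
#'   `perturb_on = FALSE` there to obtain the identity (unperturbed) signals.
#' @return list of channel values at `t`.
#' @export
apply_perturbations <- function(t, rt) {
  if (rt[["perturb_on"]] == 0 || t < 0) {
    return(list(kf_bt = 0, kf_sys = 0, sigma_drop = 0, pbt_offset = 0,
                denat_rate = 0, wound_gate = 0, m_map = 1))
  }
  fast <- function(a) perturbation_timecourse(t, a, rt[["tau1_fast"]], rt[["tau2_fast"]])
  slow <- function(a) perturbation_timecourse(t, a, rt[["tau1_slow"]], rt[["tau2_slow"]])
  list(
    kf_bt = fast(rt[["amp_kf_bt"]]),
    kf_sys = fast(rt[["amp_kf_sys"]]),
    sigma_drop = fast(rt[["amp_sigma"]]),
    pbt_offset = fast(rt[["amp_pbt"]]),
    denat_rate = fast(rt[["amp_den"]]),
    wound_gate = slow(1),
    m_map = max(0.1, 1 + slow(rt[["amp_constrict"]]) - slow(rt[["amp_dilate"]]))
  )
}
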