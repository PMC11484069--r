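# Coupled simulation: wires perturbations -> circulatory equilibrium ->
# renal pressures/flows -> nephron chain -> hormone and volume-kinetic
# derivatives, integrates with a stiff adaptive method, and runs protocol
# controllers that generate hourly infusion schedules.

#' Full-model right-hand side (reference implementation)
#'
#' Composes the documented module operations in the coupling order:
#' perturbation signals, circulatory equilibrium, renal pressures and the
#' TGF-coupled nephron chain, hormone derivatives, then the volume-kinetic
#' derivatives. The compiled integrator core is an exact translation of this
#' function; their agreement is asserted in the test suite.
#'
#' @param t hours post-burn.
#' @param state named state vector ([initialize_state()]).
#' @param rt runtime constant block ([runtime_constants()]), including the
#'   current infusion segment (`j_inf`, `na_inf`, `q_inf`).
#' @return list `(derivatives, outputs)`: the state derivative vector and the
#'   named algebraic outputs.
#' @export
model_rhs <- function(t, state, rt) {
  perturb <- apply_perturbations(t, rt)
  frozen <- rt[["vk_frozen"]] != 0

  if (frozen) {
    na_plasma <- rt[["na_plasma0"]]
    pi_c <- rt[["pi_c0"]]
  } else {
    na_plasma <- state[["Na_ECF"]] / (state[["V_P"]] + state[["V_BT"]] + state[["V_IT"]])
    pi_c <- rt[["k_pi"]] * state[["A_P"]] / state[["V_P"]]
  }

  if (rt[["renal_mode"]] == 1) {
    cv <- list(msp = rt[["msp0"]], tpr = rt[["tpr0"]], cvp = 0, co = 0,
               vr = 0, map = 0)
    renal <- renal_solve(NA, NA, pi_c, na_plasma, state[["C_angII"]],
                         state[["C_ald"]], state[["C_adh"]], rt)
  } else {
    v_b <- state[["V_P"]] + rt[["rcv"]]
    cv <- cv_block(v_b, state[["C_angII"]], perturb$m_map, rt)
    renal <- renal_solve(cv$map, cv$cvp, pi_c, na_plasma, state[["C_angII"]],
                         state[["C_ald"]], state[["C_adh"]], rt)
  }

  h <- hormone_rhs(state, renal$na_md_fp, na_plasma, rt)

  if (frozen) {
    d_vk <- stats::setNames(rep(0, 7), vk_state_names())
    fluxes <- list(j_c_bt = 0, j_c_it = 0, j_l_bt = 0, j_l_it = 0,
                   j_evap = 0, j_exud = 0)
    p_c <- rt[["p_c0"]]
    j_i <- 0; f_i <- 0
  } else {
    j_i <- rt[["j_maint"]] + rt[["j_inf"]]
    f_i <- rt[["j_maint"]] * rt[["na_maint"]] + rt[["j_inf"]] * rt[["na_inf"]]
    vk <- vk_rhs(state, rt, perturb, j_i = j_i, q_i = rt[["q_inf"]],
                 f_i = f_i, j_uo = renal$j_uo, f_uo = renal$f_uo)
    d_vk <- stats::setNames(
      c(vk$dV_P, vk$dA_P, vk$dV_BT, vk$dV_IT, vk$dA_BT, vk$dA_IT, vk$dNa_ECF),
      vk_state_names())
    fluxes <- vk$fluxes
    p_c <- vk$pressures$p_c
  }

  deriv <- c(d_vk,
             C_renin = h$dC_renin, L_angII = h$dL_angII,
             C_angII = h$dC_angII, C_ald = h$dC_ald, C_adh = h$dC_adh,
             cum_UO = renal$j_uo, cum_evap = fluxes$j_evap,
             cum_exud = fluxes$j_exud, cum_FUO = renal$f_uo,
             cum_denat = if (frozen) 0 else
               perturb$denat_rate * state[["A_BT"]])

  outputs <- c(
    hct = rt[["rcv"]] / (rt[["rcv"]] + state[["V_P"]]),
    v_b = state[["V_P"]] + rt[["rcv"]],
    pi_c = pi_c, p_c = p_c,
    msp = cv$msp, tpr = cv$tpr, cvp = cv$cvp, co = cv$co, vr = cv$co,
    map = cv$map, m_map = perturb$m_map,
    p_ra = renal$p_ra, p_rv = renal$p_rv, p_g = renal$p_g, pi_g = renal$pi_g,
    j_rpf = renal$j_rpf, j_gfr = renal$j_gfr,
    r_aff = renal$r_aff, r_eff = renal$r_eff,
    r_mm = renal$r_mm, r_tgf = renal$r_tgf,
    na_md = 1000 * renal$na_md_fp,
    r_p = renal$r_p, r_n = renal$r_n, p_e = renal$p_e,
    r_c = renal$r_c, p_cn = renal$p_c,
    j_uo = renal$j_uo, f_uo = renal$f_uo, na_uo = 1000 * renal$na_uo,
    j_pn = renal$j_pn, j_ec = renal$j_ec, na_plasma = 1000 * na_plasma,
    j_c_bt = fluxes$j_c_bt, j_c_it = fluxes$j_c_it,
    j_l_bt = fluxes$j_l_bt, j_l_it = fluxes$j_l_it,
    j_evap = fluxes$j_evap, j_exud = fluxes$j_exud,
    j_i_total = j_i, f_i = f_i, s_renin = h$s_renin
  )
  list(deriv, outputs)
}

#' Infusion schedule
#'
#' Piecewise-constant, left-closed hourly fluid dose. The only shipped fluid
#' is Lactated Ringer's (`[Na] = 130 mEq/L`, no albumin).
#'
#' @param time_h breakpoint times (hours post-burn), strictly increasing,
#'   starting at the schedule onset.
#' @param rate_mL_per_h non-negative rates; `rates[i]` applies on
#'   `[time_h[i], time_h[i+1])`.
#' @param fluid_type fluid label, currently `"LR"`.
#' @return tibble of class `burn_schedule`.
#' @export
infusion_schedule <- function(time_h, rate_mL_per_h, fluid_type = "LR") {
  stopifnot(length(time_h) == length(rate_mL_per_h))
  if (any(diff(time_h) <= 0)) stop("breakpoints must be strictly increasing")
  if (any(rate_mL_per_h < 0)) stop("rates must be non-negative")
  out <- tibble::tibble(time_h = as.numeric(time_h),
                        rate_mL_per_h = as.numeric(rate_mL_per_h),
                        fluid_type = fluid_type)
  class(out) <- c("burn_schedule", class(out))
  out
}

# Rate lookup (left-closed intervals; 0 before the first breakpoint).
schedule_rate <- function(schedule, t) {
  i <- findInterval(t, schedule$time_h)
  ifelse(i == 0, 0, schedule$rate_mL_per_h[pmax(i, 1)])
}

#' Resuscitation protocol
#'
#' Either no fluids (`"none"`, paradigm P1), a fixed over-resuscitation rate
#' (`"fixed_rate"`, paradigm P3), or hourly urine-output-titrated Lactated
#' Ringer's (`"uo_titrated"`, paradigm P2 and the clinical protocol): if the
#' previous hour's urine output is below the target band the rate is
#' multiplied by `up_step`, above the band by `down_step`, inside it held.
#'
#' @param kind `"none"`, `"uo_titrated"` or `"fixed_rate"`.
#' @param band target urine-output band `c(low, high)`; units `"mL/kg/h"`
#'   (animals) or `"mL/h"` (humans).
#' @param band_units band units, see above.
#' @param up_step,down_step multiplicative titration steps.
#' @param review_every controller review interval (h), >= 1.
#' @param fixed_rate rate for `"fixed_rate"` (mL/h).
#' @param initial_rate starting rate (mL/h); defaults to the Parkland-style
#'   first-8-hour rate `4 * weight * TBSA% / 16` when the simulation profile
#'   is known (see [parkland_initial_rate()]).
#' @param start_time hour resuscitation begins (1 h post-burn for sheep).
#' @param max_rate clip for titrated rates (mL/h).
#' @return list of class `burn_protocol`.
#' @export
resuscitation_protocol <- function(kind = c("none", "uo_titrated", "fixed_rate"),
                                   band = c(1, 1.5),
                                   band_units = c("mL/kg/h", "mL/h"),
                                   up_step = 1.25, down_step = 0.8,
                                   review_every = 1, fixed_rate = 500,
                                   initial_rate = NULL, start_time = 0,
                                   max_rate = 2000) {
  kind <- match.arg(kind)
  band_units <- match.arg(band_units)
  if (band[1] >= band[2]) stop("band low must be below band high")
  if (review_every < 1) stop("review interval must be >= 1 h")
  structure(list(kind = kind, band = band, band_units = band_units,
                 up_step = up_step, down_step = down_step,
                 review_every = review_every, fixed_rate = fixed_rate,
                 initial_rate = initial_rate, start_time = start_time,
                 max_rate = max_rate),
            class = "burn_protocol")
}

#' Canonical protocol presets
#'
#' `"P1"`: no IV fluids; `"P2"`: urine-output-titrated LR to 1-1.5 mL/kg/h
#' (pigs); `"P3"`: fixed 500 mL/h over-resuscitation; `"sheep"`: titrated to
#' 1-2 mL/kg/h starting 1 h post-burn; `"human"`: titrated to 30-50 mL/h
#' absolute with a Parkland-style initial rate.
#'
#' @param name preset name.
#' @return a [resuscitation_protocol()].
#' @export
protocol_preset <- function(name = c("P1", "P2", "P3", "sheep", "human")) {
  name <- match.arg(name)
  switch(name,
    P1 = resuscitation_protocol("none"),
    P2 = resuscitation_protocol("uo_titrated", band = c(1, 1.5),
                                band_units = "mL/kg/h"),
    P3 = resuscitation_protocol("fixed_rate", fixed_rate = 500),
    sheep = resuscitation_protocol("uo_titrated", band = c(1, 2),
                                   band_units = "mL/kg/h", start_time = 1),
    human = resuscitation_protocol("uo_titrated", band = c(30, 50),
                                   band_units = "mL/h")
  )
}

#' Parkland-style initial infusion rate
#'
#' `4 mL x weight(kg) x TBSA(%)` over 24 h with half given in the first
#' 8 h, i.e. an initial rate of `4 * W * TBSA% / 16` mL/h.
#'
#' @param weight kg; `tbsa` burned fraction.
#' @return initial rate (mL/h).
#' @export
parkland_initial_rate <- function(weight, tbsa) {
  4 * weight * (100 * tbsa) / 16
}

#' Protocol controller step
#'
#' Pure decision rule mapping the last review interval's urine output to the
#' next rate. Exported so the controller arithmetic is testable in
#' isolation; [simulate_burn()] applies it at every hourly review.
#'
#' @param protocol a [burn_protocol][resuscitation_protocol()].
#' @param last_rate current rate (mL/h).
#' @param uo_last urine output over the last review interval (mL).
#' @param weight subject weight (kg), used for per-kg bands.
#' @return next rate (mL/h).
#' @export
run_protocol_controller <- function(protocol, last_rate, uo_last, weight) {
  if (protocol$kind == "none") return(0)
  if (protocol$kind == "fixed_rate") return(protocol$fixed_rate)
  uo_rate <- uo_last / protocol$review_every
  if (protocol$band_units == "mL/kg/h") uo_rate <- uo_rate / weight
  rate <- if (uo_rate < protocol$band[1]) {
    last_rate * protocol$up_step
  } else if (uo_rate > protocol$band[2]) {
    last_rate * protocol$down_step
  } else {
    last_rate
  }
  min(max(rate, 0), protocol$max_rate)
}

#' Simulate burn injury and resuscitation
#'
#' Integrates the coupled model from the pre-injury steady state at `t = 0`
#' under either a fixed infusion schedule or a protocol controller that
#' titrates the rate at hourly reviews. Integration restarts at every
#' schedule breakpoint and review point (lsoda, stiff-capable, rtol 1e-6);
#' output is dense at `dt_out` spacing and deterministic given the inputs.
#'
#' @param profile a [burn_profile()].
#' @param params completed registry; defaults to the species preset derived
#'   for `profile`.
#' @param schedule a [infusion_schedule()]; mutually exclusive with
#'   `protocol`.
#' @param protocol a [resuscitation_protocol()].
#' @param horizon hours to simulate.
#' @param dt_out output grid spacing (h).
#' @param maintenance include the constraint-derived baseline maintenance
#'   intake (used for steady-state checks).
#' @param perturb enable the burn perturbation signals.
#' @param engine `"compiled"` (default) or `"r"` (reference implementation).
#' @param rtol,atol_scale integrator tolerances; absolute tolerance per state
#'   is `atol_scale * max(|y0|, 1)`.
#' @return object of class `burn_sim`: list with `trajectory` (tibble:
#'   `time_h`, the 16 integrated states, and every algebraic output),
#'   `schedule` (realized), `profile`, `params`.
#' @export
simulate_burn <- function(profile, params = NULL, schedule = NULL,
                          protocol = NULL, horizon = 24, dt_out = 0.1,
                          maintenance = FALSE, perturb = TRUE,
                          engine = c("compiled", "r"),
                          rtol = 1e-6, atol_scale = 1e-8) {
  engine <- match.arg(engine)
  if (is.null(params)) {
    params <- derive_constrained_parameters(profile, param_registry(profile$species))
  }
  if (!is.null(schedule) && !is.null(protocol)) {
    stop("give either a schedule or a protocol, not both")
  }
  rt <- runtime_constants(profile, params, maintenance = maintenance,
                          perturb_on = perturb)
  y <- initialize_state(profile, params)
  atol <- atol_scale * pmax(abs(y), 1)

  if (!is.null(protocol)) {
    segs <- protocol_segments_init(protocol, profile, horizon)
  } else {
    if (is.null(schedule)) schedule <- infusion_schedule(0, 0)
    brk <- sort(unique(c(0, schedule$time_h[schedule$time_h < horizon], horizon)))
    segs <- tibble::tibble(t0 = brk[-length(brk)], t1 = brk[-1])
    segs$rate <- schedule_rate(schedule, segs$t0)
  }

  pieces <- vector("list", nrow(segs))
  rate_real <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$t0[i]; t1 <- segs$t1[i]
    if (!is.null(protocol)) {
      rate <- protocol_rate_update(protocol, profile, segs, i, rate_real, pieces)
    } else {
      rate <- segs$rate[i]
    }
    rate_real[i] <- rate
    rt[["j_inf"]] <- rate
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- integrate_segment(y, times, rt, engine, rtol, atol)
    y <- sol$y_end
    pieces[[i]] <- sol$block[if (i == 1) TRUE else -1, , drop = FALSE]
  }
  traj <- tibble::as_tibble(do.call(rbind, pieces))
  names(traj)[1] <- "time_h"

  out <- list(
    trajectory = traj,
    schedule = infusion_schedule(segs$t0, rate_real),
    profile = profile, params = params,
    maintenance = maintenance, perturb = perturb
  )
  class(out) <- "burn_sim"
  out
}

# Segment table for protocol-driven runs: hourly reviews.
protocol_segments_init <- function(protocol, profile, horizon) {
  brk <- seq(0, horizon, by = protocol$review_every)
  if (brk[length(brk)] < horizon) brk <- c(brk, horizon)
  tibble::tibble(t0 = brk[-length(brk)], t1 = brk[-1])
}

# Controller decision for segment i, given realized rates and past pieces.
protocol_rate_update <- function(protocol, profile, segs, i, rate_real, pieces) {
  t0 <- segs$t0[i]
  if (t0 < protocol$start_time) return(0)
  start_rate <- protocol$initial_rate %||%
    parkland_initial_rate(profile$weight, profile$tbsa)
  if (protocol$kind == "none") return(0)
  if (protocol$kind == "fixed_rate") return(protocol$fixed_rate)
  first <- t0 == protocol$start_time ||
    (protocol$start_time < segs$t0[1] && i == 1)
  if (first) return(min(start_rate, protocol$max_rate))
  prev <- pieces[[i - 1]]
  uo_last <- prev[nrow(prev), "cum_UO"] - prev[1, "cum_UO"]
  run_protocol_controller(protocol, rate_real[i - 1], uo_last, profile$weight)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One lsoda call over `times`, returning the trajectory block (time, states,
# outputs) and the end state.
integrate_segment <- function(y, times, rt, engine, rtol, atol) {
  if (engine == "compiled") {
    sol <- deSolve::ode(y = y, times = times, func = "burnmod_derivs",
                        parms = unname(rt), dllname = "burnsim",
                        initfunc = "burnmod_init", nout = length(output_names),
                        outnames = output_names, method = "lsoda",
                        rtol = rtol, atol = atol)
  } else {
    rfun <- function(t, y, parms) {
      res <- model_rhs(t, y, parms)
      list(unname(res[[1]]), res[[2]])
    }
    sol <- deSolve::ode(y = y, times = times, func = rfun, parms = rt,
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  m <- unclass(sol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed at t = ", m[nrow(m), 1])
  }
  colnames(m) <- c("time", names(y), output_names)
  list(block = m, y_end = stats::setNames(m[nrow(m), names(y)], names(y)))
}

#' @export
print.burn_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<burn_sim> %s, %.1f kg, TBSA %.0f%%: %g h, %d time points\n",
              x$profile$species, x$profile$weight, 100 * x$profile$tbsa,
              max(tr$time_h), nrow(tr)))
  cat(sprintf("  24-h style summary at t = %.1f h: HCT %.3f, CVP %.1f mmHg, ",
              max(tr$time_h), tr$hct[nrow(tr)], tr$cvp[nrow(tr)]))
  cat(sprintf("CO %.2f L/min, MAP %.0f mmHg, UO %.0f mL/h\n",
              tr$co[nrow(tr)], tr$map[nrow(tr)], tr$j_uo[nrow(tr)]))
  invisible(x)
}

#' Evaluate the full steady-state operating point
#'
#' Evaluates the model at the pre-injury steady state (perturbations off,
#' maintenance intake on) and returns every algebraic output: the baseline
#' operating point used by the verification and acceptance analyses. A
#' self-consistency check asserts the state derivatives vanish.
#'
#' @param profile a [burn_profile()]; `params` completed registry (preset
#'   default).
#' @param check error if the baseline is not a fixed point (relative
#'   derivative above `tol`).
#' @param tol relative derivative tolerance.
#' @return one-row tibble of baseline outputs.
#' @export
baseline_operating_point <- function(profile, params = NULL, check = TRUE,
                                     tol = 1e-8) {
  if (is.null(params)) {
    params <- derive_constrained_parameters(profile, param_registry(profile$species))
  }
  rt <- runtime_constants(profile, params, maintenance = TRUE, perturb_on = FALSE)
  y <- initialize_state(profile, params)
  res <- model_rhs(-1e-9, y, rt)
  if (check) {
    d <- unlist(res[[1]])[1:12]
    rel <- abs(d) / pmax(abs(y[1:12]), 1)
    if (any(rel > tol)) {
      stop("baseline is not a steady state; max relative derivative ",
           signif(max(rel), 3), " (", names(which.max(rel)), ")")
    }
  }
  tibble::as_tibble(as.list(res[[2]]))
}
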