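#' Subject profile
#'
#' Bundle the subject descriptors that seed every per-subject simulation:
#' species, body weight, fraction of body surface burned (TBSA), baseline
#' hematocrit and, optionally, measured baseline cardiac output and mean
#' arterial pressure. Injury occurs at `t = 0`; all times are hours post-burn.
#'
#' @param species one of `"human"`, `"pig"`, `"sheep"`.
#' @param weight body weight in kg.
#' @param tbsa burned fraction of body surface area, in (0, 1).
#' @param hct0 baseline hematocrit as a fraction, in (0.1, 0.7). Defaults to
#'   the species preset.
#' @param co0 optional baseline cardiac output (L/min); overrides the preset
#'   per-kg scaling when given.
#' @param map0 optional baseline mean arterial pressure (mmHg); overrides the
#'   preset when given.
#' @return an object of class `burn_profile` (a named list).
#' @examples
#' burn_profile("human", weight = 70, tbsa = 0.4)
#' @export
burn_profile <- function(species = c("human", "pig", "sheep"),
                         weight, tbsa, hct0 = NULL,
                         co0 = NULL, map0 = NULL) {
  species <- match.arg(species)
  if (is.null(hct0)) hct0 <- species_defaults(species)$hct0
  stopifnot(is.numeric(weight), length(weight) == 1L, weight > 0)
  if (!(tbsa > 0 && tbsa < 1)) {
    stop("`tbsa` must be a fraction strictly between 0 and 1, got ", tbsa)
  }
  if (!(hct0 > 0.1 && hct0 < 0.7)) {
    stop("`hct0` must lie in (0.1, 0.7), got ", hct0)
  }
  structure(
    list(species = species, weight = weight, tbsa = tbsa, hct0 = hct0,
         co0 = co0, map0 = map0, injury_time = 0),
    class = "burn_profile"
  )
}

#' @export
print.burn_profile <- function(x, ...) {
  cat(sprintf("<burn_profile> %s, %.1f kg, TBSA %.0f%%, HCT0 %.2f\n",
              x$species, x$weight, 100 * x$tbsa, x$hct0))
  invisible(x)
}

species_defaults <- function(species) {
  switch(species,
    human = list(hct0 = 0.40, weight = 70, tbsa = 0.40),
    pig   = list(hct0 = 0.33, weight = 31.7, tbsa = 0.40),
    sheep = list(hct0 = 0.32, weight = 40, tbsa = 0.40)
  )
}

# Registry row constructor kept terse on purpose: name, value, lower, upper,
# class, units, module. Constraint-derived rows carry NA until derived.
.p <- function(name, value, lower, upper, class, units, module) {
  tibble::tibble(name = name, value = value, lower = lower, upper = upper,
                 class = class, units = units, module = module)
}

#' Full model parameter registry
#'
#' Every scalar parameter of the coupled model with its value, bounds, class
#' tag (`subject_invariant`, `subject_specific`, or `constraint_derived`),
#' units and owning module. Constraint-derived entries are `NA` until
#' [derive_constrained_parameters()] fills them from a subject profile and the
#' pre-injury steady-state constraints.
#'
#' @param species species preset applied on top of the shared defaults.
#' @return a tibble with columns `name, value, lower, upper, class, units,
#'   module`.
#' @seealso [derive_constrained_parameters()], [param_census()]
#' @export
param_registry <- function(species = c("human", "pig", "sheep")) {
  species <- match.arg(species)
  inv <- "subject_invariant"; ss <- "subject_specific"; der <- "constraint_derived"
  reg <- dplyr::bind_rows(
    ## -- volume kinetics ----------------------------------------------------
    .p("v_plasma_perkg", 40,    30,   55,  inv, "mL/kg",        "volume_kinetics"),
    .p("v_tissue_perkg", 160,   120,  220, inv, "mL/kg",        "volume_kinetics"),
    .p("c_alb_p0",       0.042, 0.03, 0.055, inv, "g/mL",       "volume_kinetics"),
    .p("c_alb_t0",       0.014, 0.008, 0.025, inv, "g/mL",      "volume_kinetics"),
    .p("pi_c0",          25,    18,   30,  inv, "mmHg",         "volume_kinetics"),
    .p("k_pi",           NA,    NA, NA, der, "mmHg.mL/g",    "volume_kinetics"),
    .p("p_c0",           15,    10,   22,  inv, "mmHg",         "volume_kinetics"),
    .p("g_pc",           20,    5,    60,  inv, "mmHg",         "volume_kinetics"),
    .p("p_t0",           -2,    -5,   0,   inv, "mmHg",         "volume_kinetics"),
    .p("g_t_above",      4,     1,    20,  inv, "mmHg",         "volume_kinetics"),
    .p("g_t_below",      60,    20,   200, inv, "mmHg",         "volume_kinetics"),
    .p("blend_w",        0.01,  0.005, 0.05, inv, "fraction",   "volume_kinetics"),
    .p("kf_perkg",       0.857, 0.2,  3,   ss,  "mL/h/mmHg/kg", "volume_kinetics"),
    .p("sigma0",         0.90,  0.70, 0.98, ss, "dimensionless", "volume_kinetics"),
    .p("sigma_a0",       0.85,  0.60, 0.95, inv, "dimensionless", "volume_kinetics"),
    .p("ps_ratio",       NA,    NA, NA, der, "dimensionless", "volume_kinetics"),
    .p("lymph_gain",     0.5,   0.1,  2,   ss,  "1/mmHg",       "volume_kinetics"),
    .p("lymph_max_mult", 8,     3,    20,  inv, "dimensionless", "volume_kinetics"),
    .p("k_evap_perkg",   1.5,   0,    5,   ss,  "mL/h/kg",      "volume_kinetics"),
    .p("k_exud",         0.01,  0,    0.1, ss,  "1/h",          "volume_kinetics"),
    .p("na_lr",          0.130, 0.125, 0.135, inv, "mEq/mL",    "volume_kinetics"),
    .p("na_plasma0",     0.140, 0.130, 0.150, inv, "mEq/mL",    "volume_kinetics"),
    ## -- burn perturbations -------------------------------------------------
    .p("amp_kf_bt",      2,     0,    30,  ss,  "dimensionless", "burn_perturbations"),
    .p("amp_kf_sys",     0.6,   0,    6,   ss,  "dimensionless", "burn_perturbations"),
    .p("amp_sigma",      0.3,   0,    1,   ss,  "dimensionless", "burn_perturbations"),
    .p("amp_pbt",        8,     0,    40,  ss,  "mmHg",          "burn_perturbations"),
    .p("amp_den",        0.02,  0,    0.2, ss,  "1/h",           "burn_perturbations"),
    .p("amp_constrict",  0.25,  0,    1,   ss,  "dimensionless", "burn_perturbations"),
    .p("amp_dilate",     0.25,  0,    1,   ss,  "dimensionless", "burn_perturbations"),
    .p("tau1_fast",      0.5,   0.1,  2,   inv, "h",             "burn_perturbations"),
    .p("tau2_fast",      8,     3,    24,  inv, "h",             "burn_perturbations"),
    .p("tau1_slow",      1,     0.3,  4,   inv, "h",             "burn_perturbations"),
    .p("tau2_slow",      24,    8,    48,  inv, "h",             "burn_perturbations"),
    ## -- cardiovascular -----------------------------------------------------
    .p("msp0",           7,     4,    12,  inv, "mmHg",          "cardiovascular"),
    .p("k_msp",          3.5,   1,    8,   ss,  "dimensionless", "cardiovascular"),
    .p("cvp0",           4,     0,    8,   ss,  "mmHg",          "cardiovascular"),
    .p("co0_perkg",      0.0714, 0.04, 0.12, ss, "L/min/kg",     "cardiovascular"),
    .p("map0",           93,    60,   120, ss,  "mmHg",          "cardiovascular"),
    .p("tpr0",           NA,    NA, NA, der, "mmHg.min/L",    "cardiovascular"),
    .p("tpr_min_frac",   0.4,   0.1,  0.8, inv, "dimensionless", "cardiovascular"),
    .p("tpr_max_frac",   2.5,   1.5,  5,   inv, "dimensionless", "cardiovascular"),
    .p("s_tpr",          1.5,   0.3,  5,   inv, "dimensionless", "cardiovascular"),
    .p("co_max_frac",    2.5,   1.5,  4,   inv, "dimensionless", "cardiovascular"),
    .p("s_co",           2,     0.5,  6,   ss,  "mmHg",          "cardiovascular"),
    .p("co_mid",         NA,    NA, NA, der, "mmHg",          "cardiovascular"),
    .p("kappa_v",        NA,    NA, NA, der, "dimensionless", "cardiovascular"),
    .p("cvp_floor",      -10,   -15,  -5,  inv, "mmHg",          "cardiovascular"),
    ## -- renal --------------------------------------------------------------
    .p("rpf0_perkg",     535.7, 300,  800, inv, "mL/h/kg",       "renal"),
    .p("pra0",           85,    70,   100, inv, "mmHg",          "renal"),
    .p("a1",             1,     0.5,  1.5, inv, "dimensionless", "renal"),
    .p("a0",             NA,    NA, NA, der, "mmHg",          "renal"),
    .p("prv0",           6,     2,    10,  inv, "mmHg",          "renal"),
    .p("b1",             1,     0.5,  1.5, inv, "dimensionless", "renal"),
    .p("b0",             NA,    NA, NA, der, "mmHg",          "renal"),
    .p("pg0",            60,    45,   75,  inv, "mmHg",          "renal"),
    .p("p_b",            18,    10,   25,  inv, "mmHg",          "renal"),
    .p("lambda_c",       1.0,   0.8,  1.2, inv, "dimensionless", "renal"),
    .p("lambda_p",       0.25,  0.05, 0.6, inv, "dimensionless", "renal"),
    .p("ff0",            0.20,  0.15, 0.25, inv, "fraction",     "renal"),
    .p("uo_frac0",       0.01,  0.003, 0.03, inv, "fraction",    "renal"),
    .p("r_rv_share",     0.1667, 0.05, 0.4, inv, "fraction",     "renal"),
    .p("r_aff0",         NA,    NA, NA, der, "mmHg.h/mL",     "renal"),
    .p("r_eff0",         NA,    NA, NA, der, "mmHg.h/mL",     "renal"),
    .p("r_rv",           NA,    NA, NA, der, "mmHg.h/mL",     "renal"),
    .p("kfg",            NA,    NA, NA, der, "mL/h/mmHg",     "renal"),
    .p("f_mm",           1.2,   0,    3,   inv, "dimensionless", "renal"),
    .p("s_mm",           15,    5,    40,  inv, "mmHg",          "renal"),
    .p("f_tgf",          1.2,   0,    3,   inv, "dimensionless", "renal"),
    .p("s_tgf",          0.25,  0.05, 1,   inv, "fraction",      "renal"),
    .p("eff_min",        0.5,   0.2,  0.9, inv, "dimensionless", "renal"),
    .p("eff_max",        1.5,   1.1,  3,   inv, "dimensionless", "renal"),
    .p("s_eff",          0.6,   0.1,  2,   inv, "dimensionless", "renal"),
    .p("r_p0",           0.70,  0.65, 0.75, inv, "fraction",     "renal"),
    .p("r_p_lo",         0.55,  0.40, 0.64, inv, "fraction",     "renal"),
    .p("r_p_hi",         0.85,  0.76, 0.95, inv, "fraction",     "renal"),
    .p("g_rp",           1.7,   0,    3,   inv, "dimensionless", "renal"),
    .p("r_n0",           0.5,   0.3,  0.7, inv, "fraction",      "renal"),
    .p("r_n_lo",         0.05,  0.01, 0.2, inv, "fraction",      "renal"),
    .p("r_n_hi",         0.85,  0.75, 0.99, inv, "fraction",     "renal"),
    .p("g_rn",           4.8,   0.2,  10,  inv, "dimensionless", "renal"),
    .p("p_k",            0.60,  0.55, 0.65, inv, "fraction",     "renal"),
    .p("p_e0",           0.70,  0.5,  0.85, inv, "fraction",     "renal"),
    .p("p_e_lo",         0.10,  0.02, 0.3, inv, "fraction",      "renal"),
    .p("p_e_hi",         0.95,  0.86, 0.99, inv, "fraction",     "renal"),
    .p("g_pe",           4.0,   0.1,  5,   inv, "dimensionless", "renal"),
    .p("r_c0",           NA,    0,    1,   der, "fraction",      "renal"),
    .p("r_c_lo",         0.05,  0.01, 0.3, inv, "fraction",      "renal"),
    .p("r_c_hi",         0.95,  0.8,  0.99, inv, "fraction",     "renal"),
    .p("g_rc",           0.8,   0.1,  5,   inv, "dimensionless", "renal"),
    .p("p_c0n",          0.30,  0.1,  0.6, inv, "fraction",      "renal"),
    .p("p_c_lo",         0.05,  0.01, 0.2, inv, "fraction",      "renal"),
    .p("p_c_hi",         0.90,  0.7,  0.99, inv, "fraction",     "renal"),
    .p("g_pc_ald",       0.8,   0.1,  5,   inv, "dimensionless", "renal"),
    .p("gfr_soft_w",     0.1,   0.01, 1,   inv, "mL/h",          "renal"),
    ## -- hormones -----------------------------------------------------------
    .p("k_renin",        2,     0.5,  6,   inv, "1/h",           "hormones"),
    .p("g_renin",        6,     1,    15,  ss,  "dimensionless", "hormones"),
    .p("tau_d",          0.25,  0.05, 1,   inv, "h",             "hormones"),
    .p("k_angii",        2,     0.5,  6,   inv, "1/h",           "hormones"),
    .p("g_angii",        1,     0.5,  2,   inv, "dimensionless", "hormones"),
    .p("k_ald",          1,     0.3,  4,   inv, "1/h",           "hormones"),
    .p("w_na",           5,     1,    15,  inv, "dimensionless", "hormones"),
    .p("w_a",            1,     0.3,  3,   inv, "dimensionless", "hormones"),
    .p("k_adh",          2,     0.5,  6,   inv, "1/h",           "hormones"),
    .p("w_v",            3,     1,    8,   ss,  "dimensionless", "hormones"),
    .p("w_s",            6,     2,    12,  inv, "dimensionless", "hormones")
  )
  preset <- species_param_overrides(species)
  if (length(preset)) {
    idx <- match(names(preset), reg$name)
    reg$value[idx] <- unlist(preset)
  }
  class(reg) <- c("burn_params", class(reg))
  reg
}

# Species-level value overrides applied on top of the shared (human) defaults.
# Baseline hemodynamics differ between species; the renal fraction anchors do
# not (they are the physiological design targets shared by all presets).
species_param_overrides <- function(species) {
  switch(species,
    human = list(),
    pig   = list(co0_perkg = 0.090, map0 = 95, cvp0 = 4.5, k_evap_perkg = 2.0),
    sheep = list(co0_perkg = 0.080, map0 = 90, cvp0 = 4.0, k_evap_perkg = 2.0)
  )
}

#' Count registry parameters per class
#'
#' @param params a parameter registry tibble.
#' @return named integer vector with counts for `subject_invariant`,
#'   `subject_specific`, `constraint_derived`, and `total`.
#' @export
param_census <- function(params) {
  tab <- table(factor(params$class, levels = c(
    "subject_invariant", "subject_specific", "constraint_derived")))
  c(as.vector(tab), total = nrow(params)) |>
    stats::setNames(c(names(tab), "total"))
}

# Named value vector from a registry tibble.
par_values <- function(params) stats::setNames(params$value, params$name)

pv <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$value[i]
}

set_pv <- function(params, name, value) {
  i <- match(name, params$name)
  if (anyNA(i)) stop("unknown parameter(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  params$value[i] <- value
  params
}

#' Fill constraint-derived parameters from pre-injury steady state
#'
#' Twelve registry entries are not free: they are pinned by requiring the
#' unperturbed model to sit exactly at its pre-injury steady state and by
#' baseline anchors (the oncotic coefficient reproducing the baseline plasma
#' oncotic pressure, the cardiac/venous-return curves passing through the
#' baseline operating point `(CVP0, CO0)`, renal pressures mapping baseline
#' MAP to the 85 mmHg renal arterial anchor, the glomerular ultrafiltration
#' coefficient reproducing the baseline filtration fraction, and the
#' collecting-duct water fraction reproducing the baseline urinary-output
#' fraction of renal plasma flow). Transcapillary albumin permeability is
#' solved so tissue albumin is in balance with lymphatic return at baseline.
#'
#' Optional measured baselines in `profile` (`co0`, `map0`) override the
#' preset per-kg scalings before derivation, mirroring how measured baselines
#' enter subject-specific simulations.
#'
#' @param profile a [burn_profile()].
#' @param params a parameter registry; free parameters must lie within bounds.
#' @return the completed registry (idempotent: re-deriving changes nothing).
#' @export
derive_constrained_parameters <- function(profile, params) {
  free <- params[params$class != "constraint_derived", ]
  bad <- which(free$value < free$lower | free$value > free$upper)
  if (length(bad)) {
    stop("free parameters out of bounds: ",
         paste(free$name[bad], collapse = ", "))
  }
  if (!is.null(profile$co0)) {
    params <- set_pv(params, "co0_perkg", profile$co0 / profile$weight)
  }
  if (!is.null(profile$map0)) params <- set_pv(params, "map0", profile$map0)
  v <- par_values(params)
  w <- profile$weight

  ## oncotic coefficient anchored at baseline plasma oncotic pressure
  k_pi <- v[["pi_c0"]] / v[["c_alb_p0"]]

  ## albumin permeability-to-filtration ratio from baseline tissue albumin
  ## balance: Patlak flux at baseline filtration equals lymphatic return
  ps_ratio <- solve_ps_ratio(v[["c_alb_p0"]], v[["c_alb_t0"]], v[["sigma_a0"]])

  ## cardiovascular anchors through (CVP0, CO0)
  co0 <- v[["co0_perkg"]] * w
  map0 <- v[["map0"]]; cvp0 <- v[["cvp0"]]; msp0 <- v[["msp0"]]
  if (map0 <= cvp0) stop("infeasible constraint: baseline MAP must exceed CVP")
  if (msp0 <= cvp0) stop("infeasible constraint: baseline MSP must exceed CVP")
  tpr0 <- (map0 - cvp0) / co0
  kappa_v <- (msp0 - cvp0) / (co0 * tpr0)
  co_mid <- cvp0 + v[["s_co"]] * log(v[["co_max_frac"]] - 1)

  ## renal pressure anchors and resistance split
  a0 <- v[["pra0"]] - v[["a1"]] * map0
  b0 <- v[["prv0"]] - v[["b1"]] * cvp0
  rpf0 <- v[["rpf0_perkg"]] * w
  r_total <- (v[["pra0"]] - v[["prv0"]]) / rpf0
  r_down <- (v[["pg0"]] - v[["prv0"]]) / rpf0
  if (r_down >= r_total || r_down <= 0) {
    stop("infeasible constraint: baseline pressures require 0 < P_RV < P_G < P_RA")
  }
  r_aff0 <- r_total - r_down
  r_rv <- v[["r_rv_share"]] * r_down
  r_eff0 <- r_down - r_rv

  ## glomerular ultrafiltration coefficient from the filtration fraction
  pi_g0 <- v[["lambda_c"]] * v[["pi_c0"]] + v[["lambda_p"]] * (v[["pg0"]] - v[["p_b"]])
  net0 <- (v[["pg0"]] - v[["p_b"]]) - pi_g0
  if (net0 <= 0) {
    stop("infeasible constraint: baseline glomerular net filtration pressure <= 0")
  }
  kfg <- v[["ff0"]] * rpf0 / net0

  ## collecting-duct baseline water fraction from the UO fraction of RPF
  r_c0 <- 1 - v[["uo_frac0"]] / (v[["ff0"]] * (1 - v[["r_p0"]]) * (1 - v[["r_n0"]]))
  if (r_c0 <= v[["r_c_lo"]] || r_c0 >= v[["r_c_hi"]]) {
    stop("infeasible constraint: derived collecting-duct water fraction ",
         signif(r_c0, 4), " outside (r_c_lo, r_c_hi)")
  }

  set_pv(params,
         c("k_pi", "ps_ratio", "tpr0", "kappa_v", "co_mid", "a0", "b0",
           "r_aff0", "r_eff0", "r_rv", "kfg", "r_c0"),
         c(k_pi, ps_ratio, tpr0, kappa_v, co_mid, a0, b0,
           r_aff0, r_eff0, r_rv, kfg, r_c0))
}

# Solve PS/J_C so the Patlak flux per unit filtration equals the lymphatic
# albumin return per unit lymph flow (tissue concentration), i.e. tissue
# albumin is at steady state when filtration equals lymph flow.
solve_ps_ratio <- function(c_p, c_t, sigma_a) {
  target <- c_t
  conv_only <- (1 - sigma_a) * c_p  # PS -> 0 limit of flux per unit J_C
  if (conv_only >= target) {
    stop("infeasible constraint: baseline convective albumin flux already ",
         "exceeds lymphatic return; lower sigma_a0 or raise c_alb_t0")
  }
  f <- function(lr) {
    pe <- (1 - sigma_a) / exp(lr)
    (1 - sigma_a) * (c_p - c_t * exp(-pe)) / (1 - exp(-pe)) - target
  }
  exp(stats::uniroot(f, c(-12, 12), tol = 1e-12)$root)
}

#' Load a species preset
#'
#' Shipped presets bundle the species parameter registry (values, bounds and
#' class tags) with nominal profile defaults. Presets are stored as packaged
#' YAML and are regenerated identically by [param_registry()]; the YAML file
#' is the serialized external interface.
#'
#' @param species `"human"`, `"pig"` or `"sheep"`.
#' @return list with elements `params` (registry tibble) and
#'   `profile_defaults`.
#' @export
load_preset <- function(species = c("human", "pig", "sheep")) {
  species <- match.arg(species)
  path <- system.file("extdata", "presets", paste0(species, ".yaml"),
                      package = "burnsim")
  if (nzchar(path)) {
    read_params_yaml(path) -> params
  } else {
    params <- param_registry(species)
  }
  list(params = params, profile_defaults = species_defaults(species))
}

#' Build the pre-injury steady state
#'
#' The initial values of every state are determined by weight and TBSA:
#' plasma and tissue water scale per kg, the burnt/intact tissue partition
#' follows TBSA, albumin contents follow the baseline concentrations, the
#' extracellular sodium content follows the baseline plasma sodium, and all
#' hormone concentrations start at their normalized baseline of 1.
#'
#' @param profile a [burn_profile()].
#' @param params a completed registry (see [derive_constrained_parameters()]).
#' @return named numeric state vector (7 volume-kinetic states, 5 hormone
#'   states including the angiotensin lag, and 5 cumulative-balance
#'   diagnostics initialized at 0).
#' @export
initialize_state <- function(profile, params) {
  v <- par_values(params)
  if (anyNA(v)) {
    stop("registry has underived constraint-derived entries; ",
         "call derive_constrained_parameters() first")
  }
  w <- profile$weight; tbsa <- profile$tbsa
  v_p0 <- v[["v_plasma_perkg"]] * w
  v_bt0 <- v[["v_tissue_perkg"]] * w * tbsa
  v_it0 <- v[["v_tissue_perkg"]] * w * (1 - tbsa)
  c(V_P = v_p0,
    A_P = v[["c_alb_p0"]] * v_p0,
    V_BT = v_bt0,
    V_IT = v_it0,
    A_BT = v[["c_alb_t0"]] * v_bt0,
    A_IT = v[["c_alb_t0"]] * v_it0,
    Na_ECF = v[["na_plasma0"]] * (v_p0 + v_bt0 + v_it0),
    C_renin = 1, L_angII = 1, C_angII = 1, C_ald = 1, C_adh = 1,
    cum_UO = 0, cum_evap = 0, cum_exud = 0, cum_FUO = 0, cum_denat = 0)
}

#' Names of the volume-kinetic ODE states
#'
#' The water/albumin/sodium kinetics proper comprise exactly these seven
#' coupled states; hormone concentrations and cumulative-balance diagnostics
#' are carried alongside them in the integrated vector.
#'
#' @return character vector of length 7.
#' @export
vk_state_names <- function() {
  c("V_P", "A_P", "V_BT", "V_IT", "A_BT", "A_IT", "Na_ECF")
}

hormone_state_names <- function() {
  c("C_renin", "L_angII", "C_angII", "C_ald", "C_adh")
}
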