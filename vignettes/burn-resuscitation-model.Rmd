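---
title: "Modelling burn shock and fluid resuscitation with burnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling burn shock and fluid resuscitation with burnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(burnsim)
```

## The problem

Extensive burns destroy capillary integrity. Plasma shifts from the
intravascular space into burnt and intact tissue, and a large fraction of any
intravenous (IV) fluid given to restore blood volume leaks along with it.
Clinicians must steer between hypovolemic shock (too little fluid) and massive
edema with its complications (too much), usually by titrating hourly Lactated
Ringer's (LR) doses against hourly urine output (UO). `burnsim` implements a
whole-body mechanistic model of this situation — volume kinetics, circulation,
kidney, and hormones, coupled into one stiff ODE system — together with
protocol controllers, verification experiments, and subject-specific parameter
estimation, all exercisable on synthetic virtual patients.

## Model structure

The integrated state vector has 12 dynamic components plus five
cumulative-balance diagnostics used by conservation checks and controllers.

**Volume kinetics (7 states).** Plasma water `V_P`, plasma albumin `A_P`,
burnt- and intact-tissue water `V_BT`, `V_IT`, tissue albumin `A_BT`, `A_IT`,
and extracellular sodium `Na_ECF`. Transcapillary water flow follows the
Starling equation `J = k_f[(P_C - P_T) - sigma(pi_C - pi_T)]` per tissue, with
a linear capillary pressure–volume relation, a continuous piecewise-linear
tissue compliance curve (stiff below baseline volume — interstitial pressure
falls steeply during dehydration — compliant above it, blended smoothly over a
1% volume band so the right-hand side stays differentiable), and linear
oncotic pressures `pi = k_pi A/V`. Lymph drains back to plasma as a bounded
sigmoid of tissue pressure, anchored so that at baseline lymph flow equals
baseline filtration tissue-by-tissue. Albumin crosses the capillary wall by
the coupled convection–diffusion (Patlak) solution
`J_s = J(1-\sigma_a)\,(C_P - C_T e^{-Pe})/(1 - e^{-Pe})`, `Pe = J(1-\sigma_a)/PS`,
which reduces to pure diffusion at zero filtration and to
`J(1-\sigma_a)C_P` at high filtration, and returns with lymph at tissue
concentration. Dermal losses (evaporation scaled by burned surface,
exudation proportional to burnt-tissue swelling) are gated by the wound
signal. Capillary and lymphatic water exchange is treated as isotonic, so
extracellular sodium changes only through infusion and urine; dermal losses
are modelled as sodium- and albumin-free, a stated simplification that makes
the sodium ledger exact.

**Burn perturbations.** Each injury channel — burnt-tissue and systemic
capillary conductance increase, reflection-coefficient drop (capillary pore
enlargement, applied to both the water and the albumin coefficient and
clipped to [0, 1]), negative burnt-tissue pressure, albumin denaturation, the
wound gate, and the vasomotor pair (constriction/dilation combined into the
multiplier `M_MAP`, floored at 0.1) — follows a double-exponential pulse
`A(e^{-t/\tau_2} - e^{-t/\tau_1})`, normalized so its peak equals the
amplitude. Amplitudes are subject-specific (the "intensity" of injury);
time-constant pairs are shared (fast: 0.5/8 h for the capillary and wound
channels, slow: 1/24 h for vasomotor tone and the wound gate). All signals
are exactly zero before injury and decay to zero, so every perturbed quantity
returns to baseline.

**Circulation.** The circulation is algebraic (quasi-steady relative to
hourly fluid shifts) and re-solved inside every derivative evaluation. Mean
systemic pressure is exponential in fractional blood volume,
`MSP = MSP_0 e^{k(V_B/V_{B0}-1)}`; total peripheral resistance is a bounded
logistic of relative angiotensin II anchored through the baseline; venous
return is linear in central venous pressure with resistance proportional to
TPR; the cardiac function curve is a logistic (Frank–Starling) dose–response
of CVP anchored through the baseline operating point. Cardiac output and CVP
are the unique intersection of the two curves, found by bracketed bisection
on `[CVP_{floor}, MSP]` to a residual below 1e-6 L/min; mean arterial
pressure is `MAP = CO \cdot TPR \cdot M_{MAP} + CVP` (the additive CVP term
is a documented modelling choice).

**Kidney.** Renal arterial and venous pressures are linear in MAP and CVP,
anchored so the preset baseline MAP maps to 85 mmHg. Plasma flow follows
Poiseuille's law over the afferent/efferent/venous resistance chain;
glomerular pressure is `J_{RPF}(R_{Eff}+R_{RV}) + P_{RV}`; the mean
glomerular oncotic pressure is the filtration-equilibrium linearization
`pi_G = \lambda_c pi_C + \lambda_p (P_G - P_B)`; and GFR is Starling
filtration with a softplus floor (width 0.1 mL/h) at zero. Afferent
resistance is the additive composition of a baseline term, a bounded
myogenic sigmoid of arterial pressure (zero at 85 mmHg), and a bounded
tubuloglomerular-feedback (TGF) sigmoid of macula densa sodium (zero at its
baseline), softly floored at 5% of baseline so saturated dilation cannot
make it non-positive. Efferent resistance is a bounded increasing function
of angiotensin II. Reabsorption runs through four nodes: proximal tubule
(water and sodium together at the aldosterone-controlled fraction `r_P`,
baseline 0.70 — the fraction, not the amount, is controlled:
glomerulotubular balance), thin descending limb (water only, fraction an
inverse sigmoid of flow — the flow dependence that powers pressure
diuresis), thick ascending limb (sodium only, fixed 60%), early distal
tubule (sodium only, inverse sigmoid of sodium inflow; its outflow
concentration *is* the macula densa sodium), and collecting duct (water
fraction driven by ADH, sodium fraction by aldosterone). Because TGF makes
macula densa sodium implicit, each evaluation solves a one-dimensional fixed
point by bisection; the curve shapes are chosen so the composed map is
strictly decreasing (see "Numerical choices").

**Hormones.** All four hormones are normalized to baseline 1 and follow
`dC/dt = k(S - C)` with secretion drives floored at zero: renin inverse-linear
in fractional macula densa sodium; angiotensin II linear in lagged renin
(first-order lag of time constant 0.25 h standing in for the release delay —
its agreement with an explicit delayed-argument reference is a test);
aldosterone exponential in the weighted sum of a negative sodium drive and a
positive angiotensin drive; ADH exponential in the weighted fractional fall
of plasma volume and rise of plasma sodium, with the osmoreceptor weight
strictly larger than the baroreceptor weight. Serum potassium's influence on
aldosterone is deliberately omitted (treated as constant).

## Baseline constraints and the parameter registry

The registry (`param_registry()`) carries every scalar with value, bounds,
units, and a class tag. Twelve entries are *constraint-derived*: the oncotic
coefficient (anchoring baseline plasma oncotic pressure at 25 mmHg), the
albumin permeability ratio (tissue albumin balanced against lymphatic return
at baseline), TPR, the venous-return resistance ratio, and the cardiac-curve
midpoint (all forcing the CO–VR intersection through the measured baseline
`(CVP_0, CO_0)`), the renal pressure intercepts, the three renal resistances
(splitting the baseline pressure profile 85/60/6 mmHg at the baseline plasma
flow), the glomerular ultrafiltration coefficient (filtration fraction
exactly 0.20), and the collecting-duct water fraction (urinary output exactly
1% of renal plasma flow). Re-deriving is idempotent, and the full derivative
at the constructed baseline is zero to integrator precision — the pre-injury
steady state is built, not searched for.

Baseline sizes scale per kg (plasma 40 mL/kg, interstitium 160 mL/kg split
between burnt and intact skin by TBSA; renal plasma flow 535.7 mL/h/kg, i.e.
the textbook 625 mL/min at 70 kg). Honouring the printed baseline fractions
means baseline urinary output is 1% of renal plasma flow (375 mL/h at 70 kg)
— far above typical clinical hourly UO. That tension is inherent in the
stated fractions and is carried as-is; the verification and acceptance
analyses are expressed relative to this operating point.

A maintenance intake balancing baseline urine output (with sodium matching
baseline urinary sodium) is available for steady-state analyses and is off
by default post-burn, matching the no-IV-fluids experimental arm.

## Calibration of the shipped presets

The supplementary parameter values behind the published model are not
available, so the presets are calibrated to the *printed* physiology and to
canonical renal behaviour, then frozen:

* the four baseline fraction anchors above (20%, 1%, 65–75%, 60%) hold by
  construction;
* the flow-dependence gains of the descending-limb and early-distal curves
  and the proximal aldosterone gain were set so the isolated kidney+RAAS
  sweep reproduces the canonical pressure-diuresis disproportionality (about
  a 250% UO rise where GFR has risen 50%) while GFR stays on a plateau over
  renal arterial pressures 65–105 mmHg (max/min ratio ≈ 1.03) and renin
  release falls monotonically with pressure;
* perturbation amplitudes were set to produce a moderately severe
  unresuscitated 40% burn: hematocrit rising from 0.40 to ≈ 0.50, CVP and CO
  roughly halved and MAP ≈ 55 mmHg at 24 h, oliguria, and activation of all
  four hormone axes.

One structural condition fell out of this calibration: the distal sodium
curve must be steep enough relative to the descending-limb water curve that
macula densa sodium *increases* with filtrate flow everywhere. If water
reabsorption saturates more slowly than sodium reabsorption, low-flow states
concentrate the distal filtrate, TGF then locks in an over-constricted
low-GFR fixed point, and the steady-state map becomes bistable. The shipped
curve anchors (`r_n` in [0.05, 0.85] with gain 4.8, `p_e` in [0.10, 0.95]
with gain 4.0) keep the composed TGF map strictly decreasing, hence a unique
fixed point.

## Protocol controllers

Three paradigms mirror the experimental arms: P1 gives no fluid; P3 gives a
fixed 500 mL/h (deliberate over-resuscitation); and the titrated protocols
review hourly urine output and multiply the LR rate by 1.25 below the target
band, 0.8 above it, holding inside (bands: pigs 1–1.5 mL/kg/h, sheep
1–2 mL/kg/h starting 1 h post-burn, humans 30–50 mL/h absolute). The initial
rate is the Parkland-style `4 mL × kg × TBSA%` over 24 h with half in the
first 8 h. The proprietary bedside controller used clinically publishes no
rule; this generic banded controller is a documented stand-in.

## Estimation

Subject-specific parameters are estimated by minimizing the normalized sum of
squares `J(\theta)=\sum_j\sum_k[(y^{d}_{jk}-y_j(t_k,\theta))/Y_j]^2` over all
measured variables, with `Y_j` the subject's baseline value of the variable
(for UO, the species target-band midpoint, since post-burn UO is managed
toward the band rather than to baseline). The observation operator is shared
between synthesis and fitting: urine output is the trailing-hour collected
volume, everything else instantaneous. The global search runs seeded
Latin-hypercube multi-starts over the registered bounds — the first start at
the population (preset) values — each refined by bounded
Levenberg–Marquardt; the best start is then polished with a longer iteration
budget. The reported NMAE shares `Y_j` with the cost; Bland–Altman limits use
the literal `bias ± 2·SD` with the sample standard deviation. For
data-sparse (UO-only) subjects, `sensitivity_rank()` reduces the free set to
the `m` most cost-sensitive parameters around a population-average vector
(bound-width-scaled central differences), fixing the rest.

## What the synthetic cohort does and does not emulate

`cohort_spec()`/`generate_cohort()` reproduce the *shape* of the study data:
species weight/TBSA distributions (pigs 31.7 ± 4.2 kg at a fixed 40% TBSA,
sheep 40 kg, humans 85 ± 18 kg with TBSA 42 ± 18%), the measurement schedules
(pigs: hourly UO plus CVP/CO/MAP/Na at hours 0,1,2,3,5,9,12,18,24 with
hematocrit generated but excluded by default because the study pigs were not
splenectomized; sheep: 48 h; humans: hourly UO only), the resuscitation
paradigms, and plausible monitor noise (multiplicative Gaussian; default CVs
UO 10%, HCT 2%, CO 5%, MAP 5%, CVP 10%, Na 1%, floored at zero). Virtual
subjects are *self-generated by the model*, so passing recovery tests shows
identifiability of the estimation machinery under the stated schedules and
noise — not that the model family matches real burn patients, which would
require the non-public animal and clinical datasets.

## Numerical choices

* Units: volumes mL, flows mL/h, pressures mmHg, sodium mEq (concentrations
  reported in mEq/L), albumin g, time in hours post-burn; CO in L/min at the
  interface.
* Stiff adaptive integration (lsoda), relative tolerance 1e-6, absolute
  tolerance 1e-8 per unit of state magnitude; the integration restarts at
  every schedule breakpoint and controller review, so the piecewise-constant
  dose is exact. Halving tolerances moves 24-h outputs by far less than
  0.1%.
* The right-hand side exists twice on purpose: documented R functions per
  operation, and a C translation used by the integrator; a test pins their
  agreement at 1e-8 relative (observed: machine precision).
* Both interior solvers are plain bracketed bisections with fixed iteration
  caps (100 for the CO–VR intersection, 80 for the TGF fixed point), chosen
  over Newton steps for unconditional robustness inside a stiff integrator.
* GFR's zero floor is smoothed by a softplus of width 0.1 mL/h and bounded
  below by a vanishing positive value (1e-9 mL/h) so downstream
  concentrations stay defined in deep shock; the collecting duct's bounded
  dose–responses guarantee urine output never reaches exactly zero.
* The verification sweep finds steady states by long-horizon integration
  (400 h) of the hormone subsystem with volume kinetics frozen, reusing the
  simulator rather than introducing a second nonlinear solver; a residual
  check fails loudly if a pressure has not settled.
* Problem sizes used by the shipped analyses: sweeps use a 2-mmHg grid over
  40–160 mmHg (with the 85 mmHg anchor added); the recovery study uses 10
  subjects x 20 multi-starts with a 6-iteration exploration and 30-iteration
  polish, sized to give sub-1% noiseless recovery at desk scale.

## Known limitations

* No heart rate, baroreflex chronotropy, or inhalation injury; no
  potassium; no intracellular compartment; no urea/counter-current
  osmolality model; nephrons are homogeneous.
* Dermal losses carry no sodium or albumin by construction.
* The supplementary functional forms of the published model were not
  available; all curve shapes here are the documented choices above, pinned
  by their stated qualitative contracts (anchors, bounds, monotonicity)
  rather than by the original coefficient tables.
* Real-data validation (the published NMAE/correlation/limits-of-agreement
  tables) requires the non-public datasets and is out of scope; the test
  suite validates structure, physiology, and identifiability on synthetic
  subjects only.

## A worked example

```{r example, eval = FALSE}
library(burnsim)
prof <- burn_profile("pig", weight = 31.7, tbsa = 0.40)
sim <- simulate_burn(prof, protocol = protocol_preset("P2"), horizon = 24)
sim
autoplot(sim)

sweep <- pra_sweep(burn_profile("human", 70, 0.4))
pressure_diuresis_stat(sweep)
autoplot(sweep)
```
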