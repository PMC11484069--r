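/* Coupled burn-injury/resuscitation model: compiled right-hand side for
 * deSolve. Mirrors the R reference implementation exactly (see R/ module
 * files); the parameter vector layout is the rt_layout contract in
 * R/runtime.R and must not be reordered independently.
 *
 * State vector (17 entries with time bookkeeping handled by deSolve):
 *  0 V_P  1 A_P  2 V_BT  3 V_IT  4 A_BT  5 A_IT  6 Na_ECF
 *  7 C_renin  8 L_angII  9 C_angII  10 C_ald  11 C_adh
 *  12 cum_UO  13 cum_evap  14 cum_exud  15 cum_FUO  16 cum_denat
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 116
#define NOUT 42

static double p[NPAR];

void burnmod_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

#define P_W            p[0]
#define P_TBSA         p[1]
#define P_RCV          p[2]
#define P_V_P0         p[3]
#define P_V_BT0        p[4]
#define P_V_IT0        p[5]
#define P_K_PI         p[6]
#define P_P_C0         p[7]
#define P_G_PC         p[8]
#define P_P_T0         p[9]
#define P_G_T_ABOVE    p[10]
#define P_G_T_BELOW    p[11]
#define P_BLEND_W      p[12]
#define P_KF_BT0       p[13]
#define P_KF_IT0       p[14]
#define P_SIGMA0       p[15]
#define P_SIGMA_A0     p[16]
#define P_PS_BT        p[17]
#define P_PS_IT        p[18]
#define P_LYMPH_GAIN   p[19]
#define P_Q_LYMPH      p[20]
#define P_JL_MAX_BT    p[21]
#define P_JL_MAX_IT    p[22]
#define P_K_EVAP_TOT   p[23]
#define P_K_EXUD       p[24]
#define P_NA_MAINT     p[25]
#define P_J_MAINT      p[26]
#define P_J_INF        p[27]
#define P_NA_INF       p[28]
#define P_Q_INF        p[29]
#define P_AMP_KF_BT    p[30]
#define P_AMP_KF_SYS   p[31]
#define P_AMP_SIGMA    p[32]
#define P_AMP_PBT      p[33]
#define P_AMP_DEN      p[34]
#define P_AMP_CONSTRICT p[35]
#define P_AMP_DILATE   p[36]
#define P_TAU1_FAST    p[37]
#define P_TAU2_FAST    p[38]
#define P_TAU1_SLOW    p[39]
#define P_TAU2_SLOW    p[40]
#define P_PERTURB_ON   p[41]
#define P_MSP0         p[42]
#define P_K_MSP        p[43]
#define P_V_B0         p[44]
#define P_KAPPA_V      p[45]
#define P_TPR0         p[46]
#define P_TPR_MIN      p[47]
#define P_TPR_MAX      p[48]
#define P_S_TPR        p[49]
#define P_Q_TPR        p[50]
#define P_CO_MAX       p[51]
#define P_S_CO         p[52]
#define P_CO_MID       p[53]
#define P_CVP_FLOOR    p[54]
#define P_A1           p[55]
#define P_A0           p[56]
#define P_B1           p[57]
#define P_B0           p[58]
#define P_R_AFF0       p[59]
#define P_R_EFF0       p[60]
#define P_R_RV         p[61]
#define P_KFG          p[62]
#define P_P_B          p[63]
#define P_LAMBDA_C     p[64]
#define P_LAMBDA_P     p[65]
#define P_F_MM         p[66]
#define P_S_MM         p[67]
#define P_PRA0         p[68]
#define P_F_TGF        p[69]
#define P_S_TGF        p[70]
#define P_NA_MD0       p[71]
#define P_EFF_MIN      p[72]
#define P_EFF_MAX      p[73]
#define P_S_EFF        p[74]
#define P_R_P_LO       p[75]
#define P_R_P_HI       p[76]
#define P_R_P0         p[77]
#define P_G_RP         p[78]
#define P_R_N_LO       p[79]
#define P_R_N_HI       p[80]
#define P_R_N0         p[81]
#define P_G_RN         p[82]
#define P_J_PN0        p[83]
#define P_P_K          p[84]
#define P_P_E_LO       p[85]
#define P_P_E_HI       p[86]
#define P_P_E0         p[87]
#define P_G_PE         p[88]
#define P_F_KE0        p[89]
#define P_R_C_LO       p[90]
#define P_R_C_HI       p[91]
#define P_R_C0         p[92]
#define P_G_RC         p[93]
#define P_P_C_LO       p[94]
#define P_P_C_HI       p[95]
#define P_P_C0N        p[96]
#define P_G_PC_ALD     p[97]
#define P_K_RENIN      p[98]
#define P_G_RENIN      p[99]
#define P_TAU_D        p[100]
#define P_K_ANGII      p[101]
#define P_G_ANGII      p[102]
#define P_K_ALD        p[103]
#define P_W_NA         p[104]
#define P_W_A          p[105]
#define P_K_ADH        p[106]
#define P_W_V          p[107]
#define P_W_S          p[108]
#define P_NA_PLASMA0   p[109]
#define P_GFR_SOFT_W   p[110]
#define P_RENAL_MODE   p[111]
#define P_PRA_FORCED   p[112]
#define P_VK_FROZEN    p[113]
#define P_PRV0         p[114]
#define P_PI_C0        p[115]

#define O_HCT          yout[0]
#define O_V_B          yout[1]
#define O_PI_C         yout[2]
#define O_P_C          yout[3]
#define O_MSP          yout[4]
#define O_TPR          yout[5]
#define O_CVP          yout[6]
#define O_CO           yout[7]
#define O_VR           yout[8]
#define O_MAP          yout[9]
#define O_M_MAP        yout[10]
#define O_P_RA         yout[11]
#define O_P_RV         yout[12]
#define O_P_G          yout[13]
#define O_PI_G         yout[14]
#define O_J_RPF        yout[15]
#define O_J_GFR        yout[16]
#define O_R_AFF        yout[17]
#define O_R_EFF        yout[18]
#define O_R_MM         yout[19]
#define O_R_TGF        yout[20]
#define O_NA_MD        yout[21]
#define O_R_P          yout[22]
#define O_R_N          yout[23]
#define O_P_E          yout[24]
#define O_R_C          yout[25]
#define O_P_CN         yout[26]
#define O_J_UO         yout[27]
#define O_F_UO         yout[28]
#define O_NA_UO        yout[29]
#define O_J_PN         yout[30]
#define O_J_EC         yout[31]
#define O_NA_PLASMA    yout[32]
#define O_J_C_BT       yout[33]
#define O_J_C_IT       yout[34]
#define O_J_L_BT       yout[35]
#define O_J_L_IT       yout[36]
#define O_J_EVAP       yout[37]
#define O_J_EXUD       yout[38]
#define O_J_I_TOTAL    yout[39]
#define O_F_I          yout[40]
#define O_S_RENIN      yout[41]

static double sigm(double x) { return 1.0 / (1.0 + exp(-x)); }

/* softplus with width w, overflow-safe; matches the R helper */
static double softplus_w(double x, double w)
{
    double z = x / w;
    if (z > 30.0) return x;
    return w * log1p(exp(z));
}

static double anchored_logistic(double x_rel, double lo, double hi,
                                double y0, double gain)
{
    double q = log((y0 - lo) / (hi - y0));
    return lo + (hi - lo) * sigm(gain * (x_rel - 1.0) + q);
}

static double pulse(double t, double amp, double tau1, double tau2)
{
    double tpk, norm;
    if (t < 0.0) return 0.0;
    tpk = tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1);
    norm = exp(-tpk / tau2) - exp(-tpk / tau1);
    return amp * (exp(-t / tau2) - exp(-t / tau1)) / norm;
}

static double tissue_pressure(double v_rel, double p_t0, double g_above,
                              double g_below, double bw)
{
    double off = (g_above - g_below) * bw * M_LN2;
    return p_t0 + g_above * softplus_w(v_rel - 1.0, bw)
                - g_below * softplus_w(1.0 - v_rel, bw) - off;
}

static double patlak_flux(double j_c, double c_p, double c_t,
                          double sigma_a, double ps)
{
    double jconv = j_c * (1.0 - sigma_a);
    double pe = jconv / ps;
    if (fabs(pe) < 1e-8)
        return ps * (c_p - c_t) + 0.5 * jconv * (c_p + c_t);
    {
        double e = exp(-pe);
        return jconv * (c_p - c_t * e) / (1.0 - e);
    }
}

static double cardiac_curve(double cvp)
{
    return P_CO_MAX / (1.0 + exp(-(cvp - P_CO_MID) / P_S_CO));
}

/* nephron chain at a given macula-densa sodium guess; returns the implied
 * macula-densa sodium and fills the chain block when out != NULL */
typedef struct {
    double r_aff, j_rpf, p_g, pi_g, j_gfr;
    double r_p, j_pn, f_pn, r_n, j_nk, f_nk, j_ke, f_ke;
    double p_e, j_ec, f_ec, na_md, r_c, p_cn, j_uo, f_uo;
} chain_t;

static double eval_chain(double na_md_guess, double p_ra, double p_rv,
                         double r_eff, double pi_c, double na_plasma,
                         double c_ald, double c_adh, chain_t *out)
{
    double r_tgf = P_F_TGF * P_R_AFF0 *
        (2.0 * sigm((na_md_guess / P_NA_MD0 - 1.0) / P_S_TGF) - 1.0);
    double r_mm = P_F_MM * P_R_AFF0 *
        (2.0 * sigm((p_ra - P_PRA0) / P_S_MM) - 1.0);
    double raw = P_R_AFF0 + r_mm + r_tgf;
    double fl = 0.05 * P_R_AFF0, w = 0.02 * P_R_AFF0;
    double z = (raw - fl) / w;
    double r_aff;
    double dp, j_rpf, p_g, pi_g, x, j_gfr;
    double f_gfr, r_p, j_pn, f_pn, r_n, j_nk, f_nk, j_ke, f_ke;
    double p_e, f_ec, na_md, r_c, p_cn, j_uo, f_uo;

    if (z > 30.0) r_aff = raw;
    else {
        double zz = z < -30.0 ? -30.0 : z;
        r_aff = fl + w * log1p(exp(zz));
    }
    dp = p_ra - p_rv; if (dp < 0.0) dp = 0.0;
    j_rpf = dp / (r_aff + r_eff + P_R_RV);
    p_g = j_rpf * (r_eff + P_R_RV) + p_rv;
    pi_g = P_LAMBDA_C * pi_c + P_LAMBDA_P * (p_g - P_P_B);
    x = P_KFG * ((p_g - P_P_B) - pi_g);
    j_gfr = softplus_w(x, P_GFR_SOFT_W);
    if (j_gfr < 1e-9) j_gfr = 1e-9;  /* keep concentrations defined */

    f_gfr = j_gfr * na_plasma;
    r_p = anchored_logistic(c_ald, P_R_P_LO, P_R_P_HI, P_R_P0, P_G_RP);
    j_pn = j_gfr * (1.0 - r_p);
    f_pn = f_gfr * (1.0 - r_p);
    r_n = anchored_logistic(j_pn / P_J_PN0, P_R_N_LO, P_R_N_HI, P_R_N0, -P_G_RN);
    j_nk = j_pn * (1.0 - r_n);
    f_nk = f_pn;
    j_ke = j_nk;
    f_ke = f_nk * (1.0 - P_P_K);
    p_e = anchored_logistic(f_ke / P_F_KE0, P_P_E_LO, P_P_E_HI, P_P_E0, -P_G_PE);
    f_ec = f_ke * (1.0 - p_e);
    na_md = f_ec / j_ke;
    r_c = anchored_logistic(c_adh, P_R_C_LO, P_R_C_HI, P_R_C0, P_G_RC);
    p_cn = anchored_logistic(c_ald, P_P_C_LO, P_P_C_HI, P_P_C0N, P_G_PC_ALD);
    j_uo = j_ke * (1.0 - r_c);
    f_uo = f_ec * (1.0 - p_cn);

    if (out) {
        out->r_aff = r_aff; out->j_rpf = j_rpf; out->p_g = p_g;
        out->pi_g = pi_g; out->j_gfr = j_gfr; out->r_p = r_p;
        out->j_pn = j_pn; out->f_pn = f_pn; out->r_n = r_n;
        out->j_nk = j_nk; out->f_nk = f_nk; out->j_ke = j_ke;
        out->f_ke = f_ke; out->p_e = p_e; out->j_ec = j_ke;
        out->f_ec = f_ec; out->na_md = na_md; out->r_c = r_c;
        out->p_cn = p_cn; out->j_uo = j_uo; out->f_uo = f_uo;
    }
    return na_md;
}

void burnmod_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double tt = *t;
    double V_P = y[0], A_P = y[1], V_BT = y[2], V_IT = y[3];
    double A_BT = y[4], A_IT = y[5], Na_ECF = y[6];
    double C_renin = y[7], L_angII = y[8], C_angII = y[9];
    double C_ald = y[10], C_adh = y[11];

    double pk_kf_bt = 0.0, pk_kf_sys = 0.0, pk_sigma = 0.0, pk_pbt = 0.0;
    double pk_den = 0.0, gate = 0.0, m_map = 1.0;

    double na_plasma, pi_c, v_b, msp, tpr, cvp, co, map;
    double p_ra, p_rv, r_eff;
    double lo, hi, mid, na_md;
    chain_t ch;
    int i;
    int frozen = (P_VK_FROZEN != 0.0);

    if (ip[0] < NOUT) error("burnmod: nout too small");

    if (P_PERTURB_ON != 0.0 && tt >= 0.0) {
        pk_kf_bt = pulse(tt, P_AMP_KF_BT, P_TAU1_FAST, P_TAU2_FAST);
        pk_kf_sys = pulse(tt, P_AMP_KF_SYS, P_TAU1_FAST, P_TAU2_FAST);
        pk_sigma = pulse(tt, P_AMP_SIGMA, P_TAU1_FAST, P_TAU2_FAST);
        pk_pbt = pulse(tt, P_AMP_PBT, P_TAU1_FAST, P_TAU2_FAST);
        pk_den = pulse(tt, P_AMP_DEN, P_TAU1_FAST, P_TAU2_FAST);
        gate = pulse(tt, 1.0, P_TAU1_SLOW, P_TAU2_SLOW);
        m_map = 1.0 + pulse(tt, P_AMP_CONSTRICT, P_TAU1_SLOW, P_TAU2_SLOW)
                    - pulse(tt, P_AMP_DILATE, P_TAU1_SLOW, P_TAU2_SLOW);
        if (m_map < 0.1) m_map = 0.1;
    }

    if (frozen) {
        na_plasma = P_NA_PLASMA0;
        pi_c = P_PI_C0;
    } else {
        na_plasma = Na_ECF / (V_P + V_BT + V_IT);
        pi_c = P_K_PI * A_P / V_P;
    }

    /* cardiovascular block: skipped when the renal arterial pressure is
     * forced (verification sweep mode) */
    if (P_RENAL_MODE == 1.0) {
        msp = P_MSP0; tpr = P_TPR0; cvp = 0.0; co = 0.0; map = 0.0;
        p_ra = P_PRA_FORCED; p_rv = P_PRV0;
    } else {
        double flo, fhi;
        v_b = V_P + P_RCV;
        msp = P_MSP0 * exp(P_K_MSP * (v_b - P_V_B0) / P_V_B0);
        tpr = P_TPR_MIN + (P_TPR_MAX - P_TPR_MIN) *
            sigm(P_S_TPR * (C_angII - 1.0) + P_Q_TPR);
        lo = P_CVP_FLOOR; hi = msp;
        if (hi <= lo)
            error("circulatory equilibrium: MSP %g below bracket floor at t=%g",
                  msp, tt);
        flo = cardiac_curve(lo) - (msp - lo) / (P_KAPPA_V * tpr);
        fhi = cardiac_curve(hi) - (msp - hi) / (P_KAPPA_V * tpr);
        if (flo > 0.0 || fhi < 0.0)
            error("circulatory equilibrium: no sign change in bracket at t=%g", tt);
        for (i = 0; i < 100; i++) {
            double fm;
            mid = 0.5 * (lo + hi);
            fm = cardiac_curve(mid) - (msp - mid) / (P_KAPPA_V * tpr);
            if (fm > 0.0) hi = mid; else lo = mid;
            if (hi - lo < 1e-10) break;
        }
        cvp = 0.5 * (lo + hi);
        co = cardiac_curve(cvp);
        map = co * tpr * m_map + cvp;
        p_ra = P_A1 * map + P_A0;
        p_rv = P_B1 * cvp + P_B0;
    }

    r_eff = P_R_EFF0 * anchored_logistic(C_angII, P_EFF_MIN, P_EFF_MAX,
                                         1.0, P_S_EFF);

    /* TGF fixed point on macula-densa sodium (strictly decreasing map) */
    lo = 1e-5; hi = 1.0;
    for (i = 0; i < 80; i++) {
        double g;
        mid = 0.5 * (lo + hi);
        g = eval_chain(mid, p_ra, p_rv, r_eff, pi_c, na_plasma,
                       C_ald, C_adh, NULL) - mid;
        if (g > 0.0) lo = mid; else hi = mid;
        if (hi - lo < 1e-13) break;
    }
    na_md = 0.5 * (lo + hi);
    eval_chain(na_md, p_ra, p_rv, r_eff, pi_c, na_plasma, C_ald, C_adh, &ch);

    /* hormone derivatives */
    {
        double s_renin = 1.0 - P_G_RENIN * (na_md / P_NA_MD0 - 1.0);
        double s_ang, s_ald, s_adh, dna, dv;
        if (s_renin < 0.0) s_renin = 0.0;
        s_ang = 1.0 + P_G_ANGII * (L_angII - 1.0);
        if (s_ang < 0.0) s_ang = 0.0;
        dna = na_plasma / P_NA_PLASMA0 - 1.0;
        s_ald = exp(-P_W_NA * dna + P_W_A * (C_angII - 1.0));
        dv = (frozen ? 0.0 : V_P / P_V_P0 - 1.0);
        s_adh = exp(-P_W_V * dv + P_W_S * dna);
        ydot[7] = P_K_RENIN * (s_renin - C_renin);
        ydot[8] = (C_renin - L_angII) / P_TAU_D;
        ydot[9] = P_K_ANGII * (s_ang - C_angII);
        ydot[10] = P_K_ALD * (s_ald - C_ald);
        ydot[11] = P_K_ADH * (s_adh - C_adh);
        O_S_RENIN = s_renin;
    }

    if (frozen) {
        for (i = 0; i < 7; i++) ydot[i] = 0.0;
        ydot[12] = ch.j_uo; ydot[13] = 0.0; ydot[14] = 0.0;
        ydot[15] = ch.f_uo; ydot[16] = 0.0;
        O_HCT = P_RCV / (P_RCV + V_P);
        O_V_B = V_P + P_RCV;
        O_PI_C = pi_c; O_P_C = P_P_C0;
        O_MSP = msp; O_TPR = tpr; O_CVP = cvp; O_CO = co; O_VR = co;
        O_MAP = map; O_M_MAP = m_map;
        O_J_C_BT = 0.0; O_J_C_IT = 0.0; O_J_L_BT = 0.0; O_J_L_IT = 0.0;
        O_J_EVAP = 0.0; O_J_EXUD = 0.0; O_J_I_TOTAL = 0.0; O_F_I = 0.0;
    } else {
        /* volume kinetics */
        double p_c = P_P_C0 + P_G_PC * (V_P / P_V_P0 - 1.0);
        double p_bt = tissue_pressure(V_BT / P_V_BT0, P_P_T0, P_G_T_ABOVE,
                                      P_G_T_BELOW, P_BLEND_W) - pk_pbt;
        double p_it = tissue_pressure(V_IT / P_V_IT0, P_P_T0, P_G_T_ABOVE,
                                      P_G_T_BELOW, P_BLEND_W);
        double pi_bt = P_K_PI * A_BT / V_BT;
        double pi_it = P_K_PI * A_IT / V_IT;
        double kf_bt = P_KF_BT0 * (1.0 + pk_kf_bt + pk_kf_sys);
        double kf_it = P_KF_IT0 * (1.0 + pk_kf_sys);
        double sig = P_SIGMA0 * (1.0 - pk_sigma);
        double sig_a = P_SIGMA_A0 * (1.0 - pk_sigma);
        double j_c_bt, j_c_it, j_l_bt, j_l_it;
        double c_p = A_P / V_P, c_bt = A_BT / V_BT, c_it = A_IT / V_IT;
        double q_bt, q_it, denat, j_evap, j_exud, j_i, f_i;

        if (sig < 0.0) sig = 0.0; if (sig > 1.0) sig = 1.0;
        if (sig_a < 0.0) sig_a = 0.0; if (sig_a > 1.0) sig_a = 1.0;

        j_c_bt = kf_bt * ((p_c - p_bt) - sig * (pi_c - pi_bt));
        j_c_it = kf_it * ((p_c - p_it) - sig * (pi_c - pi_it));
        j_l_bt = P_JL_MAX_BT * sigm(P_LYMPH_GAIN * (p_bt - P_P_T0) + P_Q_LYMPH);
        j_l_it = P_JL_MAX_IT * sigm(P_LYMPH_GAIN * (p_it - P_P_T0) + P_Q_LYMPH);
        q_bt = patlak_flux(j_c_bt, c_p, c_bt, sig_a, P_PS_BT);
        q_it = patlak_flux(j_c_it, c_p, c_it, sig_a, P_PS_IT);
        denat = pk_den * A_BT;
        j_evap = P_K_EVAP_TOT * gate;
        j_exud = P_K_EXUD * (V_BT > P_V_BT0 ? V_BT - P_V_BT0 : 0.0) * gate;
        j_i = P_J_MAINT + P_J_INF;
        f_i = P_J_MAINT * P_NA_MAINT + P_J_INF * P_NA_INF;

        ydot[0] = j_i - ch.j_uo - j_c_bt - j_c_it + j_l_bt + j_l_it;
        ydot[1] = P_Q_INF - q_bt - q_it + j_l_bt * c_bt + j_l_it * c_it;
        ydot[2] = j_c_bt - j_l_bt - j_evap - j_exud;
        ydot[3] = j_c_it - j_l_it;
        ydot[4] = q_bt - j_l_bt * c_bt - denat;
        ydot[5] = q_it - j_l_it * c_it;
        ydot[6] = f_i - ch.f_uo;
        ydot[12] = ch.j_uo;
        ydot[13] = j_evap;
        ydot[14] = j_exud;
        ydot[15] = ch.f_uo;
        ydot[16] = denat;

        O_HCT = P_RCV / (P_RCV + V_P);
        O_V_B = V_P + P_RCV;
        O_PI_C = pi_c; O_P_C = p_c;
        O_MSP = msp; O_TPR = tpr; O_CVP = cvp; O_CO = co; O_VR = co;
        O_MAP = map; O_M_MAP = m_map;
        O_J_C_BT = j_c_bt; O_J_C_IT = j_c_it;
        O_J_L_BT = j_l_bt; O_J_L_IT = j_l_it;
        O_J_EVAP = j_evap; O_J_EXUD = j_exud;
        O_J_I_TOTAL = j_i; O_F_I = f_i;
    }

    O_P_RA = p_ra; O_P_RV = p_rv;
    O_P_G = ch.p_g; O_PI_G = ch.pi_g;
    O_J_RPF = ch.j_rpf; O_J_GFR = ch.j_gfr;
    O_R_AFF = ch.r_aff; O_R_EFF = r_eff;
    O_R_MM = P_F_MM * P_R_AFF0 * (2.0 * sigm((p_ra - P_PRA0) / P_S_MM) - 1.0);
    O_R_TGF = P_F_TGF * P_R_AFF0 *
        (2.0 * sigm((na_md / P_NA_MD0 - 1.0) / P_S_TGF) - 1.0);
    O_NA_MD = 1000.0 * na_md;
    O_R_P = ch.r_p; O_R_N = ch.r_n; O_P_E = ch.p_e;
    O_R_C = ch.r_c; O_P_CN = ch.p_cn;
    O_J_UO = ch.j_uo; O_F_UO = ch.f_uo;
    O_NA_UO = 1000.0 * (ch.j_uo > 0.0 ? ch.f_uo / ch.j_uo : 0.0);
    O_J_PN = ch.j_pn; O_J_EC = ch.j_ec;
    O_NA_PLASMA = 1000.0 * na_plasma;
}

static const R_CMethodDef CEntries[] = {
    {"burnmod_derivs", (DL_FUNC) &burnmod_derivs, 6},
    {"burnmod_init",   (DL_FUNC) &burnmod_init,   1},
    {NULL, NULL, 0}
};

void R_init_burnsim(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
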