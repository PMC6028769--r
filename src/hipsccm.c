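/* Right-hand side of the hiPSC-CM ventricular-like action-potential model.
 *
 * 23 state slots (SI units: volt, second, millimolar):
 *   1 Vm, 2 Ca_SR, 3 Ca_i, 4 legacy SR-release gate (frozen, kept for layout
 *   compatibility with the published model family), 5 d, 6 f1, 7 f2, 8 fCa,
 *   9 Xr1, 10 Xr2, 11 Xs, 12 h, 13 j, 14 m, 15 Xf, 16 q, 17 r, 18 Na_i,
 *   19 mL, 20 hL, 21 RyR_a, 22 RyR_o, 23 RyR_c.
 *
 * Compiled-code interface for deSolve (initmod/derivs) plus a .Call wrapper
 * for single-point evaluation from R.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define N_PARMS 52
#define N_STATE 23
#define N_OUT   18

static double parms[N_PARMS];

/* parameter slots */
#define P_Cm        parms[0]   /* F */
#define P_Vc        parms[1]   /* um^3 */
#define P_VSR       parms[2]   /* um^3 */
#define P_Nao       parms[3]   /* mM */
#define P_Ko        parms[4]   /* mM */
#define P_Cao       parms[5]   /* mM */
#define P_Ki        parms[6]   /* mM */
#define P_gNa       parms[7]   /* S/F */
#define P_gCaL      parms[8]   /* m^3/(F s) */
#define P_gKr       parms[9]
#define P_gKs       parms[10]
#define P_gK1       parms[11]
#define P_gf        parms[12]
#define P_gto       parms[13]
#define P_gbNa      parms[14]
#define P_gbCa      parms[15]
#define P_gPCa      parms[16]  /* A/F */
#define P_KPCa      parms[17]  /* mM */
#define P_PNaK      parms[18]  /* A/F */
#define P_KmK       parms[19]
#define P_KmNa      parms[20]
#define P_kNaCa     parms[21]  /* A/F */
#define P_KmCa      parms[22]
#define P_KmNai     parms[23]
#define P_Ksat      parms[24]
#define P_gam       parms[25]
#define P_alpha     parms[26]
#define P_gNaL      parms[27]  /* S/F */
#define P_VhhL      parms[28]  /* mV */
#define P_tauhL     parms[29]  /* s */
#define P_VmaxUp    parms[30]  /* mM/s */
#define P_Kup       parms[31]  /* mM */
#define P_Vleak     parms[32]  /* 1/s */
#define P_girel     parms[33]  /* mM/s (per mM gradient: 1/s) */
#define P_RyRa1     parms[34]  /* uM */
#define P_RyRa2     parms[35]  /* uM */
#define P_RyRahalf  parms[36]  /* uM */
#define P_RyRohalf  parms[37]  /* uM */
#define P_RyRchalf  parms[38]  /* uM */
#define P_RyRak     parms[39]  /* uM */
#define P_RyRok     parms[40]  /* uM */
#define P_RyRck     parms[41]  /* uM */
#define P_tauRyRa   parms[42]  /* s */
#define P_tauRyRo   parms[43]  /* s */
#define P_tauRyRc   parms[44]  /* s */
#define P_Ef        parms[45]  /* V */
#define P_PkNa      parms[46]
#define P_stim_on   parms[47]  /* 0/1 */
#define P_stim_amp  parms[48]  /* A */
#define P_stim_per  parms[49]  /* s */
#define P_stim_dur  parms[50]  /* s */
#define P_stim_t0   parms[51]  /* s */

static const double Fday = 96485.3415;  /* C/mol */
static const double Rgas = 8.314472;    /* J/(mol K) */
static const double Temp = 310.0;       /* K */

void hipsccm_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static void rhs_core(double t, const double *y, double *dy, double *out)
{
    const double RTF  = Rgas * Temp / Fday;
    const double FRT  = 1.0 / RTF;

    double Vm   = y[0];
    double CaSR = y[1];
    double Cai  = y[2];
    double d    = y[4];
    double f1   = y[5];
    double f2   = y[6];
    double fCa  = y[7];
    double Xr1  = y[8];
    double Xr2  = y[9];
    double Xs   = y[10];
    double h    = y[11];
    double j    = y[12];
    double m    = y[13];
    double Xf   = y[14];
    double q    = y[15];
    double r    = y[16];
    double Nai  = y[17];
    double mL   = y[18];
    double hL   = y[19];
    double RyRa = y[20];
    double RyRo = y[21];
    double RyRc = y[22];

    double V = Vm * 1000.0;             /* mV, for gate kinetics */

    /* reversal potentials */
    double E_Na = RTF * log(P_Nao / Nai);
    double E_Ca = 0.5 * RTF * log(P_Cao / Cai);
    double E_K  = RTF * log(P_Ko / P_Ki);
    double E_Ks = RTF * log((P_Ko + P_PkNa * P_Nao) / (P_Ki + P_PkNa * Nai));

    /* fast Na+ current */
    double i_Na = P_gNa * m * m * m * h * j * (Vm - E_Na);

    double h_inf   = 1.0 / sqrt(1.0 + exp((V + 72.1) / 5.7));
    double alpha_h = 0.057 * exp(-(V + 80.0) / 6.8);
    double beta_h  = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    double tau_h   = (Vm < -0.0385) ? 1.5 / ((alpha_h + beta_h) * 1000.0)
                                    : 1.5 * 1.6947 / 1000.0;

    double j_inf = 1.0 / sqrt(1.0 + exp((V + 72.1) / 5.7));
    double alpha_j, beta_j;
    if (Vm < -0.04) {
        alpha_j = (-25428.0 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
                  (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        beta_j  = 0.02424 * exp(-0.01052 * V) /
                  (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        alpha_j = 0.0;
        beta_j  = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }
    double tau_j = 7.0 / ((alpha_j + beta_j) * 1000.0);

    double m_inf    = pow(1.0 / (1.0 + exp((-V - 34.1) / 5.9)), 1.0 / 3.0);
    double alpha_m  = 1.0 / (1.0 + exp((-V - 60.0) / 5.0));
    double beta_m   = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + exp((V - 50.0) / 200.0));
    double tau_m    = alpha_m * beta_m / 1000.0;

    /* late Na+ current */
    double i_NaL = P_gNaL * mL * mL * mL * hL * (Vm - E_Na);

    double mL_inf   = 1.0 / (1.0 + exp(-(V + 42.85) / 5.264));
    double alpha_mL = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    double beta_mL  = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                      0.1 / (1.0 + exp((V - 50.0) / 200.0));
    double tau_mL   = alpha_mL * beta_mL / 1000.0;

    double hL_inf = 1.0 / (1.0 + exp((V + P_VhhL) / 7.488));
    double tau_hL = P_tauhL;

    /* funny current (Na+ component feeds Na_i bookkeeping) */
    double i_f   = P_gf * Xf * (Vm - P_Ef);
    double i_fNa = 0.42 * P_gf * Xf * (Vm - E_Na);

    double Xf_inf = 1.0 / (1.0 + exp((V + 77.85) / 5.0));
    double tau_Xf = 1900.0 / (1.0 + exp((V + 15.0) / 10.0)) / 1000.0;

    /* L-type Ca2+ current (GHK-like driving term) */
    double expv = exp(2.0 * Vm * FRT);
    double i_CaL;
    if (fabs(Vm) < 1e-9) {
        i_CaL = P_gCaL * 2.0 * Fday * (Cai - 0.341 * P_Cao) * d * f1 * f2 * fCa;
    } else {
        i_CaL = P_gCaL * 4.0 * Vm * Fday * FRT *
                (Cai * expv - 0.341 * P_Cao) / (expv - 1.0) * d * f1 * f2 * fCa;
    }

    double d_inf    = 1.0 / (1.0 + exp(-(V + 9.1) / 7.0));
    double alpha_d  = 0.25 + 1.4 / (1.0 + exp((-V - 35.0) / 13.0));
    double beta_d   = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double gamma_d  = 1.0 / (1.0 + exp((-V + 50.0) / 20.0));
    double tau_d    = (alpha_d * beta_d + gamma_d) / 1000.0;

    double f1_inf   = 1.0 / (1.0 + exp((V + 26.0) / 3.0));
    double constf1  = (f1_inf - f1 > 0.0) ? 1.0 + 1433.0 * (Cai - 50.0e-6) : 1.0;
    double tau_f1   = (20.0 +
                       1102.5 * exp(-pow((V + 27.0) * (V + 27.0) / 15.0, 2.0)) +
                       200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
                       180.0 / (1.0 + exp((30.0 + V) / 10.0))) * constf1 / 1000.0;

    double f2_inf = 0.33 + 0.67 / (1.0 + exp((V + 32.0) / 4.0));
    double tau_f2 = (600.0 * exp(-(V + 25.0) * (V + 25.0) / 170.0) +
                     31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
                     16.0 / (1.0 + exp((30.0 + V) / 10.0))) / 1000.0;

    double alpha_fCa = 1.0 / (1.0 + pow(Cai / 0.0006, 8.0));
    double beta_fCa  = 0.1 / (1.0 + exp((Cai - 0.0009) / 0.0001));
    double gamma_fCa = 0.3 / (1.0 + exp((Cai - 0.00075) / 0.0008));
    double fCa_inf   = (alpha_fCa + beta_fCa + gamma_fCa) / 1.3156;
    double constfCa  = (Vm > -0.06 && fCa_inf > fCa) ? 0.0 : 1.0;
    double tau_fCa   = 0.002;

    /* transient outward K+ current */
    double i_to = P_gto * (Vm - E_K) * q * r;

    double q_inf = 1.0 / (1.0 + exp((V + 53.0) / 13.0));
    double tau_q = (6.06 + 39.102 /
                    (0.57 * exp(-0.08 * (V + 44.0)) +
                     0.065 * exp(0.1 * (V + 45.93)))) / 1000.0;

    double r_inf = 1.0 / (1.0 + exp(-(V - 22.3) / 18.75));
    double tau_r = (2.75352 + 14.40516 /
                    (1.037 * exp(0.09 * (V + 30.61)) +
                     0.369 * exp(-0.12 * (V + 23.84)))) / 1000.0;

    /* slow delayed rectifier */
    double i_Ks = P_gKs * (Vm - E_Ks) * Xs * Xs *
                  (1.0 + 0.6 / (1.0 + pow(3.8e-5 / Cai, 1.4)));

    double Xs_inf   = 1.0 / (1.0 + exp((-V - 20.0) / 16.0));
    double alpha_Xs = 1100.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
    double beta_Xs  = 1.0 / (1.0 + exp((-60.0 + V) / 20.0));
    double tau_Xs   = alpha_Xs * beta_Xs / 1000.0;

    /* rapid delayed rectifier (Ca_o-dependent activation midpoint) */
    double i_Kr = P_gKr * (Vm - E_K) * Xr1 * Xr2 * sqrt(P_Ko / 5.4);

    double L0 = 0.025, Qf = 2.3;
    double V_half = 1000.0 * (-RTF / Qf *
                    log(pow(1.0 + P_Cao / 2.6, 4.0) /
                        (L0 * pow(1.0 + P_Cao / 0.58, 4.0))) - 0.019);

    double Xr1_inf   = 1.0 / (1.0 + exp((V_half - V) / 4.9));
    double alpha_Xr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    double beta_Xr1  = 6.0 / (1.0 + exp((30.0 + V) / 11.5));
    double tau_Xr1   = alpha_Xr1 * beta_Xr1 / 1000.0;

    double Xr2_inf   = 1.0 / (1.0 + exp((V + 88.0) / 50.0));
    double alpha_Xr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    double beta_Xr2  = 1.12 / (1.0 + exp((-60.0 + V) / 20.0));
    double tau_Xr2   = alpha_Xr2 * beta_Xr2 / 1000.0;

    /* inward rectifier (instantaneous gating) */
    double VEK      = V - E_K * 1000.0;
    double alpha_K1 = 3.91 / (1.0 + exp(0.5942 * (VEK - 200.0)));
    double beta_K1  = (-1.509 * exp(0.0002 * (VEK + 100.0)) +
                       exp(0.5886 * (VEK - 10.0))) /
                      (1.0 + exp(0.4547 * VEK));
    double XK1_inf  = alpha_K1 / (alpha_K1 + beta_K1);
    double i_K1     = P_gK1 * XK1_inf * (Vm - E_K) * sqrt(P_Ko / 5.4);

    /* Na+/Ca2+ exchanger */
    double i_NaCa = P_kNaCa *
        (exp(P_gam * Vm * FRT) * Nai * Nai * Nai * P_Cao -
         exp((P_gam - 1.0) * Vm * FRT) * P_Nao * P_Nao * P_Nao * Cai * P_alpha) /
        ((P_KmNai * P_KmNai * P_KmNai + P_Nao * P_Nao * P_Nao) *
         (P_KmCa + P_Cao) *
         (1.0 + P_Ksat * exp((P_gam - 1.0) * Vm * FRT)));

    /* Na+/K+ pump */
    double i_NaK = P_PNaK * P_Ko / (P_Ko + P_KmK) * Nai / (Nai + P_KmNa) /
                   (1.0 + 0.1245 * exp(-0.1 * Vm * FRT) +
                    0.0353 * exp(-Vm * FRT));

    /* sarcolemmal Ca2+ pump and background currents */
    double i_PCa = P_gPCa * Cai / (Cai + P_KPCa);
    double i_bNa = P_gbNa * (Vm - E_Na);
    double i_bCa = P_gbCa * (Vm - E_Ca);

    /* SR fluxes: SERCA uptake, leak, RyR release */
    double i_up   = P_VmaxUp / (1.0 + P_Kup * P_Kup / (Cai * Cai));
    double i_leak = (CaSR - Cai) * P_Vleak;

    double RyR_SRCa = 1.0 - 1.0 / (1.0 + exp((CaSR - 0.3) / 0.1));
    double i_rel    = P_girel * RyR_SRCa * RyRo * RyRc * (CaSR - Cai);

    double Caium = 1000.0 * Cai;   /* uM, scale of the RyR gate sigmoids */

    double RyRa_inf = P_RyRa1 - P_RyRa2 /
                      (1.0 + exp((Caium - P_RyRahalf) / P_RyRak));
    double RyRo_inf = 1.0 - 1.0 /
                      (1.0 + exp((Caium - (RyRa + P_RyRohalf)) / P_RyRok));
    double RyRc_inf = 1.0 /
                      (1.0 + exp((Caium - (RyRa + P_RyRchalf)) / P_RyRck));

    /* asymmetric gate kinetics: deactivation 10x faster than activation,
       recovery from inactivation 2x slower than inactivation */
    double tau_o = (RyRo_inf >= RyRo) ? P_tauRyRo : 0.1 * P_tauRyRo;
    double tau_c = (RyRc_inf >= RyRc) ? 2.0 * P_tauRyRc : P_tauRyRc;

    /* stimulus (rectangular pulse train), depolarizing positive */
    double i_stim = 0.0;
    if (P_stim_on > 0.5 && t >= P_stim_t0) {
        double phase = fmod(t - P_stim_t0, P_stim_per);
        if (phase < P_stim_dur)
            i_stim = P_stim_amp / P_Cm;
    }

    /* Ca2+ buffering (rapid-buffer approximation) */
    double BufC = 0.25, KbufC = 0.001, BufSR = 10.0, KbufSR = 0.3;
    double Cai_buf  = 1.0 / (1.0 + BufC * KbufC / ((Cai + KbufC) * (Cai + KbufC)));
    double CaSR_buf = 1.0 / (1.0 + BufSR * KbufSR / ((CaSR + KbufSR) * (CaSR + KbufSR)));

    double vol_fac = P_Cm / (2.0 * P_Vc * Fday * 1e-18);  /* A/F -> mM/s */

    dy[0]  = -(i_K1 + i_to + i_Kr + i_Ks + i_CaL + i_NaK + i_Na + i_NaL +
               i_NaCa + i_PCa + i_f + i_bNa + i_bCa) + i_stim;
    dy[1]  = CaSR_buf * P_Vc / P_VSR * (i_up - (i_rel + i_leak));
    dy[2]  = Cai_buf * (i_leak - i_up + i_rel -
                        (i_CaL + i_bCa + i_PCa - 2.0 * i_NaCa) * vol_fac);
    dy[3]  = 0.0;                         /* legacy gate slot */
    dy[4]  = (d_inf - d) / tau_d;
    dy[5]  = (f1_inf - f1) / tau_f1;
    dy[6]  = (f2_inf - f2) / tau_f2;
    dy[7]  = constfCa * (fCa_inf - fCa) / tau_fCa;
    dy[8]  = (Xr1_inf - Xr1) / tau_Xr1;
    dy[9]  = (Xr2_inf - Xr2) / tau_Xr2;
    dy[10] = (Xs_inf - Xs) / tau_Xs;
    dy[11] = (h_inf - h) / tau_h;
    dy[12] = (j_inf - j) / tau_j;
    dy[13] = (m_inf - m) / tau_m;
    dy[14] = (Xf_inf - Xf) / tau_Xf;
    dy[15] = (q_inf - q) / tau_q;
    dy[16] = (r_inf - r) / tau_r;
    dy[17] = -P_Cm * (i_Na + i_NaL + i_bNa + 3.0 * i_NaK + 3.0 * i_NaCa + i_fNa) /
             (Fday * P_Vc * 1e-18);
    dy[18] = (mL_inf - mL) / tau_mL;
    dy[19] = (hL_inf - hL) / tau_hL;
    dy[20] = (RyRa_inf - RyRa) / P_tauRyRa;
    dy[21] = (RyRo_inf - RyRo) / tau_o;
    dy[22] = (RyRc_inf - RyRc) / tau_c;

    if (out) {
        out[0]  = i_Na;
        out[1]  = i_NaL;
        out[2]  = i_CaL;
        out[3]  = i_f;
        out[4]  = i_to;
        out[5]  = i_Kr;
        out[6]  = i_Ks;
        out[7]  = i_K1;
        out[8]  = i_NaK;
        out[9]  = i_NaCa;
        out[10] = i_PCa;
        out[11] = i_bNa;
        out[12] = i_bCa;
        out[13] = i_rel;
        out[14] = i_up;
        out[15] = i_leak;
        out[16] = i_stim;
        out[17] = i_fNa;
    }
}

void hipsccm_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    if (*neq != N_STATE)
        error("state vector must have %d elements", N_STATE);
    rhs_core(*t, y, ydot, (ip[0] >= N_OUT) ? yout : NULL);
}

/* single-point evaluation for tests and diagnostics */
SEXP hipsccm_rhs_call(SEXP t_, SEXP y_, SEXP p_)
{
    if (LENGTH(y_) != N_STATE)
        error("state vector must have %d elements", N_STATE);
    if (LENGTH(p_) != N_PARMS)
        error("parameter vector must have %d elements", N_PARMS);
    double t = REAL(t_)[0];
    double saved[N_PARMS];
    memcpy(saved, parms, sizeof(parms));
    memcpy(parms, REAL(p_), sizeof(parms));

    SEXP dy  = PROTECT(allocVector(REALSXP, N_STATE));
    SEXP out = PROTECT(allocVector(REALSXP, N_OUT));
    rhs_core(t, REAL(y_), REAL(dy), REAL(out));
    memcpy(parms, saved, sizeof(parms));

    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, dy);
    SET_VECTOR_ELT(res, 1, out);
    UNPROTECT(3);
    return res;
}
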