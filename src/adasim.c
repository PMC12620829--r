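/* Coupled minimal-PBPK + humoral immune response right-hand side.
 *
 * State vector (18):
 *   0 depot   SC depot, nmol drug
 *   1 plasma  nmol drug
 *   2 lymph   lymph node, nmol drug
 *   3 tisv    tissue vascular, nmol drug
 *   4 tise    tissue endosomal, nmol drug
 *   5 tisi    tissue interstitial, nmol drug
 *   6 IDi  7 IDm                immature / mature dendritic cells (count)
 *   8 NT   9 AT  10 MT          naive / activated / memory drug-specific T
 *  11 NB  12 AB  13 MB          naive / activated / memory drug-specific B
 *  14 SP  15 LP                 short- / long-lived plasma cells
 *  16 ADA   free anti-drug antibody, nM (plasma)
 *  17 CPLX  1:1 ADA-drug complex, nM (plasma)
 *
 * Parameter vector layout mirrors pack_parms() in R/rhs.R; the two must be
 * kept in lock step (cross-checked by a derivative-equality test).
 */
#include <R.h>
#include <math.h>

#define N_PARMS 224
#define MAX_MTX 160

static double p[N_PARMS];

void adasim_init(void (*odeparms)(int *, double *))
{
    int N = N_PARMS;
    odeparms(&N, p);
}

/* methotrexate central concentration (nM) from precomputed exponential
 * terms: per dose, sum_j coef[j] * exp(lambda[j] * (t - t_dose)) */
static double mtx_conc(double t)
{
    int n = (int) p[56];
    double c = 0.0;
    for (int i = 0; i < n; i++) {
        double td = p[63 + i];
        if (t >= td) {
            double dt = t - td;
            for (int j = 0; j < 3; j++)
                c += p[60 + j] * exp(p[57 + j] * dt);
        }
    }
    return c > 0.0 ? c : 0.0;
}

void adasim_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    /* non-negative working copies: transient solver undershoot must not
     * generate spurious negative fluxes */
    double depot = fmax(y[0], 0.0), plasma = fmax(y[1], 0.0);
    double lymph = fmax(y[2], 0.0), tisv = fmax(y[3], 0.0);
    double tise = fmax(y[4], 0.0), tisi = fmax(y[5], 0.0);
    double IDi = fmax(y[6], 0.0), IDm = fmax(y[7], 0.0);
    double NT = fmax(y[8], 0.0), AT = fmax(y[9], 0.0), MT = fmax(y[10], 0.0);
    double NB = fmax(y[11], 0.0), AB = fmax(y[12], 0.0), MB = fmax(y[13], 0.0);
    double SP = fmax(y[14], 0.0), LP = fmax(y[15], 0.0);
    double ADA = fmax(y[16], 0.0), CPLX = fmax(y[17], 0.0);

    double Vp = p[0], Vln = p[1], Vv = p[2], Vi = p[4];
    double Qb = p[5], Ql = p[6], sigma = p[7], kup = p[8], kret = p[9];
    double CL = p[10], ka = p[11], inf_rate = p[12];
    int immune_on = p[13] > 0.5;

    double Cp = plasma / Vp, Cln = lymph / Vln, Cv = tisv / Vv,
           Ci = tisi / Vi;

    double bind = 0.0; /* nM/h net complex formation in plasma */
    if (immune_on)
        bind = p[50] * Cp * ADA - p[51] * CPLX;

    ydot[0] = -ka * depot;
    ydot[1] = ka * depot + inf_rate - CL * Cp - Qb * Cp
              + (Qb - Ql) * Cv + Ql * Cln - bind * Vp;
    ydot[2] = Ql * Ci - Ql * Cln;
    ydot[3] = Qb * Cp - (Qb - Ql) * Cv - Ql * (1.0 - sigma) * Cv
              - kup * tisv + kret * tise;
    ydot[4] = kup * tisv - kret * tise;
    ydot[5] = Ql * (1.0 - sigma) * Cv - Ql * Ci;

    if (!immune_on) {
        for (int i = 6; i < 18; i++) ydot[i] = 0.0;
        return;
    }

    double u = p[14], K = p[15];
    int n_epi = (int) p[16];

    /* per-epitope presented-antigen signal S_e = u * AgVS * w_e with
     * w_e = sum over the subject's expressed alleles of (100/rank - 1)^2,
     * precomputed per subject */
    double AgVS = Cv;
    double Ttot = NT + AT + MT;
    double frac = (IDm + Ttot > 0.0) ? IDm / (IDm + Ttot) : 0.0;
    double S_tot = 0.0, D_sum = 0.0;
    for (int e = 0; e < n_epi; e++) {
        double S = u * AgVS * p[17 + e];
        S_tot += S;
        if (S > 0.0)
            D_sum += frac * S / (S + K);
    }
    double stim = (S_tot > 0.0) ? S_tot / (S_tot + K) : 0.0;
    /* steeper saturation gate for clonal T expansion */
    double S2 = S_tot * S_tot, Kp = p[53];
    double stim_p = (S_tot > 0.0) ? S2 / (S2 + Kp * Kp) : 0.0;

    /* methotrexate inhibitory Emax on T-cell proliferation */
    double f_mtx = 1.0;
    if (p[56] > 0.0) {
        double cm = mtx_conc(*t);
        f_mtx = 1.0 - p[54] * cm / (p[55] + cm);
    }

    /* dendritic cells: antigen-driven plus a small constitutive
     * maturation flux (keeps a baseline mature-DC pool) */
    double mat = (p[24] * stim + p[25]) * IDi;
    ydot[6] = p[22] - p[23] * IDi - mat;
    ydot[7] = mat - p[26] * IDm;

    /* T lineage */
    double actT = p[27] * D_sum * NT;
    double recall = p[33] * p[27] * D_sum * MT;
    double prolT = p[28] * f_mtx * stim_p * AT * (1.0 - AT / p[29]);
    ydot[8] = -actT;
    ydot[9] = actT + recall + prolT - (p[30] + p[31]) * AT;
    ydot[10] = p[31] * AT - p[32] * MT - recall;

    /* B lineage: activation needs antigen in blood and a trace of
     * cognate T-cell help; proliferation additionally needs an
     * expanded T compartment (larger half-constant) */
    double help_act = AT / (AT + p[35]);
    double help_prol = AT / (AT + p[36]);
    double stimB = Cp / (Cp + p[37]);
    double actB = p[34] * NB * stimB * help_act;
    double prolB = p[38] * stimB * help_prol * AB * (1.0 - AB / p[39]);
    ydot[11] = -actB;
    ydot[12] = actB + prolB - (p[40] + p[41] + p[42] + p[43]) * AB;
    ydot[13] = p[43] * AB - p[44] * MB;
    ydot[14] = p[41] * AB - p[45] * SP;
    ydot[15] = p[42] * AB - p[46] * LP;

    /* ADA secretion into plasma, 1:1 binding, complex clearance */
    double sec = (p[47] * SP + p[48] * LP) / Vp;
    ydot[16] = sec - bind - p[49] * ADA;
    ydot[17] = bind - p[52] * CPLX;
}
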