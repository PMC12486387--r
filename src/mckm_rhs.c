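/* Compiled right-hand side of the eight-state batch kinetic model,
 * in the deSolve compiled-model convention (initfunc / derivs / root).
 *
 * State order:  Xv, P, glc, glu, gln, amm, lac, mu_est
 * Parms order:  the 13 kinetic parameters in canonical order
 *               (mu_max, k_d, K_glc, Y_X_glc, Y_X_gln, Y_X_glu, Y_lac_glc,
 *                Y_X_amm, Y_gln_glu, Y_P_X, Y_X_lac, m_glc, KD_amm),
 *               then alpha_glc, then the as-printed switch flag (0/1).
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double p[15];

void mckm_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, p);
}

void mckm_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double mu_max = p[0], k_d = p[1], K_glc = p[2], Y_X_glc = p[3],
        Y_X_gln = p[4], Y_X_glu = p[5], Y_lac_glc = p[6], Y_X_amm = p[7],
        Y_gln_glu = p[8], Y_P_X = p[9], Y_X_lac = p[10], m_glc = p[11],
        KD_amm = p[12], alpha = p[13], as_printed = p[14];

    /* rates are evaluated on states clamped at zero */
    const double Xv  = y[0] > 0 ? y[0] : 0;
    const double glc = y[2] > 0 ? y[2] : 0;
    const double amm = y[5] > 0 ? y[5] : 0;

    const double mu   = mu_max * glc / (K_glc + glc);
    const double mu_d = amm > 0 ? k_d * amm / (KD_amm + amm) : 0;
    const double q_glc = mu / Y_X_glc + m_glc;

    const int consume = as_printed != 0 ? (glc >= alpha) : (glc < alpha);
    const double q_lac = consume ? -mu / Y_X_lac : Y_lac_glc * q_glc;

    ydot[0] = (mu - mu_d) * Xv;                                  /* Xv  */
    ydot[1] = mu * Y_P_X * Xv;                                   /* P   */
    ydot[2] = -q_glc * Xv;                                       /* glc */
    ydot[3] = -(mu / Y_X_glu) * Xv;                              /* glu */
    ydot[4] = -(mu / Y_X_gln) * Xv + Y_gln_glu * (mu / Y_X_glu) * Xv;
    ydot[5] = (mu / Y_X_amm) * Xv;                               /* amm */
    ydot[6] = q_lac * Xv;                                        /* lac */

    /* no concentration leaves zero downwards: outgoing flux ramps linearly
     * to zero over the last 1e-6 concentration units, keeping the RHS
     * continuous for the step-size control */
    for (int i = 0; i < 7; i++)
        if (ydot[i] < 0) {
            double w = y[i] / 1e-6;
            if (w < 0) w = 0; else if (w > 1) w = 1;
            ydot[i] *= w;
        }

    ydot[7] = mu_max * ydot[2] * K_glc /
        ((K_glc + glc) * (K_glc + glc));                         /* mu_est */
}

/* root: glucose crossing the lactate-switch threshold */
void mckm_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    gout[0] = y[2] - p[13];
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_mckm(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
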