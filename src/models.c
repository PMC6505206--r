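/* Right-hand sides of the c-Myc degradation ODE systems, in the
 * deSolve compiled-model convention (initializer + derivative pair).
 *
 * The pulsed inputs E(t), G(t) and the switch alpha(t) are piecewise
 * constant; the R-level integrator restarts at every discontinuity and
 * passes the segment-constant signal levels in through the parameter
 * vector, so the derivatives seen by the solver are smooth.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* --- Model 1: FBXW7, phosphorylation-dependent ------------------------
 * parms: k1..k11, GF, F_T, E, G                       (15 values)
 * states: x1, x2, x3, x4, Fstar                        (5 states)
 */
static double p1[15];

void mycdeg_init1(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, p1);
}

void mycdeg_deriv1(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *k = p1;           /* k[0] = k1, ..., k[10] = k11 */
    const double GF = p1[11], FT = p1[12], E = p1[13], G = p1[14];
    const double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3], Fs = y[4];

    ydot[0] = k[0] * GF - k[1] * x1 - k[2] * E * x1;
    ydot[1] = k[2] * E * x1 - k[3] * x2 - k[4] * G * x2;
    ydot[2] = k[4] * G * x2 - k[5] * x3 - k[6] * Fs * x3 + k[9] * x4;
    ydot[3] = k[6] * Fs * x3 - (k[9] + k[10]) * x4;
    ydot[4] = k[7] * x3 * (FT - Fs) - k[8] * Fs;
}

/* --- Model 2: Skp2, phosphorylation-independent -----------------------
 * parms: k1, k2, k11, k12, k13, k14, GF                (7 values)
 * states: x1, x4, S                                    (3 states)
 */
static double p2[7];

void mycdeg_init2(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, p2);
}

void mycdeg_deriv2(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double k1 = p2[0], k2 = p2[1], k11 = p2[2], k12 = p2[3],
                 k13 = p2[4], k14 = p2[5], GF = p2[6];
    const double x1 = y[0], x4 = y[1], S = y[2];

    ydot[0] = k1 * GF - k2 * x1 - k12 * x1 * S;
    ydot[1] = k12 * x1 * S - k11 * x4;
    ydot[2] = k13 * x1 - k14 * S;
}

/* --- Combined model with exclusive switch -----------------------------
 * parms: k1..k14, GF, F_T, E, G, aF, aS               (20 values)
 * states: x1, x2, x3, x4, Fstar, S                     (6 states)
 *
 * aF multiplies the FBXW7 activation term and aS the Skp2 activation
 * term.  The switched model uses (aF, aS) = (alpha, 1 - alpha); the
 * no-switch variant runs with both set to 1.
 */
static double pc[20];

void mycdeg_initc(void (*odeparms)(int *, double *))
{
    int n = 20;
    odeparms(&n, pc);
}

void mycdeg_derivc(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *k = pc;           /* k[0] = k1, ..., k[13] = k14 */
    const double GF = pc[14], FT = pc[15], E = pc[16], G = pc[17],
                 aF = pc[18], aS = pc[19];
    const double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3],
                 Fs = y[4], S = y[5];

    ydot[0] = k[0] * GF - k[1] * x1 - k[2] * E * x1 - k[11] * x1 * S;
    ydot[1] = k[2] * E * x1 - k[3] * x2 - k[4] * G * x2;
    ydot[2] = k[4] * G * x2 - k[5] * x3 - k[6] * Fs * x3 + k[9] * x4;
    ydot[3] = k[6] * Fs * x3 - (k[9] + k[10]) * x4 + k[11] * x1 * S;
    ydot[4] = aF * k[7] * x3 * (FT - Fs) - k[8] * Fs;
    ydot[5] = aS * k[12] * x1 - k[13] * S;
}

static const R_CMethodDef CEntries[] = {
    {NULL, NULL, 0}
};

void R_init_mycdeg(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);  /* deSolve looks the symbols up by name */
}
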