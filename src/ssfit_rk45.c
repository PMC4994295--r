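/* Self-contained adaptive Dormand-Prince 5(4) integrator for the
 * compiled model zoo. Used for the inner (perturbation-experiment)
 * simulations during integration of the optimization flow: the outer
 * stiff solver then never needs to re-enter an external ODE library.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define SSFIT_MAXEQ 160

/* from ssfit_models.c */
void ssfit_init(void (*odeparms)(int *, double *));
void ssfit_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static double *g_parms;
static void local_odeparms(int *n, double *dest)
{
    int i;
    for (i = 0; i < *n; i++) dest[i] = g_parms[i];
}

static void frhs(int neq, double t, double *y, double *ydot)
{
    ssfit_derivs(&neq, &t, y, ydot, NULL, NULL);
}

/* Dormand-Prince coefficients */
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                    c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113,
                    b4 = 125.0 / 192, b5 = -2187.0 / 6784,
                    b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

/* integrate from times[0] through all output times; returns the
 * deSolve-style output matrix [t | y] or signals an R error */
SEXP ssfit_rk45(SEXP s_parms, SEXP s_y0, SEXP s_times, SEXP s_rtol,
                SEXP s_atol)
{
    int neq = LENGTH(s_y0), n_t = LENGTH(s_times);
    double rtol = REAL(s_rtol)[0], atol = REAL(s_atol)[0];
    double *times = REAL(s_times);
    double y[SSFIT_MAXEQ], ynew[SSFIT_MAXEQ], err[SSFIT_MAXEQ];
    double k1[SSFIT_MAXEQ], k2[SSFIT_MAXEQ], k3[SSFIT_MAXEQ],
           k4[SSFIT_MAXEQ], k5[SSFIT_MAXEQ], k6[SSFIT_MAXEQ],
           k7[SSFIT_MAXEQ], ytmp[SSFIT_MAXEQ];
    double t, h, tend;
    int i, j, out, fsal = 0;
    long nstep = 0;
    SEXP ans;
    double *res;

    if (neq > SSFIT_MAXEQ)
        error("ssfit_rk45: system too large (%d equations)", neq);
    g_parms = REAL(s_parms);
    ssfit_init(local_odeparms);

    ans = PROTECT(allocMatrix(REALSXP, n_t, neq + 1));
    res = REAL(ans);
    for (i = 0; i < neq; i++) y[i] = REAL(s_y0)[i];
    t = times[0];
    res[0] = t;
    for (i = 0; i < neq; i++) res[(i + 1) * n_t] = y[i];

    tend = times[n_t - 1];
    h = (tend - t) * 1e-3;
    if (h <= 0) h = 1e-6;

    for (out = 1; out < n_t; out++) {
        double tout = times[out];
        while (t < tout * (1 - 1e-14) && t < tout) {
            double hs = h, enorm, scale_fac;
            if (t + hs > tout) hs = tout - t;
            if (!fsal) frhs(neq, t, y, k1);
            for (i = 0; i < neq; i++)
                ytmp[i] = y[i] + hs * a21 * k1[i];
            frhs(neq, t + c2 * hs, ytmp, k2);
            for (i = 0; i < neq; i++)
                ytmp[i] = y[i] + hs * (a31 * k1[i] + a32 * k2[i]);
            frhs(neq, t + c3 * hs, ytmp, k3);
            for (i = 0; i < neq; i++)
                ytmp[i] = y[i] + hs * (a41 * k1[i] + a42 * k2[i] +
                                       a43 * k3[i]);
            frhs(neq, t + c4 * hs, ytmp, k4);
            for (i = 0; i < neq; i++)
                ytmp[i] = y[i] + hs * (a51 * k1[i] + a52 * k2[i] +
                                       a53 * k3[i] + a54 * k4[i]);
            frhs(neq, t + c5 * hs, ytmp, k5);
            for (i = 0; i < neq; i++)
                ytmp[i] = y[i] + hs * (a61 * k1[i] + a62 * k2[i] +
                                       a63 * k3[i] + a64 * k4[i] +
                                       a65 * k5[i]);
            frhs(neq, t + hs, ytmp, k6);
            for (i = 0; i < neq; i++)
                ynew[i] = y[i] + hs * (b1 * k1[i] + b3 * k3[i] +
                                       b4 * k4[i] + b5 * k5[i] +
                                       b6 * k6[i]);
            frhs(neq, t + hs, ynew, k7);
            enorm = 0.0;
            for (i = 0; i < neq; i++) {
                double sc, e;
                e = hs * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                          e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
                sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew[i]));
                e /= sc;
                enorm += e * e;
            }
            enorm = sqrt(enorm / neq);
            if (!R_FINITE(enorm)) {
                UNPROTECT(1);
                error("ssfit_rk45: non-finite state near t = %g", t);
            }
            if (enorm <= 1.0) {
                t += hs;
                for (i = 0; i < neq; i++) {
                    y[i] = ynew[i];
                    k1[i] = k7[i]; /* FSAL */
                }
                fsal = 1;
            }
            /* on rejection k1 = f(t, y) remains valid */
            scale_fac = 0.9 * pow(fmax(enorm, 1e-10), -0.2);
            if (scale_fac < 0.2) scale_fac = 0.2;
            if (scale_fac > 5.0) scale_fac = 5.0;
            h = hs * scale_fac;
            if (++nstep > 2000000) {
                UNPROTECT(1);
                error("ssfit_rk45: step budget exhausted near t = %g", t);
            }
        }
        res[out] = tout;
        for (j = 0; j < neq; j++) res[(j + 1) * n_t + out] = y[j];
    }
    UNPROTECT(1);
    return ans;
}
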