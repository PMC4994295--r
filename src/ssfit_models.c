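/* Compiled vector fields, Jacobians and forward-sensitivity systems for
 * the built-in model zoo, in the deSolve compiled-function interface.
 *
 * The augmented state is laid out as
 *   y = [ x (n_x) | S_theta (n_x * n_theta, column-major)
 *        | S_x0 (n_x * n_x, column-major) ]
 * matching the R-level fallback in simulate_trajectory().
 *
 * Parameter vector layout (padded to SSFIT_MAXPARMS from R):
 *   p = [ model_id, n_x, n_theta, n_u, sens_flag, freeze_flag,
 *         theta (n_theta), u (n_u) ]
 * freeze_flag = 1 evaluates nonautonomous terms at t = 0 (the control
 * vector field used by the steady-state machinery).
 */

#include <R.h>
#include <math.h>

#define SSFIT_MAXPARMS 128
#define SSFIT_MAXNX 8

static double p[SSFIT_MAXPARMS];

void ssfit_init(void (*odeparms)(int *, double *))
{
    int n = SSFIT_MAXPARMS;
    odeparms(&n, p);
}

/* conversion process: dx/dt = th2 - (th1 u + th2) x */
static void conversion_eval(double t, const double *x, const double *th,
                            const double *u, double *f, double *jx,
                            double *jth, int want_jac)
{
    double k = th[0] * u[0] + th[1];
    f[0] = th[1] - k * x[0];
    if (want_jac) {
        jx[0] = -k;
        jth[0] = -u[0] * x[0]; /* d f / d th1 */
        jth[1] = 1.0 - x[0];   /* d f / d th2 */
    }
}

/* NGF-ERK: theta = (k1, k2, k3T, k4, sE, k5, sigma2) */
static void ngf_eval(double t, const double *x, const double *th,
                     const double *u, double *f, double *jx, double *jth,
                     int want_jac)
{
    double k1 = th[0], k2 = th[1], k3T = th[2], k4 = th[3], sE = th[4],
           k5 = th[5];
    f[0] = k1 * u[0] * (k3T - x[0]) - k2 * x[0];
    f[1] = (x[0] + k4) * (sE - x[1]) - k5 * x[1];
    if (want_jac) {
        /* jx column-major 2x2 */
        jx[0] = -k1 * u[0] - k2; /* df1/dx1 */
        jx[1] = sE - x[1];       /* df2/dx1 */
        jx[2] = 0.0;             /* df1/dx2 */
        jx[3] = -(x[0] + k4) - k5;
        /* jth column-major 2x7 (zero-initialized by caller) */
        jth[0] = u[0] * (k3T - x[0]); /* df1/dk1 */
        jth[2] = -x[0];               /* df1/dk2 */
        jth[4] = k1 * u[0];           /* df1/dk3T */
        jth[7] = sE - x[1];           /* df2/dk4  (col 4, row 2) */
        jth[9] = x[0] + k4;           /* df2/dsE */
        jth[11] = -x[1];              /* df2/dk5 */
    }
}

/* Raf/MEK/ERK in relative phosphorylation levels.
 * theta = (k1_0, k1_1, tau1, tau2, k2, k3Raf0, K2, k4, k5MEK0, K3, k6,
 *          [K1 if h1], s1_1.., s2_1..); u = (sora, UO126).
 * Scaling parameters enter only the observation map (R level): their
 * vector-field Jacobian columns stay zero. */
static void raf_eval(double t, const double *x, const double *th,
                     const double *u, double *f, double *jx, double *jth,
                     int want_jac, int h1, int nth)
{
    double k10 = th[0], k11 = th[1], tau1 = th[2], tau2 = th[3],
           k2 = th[4], k3R = th[5], K2 = th[6], k4 = th[7], k5M = th[8],
           K3 = th[9], k6 = th[10];
    double e1 = exp(-t / tau1), e2 = exp(-t / tau2);
    double km = k10 + k11 * (1.0 - e1) * e2;
    double xi = 1.0, K1 = 0.0;
    double a2 = k3R * K2 / (K2 + u[0]);
    double a3 = k5M * K3 / (K3 + u[1]);

    if (h1) {
        K1 = th[11];
        xi = K1 / (K1 + x[2]);
    }
    f[0] = km * xi * (1.0 - x[0]) - k2 * x[0];
    f[1] = a2 * x[0] * (1.0 - x[1]) - k4 * x[1];
    f[2] = a3 * x[1] * (1.0 - x[2]) - k6 * x[2];

    if (want_jac) {
        /* jx column-major 3x3, zero-initialized by caller */
        jx[0] = -km * xi - k2;      /* df1/dx1 */
        jx[1] = a2 * (1.0 - x[1]);  /* df2/dx1 */
        jx[4] = -a2 * x[0] - k4;    /* df2/dx2 */
        jx[5] = a3 * (1.0 - x[2]);  /* df3/dx2 */
        jx[8] = -a3 * x[1] - k6;    /* df3/dx3 */
        if (h1) {
            double d = K1 + x[2];
            jx[6] = -km * (1.0 - x[0]) * K1 / (d * d); /* df1/dx3 */
        }
        /* jth column-major 3 x nth, zero-initialized by caller;
         * entry (row i, col j) at jth[i + 3*j] */
        jth[0 + 3 * 0] = xi * (1.0 - x[0]);                  /* k1_0 */
        jth[0 + 3 * 1] = (1.0 - e1) * e2 * xi * (1.0 - x[0]); /* k1_1 */
        jth[0 + 3 * 2] = -k11 * e1 * (t / (tau1 * tau1)) * e2 * xi *
                         (1.0 - x[0]);                       /* tau1 */
        jth[0 + 3 * 3] = k11 * (1.0 - e1) * e2 * (t / (tau2 * tau2)) *
                         xi * (1.0 - x[0]);                  /* tau2 */
        jth[0 + 3 * 4] = -x[0];                              /* k2 */
        jth[1 + 3 * 5] = (K2 / (K2 + u[0])) * x[0] * (1.0 - x[1]);
        jth[1 + 3 * 6] = k3R * u[0] / ((K2 + u[0]) * (K2 + u[0])) *
                         x[0] * (1.0 - x[1]);                /* K2 */
        jth[1 + 3 * 7] = -x[1];                              /* k4 */
        jth[2 + 3 * 8] = (K3 / (K3 + u[1])) * x[1] * (1.0 - x[2]);
        jth[2 + 3 * 9] = k5M * u[1] / ((K3 + u[1]) * (K3 + u[1])) *
                         x[1] * (1.0 - x[2]);                /* K3 */
        jth[2 + 3 * 10] = -x[2];                             /* k6 */
        if (h1) {
            double d = K1 + x[2];
            jth[0 + 3 * 11] = km * (1.0 - x[0]) * x[2] / (d * d);
        }
    }
}

void ssfit_model_eval(int id, double t, const double *x,
                       const double *th, const double *u, double *f,
                       double *jx, double *jth, int nx, int nth,
                       int want_jac)
{
    if (want_jac) {
        int k;
        for (k = 0; k < nx * nx; k++) jx[k] = 0.0;
        for (k = 0; k < nx * nth; k++) jth[k] = 0.0;
    }
    switch (id) {
    case 1: conversion_eval(t, x, th, u, f, jx, jth, want_jac); break;
    case 2: ngf_eval(t, x, th, u, f, jx, jth, want_jac); break;
    case 3: raf_eval(t, x, th, u, f, jx, jth, want_jac, 1, nth); break;
    case 4: raf_eval(t, x, th, u, f, jx, jth, want_jac, 0, nth); break;
    default: error("ssfit: unknown compiled model id %d", id);
    }
}

void ssfit_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int id = (int) p[0], nx = (int) p[1], nth = (int) p[2],
        nu = (int) p[3], sens = (int) p[4], freeze = (int) p[5];
    const double *th = p + 6, *u = p + 6 + nth;
    double tt = freeze ? 0.0 : *t;
    double f[SSFIT_MAXNX];
    double jx[SSFIT_MAXNX * SSFIT_MAXNX];
    double jth[SSFIT_MAXNX * (SSFIT_MAXPARMS - 6)];
    int i, j, k;

    (void) neq; (void) yout; (void) ip; (void) nu;
    ssfit_model_eval(id, tt, y, th, u, f, jx, jth, nx, nth, sens);
    for (i = 0; i < nx; i++) ydot[i] = f[i];
    if (sens) {
        /* d S_theta = Jx S_theta + Jth */
        for (j = 0; j < nth; j++)
            for (i = 0; i < nx; i++) {
                double s = jth[i + nx * j];
                for (k = 0; k < nx; k++)
                    s += jx[i + nx * k] * y[nx + nx * j + k];
                ydot[nx + nx * j + i] = s;
            }
        /* d S_x0 = Jx S_x0 */
        for (j = 0; j < nx; j++)
            for (i = 0; i < nx; i++) {
                double s = 0.0;
                for (k = 0; k < nx; k++)
                    s += jx[i + nx * k] * y[nx + nx * nth + nx * j + k];
                ydot[nx + nx * nth + nx * j + i] = s;
            }
    }
}
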