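/* Linearly-implicit Rosenbrock-W integrator (two-stage, second order,
 * L-stable, gamma = 1 + 1/sqrt(2)) for the compiled augmented
 * sensitivity systems. The W-matrix uses the state Jacobian df/dx
 * applied block-wise to the state and every sensitivity column — the
 * exact stiff coupling — while the mild cross-coupling through the
 * Jacobians' state dependence is left to the W-property. One n_x * n_x
 * LU factorization per step integrates the whole augmented system, so
 * the cost per step is independent of the stiffness that cripples
 * explicit methods at extreme parameter draws.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define SSFIT_MAXPARMS 128
#define SSFIT_MAXEQ 160
#define SSFIT_MAXNX 8

void ssfit_model_eval(int id, double t, const double *x,
                      const double *th, const double *u, double *f,
                      double *jx, double *jth, int nx, int nth,
                      int want_jac);

/* augmented rhs straight from the model callbacks (no static state) */
static void aug_rhs(int id, int nx, int nth, int sens, int freeze,
                    const double *th, const double *u, double t,
                    const double *y, double *ydot)
{
    double f[SSFIT_MAXNX];
    double jx[SSFIT_MAXNX * SSFIT_MAXNX];
    double jth[SSFIT_MAXNX * (SSFIT_MAXPARMS - 6)];
    double tt = freeze ? 0.0 : t;
    int i, j, k;

    ssfit_model_eval(id, tt, y, th, u, f, jx, jth, nx, nth, sens);
    for (i = 0; i < nx; i++) ydot[i] = f[i];
    if (sens) {
        for (j = 0; j < nth; j++)
            for (i = 0; i < nx; i++) {
                double s = jth[i + nx * j];
                for (k = 0; k < nx; k++)
                    s += jx[i + nx * k] * y[nx + nx * j + k];
                ydot[nx + nx * j + i] = s;
            }
        for (j = 0; j < nx; j++)
            for (i = 0; i < nx; i++) {
                double s = 0.0;
                for (k = 0; k < nx; k++)
                    s += jx[i + nx * k] * y[nx + nx * nth + nx * j + k];
                ydot[nx + nx * nth + nx * j + i] = s;
            }
    }
}

/* LU with partial pivoting for the small W-matrix */
static int lu_factor(double *a, int n, int *piv)
{
    int i, j, k;
    for (k = 0; k < n; k++) {
        int pk = k;
        double amax = fabs(a[k + n * k]);
        for (i = k + 1; i < n; i++)
            if (fabs(a[i + n * k]) > amax) {
                amax = fabs(a[i + n * k]); pk = i;
            }
        if (amax < 1e-300) return 1;
        piv[k] = pk;
        if (pk != k)
            for (j = 0; j < n; j++) {
                double tmp = a[k + n * j];
                a[k + n * j] = a[pk + n * j];
                a[pk + n * j] = tmp;
            }
        for (i = k + 1; i < n; i++) {
            a[i + n * k] /= a[k + n * k];
            for (j = k + 1; j < n; j++)
                a[i + n * j] -= a[i + n * k] * a[k + n * j];
        }
    }
    return 0;
}

static void lu_solve(const double *a, int n, const int *piv, double *b)
{
    int i, j;
    for (i = 0; i < n; i++) {
        if (piv[i] != i) {
            double tmp = b[i]; b[i] = b[piv[i]]; b[piv[i]] = tmp;
        }
        for (j = 0; j < i; j++) b[i] -= a[i + n * j] * b[j];
    }
    for (i = n - 1; i >= 0; i--) {
        for (j = i + 1; j < n; j++) b[i] -= a[i + n * j] * b[j];
        b[i] /= a[i + n * i];
    }
}

SEXP ssfit_rosw(SEXP s_parms, SEXP s_y0, SEXP s_times, SEXP s_rtol,
                SEXP s_atol)
{
    const double *p = REAL(s_parms);
    int id = (int) p[0], nx = (int) p[1], nth = (int) p[2],
        sens = (int) p[4], freeze = (int) p[5];
    const double *th = p + 6, *u = p + 6 + nth;
    int neq = LENGTH(s_y0), n_t = LENGTH(s_times);
    double rtol = REAL(s_rtol)[0], atol = REAL(s_atol)[0];
    const double gam = 1.0 + 1.0 / M_SQRT2;
    double *times = REAL(s_times);
    double y[SSFIT_MAXEQ], f0[SSFIT_MAXEQ], f1[SSFIT_MAXEQ];
    double k1[SSFIT_MAXEQ], k2[SSFIT_MAXEQ], ytmp[SSFIT_MAXEQ];
    double jx[SSFIT_MAXNX * SSFIT_MAXNX];
    double jth[SSFIT_MAXNX * (SSFIT_MAXPARMS - 6)];
    double fdum[SSFIT_MAXNX];
    double W[SSFIT_MAXNX * SSFIT_MAXNX];
    int piv[SSFIT_MAXNX];
    int n_blocks = neq / nx;
    double t, h, tend;
    long nstep = 0;
    int i, b, out;
    SEXP ans;
    double *res;

    if (neq > SSFIT_MAXEQ || nx > SSFIT_MAXNX || neq % nx != 0)
        error("ssfit_rosw: bad system dimensions");
    (void) sens;

    ans = PROTECT(allocMatrix(REALSXP, n_t, neq + 1));
    res = REAL(ans);
    for (i = 0; i < neq; i++) y[i] = REAL(s_y0)[i];
    t = times[0];
    res[0] = t;
    for (i = 0; i < neq; i++) res[(i + 1) * n_t] = y[i];

    tend = times[n_t - 1];
    h = (tend - t) * 1e-2;
    if (h <= 0) h = 1e-6;

    for (out = 1; out < n_t; out++) {
        double tout = times[out];
        while (t < tout * (1 - 1e-14) && t < tout) {
            double hs = h, enorm, fac;
            int singular;
            if (t + hs > tout) hs = tout - t;

            aug_rhs(id, nx, nth, LENGTH(s_y0) > nx, freeze, th, u, t, y,
                    f0);
            ssfit_model_eval(id, freeze ? 0.0 : t, y, th, u, fdum, jx,
                             jth, nx, nth, 1);
            /* W = I - gam*h*Jx, shared by all blocks */
            for (i = 0; i < nx * nx; i++) W[i] = -gam * hs * jx[i];
            for (i = 0; i < nx; i++) W[i + nx * i] += 1.0;
            singular = lu_factor(W, nx, piv);
            if (singular) {
                h = hs / 4; if (++nstep > 500000) goto fail;
                continue;
            }
            /* stage 1: (I - gam h J) k1 = h F(y) */
            for (i = 0; i < neq; i++) k1[i] = hs * f0[i];
            for (b = 0; b < n_blocks; b++)
                lu_solve(W, nx, piv, k1 + b * nx);
            /* stage 2: (I - gam h J) k2 = h F(y + k1) - 2 k1 */
            for (i = 0; i < neq; i++) ytmp[i] = y[i] + k1[i];
            aug_rhs(id, nx, nth, LENGTH(s_y0) > nx, freeze, th, u,
                    t + hs, ytmp, f1);
            for (i = 0; i < neq; i++) k2[i] = hs * f1[i] - 2.0 * k1[i];
            for (b = 0; b < n_blocks; b++)
                lu_solve(W, nx, piv, k2 + b * nx);

            enorm = 0.0;
            for (i = 0; i < neq; i++) {
                double ynew = y[i] + 1.5 * k1[i] + 0.5 * k2[i];
                double e = 0.5 * (k1[i] + k2[i]);
                double sc = atol + rtol * fmax(fabs(y[i]), fabs(ynew));
                e /= sc;
                enorm += e * e;
                ytmp[i] = ynew;
            }
            enorm = sqrt(enorm / neq);
            if (!R_FINITE(enorm)) {
                h = hs / 4;
                if (++nstep > 500000) goto fail;
                continue;
            }
            if (enorm <= 1.0) {
                t += hs;
                for (i = 0; i < neq; i++) y[i] = ytmp[i];
            }
            fac = 0.9 * pow(fmax(enorm, 1e-10), -1.0 / 3.0);
            if (fac < 0.2) fac = 0.2;
            if (fac > 5.0) fac = 5.0;
            h = hs * fac;
            if (++nstep > 500000) goto fail;
        }
        res[out] = tout;
        for (i = 0; i < neq; i++) res[(i + 1) * n_t + out] = y[i];
    }
    UNPROTECT(1);
    return ans;
fail:
    UNPROTECT(1);
    error("ssfit_rosw: step budget exhausted near t = %g", t);
    return R_NilValue;
}
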