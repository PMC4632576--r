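/* Fixed-step classical 4th-order Runge-Kutta reference integrator with
 * event detection by sign change + linear interpolation inside a step.
 * Deterministic oracle for the adaptive solver; same state layout as rhs.c.
 *
 * Event semantics mirror the model: the response spans naive-cell
 * activation to the end of clonal contraction. The first downward crossing
 * of p_min by P (pathogen controlled) is recorded but NOT terminal;
 * integration continues until the total effector population returns to its
 * baseline after having exceeded baseline + eps (contraction end, terminal)
 * or until t_max.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

#define RK_MAXN 64
#define RK_MAXDIM (2 * RK_MAXN + 1)

static void deriv(int n, double alpha, const double *k, const double *lam,
                  const double *beta, const double *y, double *ydot)
{
    double P = y[2 * n];
    double clearance = 0.0;
    for (int i = 0; i < n; i++) {
        double T = y[2 * i];
        ydot[2 * i] = y[2 * i + 1];
        ydot[2 * i + 1] = -k[i] * T + lam[i] * P;
        clearance += beta[i] * T;
    }
    ydot[2 * n] = alpha * P - clearance * P;
}

static double total_T(int n, const double *y)
{
    double s = 0.0;
    for (int i = 0; i < n; i++) s += y[2 * i];
    return s;
}

SEXP C_rk4_run(SEXP s_y0, SEXP s_k, SEXP s_lam, SEXP s_beta, SEXP s_alpha,
               SEXP s_h, SEXP s_tmax, SEXP s_pmin, SEXP s_T0tot, SEXP s_eps,
               SEXP s_dtout)
{
    int n = LENGTH(s_k);
    int dim = 2 * n + 1;
    double alpha = REAL(s_alpha)[0];
    double h = REAL(s_h)[0];
    double tmax = REAL(s_tmax)[0];
    double pmin = REAL(s_pmin)[0];
    double T0tot = REAL(s_T0tot)[0];
    double eps = REAL(s_eps)[0];
    double dtout = REAL(s_dtout)[0];
    const double *k = REAL(s_k), *lam = REAL(s_lam), *beta = REAL(s_beta);

    if (n > RK_MAXN) error("at most %d clones are supported", RK_MAXN);
    if (LENGTH(s_y0) != dim)
        error("state length %d does not match %d clones", LENGTH(s_y0), n);
    if (h <= 0 || tmax <= 0 || dtout <= 0)
        error("h, t_max and dt_out must all be positive");

    long nsteps = (long) ceil(tmax / h - 1e-12);
    long stride = (long) fmax(1.0, floor(dtout / h + 0.5));
    long mmax = nsteps / stride + 4;

    double *times = (double *) R_alloc(mmax, sizeof(double));
    double *states = (double *) R_alloc((size_t) mmax * dim, sizeof(double));
    double y[RK_MAXDIM], ynew[RK_MAXDIM], yev[RK_MAXDIM];
    double k1[RK_MAXDIM], k2[RK_MAXDIM], k3[RK_MAXDIM], k4[RK_MAXDIM],
           tmp[RK_MAXDIM];

    memcpy(y, REAL(s_y0), dim * sizeof(double));

    int armed = total_T(n, y) > T0tot + eps;
    int controlled = 0, ended = 0;
    double t_control = NA_REAL, t_end = NA_REAL;
    double y_control[RK_MAXDIM], y_end[RK_MAXDIM];
    long m = 0;

    times[m] = 0.0;
    memcpy(states + (size_t) m * dim, y, dim * sizeof(double));
    m++;

    double t = 0.0;
    for (long step = 0; step < nsteps && !ended; step++) {
        double hs = fmin(h, tmax - t);
        if (hs <= 0) break;

        deriv(n, alpha, k, lam, beta, y, k1);
        for (int j = 0; j < dim; j++) tmp[j] = y[j] + 0.5 * hs * k1[j];
        deriv(n, alpha, k, lam, beta, tmp, k2);
        for (int j = 0; j < dim; j++) tmp[j] = y[j] + 0.5 * hs * k2[j];
        deriv(n, alpha, k, lam, beta, tmp, k3);
        for (int j = 0; j < dim; j++) tmp[j] = y[j] + hs * k3[j];
        deriv(n, alpha, k, lam, beta, tmp, k4);
        for (int j = 0; j < dim; j++)
            ynew[j] = y[j] + hs / 6.0 *
                      (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

        double tnew = t + hs;
        if (!R_FINITE(ynew[2 * n]) || fabs(ynew[2 * n]) > 1e15)
            error("pathogen population overflow at t = %g (alpha = %g)",
                  tnew, alpha);

        /* first downward crossing of p_min: record, keep integrating */
        if (!controlled) {
            double g1a = y[2 * n] - pmin, g1b = ynew[2 * n] - pmin;
            if (g1a > 0 && g1b <= 0) {
                double frac = g1a / (g1a - g1b);
                controlled = 1;
                t_control = t + frac * hs;
                for (int j = 0; j < dim; j++)
                    y_control[j] = y[j] + frac * (ynew[j] - y[j]);
                if (t_control > times[m - 1] + 1e-15 * fmax(1.0, t_control)) {
                    times[m] = t_control;
                    memcpy(states + (size_t) m * dim, y_control,
                           dim * sizeof(double));
                    m++;
                }
            }
        }

        /* contraction end: total T back to baseline after the guarded
         * excursion; terminal */
        if (armed) {
            double g2a = total_T(n, y) - T0tot;
            double g2b = total_T(n, ynew) - T0tot;
            if (g2a > 0 && g2b <= 0) {
                double frac = g2a / (g2a - g2b);
                ended = 1;
                t_end = t + frac * hs;
                for (int j = 0; j < dim; j++)
                    yev[j] = y[j] + frac * (ynew[j] - y[j]);
                /* pathogen control inside the same step, before the end */
                if (!controlled) {
                    double g1a = y[2 * n] - pmin;
                    double g1b = yev[2 * n] - pmin;
                    if (g1a > 0 && g1b <= 0) {
                        double fr = g1a / (g1a - g1b);
                        controlled = 1;
                        t_control = t + fr * frac * hs;
                        for (int j = 0; j < dim; j++)
                            y_control[j] = y[j] + fr * (yev[j] - y[j]);
                    }
                }
                memcpy(y_end, yev, dim * sizeof(double));
                if (t_end > times[m - 1] + 1e-15 * fmax(1.0, t_end)) {
                    times[m] = t_end;
                    memcpy(states + (size_t) m * dim, yev,
                           dim * sizeof(double));
                    m++;
                }
                break;
            }
        } else if (total_T(n, ynew) > T0tot + eps) {
            armed = 1;
        }

        memcpy(y, ynew, dim * sizeof(double));
        t = tnew;
        if ((step + 1) % stride == 0 || step == nsteps - 1) {
            times[m] = t;
            memcpy(states + (size_t) m * dim, y, dim * sizeof(double));
            m++;
        }
    }

    SEXP r_times = PROTECT(allocVector(REALSXP, m));
    SEXP r_states = PROTECT(allocMatrix(REALSXP, m, dim));
    for (long i = 0; i < m; i++) {
        REAL(r_times)[i] = times[i];
        for (int j = 0; j < dim; j++)
            REAL(r_states)[i + m * (size_t) j] = states[(size_t) i * dim + j];
    }
    SEXP r_tc = PROTECT(ScalarReal(t_control));
    SEXP r_yc = PROTECT(allocVector(REALSXP, controlled ? dim : 0));
    if (controlled) memcpy(REAL(r_yc), y_control, dim * sizeof(double));
    SEXP r_te = PROTECT(ScalarReal(t_end));
    SEXP r_ye = PROTECT(allocVector(REALSXP, ended ? dim : 0));
    if (ended) memcpy(REAL(r_ye), y_end, dim * sizeof(double));

    const char *nms[] = {"times", "states", "t_control", "state_control",
                         "t_end", "state_end", ""};
    SEXP out = PROTECT(mkNamed(VECSXP, nms));
    SET_VECTOR_ELT(out, 0, r_times);
    SET_VECTOR_ELT(out, 1, r_states);
    SET_VECTOR_ELT(out, 2, r_tc);
    SET_VECTOR_ELT(out, 3, r_yc);
    SET_VECTOR_ELT(out, 4, r_te);
    SET_VECTOR_ELT(out, 5, r_ye);
    UNPROTECT(7);
    return out;
}
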