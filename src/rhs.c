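/* Right-hand sides and root functions for the clonal-response ODE system,
 * callable from deSolve's lsodar.
 *
 * State layout: (T_1, V_1, ..., T_n, V_n, P), length 2n + 1, where V_i = T_i'.
 * Parameter vector layout (padded to fixed length on the R side):
 *   [0] n        number of clones
 *   [1] alpha    pathogen per-capita growth rate
 *   [2] p_min    pathogen infectivity threshold (root 1)
 *   [3] T_thresh total-T threshold (root 2; arming or baseline, set per phase)
 *   [4          .. 4 +   n) k_i    per-clone elastic coefficients
 *   [4 +   MAXN .. 4 + MAXN + n)   lam_i  per-clone antigenic coefficients
 *   [4 + 2*MAXN .. 4 + 2*MAXN + n) beta_i per-clone clearance coefficients
 */

#include <R.h>

#define TCT_MAXN 64
#define TCT_NPAR (4 + 3 * TCT_MAXN)

static double pars[TCT_NPAR];

void tct_init_clones(void (*odeparms)(int *, double *))
{
    int N = TCT_NPAR;
    odeparms(&N, pars);
}

void tct_deriv_clones(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int n = (int) pars[0];
    double alpha = pars[1];
    const double *k = pars + 4;
    const double *lam = pars + 4 + TCT_MAXN;
    const double *beta = pars + 4 + 2 * TCT_MAXN;
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

void tct_root_clones(int *neq, double *t, double *y, int *ng, double *gout,
                     double *out, int *ip)
{
    int n = (int) pars[0];
    double Ttot = 0.0;
    for (int i = 0; i < n; i++) Ttot += y[2 * i];
    gout[0] = y[2 * n] - pars[2];
    gout[1] = Ttot - pars[3];
}
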