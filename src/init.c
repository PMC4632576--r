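#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_rk4_run(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
               SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_rk4_run", (DL_FUNC) &C_rk4_run, 11},
    {NULL, NULL, 0}
};

void R_init_tcelltol(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* deSolve looks up tct_deriv_clones / tct_root_clones / tct_init_clones
     * by name, so dynamic symbol lookup stays enabled. */
    R_useDynamicSymbols(dll, TRUE);
}
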