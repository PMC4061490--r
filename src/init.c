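#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_eig_partial(SEXP Cmat, SEXP vlow);
SEXP C_psd_medavg(SEXP P, SEXP wmap, SEXP order);

static const R_CallMethodDef CallEntries[] = {
    {"C_eig_partial", (DL_FUNC) &C_eig_partial, 2},
    {"C_psd_medavg", (DL_FUNC) &C_psd_medavg, 3},
    {NULL, NULL, 0}
};

void R_init_perfspec(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
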