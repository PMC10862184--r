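#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_bmntd(SEXP Ds, SEXP Fs, SEXP perms);
SEXP C_bmntd_pairs(SEXP Ds, SEXP Fs, SEXP perms, SEXP ai, SEXP bi);

static const R_CallMethodDef CallEntries[] = {
    {"C_bmntd", (DL_FUNC) &C_bmntd, 3},
    {"C_bmntd_pairs", (DL_FUNC) &C_bmntd_pairs, 5},
    {NULL, NULL, 0}
};

void R_init_micropart(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
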