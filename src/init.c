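#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void burster_init(void (*odeparms)(int *, double *));
void burster_derivs(int *, double *, double *, double *, double *, int *);
void hco_init(void (*odeparms)(int *, double *));
void hco_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"burster_init",   (DL_FUNC) &burster_init,   1},
    {"burster_derivs", (DL_FUNC) &burster_derivs, 6},
    {"hco_init",       (DL_FUNC) &hco_init,       1},
    {"hco_derivs",     (DL_FUNC) &hco_derivs,     6},
    {NULL, NULL, 0}
};

void R_init_burstscan(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
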