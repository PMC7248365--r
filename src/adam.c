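/* In-place Adam parameter update.
 *
 * Updates par, m and v in place:
 *   m <- b1 * m + (1 - b1) * g
 *   v <- b2 * v + (1 - b2) * g^2
 *   par <- par - lr * (m / c1) / (sqrt(v / c2) + eps)
 * where c1, c2 are the bias-correction terms 1 - b1^t, 1 - b2^t.
 *
 * The caller (train_separator) owns all three buffers exclusively, so
 * the in-place mutation is safe and avoids re-allocating the full
 * parameter set on every mini-batch step.
 */
#include <R.h>
#include <Rinternals.h>
#include <math.h>

SEXP voxsep_adam_step(SEXP par, SEXP g, SEXP m, SEXP v,
                      SEXP lr, SEXP b1, SEXP b2, SEXP eps,
                      SEXP c1, SEXP c2)
{
    R_xlen_t n = XLENGTH(par);
    if (XLENGTH(g) != n || XLENGTH(m) != n || XLENGTH(v) != n)
        error("adam_step: length mismatch");
    double *p = REAL(par), *gr = REAL(g), *mm = REAL(m), *vv = REAL(v);
    const double LR = asReal(lr), B1 = asReal(b1), B2 = asReal(b2),
                 EPS = asReal(eps), C1 = asReal(c1), C2 = asReal(c2);
    for (R_xlen_t i = 0; i < n; i++) {
        const double gi = gr[i];
        mm[i] = B1 * mm[i] + (1.0 - B1) * gi;
        vv[i] = B2 * vv[i] + (1.0 - B2) * gi * gi;
        p[i] -= LR * (mm[i] / C1) / (sqrt(vv[i] / C2) + EPS);
    }
    return R_NilValue;
}

static const R_CallMethodDef CallEntries[] = {
    {"voxsep_adam_step", (DL_FUNC) &voxsep_adam_step, 10},
    {NULL, NULL, 0}
};

void R_init_voxsep(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
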