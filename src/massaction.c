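/* Generic mass-action derivative for deSolve.
 *
 * The network (reactant/net stoichiometry matrices and rate constants) is
 * staged from R with ma_set_network(); ma_deriv() is then passed to
 * deSolve::lsoda as a compiled derivative ("ma_deriv", dllname = "stochcrn",
 * initfunc = NULL).  Velocity of reaction j: k_j * prod_s conc_s^R[s,j],
 * with concentrations clipped to 0 inside the rate law only (integrator
 * state is never modified).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static int ns = 0, nr = 0;
static double *Rm = NULL;   /* ns x nr reactant coefficients */
static double *Sm = NULL;   /* ns x nr net stoichiometry (products - reactants) */
static double *kk = NULL;   /* nr rate constants */

SEXP ma_set_network(SEXP R_, SEXP S_, SEXP k_)
{
    if (Rm) { R_Free(Rm); R_Free(Sm); R_Free(kk); Rm = Sm = kk = NULL; }
    ns = Rf_nrows(R_);
    nr = Rf_ncols(R_);
    if (Rf_nrows(S_) != ns || Rf_ncols(S_) != nr || Rf_length(k_) != nr)
        Rf_error("inconsistent network dimensions");
    Rm = R_Calloc((size_t) ns * nr, double);
    Sm = R_Calloc((size_t) ns * nr, double);
    kk = R_Calloc((size_t) nr, double);
    memcpy(Rm, REAL(R_), sizeof(double) * ns * nr);
    memcpy(Sm, REAL(S_), sizeof(double) * ns * nr);
    memcpy(kk, REAL(k_), sizeof(double) * nr);
    return R_NilValue;
}

void ma_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    int s, j;
    if (*neq != ns) Rf_error("state length does not match staged network");
    for (s = 0; s < ns; s++) ydot[s] = 0.0;
    for (j = 0; j < nr; j++) {
        double v = kk[j];
        const double *rcol = Rm + (size_t) j * ns;
        const double *scol = Sm + (size_t) j * ns;
        for (s = 0; s < ns; s++) {
            double e = rcol[s];
            if (e != 0.0) {
                double c = y[s] > 0.0 ? y[s] : 0.0;
                v *= (e == 1.0) ? c : pow(c, e);
            }
        }
        for (s = 0; s < ns; s++)
            if (scol[s] != 0.0) ydot[s] += scol[s] * v;
    }
}

static const R_CallMethodDef callMethods[] = {
    {"ma_set_network", (DL_FUNC) &ma_set_network, 3},
    {NULL, NULL, 0}
};

/* registered as a C routine so deSolve can resolve it by name */
static const R_CMethodDef cMethods[] = {
    {"ma_deriv", (DL_FUNC) &ma_deriv, 6},
    {NULL, NULL, 0}
};

void R_init_stochcrn(DllInfo *info)
{
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
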