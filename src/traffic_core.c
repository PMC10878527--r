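/* Mass-action ODE core for the receptor trafficking network, in the
 * deSolve compiled-function interface. The network is passed as a flat,
 * fixed-length parameter vector:
 *
 *   p[0]        number of reactions nr (<= 128)
 *   p[1]        number of stoichiometry triplets m (<= 1024)
 *   p[2 .. ]    nr rate constants (statistical factor and area scaling
 *               already folded in)
 *   next nr     1-based index of first reactant (0 = zeroth order)
 *   next nr     1-based index of second reactant (0 = none; equal to the
 *               first index for homodimerization, giving k*x^2)
 *   next m      triplet row (species, 1-based)
 *   next m      triplet column (reaction, 1-based)
 *   next m      triplet value (signed stoichiometry)
 *
 * The vector is padded with zeros to PARMS_LEN on the R side.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define PARMS_LEN 2048
#define MAX_RXN 128

static double parms[PARMS_LEN];

void traffic_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

void traffic_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int nr = (int) parms[0];
    int m = (int) parms[1];
    const double *k = parms + 2;
    const double *i1 = parms + 2 + nr;
    const double *i2 = parms + 2 + 2 * nr;
    const double *ti = parms + 2 + 3 * nr;
    const double *tj = ti + m;
    const double *tv = tj + m;
    double rates[MAX_RXN];
    int j;

    for (j = 0; j < nr; j++) {
        double v = k[j];
        int a = (int) i1[j];
        int b = (int) i2[j];
        if (a > 0) v *= y[a - 1];
        if (b > 0) v *= y[b - 1];
        rates[j] = v;
    }
    for (j = 0; j < *neq; j++) ydot[j] = 0.0;
    for (j = 0; j < m; j++)
        ydot[(int) ti[j] - 1] += tv[j] * rates[(int) tj[j] - 1];
}

static const R_CMethodDef CEntries[] = {
    {NULL, NULL, 0}
};

void R_init_vegfrtraffic(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
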