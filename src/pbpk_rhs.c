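/* Whole-body PBPK right-hand side for deSolve.
 *
 * Two chemically identical species circulate: hot (radiolabelled) and cold
 * (unlabelled). Physical decay converts hot to cold in place; the species
 * sum is conserved together with cumulative urine.
 *
 * Parameter vector layout (see build_system() in R):
 *   p[0] = nt (number of tissues)
 *   p[1] = Vp (plasma volume, L)
 *   p[2] = fu (unbound plasma fraction)
 *   p[3] = GFR (L/min)
 *   p[4] = lambda_phys (1/min)
 *   p[5] = kon (L/nmol/min), p[6] = koff (1/min), p[7] = lambda_int (1/min)
 *   per tissue j (base = 8 + 5*j):
 *     Veff (accessible volume, L), Flow (L/min), Rtot (receptor capacity,
 *     nmol), lambda_rel (1/min), lambda_ns (1/min)
 *
 * State layout, per species block of size m = 2 + 3*nt (hot first):
 *   y[0] = plasma amount P (nmol)
 *   y[1+3j], y[2+3j], y[3+3j] = tissue j free F, bound B, internalized N
 *   y[1+3nt] = cumulative urine U (nmol)
 */
#include <R.h>

#define MAXPAR 128
static double parms[MAXPAR];

void initmod(void (*odeparms)(int *, double *))
{
    int n = MAXPAR;
    odeparms(&n, parms);
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    const int nt = (int) parms[0];
    const double Vp = parms[1], fu = parms[2], gfr = parms[3];
    const double lam = parms[4];
    const double kon = parms[5], koff = parms[6], lint = parms[7];
    const int m = 2 + 3 * nt;

    for (int s = 0; s < 2; s++) {
        const int o = s * m;
        const double Cp = y[o] / Vp;
        const double renal = gfr * fu * Cp;
        double dP = -renal;
        ydot[o + 1 + 3 * nt] = renal; /* urine */
        for (int j = 0; j < nt; j++) {
            const double Veff = parms[8 + 5 * j];
            const double flw  = parms[9 + 5 * j];
            const double Rtot = parms[10 + 5 * j];
            const double lrel = parms[11 + 5 * j];
            const double lns  = parms[12 + 5 * j];
            const double F = y[o + 1 + 3 * j];
            const double B = y[o + 2 + 3 * j];
            const double N = y[o + 3 + 3 * j];
            /* free receptors shared by both species */
            double Rfree = Rtot - y[2 + 3 * j] - y[m + 2 + 3 * j];
            if (Rfree < 0.0) Rfree = 0.0;
            const double Cf = F / Veff;
            const double exch = flw * (fu * Cp - Cf);
            const double bind = kon * Cf * Rfree;
            ydot[o + 1 + 3 * j] = exch - bind + koff * B + lrel * N - lns * F;
            ydot[o + 2 + 3 * j] = bind - (koff + lint) * B;
            ydot[o + 3 + 3 * j] = lint * B + lns * F - lrel * N;
            dP -= exch;
        }
        ydot[o] = dP;
    }
    /* physical decay: hot -> cold, every compartment incl. urine */
    for (int k = 0; k < m; k++) {
        const double d = lam * y[k];
        ydot[k]     -= d;
        ydot[m + k] += d;
    }
}
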