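/* Within-year yelloweye dynamics for deSolve::lsoda.
 *
 * State: Y[NAGE] (prey numbers-at-age). Predator numbers decay analytically
 * within the year, L_c(t) = L0_c * exp(-ZL_c * t), so they enter the RHS as
 * known functions of time rather than additional state.
 *
 * dY_i/dt = -(z_i + sum_c a[i,c] * L_c(t) / (1 + delta * sum_i' a[i',c] Y_i'
 *            + delta * q)) * Y_i
 *
 * where z_i = M^Y + nu_i * f (natural + bycatch/direct fishing mortality)
 * and c indexes the 2*NPRED predator (age, sex) classes.
 *
 * Parameter vector layout (doubles, fixed length):
 *   [0]                  delta
 *   [1]                  q
 *   [2 .. 2+NAGE-1]      z_i
 *   [.. +NCLS]           L0_c
 *   [.. +NCLS]           ZL_c
 *   [.. +NAGE*NCLS]      a[i,c], column-major (prey age fastest)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NAGE 65
#define NCLS 40
#define NPARMS (2 + NAGE + 2 * NCLS + NAGE * NCLS)

static double parms[NPARMS];

void ye_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void ye_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    const double delta = parms[0];
    const double q = parms[1];
    const double *z = parms + 2;
    const double *L0 = parms + 2 + NAGE;
    const double *ZL = parms + 2 + NAGE + NCLS;
    const double *a = parms + 2 + NAGE + 2 * NCLS;
    double pred[NAGE];
    int i, c;

    for (i = 0; i < NAGE; i++) pred[i] = 0.0;

    for (c = 0; c < NCLS; c++) {
        const double *ac = a + (size_t) NAGE * c;
        double Lc, s, w;
        if (L0[c] <= 0.0) continue;
        s = 0.0;
        for (i = 0; i < NAGE; i++) s += ac[i] * y[i];
        if (s == 0.0 && q == 0.0) continue;
        Lc = L0[c] * exp(-ZL[c] * (*t));
        w = Lc / (1.0 + delta * s + delta * q);
        for (i = 0; i < NAGE; i++) pred[i] += ac[i] * w;
    }

    for (i = 0; i < NAGE; i++)
        ydot[i] = -(z[i] + pred[i]) * y[i];
}
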