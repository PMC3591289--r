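/* Compiled right-hand sides for the fast-slow surrogate burster and the
 * two-cell half-center oscillator built from it, in the deSolve
 * compiled-function calling convention.  Units: state 1 is membrane
 * potential in mV, time in seconds; the underlying fast-slow system is
 * evaluated on the dimensionless variable x = (V - voff) / vsc and
 * sped up by the time-scale factor kappa (model time units per second).
 */
#include <R.h>
#include <math.h>

/* single cell: kappa a b c d r s xR I0 q g vsc voff */
#define NP_CELL 13
static double pc[NP_CELL];

void burster_init(void (*odeparms)(int *, double *))
{
    int n = NP_CELL;
    odeparms(&n, pc);
}

void burster_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double kappa = pc[0], a = pc[1], b = pc[2], c = pc[3], d = pc[4];
    double r = pc[5], s = pc[6], xR = pc[7], I0 = pc[8], q = pc[9];
    double g = pc[10], vsc = pc[11], voff = pc[12];
    double x = (y[0] - voff) / vsc;
    double I = I0 - q * g;

    ydot[0] = kappa * vsc * (y[1] - a*x*x*x + b*x*x - y[2] + I);
    ydot[1] = kappa * (c - d*x*x - y[1]);
    ydot[2] = kappa * r * (s * (x - xR) - y[2]);
}

/* HCO: kappa a b c d r s xR I0 q vsc voff g1 g2 gs xrev xth xsig taus */
#define NP_HCO 19
static double ph[NP_HCO];

void hco_init(void (*odeparms)(int *, double *))
{
    int n = NP_HCO;
    odeparms(&n, ph);
}

static double syn_gate(double x, double xth, double xsig)
{
    return 1.0 / (1.0 + exp(-(x - xth) / xsig));
}

/* state: V1 y1 z1 V2 y2 z2 s1 s2 */
void hco_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double kappa = ph[0], a = ph[1], b = ph[2], c = ph[3], d = ph[4];
    double r = ph[5], s = ph[6], xR = ph[7], I0 = ph[8], q = ph[9];
    double vsc = ph[10], voff = ph[11];
    double g1 = ph[12], g2 = ph[13], gs = ph[14], xrev = ph[15];
    double xth = ph[16], xsig = ph[17], taus = ph[18];

    double x1 = (y[0] - voff) / vsc, x2 = (y[3] - voff) / vsc;
    double isyn1 = gs * y[7] * (x1 - xrev);   /* onto cell 1 from cell 2 */
    double isyn2 = gs * y[6] * (x2 - xrev);

    ydot[0] = kappa * vsc * (y[1] - a*x1*x1*x1 + b*x1*x1 - y[2] + (I0 - q*g1) - isyn1);
    ydot[1] = kappa * (c - d*x1*x1 - y[1]);
    ydot[2] = kappa * r * (s * (x1 - xR) - y[2]);
    ydot[3] = kappa * vsc * (y[4] - a*x2*x2*x2 + b*x2*x2 - y[5] + (I0 - q*g2) - isyn2);
    ydot[4] = kappa * (c - d*x2*x2 - y[4]);
    ydot[5] = kappa * r * (s * (x2 - xR) - y[5]);
    ydot[6] = kappa * (syn_gate(x1, xth, xsig) - y[6]) / taus;
    ydot[7] = kappa * (syn_gate(x2, xth, xsig) - y[7]) / taus;
}
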