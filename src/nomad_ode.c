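/* Right-hand side and root (event test) functions for the nomadic-colonial
 * ODE system, in the deSolve compiled-code convention.
 *
 * State y = (n1, n2, K).  Populations are clamped at 0 and K is floored at
 * eps_K for rate evaluation only: an adaptive solver may probe slightly
 * outside the admissible region during a trial step, and the 1/K term in the
 * colonial growth rate is singular at K = 0.
 *
 * The switching rates of the threshold rule are discontinuous in K, so the
 * engine freezes the active branch (s12_on / s21_on) per integration segment
 * and restarts at every located root; the flags arrive here through the
 * parameter block.  Thresholds with sentinel magnitude >= 1e29 mean "watch
 * disabled" (the corresponding root function stays bounded away from zero).
 */

#include <R.h>

static double p[14];

#define P_R1      p[0]
#define P_R2      p[1]
#define P_RS      p[2]
#define P_A       p[3]
#define P_KMAX    p[4]
#define P_BOUNDED p[5]
#define P_S12     p[6]
#define P_S21     p[7]
#define P_L1W     p[8]
#define P_L2W     p[9]
#define P_BW      p[10]
#define P_WN2K    p[11]
#define P_WB      p[12]
#define P_EPSK    p[13]

void nc_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, p);
}

void nc_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double n1 = y[0] > 0.0 ? y[0] : 0.0;
    double n2 = y[1] > 0.0 ? y[1] : 0.0;
    double K  = y[2] > P_EPSK ? y[2] : P_EPSK;
    double mAK = P_A < K ? P_A : K;

    double g1 = -P_R1 * n1;
    double g2 = P_R2 * n2 * (n2 / mAK - 1.0) * (1.0 - n2 / K);
    double s12 = P_S12 > 0.5 ? P_RS : 0.0;
    double s21 = P_S21 > 0.5 ? P_RS : 0.0;

    double dK = 1.0 - n2;
    if (P_BOUNDED > 0.5)
        dK *= (1.0 - y[2] / P_KMAX);

    ydot[0] = g1 + s12 * n2 - s21 * n1;
    ydot[1] = g2 + s21 * n1 - s12 * n2;
    ydot[2] = dK;
}

void nc_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    gout[0] = (P_L1W > -1e29)              ? y[2] - P_L1W : 1.0;
    gout[1] = (P_L2W <  1e29)              ? y[2] - P_L2W : 1.0;
    gout[2] = (P_WN2K > 0.5)               ? y[1] - y[2]  : 1.0;
    gout[3] = (P_WB   > 0.5)               ? y[0] - P_BW  : 1.0;
}
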