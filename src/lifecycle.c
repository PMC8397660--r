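/* Six-compartment neutrophil life-cycle model for deSolve.
 *
 * States: prol, transit1, transit2, transit3, reserv, circ (cells/L).
 * One forcing function: the drug effect in (0, 1] multiplying the
 * Michaelis-Menten maturation flux between transit 2 and transit 3.
 * Feedback ratios clamp their state argument to a 1 cell/L floor; the
 * egress exponent (beta ~ 20) would otherwise overflow as circ -> 0.
 */
#include <R.h>
#include <math.h>

static double parms[13];
static double forcs[1];

#define k_prol parms[0]
#define k_tr1  parms[1]
#define k_tr2  parms[2]
#define k_d    parms[3]
#define k_tr4  parms[4]
#define k_out  parms[5]
#define k_elim parms[6]
#define v_max  parms[7]
#define k_m    parms[8]
#define gamma_ parms[9]
#define beta_  parms[10]
#define t2_h   parms[11]
#define circ_h parms[12]

#define effect forcs[0]

#define STATE_FLOOR 1.0

void lifecycle_init(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void lifecycle_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forcs);
}

void lifecycle_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double prol = y[0], t1 = y[1], t2 = y[2], t3 = y[3];
    double reserv = y[4], circ = y[5];

    double t2f = t2 > STATE_FLOOR ? t2 : STATE_FLOOR;
    double cf  = circ > STATE_FLOOR ? circ : STATE_FLOOR;
    double fb_prol = pow(t2_h / t2f, gamma_);
    double fb_egr  = pow(circ_h / cf, beta_);
    double mm = v_max * effect * t2 / (k_m + t2);

    ydot[0] = k_prol * fb_prol * prol - k_tr1 * prol;
    ydot[1] = k_tr1 * prol - (k_tr2 + k_d) * t1;
    ydot[2] = k_tr2 * t1 - mm - k_d * t2;
    ydot[3] = mm - (k_tr4 + k_d) * t3;
    ydot[4] = k_tr4 * t3 - (k_d + k_out * fb_egr) * reserv;
    ydot[5] = k_out * fb_egr * reserv - k_elim * circ;
}
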