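/* Compiled right-hand sides of the NF-kB model for deSolve.
 *
 * Parameter vector order must match .param_order in R/params.R:
 *  0 TR        1 totalIKK  2 totalNFkB 3 kv      4 kp      5 ka
 *  6 ki        7 kda       8 kbA20     9 kc2    10 kc3    11 kdegpin
 * 12 ka1      13 kd1      14 kdegf    15 kdegc  16 ki1    17 ke1f
 * 18 ke1c     19 ki2      20 ke2      21 h      22 k      23 kitria
 * 24 ktria    25 kdegtia  26 kitra    27 ktra   28 kdegta
 *
 * States are cytoplasmic-equivalent uM; derivatives are per minute
 * (uniform factor 60 over the per-second rate constants).
 */

#include <R.h>
#include <math.h>

#define NPAR 29
static double p[NPAR];

#define TR        p[0]
#define totalIKK  p[1]
#define totalNFkB p[2]
#define kv        p[3]
#define kp        p[4]
#define ka        p[5]
#define ki        p[6]
#define kda       p[7]
#define kbA20     p[8]
#define kc2       p[9]
#define kc3       p[10]
#define kdegpin   p[11]
#define ka1       p[12]
#define kd1       p[13]
#define kdegf     p[14]
#define kdegc     p[15]
#define ki1       p[16]
#define ke1f      p[17]
#define ke1c      p[18]
#define ki2       p[19]
#define ke2       p[20]
#define hillh     p[21]
#define hillk     p[22]
#define kitria    p[23]
#define ktria     p[24]
#define kdegtia   p[25]
#define kitra     p[26]
#define ktra      p[27]
#define kdegta    p[28]

#define TSCALE 60.0

void nfkb_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

/* reduced model, 11 states:
 * 0 IKKn 1 IKK 2 IkBa 3 IkBan 4 NFkB 5 NFkBn 6 IkBaNFkBn 7 pIkBaNFkB
 * 8 A20 9 A20t 10 IkBat */
void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double IKKn = y[0], IKK = y[1], IkBa = y[2], IkBan = y[3];
    double NFkB = y[4], NFkBn = y[5], Cn = y[6], Pc = y[7];
    double A20 = y[8], A20t = y[9], IkBat = y[10];

    double IKKi = totalIKK - IKKn - IKK;
    double Cc = totalNFkB - NFkB - NFkBn - Cn - Pc;

    double xn = kv * NFkBn;
    double xh = (xn > 0.0) ? pow(xn, hillh) : 0.0;
    double hillTx = xh / (pow(hillk, hillh) + xh);
    double inh = kbA20 / (kbA20 + TR * A20);

    ydot[0] = TSCALE * (kp * IKKi * inh - TR * ka * IKKn);
    ydot[1] = TSCALE * (TR * ka * IKKn - ki * IKK);
    ydot[2] = TSCALE * (ktria * IkBat - ka1 * IkBa * NFkB + kd1 * Cc
                        - kc2 * IKK * IkBa - kdegf * IkBa - ki2 * IkBa
                        + kv * ke2 * IkBan);
    ydot[3] = TSCALE * (ki2 * IkBa - kv * ke2 * IkBan
                        - kv * ka1 * IkBan * NFkBn + kd1 * Cn
                        - kdegf * IkBan);
    ydot[4] = TSCALE * (-ka1 * IkBa * NFkB + (kd1 + kdegc) * Cc
                        + kdegpin * Pc - ki1 * NFkB + kv * ke1f * NFkBn);
    ydot[5] = TSCALE * (ki1 * NFkB - kv * ke1f * NFkBn
                        - kv * ka1 * IkBan * NFkBn + kd1 * Cn);
    ydot[6] = TSCALE * (kv * ka1 * IkBan * NFkBn - kd1 * Cn
                        - kv * ke1c * Cn);
    ydot[7] = TSCALE * (kc3 * IKK * Cc - kdegpin * Pc);
    ydot[8] = TSCALE * (ktra * A20t - kda * A20);
    ydot[9] = TSCALE * (kitra * hillTx - kdegta * A20t);
    ydot[10] = TSCALE * (kitria * hillTx - kdegtia * IkBat);
}

/* full model, 14 states: reduced order plus 11 IKKi, 12 IkBaNFkB, 13 pIkBa */
void nfkb_derivs_full(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double IKKn = y[0], IKK = y[1], IkBa = y[2], IkBan = y[3];
    double NFkB = y[4], NFkBn = y[5], Cn = y[6], Pc = y[7];
    double A20 = y[8], A20t = y[9], IkBat = y[10];
    double IKKi = y[11], Cc = y[12], pIkBa = y[13];

    double xn = kv * NFkBn;
    double xh = (xn > 0.0) ? pow(xn, hillh) : 0.0;
    double hillTx = xh / (pow(hillk, hillh) + xh);
    double inh = kbA20 / (kbA20 + TR * A20);

    ydot[0] = TSCALE * (kp * IKKi * inh - TR * ka * IKKn);
    ydot[1] = TSCALE * (TR * ka * IKKn - ki * IKK);
    ydot[2] = TSCALE * (ktria * IkBat - ka1 * IkBa * NFkB + kd1 * Cc
                        - kc2 * IKK * IkBa - kdegf * IkBa - ki2 * IkBa
                        + kv * ke2 * IkBan);
    ydot[3] = TSCALE * (ki2 * IkBa - kv * ke2 * IkBan
                        - kv * ka1 * IkBan * NFkBn + kd1 * Cn
                        - kdegf * IkBan);
    ydot[4] = TSCALE * (-ka1 * IkBa * NFkB + (kd1 + kdegc) * Cc
                        + kdegpin * Pc - ki1 * NFkB + kv * ke1f * NFkBn);
    ydot[5] = TSCALE * (ki1 * NFkB - kv * ke1f * NFkBn
                        - kv * ka1 * IkBan * NFkBn + kd1 * Cn);
    ydot[6] = TSCALE * (kv * ka1 * IkBan * NFkBn - kd1 * Cn
                        - kv * ke1c * Cn);
    ydot[7] = TSCALE * (kc3 * IKK * Cc - kdegpin * Pc);
    ydot[8] = TSCALE * (ktra * A20t - kda * A20);
    ydot[9] = TSCALE * (kitra * hillTx - kdegta * A20t);
    ydot[10] = TSCALE * (kitria * hillTx - kdegtia * IkBat);
    ydot[11] = TSCALE * (ki * IKK - kp * IKKi * inh);
    ydot[12] = TSCALE * (ka1 * IkBa * NFkB - kd1 * Cc - kc3 * IKK * Cc
                         - kdegc * Cc + kv * ke1c * Cn);
    ydot[13] = TSCALE * (kc2 * IKK * IkBa - kdegpin * pIkBa);
}
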