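/* Compiled right-hand side of the Method-of-Lines system, node-major
 * layout: y[3i], y[3i+1], y[3i+2] = C_E^F, C_E^S, eps of interior node i
 * (0-based, node centre r_i = (i + 1/2) dr), bulk triple last.  Mirrors the
 * R reference implementation hydrolysis_rhs(); the free-enzyme balance is in
 * conservative finite-volume form so that total enzyme moles telescope
 * exactly.  Parameters are the scalars of one model instance, passed through
 * the deSolve initializer. */

#include <R.h>

static double parms[11];
#define N_NODES parms[0]  /* interior node count n                   */
#define DR      parms[1]  /* radial spacing, cm                      */
#define D_E     parms[2]  /* D_pore / tau, cm2/min                   */
#define K_ADS   parms[3]  /* cm3/(mol min)                           */
#define K_DES   parms[4]  /* 1/min                                   */
#define EROS    parms[5]  /* M_p MM_glu H_glu / rho_C_IV, cm3/mol    */
#define EPS_0   parms[6]
#define EPS_F   parms[7]
#define CS_MAX0 parms[8]  /* mol/cm3 total volume                    */
#define V_B     parms[9]  /* bulk volume per unit length, cm3        */
#define S_CYL   parms[10] /* outer surface per unit length, 2 pi R   */

void lignosim_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void lignosim_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int n = (int) N_NODES;
    const double dr = DR, de = D_E;
    const double span = EPS_F - EPS_0;
    const double cf_bulk = y[3 * n];
    double q_in = 0.0;          /* flux through the inner face of cell i */

    for (int i = 0; i < n; i++) {
        const double cf  = y[3 * i];
        const double cs  = y[3 * i + 1];
        const double eps = y[3 * i + 2];

        double eps_cl = eps;
        if (eps_cl < EPS_0) eps_cl = EPS_0;
        if (eps_cl > EPS_F) eps_cl = EPS_F;

        double cmax = 0.0;
        if (span > 0.0) {
            double frac = (EPS_F - eps_cl) / span;
            if (frac < 0.0) frac = 0.0;
            if (frac > 1.0) frac = 1.0;
            cmax = CS_MAX0 * frac;
        }
        const double dcs  = K_ADS * cf * (cmax - cs) - K_DES * cs;
        const double deps = (eps >= EPS_F) ? 0.0 : K_DES * cs * EROS;

        /* outward flux through the outer face of cell i (face radius
         * (i + 1) dr); the last face uses the one-sided second-order
         * surface gradient through the bulk value and the bulk-node
         * porosity (1) */
        double q_out;
        if (i < n - 1) {
            const double eps_next_raw = y[3 * (i + 1) + 2];
            double eps_next = eps_next_raw;
            if (eps_next < EPS_0) eps_next = EPS_0;
            if (eps_next > EPS_F) eps_next = EPS_F;
            const double eps_face = 0.5 * (eps_cl + eps_next);
            q_out = -eps_face * de * (y[3 * (i + 1)] - cf) / dr;
        } else {
            const double grad_R =
                (8.0 * cf_bulk - 9.0 * cf + y[3 * (n - 2)]) / (3.0 * dr);
            q_out = -de * grad_R;
        }

        /* net molar influx per shell volume: faces at (i+1)dr and i dr,
         * cell centre at (i + 1/2) dr */
        const double influx =
            -((i + 1) * q_out - i * q_in) / ((i + 0.5) * dr);

        double dcf;
        if (eps < 1e-12) {
            dcf = 0.0;          /* fully closed matrix transports nothing */
        } else {
            dcf = (influx - dcs - cf * deps) / eps;
        }

        ydot[3 * i]     = dcf;
        ydot[3 * i + 1] = dcs;
        ydot[3 * i + 2] = deps;

        q_in = q_out;
    }

    /* bulk node loses exactly what flows through the outer face */
    ydot[3 * n]     = S_CYL * q_in / V_B;
    ydot[3 * n + 1] = 0.0;
    ydot[3 * n + 2] = 0.0;
}
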