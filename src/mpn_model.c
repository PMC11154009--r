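/* Right-hand side of the 8-compartment MPN haematopoiesis model, compiled
 * for use with deSolve.  State ordering: x0, x1, x2, y0, y1, y2, a, s.
 * Parameter ordering must match mpn_param_names() on the R side. */

#include <R.h>

static double parms[26];

void mpn_initmod(void (*odeparms)(int *, double *))
{
    int n = 26;
    odeparms(&n, parms);
}

void mpn_derivs(int *neq, double *t, double *yv, double *ydot,
                double *yout, int *ip)
{
    /* The vector field is evaluated as-is also for marginally negative
     * iterates probed by adaptive steps: it is smooth there and restoring
     * (the orthant is forward-invariant), and keeping it smooth preserves
     * the accuracy of the solver's internal Jacobian. */
    double x0 = yv[0], x1 = yv[1], x2 = yv[2];
    double y0 = yv[3], y1 = yv[4], y2 = yv[5];
    double a  = yv[6], s  = yv[7];

    double alpha_x0 = parms[0],  alpha_x1 = parms[1];
    double alpha_y0 = parms[2],  alpha_y1 = parms[3];
    double p_x0 = parms[4],  p_x1 = parms[5];
    double p_y0 = parms[6],  p_y1 = parms[7];
    double c_xx = parms[8],  c_xy = parms[9];
    double c_yx = parms[10], c_yy = parms[11];
    double s_x0 = parms[12], s_y0 = parms[13];
    double A_x0 = parms[14], A_x1 = parms[15];
    double A_y0 = parms[16], A_y1 = parms[17];
    double d_x1 = parms[18], d_x2 = parms[19];
    double d_y1 = parms[20], d_y2 = parms[21];
    double e_a = parms[22], r_s = parms[23], e_s = parms[24], I = parms[25];

    double phi_x = 1.0 / (1.0 + c_xx * x0 + c_xy * y0);
    double phi_y = 1.0 / (1.0 + c_yx * x0 + c_yy * y0);
    double sig_x = s / (s_x0 + s);
    double sig_y = s / (s_y0 + s);

    /* realized self-renewal fractions of the two stem-cell pools */
    double rx = p_x0 * phi_x * sig_x;
    double ry = p_y0 * phi_y * sig_y;

    ydot[0] = alpha_x0 * (2.0 * rx - 1.0) * x0;
    ydot[1] = alpha_x1 * (2.0 * p_x1 - 1.0) * x1
            + 2.0 * A_x0 * alpha_x0 * (1.0 - rx) * x0
            - d_x1 * x1;
    ydot[2] = 2.0 * A_x1 * alpha_x1 * (1.0 - p_x1) * x1 - d_x2 * x2;
    ydot[3] = alpha_y0 * (2.0 * ry - 1.0) * y0;
    ydot[4] = alpha_y1 * (2.0 * p_y1 - 1.0) * y1
            + 2.0 * A_y0 * alpha_y0 * (1.0 - ry) * y0
            - d_y1 * y1;
    ydot[5] = 2.0 * A_y1 * alpha_y1 * (1.0 - p_y1) * y1 - d_y2 * y2;
    ydot[6] = d_x1 * x1 + d_y1 * y1 + d_x2 * x2 + d_y2 * y2 - e_a * a * s;
    ydot[7] = r_s * a - e_s * s + I;
}

/* Single-lineage 5-variable reductions (n0, n1, n2, a, s): used for the
 * healthy-only / malignant-only experiments, where carrying the other
 * lineage as exact zeros would expose its unstable directions to solver
 * round-off (any leaked cell of a fitter clone eventually takes over). */

static void derivs_lineage(double *yv, double *ydot,
                           double alpha0, double alpha1, double p0,
                           double p1, double cself, double s_half,
                           double A0, double A1, double d1, double d2)
{
    double n0 = yv[0], n1 = yv[1], n2 = yv[2];
    double a = yv[3], s = yv[4];
    double e_a = parms[22], r_s = parms[23], e_s = parms[24], I = parms[25];

    double r0 = p0 * (1.0 / (1.0 + cself * n0)) * s / (s_half + s);

    ydot[0] = alpha0 * (2.0 * r0 - 1.0) * n0;
    ydot[1] = alpha1 * (2.0 * p1 - 1.0) * n1
            + 2.0 * A0 * alpha0 * (1.0 - r0) * n0
            - d1 * n1;
    ydot[2] = 2.0 * A1 * alpha1 * (1.0 - p1) * n1 - d2 * n2;
    ydot[3] = d1 * n1 + d2 * n2 - e_a * a * s;
    ydot[4] = r_s * a - e_s * s + I;
}

void mpn_derivs_healthy(int *neq, double *t, double *yv, double *ydot,
                        double *yout, int *ip)
{
    derivs_lineage(yv, ydot,
                   parms[0], parms[1], parms[4], parms[5],
                   parms[8],  /* c_xx */
                   parms[12], /* s_x0 */
                   parms[14], parms[15], parms[18], parms[19]);
}

void mpn_derivs_malignant(int *neq, double *t, double *yv, double *ydot,
                          double *yout, int *ip)
{
    derivs_lineage(yv, ydot,
                   parms[2], parms[3], parms[6], parms[7],
                   parms[11], /* c_yy */
                   parms[13], /* s_y0 */
                   parms[16], parms[17], parms[20], parms[21]);
}
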