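/* Compiled right-hand side of the cellular PK(/PD) model for deSolve.
 *
 * States (amounts, pmol):
 *   y[0] A_medium, y[1] A_exo, y[2] A_cell_free, y[3] A_tubulin, y[4] A_ves
 *   y[5] N (cell count; integrated only when with_pd = 1)
 *
 * Parameter vector (filled by the R side, see .rhs_parms()):
 *   0 D_fd, 1 Jmax_pgp, 2 Kd_pgp, 3 k_on, 4 k_off, 5 Bmax,
 *   6 kf_free, 7 kf_tub, 8 k_release, 9 Jmax_ie, 10 Kd_ie, 11 fu,
 *   12 V_medium, 13 v_cell, 14 N0, 15 alpha, 16 beta,
 *   17 reuptake_to_cytosol (0/1), 18 alpha_on_both (0/1),
 *   19 with_pd (0/1), 20 k_kill, 21 EC50_initial, 22 gamma_EC50,
 *   23 n_hill, 24 k_g, 25 ec50_exponential (0/1), 26 ec50_floor
 */
#include <R.h>
#include <math.h>

#define N_PARMS 27
static double parms[N_PARMS];

void qp_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void qp_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double D_fd = parms[0], Jmax_pgp = parms[1], Kd_pgp = parms[2];
    const double k_on = parms[3], k_off = parms[4], Bmax = parms[5];
    const double kf_free = parms[6], kf_tub = parms[7], k_rel = parms[8];
    const double Jmax_ie = parms[9], Kd_ie = parms[10], fu = parms[11];
    const double V_m = parms[12], v_cell = parms[13], N0 = parms[14];
    const double alpha = parms[15], beta = parms[16];
    const int up_cyto = parms[17] > 0.5, a_both = parms[18] > 0.5;
    const int with_pd = parms[19] > 0.5;

    const double V_cells = N0 * v_cell;
    const double ncell6 = N0 / 1e6;

    /* concentrations in nM = pmol / (1000 L) */
    const double C_mf = fu * y[0] / (1000.0 * V_m);
    const double C_exo = y[1] / (1000.0 * V_m);
    const double C_cf = y[2] / (1000.0 * V_cells);
    const double C_tub = y[3] / (1000.0 * V_cells);

    const double J_diff = D_fd * 1000.0 * V_cells * (C_mf - C_cf);
    const double J_pgp = Jmax_pgp * ncell6 * C_cf / (Kd_pgp + C_cf);
    const double J_on = k_on * C_cf * (Bmax - C_tub) * 1000.0 * V_cells;
    const double J_off = k_off * y[3];
    double sort_free = kf_free * y[2];
    double sort_tub = kf_tub * y[3];
    sort_free *= (1.0 - alpha);
    if (a_both) sort_tub *= (1.0 - alpha);
    const double J_rel = (1.0 - beta) * k_rel * y[4];
    const double J_up = Jmax_ie * ncell6 * C_exo / (Kd_ie + C_exo);

    ydot[0] = -J_diff + J_pgp;
    ydot[1] = J_rel - J_up;
    ydot[2] = J_diff - J_pgp - J_on + J_off - sort_free;
    ydot[3] = J_on - J_off - sort_tub;
    ydot[4] = sort_free + sort_tub - J_rel;
    if (up_cyto) ydot[2] += J_up; else ydot[4] += J_up;

    if (with_pd && *neq > 5) {
        const double k_kill = parms[20], EC50_i = parms[21];
        const double gamma = parms[22], n_hill = parms[23];
        const double k_g = parms[24];
        double ec50 = parms[25] > 0.5 ? EC50_i * exp(-gamma * *t)
                                      : EC50_i - gamma * *t;
        if (ec50 < parms[26]) ec50 = parms[26];
        double hill = 0.0;
        if (C_tub > 0.0) {
            const double r = pow(C_tub / ec50, n_hill);
            hill = r / (1.0 + r);
        }
        ydot[5] = (k_g - k_kill * hill) * y[5];
    }
}
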