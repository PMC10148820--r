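/* Generic mass-action / Michaelis-Menten reaction-network RHS for deSolve,
 * with an osmotic cell-volume module and analytic input protocols.
 *
 * The whole problem (network structure, protocol, parameter values) is packed
 * into a fixed-length double vector passed as `parms`; see pack_parms() on the
 * R side for the layout.  States are [species amounts, volume, glycerol]; the
 * last two are present only when the volume module is switched on.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define PARMS_LEN 6000

/* header slots (0-based) */
#define H_NSPEC   0
#define H_NREAC   1
#define H_NSTO    2
#define H_NPAR    3
#define H_NHOGW   4
#define H_VOLON   5
#define H_SIGMODE 6
#define H_PKIND   7
#define H_AMP     8
#define H_ONSET   9
#define H_RDUR   10
#define H_PER    11
#define H_BASE   12
#define H_KPV    13
#define H_PT0    14
#define H_VLP    15
#define H_OSMI   16
#define H_VHOG   17
#define H_VIND   18
#define H_KGOUT  19
#define H_V0G    20
#define H_HDR    24

static double gp[PARMS_LEN];

void hog_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, gp);
}

static double osm_external(const double *p, double t)
{
    double base = p[H_BASE], amp = p[H_AMP], onset = p[H_ONSET];
    int kind = (int) p[H_PKIND];
    if (kind == 0 || t < onset)
        return base;
    if (kind == 1)
        return base + amp;
    if (kind == 2) {
        double dur = p[H_RDUR];
        double f = (t - onset) / dur;
        return base + amp * (f < 1.0 ? f : 1.0);
    }
    /* pulse train: high for the first half-period */
    {
        double per = p[H_PER];
        double ph = fmod(t - onset, per);
        return (ph < 0.5 * per) ? base + amp : base;
    }
}

/* smooth positive part: 0.5*(x + sqrt(x^2 + w^2)); C1, avoids Jacobian
 * discontinuities that make the stiff solver chatter near the clamps */
#define SMOOTH_W 1e-3
static double spos(double x)  { return 0.5 * (x + sqrt(x * x + SMOOTH_W * SMOOTH_W)); }
static double dspos(double x) { return 0.5 * (1.0 + x / sqrt(x * x + SMOOTH_W * SMOOTH_W)); }

/* turgor pressure: smooth saturating-linear in volume above the loss point */
static double turgor_of(const double *p, double V)
{
    double Pt0 = p[H_PT0], Vlp = p[H_VLP];
    return Pt0 * spos((V - Vlp) / (1.0 - Vlp));
}

static double dturgor_dV(const double *p, double V)
{
    double Pt0 = p[H_PT0], Vlp = p[H_VLP];
    return Pt0 * dspos((V - Vlp) / (1.0 - Vlp)) / (1.0 - Vlp);
}

/* stress signal = relative turgor deficit, smoothly clipped at 0 */
static double signal_of(const double *p, double t, const double *y, int nspec)
{
    if ((int) p[H_VOLON]) {
        double tg = turgor_of(p, y[nspec]);
        return spos(1.0 - tg / p[H_PT0]);
    }
    return osm_external(p, t); /* direct-input mode (basic cascade) */
}

static double dsignal_dV(const double *p, const double *y, int nspec)
{
    double tg = turgor_of(p, y[nspec]);
    return -dspos(1.0 - tg / p[H_PT0]) * dturgor_dV(p, y[nspec]) / p[H_PT0];
}

static void core_derivs(const double *p, double t, const double *y,
                        double *ydot, double *sig_out)
{
    int nspec = (int) p[H_NSPEC];
    int nreac = (int) p[H_NREAC];
    int nsto  = (int) p[H_NSTO];
    int npar  = (int) p[H_NPAR];
    int nhw   = (int) p[H_NHOGW];
    int volon = (int) p[H_VOLON];
    const double *hw  = p + H_HDR;
    const double *rt  = hw + nhw;           /* reaction table, 6 per reaction */
    const double *st  = rt + 6 * nreac;     /* stoichiometry triplets        */
    const double *par = st + 3 * nsto;      /* parameter values (linear)     */
    double v[512];
    double s = signal_of(p, t, y, nspec);
    int i;

    if (npar > 0) { /* silence unused warnings on some compilers */ }
    if (sig_out) *sig_out = s;

    for (i = 0; i < nreac; i++) {
        int kind = (int) rt[6 * i];
        int ip1  = (int) rt[6 * i + 1];
        int ip2  = (int) rt[6 * i + 2];
        int is1  = (int) rt[6 * i + 3];
        int is2  = (int) rt[6 * i + 4];
        double y1 = (is1 >= 0 && y[is1] > 0.0) ? y[is1] : 0.0;
        double y2 = (is2 >= 0 && y[is2] > 0.0) ? y[is2] : 0.0;
        double k1 = par[ip1];

        if (kind == 0) {            /* mass action, 1-2 reactants */
            v[i] = k1 * y1 * (is2 >= 0 ? y2 : 1.0);
        } else if (kind == 1) {     /* MM: enzyme is1, substrate is2 */
            double Km = par[ip2];
            v[i] = k1 * y1 * y2 / (Km + y2);
        } else {                    /* signal-driven mass action */
            v[i] = k1 * s * y1;
        }
    }

    for (i = 0; i < nspec; i++) ydot[i] = 0.0;
    for (i = 0; i < nsto; i++) {
        int ir = (int) st[3 * i];
        int is = (int) st[3 * i + 1];
        ydot[is] += st[3 * i + 2] * v[ir];
    }

    if (volon) {
        double V = y[nspec] > 0.1 ? y[nspec] : 0.1;
        double G = y[nspec + 1];
        double tg = turgor_of(p, V);
        double osm_e = osm_external(p, t);
        double pii = (p[H_OSMI] + G) / V;
        double hogpp = 0.0;
        for (i = 0; i < nhw; i++) hogpp += y[(int) hw[i]] > 0.0 ? y[(int) hw[i]] : 0.0;
        /* glycerol efflux scales with relative turgor (Fps1 closes under
         * stress, reopens when turgor is restored or excessive) */
        ydot[nspec] = -p[H_KPV] * (osm_e + tg - pii);
        {
            double fac = tg / p[H_PT0];
            fac = fac * fac * fac;
            ydot[nspec + 1] = p[H_V0G] + p[H_VHOG] * hogpp + p[H_VIND] * s
                - p[H_KGOUT] * (G > 0.0 ? G : 0.0) * fac;
        }
    }
}

void hog_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double s;
    core_derivs(gp, *t, y, ydot, &s);
    if (ip[0] >= 1) yout[0] = s;
}

/* analytic full Jacobian (column-major pd[i + j*nrow] = d ydot_i / d y_j) */
void hog_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    const double *p = gp;
    int nspec = (int) p[H_NSPEC];
    int nreac = (int) p[H_NREAC];
    int nsto  = (int) p[H_NSTO];
    int nhw   = (int) p[H_NHOGW];
    int volon = (int) p[H_VOLON];
    const double *hw  = p + H_HDR;
    const double *rt  = hw + nhw;
    const double *st  = rt + 6 * nreac;
    const double *par = st + 3 * nsto;
    int n = *neq, nr = *nrowpd;
    int i, j, r;
    /* dv[r] w.r.t. up to two species + volume */
    double dv1[512], dv2[512], dvV[512];
    int ix1[512], ix2[512];
    double s = signal_of(p, *t, y, nspec);
    double dsdV = volon ? dsignal_dV(p, y, nspec) : 0.0;

    for (i = 0; i < n * nr; i++) pd[i] = 0.0;

    for (r = 0; r < nreac; r++) {
        int kind = (int) rt[6 * r];
        int ip1  = (int) rt[6 * r + 1];
        int ip2  = (int) rt[6 * r + 2];
        int is1  = (int) rt[6 * r + 3];
        int is2  = (int) rt[6 * r + 4];
        double y1 = (is1 >= 0 && y[is1] > 0.0) ? y[is1] : 0.0;
        double y2 = (is2 >= 0 && y[is2] > 0.0) ? y[is2] : 0.0;
        int pos1 = (is1 >= 0 && y[is1] > 0.0);
        int pos2 = (is2 >= 0 && y[is2] > 0.0);
        double k1 = par[ip1];
        ix1[r] = is1; ix2[r] = is2;
        dv1[r] = dv2[r] = dvV[r] = 0.0;
        if (kind == 0) {
            if (is2 >= 0) {
                if (pos1) dv1[r] = k1 * y2;
                if (pos2) dv2[r] = k1 * y1;
            } else if (pos1) dv1[r] = k1;
        } else if (kind == 1) {
            double Km = par[ip2];
            double den = Km + y2;
            if (pos1) dv1[r] = k1 * y2 / den;
            if (pos2) dv2[r] = k1 * y1 * Km / (den * den);
        } else {
            if (pos1) dv1[r] = k1 * s;
            dvV[r] = k1 * y1 * dsdV;
        }
    }

    for (i = 0; i < nsto; i++) {
        int ir = (int) st[3 * i];
        int is = (int) st[3 * i + 1];
        double c = st[3 * i + 2];
        if (ix1[ir] >= 0) pd[is + ix1[ir] * nr] += c * dv1[ir];
        if (ix2[ir] >= 0) pd[is + ix2[ir] * nr] += c * dv2[ir];
        if (volon && dvV[ir] != 0.0) pd[is + nspec * nr] += c * dvV[ir];
    }

    if (volon) {
        int iV = nspec, iG = nspec + 1;
        double V = y[nspec] > 0.1 ? y[nspec] : 0.1;
        double G = y[nspec + 1];
        double dtg = dturgor_dV(p, V);
        double Gp = G > 0.0 ? G : 0.0;
        pd[iV + iV * nr] += -p[H_KPV] * (dtg + (p[H_OSMI] + G) / (V * V));
        pd[iV + iG * nr] += p[H_KPV] / V;
        for (j = 0; j < nhw; j++) {
            int is = (int) hw[j];
            if (y[is] > 0.0) pd[iG + is * nr] += p[H_VHOG];
        }
        {
            double tg = turgor_of(p, V);
            double rat = tg / p[H_PT0];
            double fac = rat * rat * rat;
            pd[iG + iG * nr] += (G > 0.0) ? -p[H_KGOUT] * fac : 0.0;
            pd[iG + iV * nr] += p[H_VIND] * dsdV
                - p[H_KGOUT] * Gp * 3.0 * rat * rat * dtg / p[H_PT0];
        }
    }
}

/* R-callable RHS evaluation (used for steady-state residual norms and tests) */
SEXP hog_rhs_C(SEXP t_, SEXP y_, SEXP p_)
{
    double t = REAL(t_)[0];
    int n = LENGTH(y_);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    core_derivs(REAL(p_), t, REAL(y_), REAL(out), NULL);
    UNPROTECT(1);
    return out;
}

SEXP hog_osm_C(SEXP t_, SEXP p_)
{
    int n = LENGTH(t_), i;
    SEXP out = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++)
        REAL(out)[i] = osm_external(REAL(p_), REAL(t_)[i]);
    UNPROTECT(1);
    return out;
}

#include <R_ext/Rdynload.h>

static const R_CallMethodDef callMethods[] = {
    {"hog_rhs_C", (DL_FUNC) &hog_rhs_C, 3},
    {"hog_osm_C", (DL_FUNC) &hog_osm_C, 2},
    {NULL, NULL, 0}
};

void R_init_hogmix(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
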