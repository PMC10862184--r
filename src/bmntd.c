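#include <R.h>
#include <Rinternals.h>
#include <float.h>

static void fill_dmin(const double *D, const double *F, const int *perm,
                      int n, int k, int *npres, int *pres, double *dmin)
{
    for (int b = 0; b < n; b++) {
        int m = 0;
        for (int j = 0; j < k; j++)
            if (F[b + (size_t) j * n] > 0) pres[(size_t) b * k + m++] = j;
        npres[b] = m;
    }
    for (int b = 0; b < n; b++) {
        double *db = dmin + (size_t) b * k;
        if (npres[b] == 0) continue;
        for (int i = 0; i < k; i++) db[i] = DBL_MAX;
        for (int jj = 0; jj < npres[b]; jj++) {
            int j = pres[(size_t) b * k + jj];
            const double *col = D + (size_t) (perm[j] - 1) * k;
            for (int i = 0; i < k; i++) {
                double d = col[perm[i] - 1];
                if (d < db[i]) db[i] = d;
            }
        }
    }
}

static double pair_bmntd(const double *F, const double *dmin,
                         const int *npres, const int *pres,
                         int n, int k, int a, int b)
{
    if (npres[a] == 0 || npres[b] == 0) return NA_REAL;
    double s1 = 0.0, s2 = 0.0;
    const double *db = dmin + (size_t) b * k;
    const double *da = dmin + (size_t) a * k;
    for (int ii = 0; ii < npres[a]; ii++) {
        int i = pres[(size_t) a * k + ii];
        s1 += F[a + (size_t) i * n] * db[i];
    }
    for (int jj = 0; jj < npres[b]; jj++) {
        int j = pres[(size_t) b * k + jj];
        s2 += F[b + (size_t) j * n] * da[j];
    }
    return 0.5 * (s1 + s2);
}

/* Beta-MNTD for an explicit list of sample pairs (1-based row indices),
 * sharing the per-sample nearest-taxon distances across pairs. */
SEXP C_bmntd_pairs(SEXP Ds, SEXP Fs, SEXP perms, SEXP ai, SEXP bi)
{
    const double *D = REAL(Ds);
    const double *F = REAL(Fs);
    const int *perm = INTEGER(perms);
    const int k = Rf_nrows(Ds);
    const int n = Rf_nrows(Fs);
    const int P = Rf_length(ai);

    if (Rf_ncols(Fs) != k || Rf_length(perms) != k || Rf_length(bi) != P)
        Rf_error("dimension mismatch in C_bmntd_pairs");

    int *npres = (int *) R_alloc(n, sizeof(int));
    int *pres = (int *) R_alloc((size_t) n * k, sizeof(int));
    double *dmin = (double *) R_alloc((size_t) n * k, sizeof(double));
    fill_dmin(D, F, perm, n, k, npres, pres, dmin);

    SEXP ans = PROTECT(Rf_allocVector(REALSXP, P));
    double *out = REAL(ans);
    const int *a = INTEGER(ai), *b = INTEGER(bi);
    for (int p = 0; p < P; p++)
        out[p] = pair_bmntd(F, dmin, npres, pres, n, k, a[p] - 1, b[p] - 1);
    UNPROTECT(1);
    return ans;
}

/* Abundance-weighted between-community mean nearest-taxon distance for all
 * sample pairs at once.
 *
 * D:    k x k symmetric patristic distance matrix (column-major).
 * F:    n x k matrix of within-bin relative abundances (rows sum to 1, or to
 *       0 for samples empty on the bin).
 * perm: integer vector of length k, a 1-based permutation applied to the
 *       taxon labels of D (the taxa-shuffle null); identity gives the
 *       observed statistic.
 *
 * Returns an n x n matrix; entries involving an empty sample are NA.
 */
SEXP C_bmntd(SEXP Ds, SEXP Fs, SEXP perms)
{
    const double *D = REAL(Ds);
    const double *F = REAL(Fs);
    const int *perm = INTEGER(perms);
    const int k = Rf_nrows(Ds);
    const int n = Rf_nrows(Fs);

    if (Rf_ncols(Fs) != k || Rf_length(perms) != k)
        Rf_error("dimension mismatch in C_bmntd");

    SEXP ans = PROTECT(Rf_allocMatrix(REALSXP, n, n));
    double *out = REAL(ans);

    int *npres = (int *) R_alloc(n, sizeof(int));
    int *pres = (int *) R_alloc((size_t) n * k, sizeof(int));
    for (int b = 0; b < n; b++) {
        int m = 0;
        for (int j = 0; j < k; j++)
            if (F[b + (size_t) j * n] > 0) pres[(size_t) b * k + m++] = j;
        npres[b] = m;
    }

    /* dmin[b*k + i]: distance from taxon i to its nearest taxon present in
     * sample b, under the permuted labels. */
    double *dmin = (double *) R_alloc((size_t) n * k, sizeof(double));
    for (int b = 0; b < n; b++) {
        double *db = dmin + (size_t) b * k;
        if (npres[b] == 0) continue;
        for (int i = 0; i < k; i++) db[i] = DBL_MAX;
        for (int jj = 0; jj < npres[b]; jj++) {
            int j = pres[(size_t) b * k + jj];
            const double *col = D + (size_t) (perm[j] - 1) * k;
            for (int i = 0; i < k; i++) {
                double d = col[perm[i] - 1];
                if (d < db[i]) db[i] = d;
            }
        }
    }

    for (int a = 0; a < n; a++) {
        for (int b = 0; b <= a; b++) {
            if (npres[a] == 0 || npres[b] == 0) {
                out[a + (size_t) b * n] = out[b + (size_t) a * n] = NA_REAL;
                continue;
            }
            double s1 = 0.0, s2 = 0.0;
            const double *db = dmin + (size_t) b * k;
            const double *da = dmin + (size_t) a * k;
            for (int ii = 0; ii < npres[a]; ii++) {
                int i = pres[(size_t) a * k + ii];
                s1 += F[a + (size_t) i * n] * db[i];
            }
            for (int jj = 0; jj < npres[b]; jj++) {
                int j = pres[(size_t) b * k + jj];
                s2 += F[b + (size_t) j * n] * da[j];
            }
            double v = 0.5 * (s1 + s2);
            out[a + (size_t) b * n] = v;
            out[b + (size_t) a * n] = v;
        }
    }
    UNPROTECT(1);
    return ans;
}
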