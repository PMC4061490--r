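/* Partial symmetric eigendecomposition via LAPACK dsyevr.
 *
 * Returns the eigenpairs with eigenvalue strictly greater than a lower
 * bound `vl`, in descending order.  If no eigenvalue exceeds the bound,
 * the single largest eigenpair is returned instead (degenerate-input
 * guard used by the variance-retention rule).  Only the requested
 * eigenvectors are back-transformed, which is substantially cheaper than
 * a full decomposition when few components are retained.
 */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Lapack.h>
#include <float.h>
#include <string.h>

#ifndef FCONE
#define FCONE
#endif

SEXP C_eig_partial(SEXP Cmat, SEXP vlow)
{
    if (!isReal(Cmat) || !isMatrix(Cmat))
        error("C must be a numeric matrix");
    int n = nrows(Cmat);
    if (ncols(Cmat) != n)
        error("C must be square");
    double vl = asReal(vlow);
    double vu = DBL_MAX / 4.0;

    /* dsyevr overwrites A: work on a copy */
    double *a = (double *) R_alloc((size_t) n * n, sizeof(double));
    memcpy(a, REAL(Cmat), (size_t) n * n * sizeof(double));

    int m = 0, info = 0, lda = n, ldz = n;
    int il = 1, iu = n;
    double abstol = 0.0;
    double *w = (double *) R_alloc(n, sizeof(double));
    double *z = (double *) R_alloc((size_t) n * n, sizeof(double));
    int *isuppz = (int *) R_alloc(2 * (size_t) n, sizeof(int));

    /* workspace query */
    double wkopt;
    int iwkopt, lwork = -1, liwork = -1;
    F77_CALL(dsyevr)("V", "V", "U", &n, a, &lda, &vl, &vu, &il, &iu,
                     &abstol, &m, w, z, &ldz, isuppz,
                     &wkopt, &lwork, &iwkopt, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0)
        error("dsyevr workspace query failed (info = %d)", info);
    lwork = (int) wkopt;
    liwork = iwkopt;
    double *work = (double *) R_alloc(lwork, sizeof(double));
    int *iwork = (int *) R_alloc(liwork, sizeof(int));

    F77_CALL(dsyevr)("V", "V", "U", &n, a, &lda, &vl, &vu, &il, &iu,
                     &abstol, &m, w, z, &ldz, isuppz,
                     work, &lwork, iwork, &liwork, &info
                     FCONE FCONE FCONE);
    if (info != 0)
        error("dsyevr failed (info = %d)", info);

    if (m == 0) {
        /* nothing above the bound: fall back to the largest eigenpair */
        memcpy(a, REAL(Cmat), (size_t) n * n * sizeof(double));
        il = iu = n;
        F77_CALL(dsyevr)("V", "I", "U", &n, a, &lda, &vl, &vu, &il, &iu,
                         &abstol, &m, w, z, &ldz, isuppz,
                         work, &lwork, iwork, &liwork, &info
                         FCONE FCONE FCONE);
        if (info != 0 || m != 1)
            error("dsyevr fallback failed (info = %d, m = %d)", info, m);
    }

    /* dsyevr returns ascending order: reverse into descending */
    SEXP values = PROTECT(allocVector(REALSXP, m));
    SEXP vectors = PROTECT(allocMatrix(REALSXP, n, m));
    double *pv = REAL(values), *pz = REAL(vectors);
    for (int j = 0; j < m; j++) {
        pv[j] = w[m - 1 - j];
        memcpy(pz + (size_t) j * n, z + (size_t) (m - 1 - j) * n,
               (size_t) n * sizeof(double));
    }

    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, values);
    SET_VECTOR_ELT(out, 1, vectors);
    SEXP nm = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nm, 0, mkChar("values"));
    SET_STRING_ELT(nm, 1, mkChar("vectors"));
    setAttrib(out, R_NamesSymbol, nm);
    UNPROTECT(4);
    return out;
}
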