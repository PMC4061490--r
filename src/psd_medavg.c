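/* Median-filter-then-average kernel for PSD epochs.
 *
 * Input: P, an n_freq x n_win matrix of segment power spectra (all unique
 * segments); wmap, an nwin x n_epoch integer matrix of 1-based column
 * indices into P giving the segments of each epoch; the odd median order.
 * For each epoch and frequency bin, applies a sliding median across the
 * epoch's segments (symmetric window, shrunk at the edges) and averages
 * the filtered values.  Returns an n_freq x n_epoch matrix.
 */
#include <R.h>
#include <Rinternals.h>

static double small_median(double *buf, int m)
{
    /* insertion sort; m is tiny (<= median order) and odd */
    for (int i = 1; i < m; i++) {
        double v = buf[i];
        int j = i - 1;
        while (j >= 0 && buf[j] > v) {
            buf[j + 1] = buf[j];
            j--;
        }
        buf[j + 1] = v;
    }
    return buf[m / 2];
}

SEXP C_psd_medavg(SEXP P, SEXP wmap, SEXP order)
{
    if (!isReal(P) || !isMatrix(P)) error("P must be a numeric matrix");
    if (!isInteger(wmap) || !isMatrix(wmap)) error("wmap must be an integer matrix");
    int n_freq = nrows(P);
    int n_seg = ncols(P);
    int nwin = nrows(wmap);
    int n_epoch = ncols(wmap);
    int ord = asInteger(order);
    if (ord < 1 || ord % 2 == 0) error("order must be odd and positive");
    int r_max = (ord - 1) / 2;
    double *p = REAL(P);
    int *wm = INTEGER(wmap);

    SEXP out = PROTECT(allocMatrix(REALSXP, n_freq, n_epoch));
    double *o = REAL(out);
    double *win = (double *) R_alloc(nwin, sizeof(double));
    double *buf = (double *) R_alloc(ord, sizeof(double));

    for (int e = 0; e < n_epoch; e++) {
        int *cols = wm + (size_t) e * nwin;
        for (int c = 0; c < nwin; c++) {
            if (cols[c] < 1 || cols[c] > n_seg) error("wmap index out of range");
        }
        for (int f = 0; f < n_freq; f++) {
            for (int c = 0; c < nwin; c++) {
                win[c] = p[(size_t) (cols[c] - 1) * n_freq + f];
            }
            double acc = 0.0;
            for (int j = 0; j < nwin; j++) {
                int r = r_max;
                if (j < r) r = j;
                if (nwin - 1 - j < r) r = nwin - 1 - j;
                if (r == 0) {
                    acc += win[j];
                } else {
                    int m = 2 * r + 1;
                    for (int c = 0; c < m; c++) buf[c] = win[j - r + c];
                    acc += small_median(buf, m);
                }
            }
            o[(size_t) e * n_freq + f] = acc / nwin;
        }
    }
    UNPROTECT(1);
    return out;
}
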