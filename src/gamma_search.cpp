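#include <Rcpp.h>
using namespace Rcpp;

// Gamma-index spatial search over a pre-interpolated fine grid.
//
// ref:   reference dose matrix (ny x nx); NA or below-threshold cells are
//        encoded as NA and skipped.
// fine:  evaluated dose interpolated on the aligned fine grid; NA where the
//        evaluated plane has no data.
// row0/col0: 0-based fine-grid index of ref cell (1,1).
// ky/kx: fine steps per reference step, per axis.
// di/dj: integer fine-grid offsets of the search neighbourhood, sorted by
//        increasing distance; dist2: (offset distance / dta)^2, same order.
// denom: dose-difference normalization, D0 * dose_tol / 100 (cGy).
//
// Offsets are sorted, so once the pure-distance term exceeds the best
// gamma^2 found the scan can stop: every later candidate is worse.
// [[Rcpp::export(name = ".gamma_search_cpp")]]
NumericMatrix gamma_search_cpp(NumericMatrix ref, NumericMatrix fine,
                               int row0, int col0, int ky, int kx,
                               IntegerVector di, IntegerVector dj,
                               NumericVector dist2, double denom) {
  const int ny = ref.nrow(), nx = ref.ncol();
  const int fny = fine.nrow(), fnx = fine.ncol();
  const int noff = di.size();
  NumericMatrix out(ny, nx);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int j = 0; j < nx; ++j) {
    const int fj0 = col0 + j * kx;
    for (int i = 0; i < ny; ++i) {
      const double d_ref = ref(i, j);
      if (NumericMatrix::is_na(d_ref)) continue;
      const int fi0 = row0 + i * ky;
      double best = R_PosInf;
      bool seen = false;
      for (int o = 0; o < noff; ++o) {
        if (dist2[o] >= best) break;
        const int fi = fi0 + di[o], fj = fj0 + dj[o];
        if (fi < 0 || fi >= fny || fj < 0 || fj >= fnx) continue;
        const double d_eval = fine(fi, fj);
        if (NumericMatrix::is_na(d_eval)) continue;
        const double dd = (d_eval - d_ref) / denom;
        const double g2 = dist2[o] + dd * dd;
        seen = true;
        if (g2 < best) best = g2;
      }
      if (seen) out(i, j) = std::sqrt(best);
    }
  }
  return out;
}
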