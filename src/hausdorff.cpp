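#include <Rcpp.h>
using namespace Rcpp;

// Directed Hausdorff distance sup_{a in A} inf_{b in B} ||a - b|| with the
// classic early-break scan: the inner loop over B aborts as soon as a
// neighbour closer than the current supremum is found, which makes the scan
// near-linear on overlapping point clouds while remaining exact.
// A, B: point sets, one row per point, same number of columns.
// [[Rcpp::export(name = ".directed_hausdorff_cpp")]]
double directed_hausdorff_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  if (d != B.ncol()) stop("point sets must have the same dimension");
  if (na == 0 || nb == 0) stop("point sets must be non-empty");

  double cmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double cmin = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      // accumulate in extended precision to match R's colSums() bit-for-bit
      long double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        acc += (long double)(diff * diff);
      }
      const double s = (double)acc;
      if (s < cmin) {
        cmin = s;
        if (cmin <= cmax) break;  // this point cannot raise the supremum
      }
    }
    if (cmin > cmax && R_finite(cmin)) cmax = cmin;
  }
  return std::sqrt(cmax);
}
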