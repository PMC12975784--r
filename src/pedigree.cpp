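#include <Rcpp.h>

// Meuwissen & Luo (1992) recursive inbreeding coefficients.
// sire/dam are 1-based codes into a topologically sorted pedigree, 0 = unknown.
// For each animal with both parents known, a dummy progeny's L-row is traced
// back through the ancestry; F = sum_j x_j^2 D_j + D_dummy - 1.
// [[Rcpp::export]]
Rcpp::NumericVector inbreeding_ml_cpp(Rcpp::IntegerVector sire,
                                      Rcpp::IntegerVector dam) {
  const int n = sire.size();
  Rcpp::NumericVector F(n);
  std::vector<double> D(n), x(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > i || d > i)
      Rcpp::stop("pedigree not sorted: parent code exceeds offspring code");
    const double fs = s > 0 ? F[s - 1] : 0.0;
    const double fd = d > 0 ? F[d - 1] : 0.0;
    if (s > 0 && d > 0)      D[i] = 0.5 - 0.25 * (fs + fd);
    else if (s > 0)          D[i] = 0.75 - 0.25 * fs;
    else if (d > 0)          D[i] = 0.75 - 0.25 * fd;
    else                     D[i] = 1.0;
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    const int top = std::max(s, d) - 1;
    std::fill(x.begin(), x.begin() + top + 1, 0.0);
    x[s - 1] += 0.5;
    x[d - 1] += 0.5;
    double acc = 0.0;
    for (int j = top; j >= 0; --j) {
      const double xj = x[j];
      if (xj == 0.0) continue;
      const int sj = sire[j], dj = dam[j];
      if (sj > 0) x[sj - 1] += 0.5 * xj;
      if (dj > 0) x[dj - 1] += 0.5 * xj;
      acc += xj * xj * D[j];
    }
    F[i] = acc + (0.5 - 0.25 * (fs + fd)) - 1.0;
  }
  return F;
}
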