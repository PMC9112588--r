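#include <Rcpp.h>
using namespace Rcpp;

// Pedigree algebra on topologically ordered pedigrees.
// Parent codes: 1-based indices, 0 = unknown.

// Tabular-method numerator relationship matrix (includes inbreeding).
// [[Rcpp::export(name = ".tabular_A")]]
NumericMatrix tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
    double aii = 1.0;
    if (s >= 0 && d >= 0) aii += 0.5 * A(s, d);
    A(i, i) = aii;
  }
  return A;
}

// Inbreeding coefficients by the Meuwissen & Luo (1992) recursion: for each
// animal, accumulate ancestor contributions L_j^2 * d_j over the ancestor
// list, where d_j is the Mendelian sampling variance of ancestor j.
// [[Rcpp::export(name = ".inbreeding_ml")]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, dd = dam[i] - 1;
    // Mendelian sampling variance given parental inbreeding
    double di;
    if (s >= 0 && dd >= 0)      di = 0.5 - 0.25 * (F[s] + F[dd]);
    else if (s >= 0)            di = 0.75 - 0.25 * F[s];
    else if (dd >= 0)           di = 0.75 - 0.25 * F[dd];
    else                        di = 1.0;
    d[i] = di;
    if (s < 0 || dd < 0) { F[i] = 0.0; continue; }
    // walk ancestors of i from youngest to oldest; a_ii = sum_j L_j^2 d_j
    double aii = 0.0;
    std::vector<double> Lloc(i + 1, 0.0);
    Lloc[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      if (Lloc[j] == 0.0) continue;
      int js = sire[j] - 1, jd = dam[j] - 1;
      if (js >= 0) Lloc[js] += 0.5 * Lloc[j];
      if (jd >= 0) Lloc[jd] += 0.5 * Lloc[j];
      aii += Lloc[j] * Lloc[j] * d[j];
    }
    F[i] = aii - 1.0;
  }
  return F;
}
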