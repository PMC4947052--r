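#include <Rcpp.h>
using namespace Rcpp;

// Binary C-SVC trained by sequential minimal optimization (Platt's
// simplified variant with an examine-all outer loop) on a precomputed
// kernel matrix. The decision-function cache G[i] = sum_j alpha_j y_j
// K(i,j) is updated incrementally, making each working-set update O(n);
// problem sizes here are tiny (n <= 64 responses per recording), so no
// shrinking or full QP machinery is needed.
//
// K: n x n kernel matrix, y: labels in {-1, +1}, C: box constraint.
// Returns alpha (length n) and the bias b.
// [[Rcpp::export(name = ".cpp_smo_train")]]
List cpp_smo_train(NumericMatrix K, NumericVector y, double C,
                   double tol = 1e-3, int max_passes = 1,
                   int max_iter = 200000) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, 0.0);
  double b = 0.0;
  int passes = 0, iter = 0;
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n && iter < max_iter; ++i, ++iter) {
      double Ei = G[i] + b - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0)))
        continue;
      // second working-set member: maximize |Ei - Ej|
      int j = -1;
      double best = -1.0, Ej = 0.0;
      for (int jj = 0; jj < n; ++jj) {
        if (jj == i) continue;
        double Etmp = G[jj] + b - y[jj];
        double d = std::fabs(Ei - Etmp);
        if (d > best) { best = d; j = jj; Ej = Etmp; }
      }
      if (j < 0) continue;
      double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (L >= H) continue;
      double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
      if (eta >= 0) continue;
      double aj = aj_old - y[j] * (Ei - Ej) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-7) continue;
      double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      double dai = ai - ai_old, daj = aj - aj_old;
      alpha[i] = ai;
      alpha[j] = aj;
      for (int m = 0; m < n; ++m)
        G[m] += y[i] * dai * K(m, i) + y[j] * daj * K(m, j);
      double b1 = b - Ei - y[i] * dai * K(i, i) - y[j] * daj * K(i, j);
      double b2 = b - Ej - y[i] * dai * K(i, j) - y[j] * daj * K(j, j);
      if (ai > 0 && ai < C) b = b1;
      else if (aj > 0 && aj < C) b = b2;
      else b = 0.5 * (b1 + b2);
      ++changed;
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}
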