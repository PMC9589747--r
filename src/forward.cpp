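#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihood of capture histories under the
// height-structured multi-state model, conditioned on first capture.
//
// y:    n x T integer matrix, 0 = not seen, 1..H = seen at that height.
// f:    first-capture occasion per history (1-based).
// last: last occasion entering the likelihood (T, or the truncation
//       occasion for individuals removed on recovery).
// phi, p: length-H survival and recapture probabilities.
// alpha:  H x H movement simplex (rows sum to 1).
//
// Returns the per-history log-likelihood vector.  A history whose
// observations have probability zero under the parameters gets -Inf
// (never NaN); per-step renormalization keeps the recursion stable.
// [[Rcpp::export(name = ".msForwardLoglik")]]
NumericVector ms_forward_loglik(IntegerMatrix y, IntegerVector f,
                                IntegerVector last, NumericVector phi,
                                NumericMatrix alpha, NumericVector p) {
  const int n = y.nrow();
  const int H = phi.size();
  const int S = H + 1;  // dead state is S - 1 (0-based)

  // transition matrix psi[s][s']
  std::vector<double> psi(S * S, 0.0);
  for (int h = 0; h < H; ++h) {
    for (int k = 0; k < H; ++k) psi[h * S + k] = phi[h] * alpha(h, k);
    psi[h * S + H] = 1.0 - phi[h];
  }
  psi[H * S + H] = 1.0;

  // column-major transition for the inner product: psiT[k][s]
  std::vector<double> psiT(S * S);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < S; ++k) psiT[k * S + s] = psi[s * S + k];

  NumericVector out(n);
  std::vector<double> g(S), g2(S);

  for (int i = 0; i < n; ++i) {
    const int fi = f[i];       // 1-based
    const int li = last[i];    // 1-based
    const int y0 = y(i, fi - 1);
    if (y0 < 1 || y0 > H) { out[i] = NA_REAL; continue; }
    std::fill(g.begin(), g.end(), 0.0);
    g[y0 - 1] = 1.0;
    double ll = 0.0;       // accumulated log of rescaling factors
    double scale = 1.0;    // running unnormalized mass
    bool dead_end = false;
    for (int t = fi; t < li; ++t) {  // occasions fi+1 .. li (1-based)
      const int o = y(i, t);  // observation at occasion t+1 (1-based)
      if (o > 0) {
        // seen at height o: only state o-1 survives the weighting
        const double* col = &psiT[(o - 1) * S];
        double acc = 0.0;
        for (int s = 0; s < S; ++s) acc += g[s] * col[s];
        acc *= p[o - 1];
        if (acc <= 0.0) { out[i] = R_NegInf; dead_end = true; break; }
        std::fill(g.begin(), g.end(), 0.0);
        g[o - 1] = 1.0;
        scale *= acc;
      } else {
        double tot = 0.0;
        for (int k = 0; k < H; ++k) {
          const double* col = &psiT[k * S];
          double acc = 0.0;
          for (int s = 0; s < S; ++s) acc += g[s] * col[s];
          g2[k] = acc * (1.0 - p[k]);
          tot += g2[k];
        }
        {
          const double* col = &psiT[H * S];
          double acc = 0.0;
          for (int s = 0; s < S; ++s) acc += g[s] * col[s];
          g2[H] = acc;
          tot += g2[H];
        }
        if (tot <= 0.0) { out[i] = R_NegInf; dead_end = true; break; }
        g.swap(g2);
        scale *= tot;
        for (int k = 0; k < S; ++k) g[k] /= tot;
      }
      if (scale < 1e-280) { ll += std::log(scale); scale = 1.0; }
    }
    if (!dead_end) out[i] = ll + std::log(scale);
  }
  return out;
}
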