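#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closed-form HKY transition probabilities.  d is the expected number of
// substitutions on the branch (the rate matrix is normalised to unit mean
// rate at stationarity).  Base order: A, C, G, T.  P is row-major 4x4,
// P[4*i+j] = P(j at child | i at parent).
static void hky_pmat(double d, double kappa, const double *pi, double *P) {
  const bool purine[4] = {true, false, true, false};
  double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
  double beta = 1.0 / (2.0 * kappa * (pi[0] * pi[2] + pi[1] * pi[3]) +
                       2.0 * piR * piY);
  double t = d * beta;
  double e1 = std::exp(-t);
  double eR = std::exp(-t * (piR * kappa + piY));
  double eY = std::exp(-t * (piY * kappa + piR));
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) {
      double Pj = purine[j] ? piR : piY;
      double ej = purine[j] ? eR : eY;
      double v;
      if (i == j)
        v = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 + ((Pj - pi[j]) / Pj) * ej;
      else if (purine[i] == purine[j])  // transition
        v = pi[j] + pi[j] * (1.0 / Pj - 1.0) * e1 - (pi[j] / Pj) * ej;
      else                              // transversion
        v = pi[j] * (1.0 - e1);
      P[4 * i + j] = v;
    }
  }
}

// [[Rcpp::export(name = ".cpp_hky_pmat")]]
NumericMatrix cpp_hky_pmat(double d, double kappa, NumericVector freqs) {
  if (d < 0) stop("negative branch distance");
  NumericMatrix out(4, 4);
  double P[16];
  hky_pmat(d, kappa, REAL(freqs), P);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[4 * i + j];
  return out;
}

// Felsenstein pruning over compressed site patterns for one partition.
//   child:     2 x nnode matrix of child indices (1-based, NA/0 for tips)
//   postorder: node visitation order (1-based), root last
//   dist:      expected substitutions on each node's parental branch
//   pat:       N x npat integer codes (0 = missing/ambiguous, 1..4 = ACGT)
//   wts:       pattern weights
// Tip children contribute a single transition-matrix entry per state, so
// partials are only stored for internal nodes.
// [[Rcpp::export(name = ".cpp_hky_loglik")]]
double cpp_hky_loglik(IntegerMatrix child, IntegerVector postorder, int root,
                      NumericVector dist, double kappa, NumericVector freqs,
                      IntegerMatrix pat, NumericVector wts) {
  int nnode = child.ncol();
  int npat = pat.ncol();
  int N = pat.nrow();
  std::vector<double> part((size_t)(nnode - N) * 4 * npat);
  std::vector<double> logscale(npat, 0.0);
  const double *pi = REAL(freqs);
  const int *patp = INTEGER(pat);
  const int *ch = INTEGER(child);
  double Pm[2][16];

  for (int k = 0; k < nnode; ++k) {
    int u = postorder[k] - 1;
    if (u < N) continue;                       // tips carry no partials
    int v[2] = {ch[2 * u], ch[2 * u + 1]};     // 1-based child ids
    bool tip[2];
    for (int c = 0; c < 2; ++c) {
      tip[c] = v[c] <= N;
      hky_pmat(dist[v[c] - 1], kappa, pi, Pm[c]);
    }
    const double *p1 = tip[0] ? nullptr
                              : &part[(size_t)(v[0] - 1 - N) * 4 * npat];
    const double *p2 = tip[1] ? nullptr
                              : &part[(size_t)(v[1] - 1 - N) * 4 * npat];
    double *pu = &part[(size_t)(u - N) * 4 * npat];
    bool is_root = (u == root - 1);
    for (int s = 0; s < npat; ++s) {
      double ab[2];
      double mx = 0.0;
      for (int x = 0; x < 4; ++x) {
        for (int c = 0; c < 2; ++c) {
          if (tip[c]) {
            int code = patp[(size_t)s * N + (v[c] - 1)];
            ab[c] = code == 0 ? 1.0 : Pm[c][4 * x + (code - 1)];
          } else {
            const double *pc = (c == 0 ? p1 : p2) + 4 * s;
            ab[c] = Pm[c][4 * x] * pc[0] + Pm[c][4 * x + 1] * pc[1] +
                    Pm[c][4 * x + 2] * pc[2] + Pm[c][4 * x + 3] * pc[3];
          }
        }
        double val = ab[0] * ab[1];
        pu[4 * s + x] = val;
        if (val > mx) mx = val;
      }
      if (is_root) continue;
      if (mx < 1e-290) {
        if (mx <= 0.0) return R_NegInf;
        for (int x = 0; x < 4; ++x) pu[4 * s + x] /= mx;
        logscale[s] += std::log(mx);
      }
    }
  }
  double ll = 0.0;
  const double *pr = &part[(size_t)(root - 1 - N) * 4 * npat];
  for (int s = 0; s < npat; ++s) {
    double site = 0.0;
    for (int x = 0; x < 4; ++x) site += pi[x] * pr[4 * s + x];
    if (site <= 0.0) return R_NegInf;
    ll += wts[s] * (std::log(site) + logscale[s]);
  }
  return ll;
}
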