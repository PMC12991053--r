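// Gibbs sampler for the Barry-Hartigan product-partition changepoint model.
//
// A partition rho with b blocks has marginal weight
//   Ip(b) * Iw(W, B, b)
// with
//   Ip(b)       = int_0^p0 p^(b-1) (1-p)^(n-b) dp
//   Iw(W, B, b) = int_0^w0 w^((b-1)/2) (W + w B)^(-(n-1)/2) dw
// where W / B are the within- / between-block sums of squares about the
// grand mean.  Both integrals are evaluated in log space; the w-integral
// reduces to a regularized incomplete beta via u = wB / (W + wB).
//
// Degenerate data (W = 0 on some blocks) is handled as the limit of the
// prior support [eps, w0], eps -> 0: partitions achieving W = 0 dominate,
// and among those, partitions with fewer blocks dominate.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct BHModel {
  int n;
  double p0, w0;
  std::vector<double> s1, s2;  // prefix sums of x and x^2
  double gm, tss, ztol;
  // caches indexed by block count b (1..n)
  std::vector<double> lp_cache;          // log Ip(b)
  std::vector<double> lbeta_cache;       // lbeta((b+1)/2, (n-b-2)/2)
  std::vector<double> lbeta_cache_ew;    // lbeta((b+3)/2, (n-b-4)/2)

  BHModel(const NumericVector& x, double p0_, double w0_)
      : n(x.size()), p0(p0_), w0(w0_) {
    s1.assign(n + 1, 0.0);
    s2.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      s1[i + 1] = s1[i] + x[i];
      s2[i + 1] = s2[i] + x[i] * x[i];
    }
    gm = s1[n] / n;
    tss = std::max(s2[n] - n * gm * gm, 0.0);
    ztol = 1e-10 * std::max(tss, 1e-300);
    lp_cache.assign(n + 1, NA_REAL);
    lbeta_cache.assign(n + 5, NA_REAL);
    lbeta_cache_ew.assign(n + 5, NA_REAL);
  }

  bool degenerate() const { return tss <= 1e-300; }

  double log_p_int(int b) {
    double& v = lp_cache[b];
    if (!ISNA(v))
      return v;
    v = R::lbeta((double)b, (double)(n - b + 1)) +
        R::pbeta(p0, (double)b, (double)(n - b + 1), 1, 1);
    return v;
  }

  // log int_0^w0 w^a (W + wB)^(-c) dw, c = (n-1)/2, a = (b-1)/2 (+1 for E[w])
  // returns +Inf for the divergent W=0 limit
  double log_w_int(double W, double B, int b, bool for_ew) {
    double a = 0.5 * (b - 1) + (for_ew ? 1.0 : 0.0);
    double c = 0.5 * (n - 1);
    if (W <= ztol && B <= ztol)  // flat likelihood; caller handles
      return 0.0;
    if (B <= ztol)
      return -c * std::log(W) + (a + 1.0) * std::log(w0) - std::log(a + 1.0);
    if (W <= ztol) {
      double e = a - c;  // integrand ~ w^e
      if (e <= -1.0)
        return R_PosInf;  // divergent at w -> 0
      return -c * std::log(B) + (e + 1.0) * std::log(w0) - std::log(e + 1.0);
    }
    double al = a + 1.0, be = c - a - 1.0;
    if (be > 0.0) {
      double u0 = w0 * B / (W + w0 * B);
      double lb;
      std::vector<double>& cache = for_ew ? lbeta_cache_ew : lbeta_cache;
      if (b >= 1 && b < (int)cache.size()) {
        if (ISNA(cache[b])) cache[b] = R::lbeta(al, be);
        lb = cache[b];
      } else {
        lb = R::lbeta(al, be);
      }
      return (al - c) * std::log(W) - al * std::log(B) + lb +
             R::pbeta(u0, al, be, 1, 1);
    }
    // rare fallback (b >= n-2): composite Simpson in log scale after the
    // substitution w = t^2, which removes the half-integer-power
    // singularity at the origin (integrand becomes 2 t^(2a+1) (W+t^2 B)^-c)
    const int N = 512;
    double tmax = std::sqrt(w0);
    double h = tmax / N, mx = R_NegInf;
    std::vector<double> lf(N + 1);
    for (int k = 0; k <= N; ++k) {
      double t = k * h;
      if (k == 0)
        lf[k] = (2.0 * a + 1.0 > 0.0) ? R_NegInf
                                      : M_LN2 - c * std::log(W);
      else
        lf[k] = M_LN2 + (2.0 * a + 1.0) * std::log(t) -
                c * std::log(W + t * t * B);
      if (lf[k] > mx) mx = lf[k];
    }
    double s = 0.0;
    for (int k = 0; k <= N; ++k) {
      double wgt = (k == 0 || k == N) ? 1.0 : (k % 2 ? 4.0 : 2.0);
      if (R_FINITE(lf[k])) s += wgt * std::exp(lf[k] - mx);
    }
    return mx + std::log(s * h / 3.0);
  }

  double block_w(int l, int r) const {  // within-SS of bins l..r inclusive
    int len = r - l + 1;
    double a1 = s1[r + 1] - s1[l], a2 = s2[r + 1] - s2[l];
    return std::max(a2 - a1 * a1 / len, 0.0);
  }
  double block_b(int l, int r) const {  // between-SS contribution
    int len = r - l + 1;
    double d = (s1[r + 1] - s1[l]) / len - gm;
    return len * d * d;
  }

  // log odds for U_i = 1 vs 0 given block stats under each setting
  double log_odds(int b1, double W1, double B1, double W0, double B0) {
    double lp = log_p_int(b1) - log_p_int(b1 - 1);
    if (degenerate())
      return lp;  // data contribute nothing
    double l1 = log_w_int(W1, B1, b1, false);
    double l0 = log_w_int(W0, B0, b1 - 1, false);
    if (!R_FINITE(l1) && !R_FINITE(l0))
      return R_NegInf;  // both W=0: fewer blocks dominate in the limit
    if (!R_FINITE(l1)) return R_PosInf;
    if (!R_FINITE(l0)) return R_NegInf;
    return lp + l1 - l0;
  }

  double expected_w(double W, double B, int b) {
    if (degenerate()) return 0.0;
    double den = log_w_int(W, B, b, false);
    if (!R_FINITE(den)) return 0.0;  // divergent limit -> mass at w = 0
    double num = log_w_int(W, B, b, true);
    double ew = std::exp(num - den);
    if (ew < 0.0) ew = 0.0;
    if (ew > w0) ew = w0;
    return ew;
  }
};

}  // namespace

// One systematic left-to-right Gibbs sweep over U_1..U_{n-1}; U_n fixed 1.
static void sweep(BHModel& M, std::vector<int>& u, int& b, double& W, double& B) {
  int n = M.n;
  int prev = -1;  // last changepoint strictly before i
  for (int i = 0; i < n - 1; ++i) {
    int end = i + 1;  // first changepoint strictly after i
    while (u[end] != 1) ++end;
    int l = prev + 1;
    // stats of the stretch l..end under the two settings of U_i
    double wA = M.block_w(l, end), bA = M.block_b(l, end);
    double wL = M.block_w(l, i), bL = M.block_b(l, i);
    double wR = M.block_w(i + 1, end), bR = M.block_b(i + 1, end);
    double Wb, Bb;  // stats excluding this stretch
    int bb;         // block count excluding this stretch
    if (u[i] == 1) {
      Wb = W - wL - wR; Bb = B - bL - bR; bb = b - 2;
    } else {
      Wb = W - wA; Bb = B - bA; bb = b - 1;
    }
    if (Wb < 0) Wb = 0;
    if (Bb < 0) Bb = 0;
    double W1 = Wb + wL + wR, B1 = Bb + bL + bR;
    double W0 = Wb + wA, B0 = Bb + bA;
    double lo = M.log_odds(bb + 2, W1, B1, W0, B0);
    double p;
    if (lo == R_PosInf) p = 1.0;
    else if (lo == R_NegInf) p = 0.0;
    else p = 1.0 / (1.0 + std::exp(-lo));
    int newu = (unif_rand() < p) ? 1 : 0;
    u[i] = newu;
    if (newu == 1) {
      b = bb + 2; W = W1; B = B1;
      prev = i;
    } else {
      b = bb + 1; W = W0; B = B0;
    }
  }
}

static void recompute_stats(const BHModel& M, const std::vector<int>& u,
                            int& b, double& W, double& B) {
  b = 0; W = 0.0; B = 0.0;
  int l = 0;
  for (int i = 0; i < M.n; ++i) {
    if (u[i] == 1) {
      W += M.block_w(l, i);
      B += M.block_b(l, i);
      ++b;
      l = i + 1;
    }
  }
}

// [[Rcpp::export]]
List bcp_mcmc_cpp(NumericVector x, double p0, double w0, int burnin, int m,
                  bool keep_means) {
  BHModel M(x, p0, w0);
  int n = M.n;
  std::vector<int> u(n, 0);
  u[n - 1] = 1;
  int b; double W, B;
  recompute_stats(M, u, b, W, B);

  NumericVector prob(n);
  NumericMatrix means(keep_means ? m : 0, keep_means ? n : 0);
  NumericVector mean_acc(n);

  for (int it = 0; it < burnin + m; ++it) {
    sweep(M, u, b, W, B);
    recompute_stats(M, u, b, W, B);  // refresh accumulated float error
    if (it < burnin) continue;
    int r = it - burnin;
    // conditional posterior means for the current partition
    double ew = M.expected_w(W, B, b);
    int l = 0;
    for (int i = 0; i < n; ++i) {
      if (u[i] == 1) {
        double bm = (M.s1[i + 1] - M.s1[l]) / (i - l + 1);
        double val = (1.0 - ew) * bm + ew * M.gm;
        for (int j = l; j <= i; ++j) {
          mean_acc[j] += val;
          if (keep_means) means(r, j) = val;
        }
        prob[i] += u[i];
        l = i + 1;
      } else {
        prob[i] += u[i];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    prob[i] /= m;
    mean_acc[i] /= m;
  }
  return List::create(_["prob"] = prob, _["mean"] = mean_acc,
                      _["draws"] = means);
}

// [[Rcpp::export]]
IntegerVector bcp_sweep_cpp(NumericVector x, IntegerVector u, double p0,
                            double w0) {
  BHModel M(x, p0, w0);
  std::vector<int> uu(u.begin(), u.end());
  int b; double W, B;
  recompute_stats(M, uu, b, W, B);
  sweep(M, uu, b, W, B);
  return IntegerVector(uu.begin(), uu.end());
}

// [[Rcpp::export]]
double bcp_log_odds_cpp(NumericVector x, IntegerVector u, int i, double p0,
                        double w0) {
  // i is a 0-based position index < n-1; u gives the states of all others
  BHModel M(x, p0, w0);
  int n = M.n;
  std::vector<int> u1(u.begin(), u.end()), u0(u.begin(), u.end());
  u1[i] = 1; u0[i] = 0;
  int b1, b0; double W1, B1, W0, B0;
  recompute_stats(M, u1, b1, W1, B1);
  recompute_stats(M, u0, b0, W0, B0);
  (void)n;
  return M.log_odds(b1, W1, B1, W0, B0);
}
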