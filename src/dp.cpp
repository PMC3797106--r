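#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact least-squares segmentation of a 1-d signal.
//
// Both engines minimise, for every k = 0..kmax, the within-segment sum of
// squared deviations from segment means over all placements of k breakpoints.
// dp_naive is the textbook O(kmax * n^2) dynamic program; dp_pruned keeps,
// for each segment count, the cost as an explicit piecewise-quadratic
// function of the last segment mean and prunes candidate change points whose
// quadratic is dominated everywhere (functional pruning), which brings the
// expected complexity close to linear in n. They return identical optima.
//
// Breakpoints are reported 1-based: value i means a boundary after probe i
// (between probes i and i+1), i in 1..n-1.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List dp_naive(NumericVector y, int kmax) {
  const int n = y.size();
  if (n < 1) stop("empty signal");
  if (kmax < 0) stop("kmax must be >= 0");
  if (kmax > n - 1) kmax = n - 1;

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + y[i];
    s2[i + 1] = s2[i] + y[i] * y[i];
  }
  // cost of segment covering probes i..j (0-based, inclusive)
  auto cost = [&](int i, int j) {
    double sum = s1[j + 1] - s1[i];
    double ss  = s2[j + 1] - s2[i];
    double c   = ss - sum * sum / (j - i + 1);
    return c > 0.0 ? c : 0.0;
  };

  // D[k][j]: optimal cost of y[0..j] with k breakpoints
  std::vector< std::vector<double> > D(kmax + 1, std::vector<double>(n, INF));
  std::vector< std::vector<int> > B;
  if (kmax > 0) B.assign(kmax + 1, std::vector<int>(n, -1));
  for (int j = 0; j < n; ++j) D[0][j] = cost(0, j);
  for (int k = 1; k <= kmax; ++k) {
    for (int j = k; j < n; ++j) {
      double best = INF;
      int arg = -1;
      // tau = index of last probe of the previous part (0-based)
      for (int tau = k - 1; tau < j; ++tau) {
        double v = D[k - 1][tau] + cost(tau + 1, j);
        if (v < best) { best = v; arg = tau; }  // strict <: leftmost tie-break
      }
      D[k][j] = best;
      B[k][j] = arg;
    }
  }

  NumericVector rss(kmax + 1);
  List bp(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    rss[k] = D[k][n - 1];
    IntegerVector b(k);
    int j = n - 1;
    for (int kk = k; kk >= 1; --kk) {
      int tau = B[kk][j];
      b[kk - 1] = tau + 1;  // boundary after probe tau+1 (1-based)
      j = tau;
    }
    bp[k] = b;
  }
  return List::create(_["rss"] = rss, _["breakpoints"] = bp);
}

struct Piece {
  double lo, hi;   // interval of the candidate segment mean mu
  double a, b, c;  // quadratic a*mu^2 + b*mu + c on [lo, hi]
  int tau;         // candidate last change point (prefix length)
};

// [[Rcpp::export]]
List dp_pruned(NumericVector y, int kmax) {
  const int n = y.size();
  if (n < 1) stop("empty signal");
  if (kmax < 0) stop("kmax must be >= 0");
  if (kmax > n - 1) kmax = n - 1;

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  double ymin = y[0], ymax = y[0];
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + y[i];
    s2[i + 1] = s2[i] + y[i] * y[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double pad = (ymax - ymin) * 1e-9 + 1e-9;
  const double LO = ymin - pad, HI = ymax + pad;
  auto cost = [&](int i, int j) {
    double sum = s1[j + 1] - s1[i];
    double ss  = s2[j + 1] - s2[i];
    double c   = ss - sum * sum / (j - i + 1);
    return c > 0.0 ? c : 0.0;
  };

  NumericVector rss(kmax + 1);
  rss[0] = cost(0, n - 1);
  List bp(kmax + 1);
  bp[0] = IntegerVector(0);
  if (kmax == 0) return List::create(_["rss"] = rss, _["breakpoints"] = bp);

  // D_prev[t]: optimal cost of the first t probes with p-1 segments
  std::vector<double> D_prev(n + 1, INF), D_cur(n + 1, INF);
  for (int t = 1; t <= n; ++t) D_prev[t] = cost(0, t - 1);
  // last_cp[p][t]: optimal last change point of D_p(t)
  std::vector< std::vector<int> > last_cp(kmax + 2, std::vector<int>(n + 1, -1));

  const double WEPS = 1e-12;

  for (int p = 2; p <= kmax + 1; ++p) {
    std::vector<Piece> pieces;
    pieces.reserve(64);
    std::fill(D_cur.begin(), D_cur.end(), INF);

    for (int t = p; t <= n; ++t) {
      // 1) insert candidate tau = t-1 with constant value v = D_prev[t-1]
      double v = D_prev[t - 1];
      if (R_finite(v)) {
        std::vector<Piece> np;
        np.reserve(pieces.size() + 2);
        auto push_new = [&](double lo, double hi) {
          if (hi - lo <= WEPS) return;
          if (!np.empty() && np.back().tau == t - 1 &&
              std::abs(np.back().hi - lo) <= WEPS) {
            np.back().hi = hi;  // merge adjacent intervals of the new candidate
          } else {
            Piece q; q.lo = lo; q.hi = hi; q.a = 0.0; q.b = 0.0; q.c = v;
            q.tau = t - 1; np.push_back(q);
          }
        };
        if (pieces.empty()) {
          push_new(LO, HI);
        } else {
          for (size_t ip = 0; ip < pieces.size(); ++ip) {
            Piece &P = pieces[ip];
            if (P.a <= 0.0) {  // constant piece (cannot occur after a point add, kept for safety)
              if (P.c <= v) np.push_back(P); else push_new(P.lo, P.hi);
              continue;
            }
            // q(mu) - v < 0 between the roots (upward parabola)
            double disc = P.b * P.b - 4.0 * P.a * (P.c - v);
            if (disc <= 0.0) {           // old piece nowhere better
              push_new(P.lo, P.hi);
            } else {
              double sd = std::sqrt(disc);
              double r1 = (-P.b - sd) / (2.0 * P.a);
              double r2 = (-P.b + sd) / (2.0 * P.a);
              double keep_lo = std::max(P.lo, r1);
              double keep_hi = std::min(P.hi, r2);
              if (keep_hi - keep_lo <= WEPS) {
                push_new(P.lo, P.hi);
              } else {
                if (keep_lo - P.lo > WEPS) push_new(P.lo, keep_lo);
                Piece K = P; K.lo = keep_lo; K.hi = keep_hi; np.push_back(K);
                if (P.hi - keep_hi > WEPS) push_new(keep_hi, P.hi);
              }
            }
          }
        }
        pieces.swap(np);
      }

      // 2) add data point y[t-1] to every piece
      double yt = y[t - 1];
      for (size_t ip = 0; ip < pieces.size(); ++ip) {
        pieces[ip].a += 1.0;
        pieces[ip].b -= 2.0 * yt;
        pieces[ip].c += yt * yt;
      }

      // 3) global minimum over mu
      double best = INF; int arg = -1;
      for (size_t ip = 0; ip < pieces.size(); ++ip) {
        const Piece &P = pieces[ip];
        double mu = -P.b / (2.0 * P.a);
        double val;
        if (mu < P.lo) mu = P.lo; else if (mu > P.hi) mu = P.hi;
        val = (P.a * mu + P.b) * mu + P.c;
        if (val < best) { best = val; arg = P.tau; }
      }
      D_cur[t] = best;
      last_cp[p][t] = arg;
    }

    rss[p - 1] = D_cur[n] > 0.0 ? D_cur[n] : 0.0;
    IntegerVector b(p - 1);
    int t = n;
    for (int pp = p; pp >= 2; --pp) {
      int tau = last_cp[pp][t];
      b[pp - 2] = tau;  // prefix length tau = boundary after probe tau
      t = tau;
    }
    bp[p - 1] = b;
    D_prev.swap(D_cur);
  }

  return List::create(_["rss"] = rss, _["breakpoints"] = bp);
}
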