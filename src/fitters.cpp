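#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solve a 4x4 linear system in place (Gaussian elimination, partial pivot).
// Returns false when the system is numerically singular.
static bool solve4(double A[4][4], double b[4], double x[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < 4; ++c) {
    int p = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[p]][c])) p = r;
    std::swap(piv[c], piv[p]);
    double d = A[piv[c]][c];
    if (std::fabs(d) < 1e-300) return false;
    for (int r = c + 1; r < 4; ++r) {
      double f = A[piv[r]][c] / d;
      for (int k = c; k < 4; ++k) A[piv[r]][k] -= f * A[piv[c]][k];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = 3; c >= 0; --c) {
    double s = b[piv[c]];
    for (int k = c + 1; k < 4; ++k) s -= A[piv[c]][k] * x[k];
    double d = A[piv[c]][c];
    if (std::fabs(d) < 1e-300) return false;
    x[c] = s / d;
  }
  return true;
}

// Sum of squared residuals of the fixed-width Gaussian model on a window.
// Window pixel centers: xc = j - 0.5, yc = i - 0.5 (1-based i, j).
static double cost_of(const NumericMatrix &fr, int i0, int j0, int hf,
                      const double p[4], double s0) {
  double inv2s2 = 1.0 / (2.0 * s0 * s0);
  double norm = 1.0 / (2.0 * M_PI * s0 * s0);
  double ss = 0.0;
  for (int i = i0 - hf; i <= i0 + hf; ++i) {
    double yc = i - 0.5;
    for (int j = j0 - hf; j <= j0 + hf; ++j) {
      double xc = j - 0.5;
      double dx = xc - p[0], dy = yc - p[1];
      double g = std::exp(-(dx * dx + dy * dy) * inv2s2);
      double m = p[2] * norm * g + p[3];
      double r = fr(i - 1, j - 1) - m;
      ss += r * r;
    }
  }
  return ss;
}

// Levenberg-Marquardt fit of n_psf/(2 pi s0^2) exp(-((x-x0)^2+(y-y0)^2)/
// (2 s0^2)) + n_b to the (2 hf + 1)^2 window around each candidate peak.
// Free parameters: x0, y0, n_psf, n_b; s0 fixed.
// [[Rcpp::export]]
NumericMatrix fit_spots_cpp(NumericMatrix frame, IntegerVector ipeak,
                            IntegerVector jpeak, NumericVector bg0,
                            int hf, double s0, double npsf_floor = 1.0,
                            int maxit = 200, double tol = 1e-8) {
  int n = ipeak.size();
  int nr = frame.nrow(), nc = frame.ncol();
  NumericMatrix out(n, 7);
  colnames(out) = CharacterVector::create("x0", "y0", "n_psf", "n_b",
                                          "rss", "iter", "converged");
  double inv2s2 = 1.0 / (2.0 * s0 * s0);
  double norm = 1.0 / (2.0 * M_PI * s0 * s0);

  for (int c = 0; c < n; ++c) {
    int i0 = ipeak[c], j0 = jpeak[c];
    if (i0 - hf < 1 || i0 + hf > nr || j0 - hf < 1 || j0 + hf > nc)
      stop("fit window out of bounds for candidate %d", c + 1);
    double p[4];
    p[0] = j0 - 0.5;                       // x0 at the peak pixel center
    p[1] = i0 - 0.5;                       // y0
    double amp0 = frame(i0 - 1, j0 - 1) - bg0[c];
    p[2] = std::max(2.0 * M_PI * s0 * s0 * amp0, npsf_floor);
    p[3] = bg0[c];

    double cost = cost_of(frame, i0, j0, hf, p, s0);
    double lambda = 1e-3;
    bool converged = false;
    int it = 0;
    for (; it < maxit && !converged; ++it) {
      // accumulate JtJ and Jtr
      double JtJ[4][4] = {{0}}, Jtr[4] = {0};
      for (int i = i0 - hf; i <= i0 + hf; ++i) {
        double yc = i - 0.5;
        for (int j = j0 - hf; j <= j0 + hf; ++j) {
          double xc = j - 0.5;
          double dx = xc - p[0], dy = yc - p[1];
          double g = std::exp(-(dx * dx + dy * dy) * inv2s2);
          double Ag = p[2] * norm * g;
          double r = frame(i - 1, j - 1) - (Ag + p[3]);
          double J0 = Ag * dx / (s0 * s0);  // d model / d x0
          double J1 = Ag * dy / (s0 * s0);  // d model / d y0
          double J2 = norm * g;             // d model / d n_psf
          double J3 = 1.0;                  // d model / d n_b
          double Jv[4] = {J0, J1, J2, J3};
          for (int a = 0; a < 4; ++a) {
            Jtr[a] += Jv[a] * r;
            for (int b = a; b < 4; ++b) JtJ[a][b] += Jv[a] * Jv[b];
          }
        }
      }
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < a; ++b) JtJ[a][b] = JtJ[b][a];

      bool stepped = false;
      for (int attempt = 0; attempt < 40 && !stepped; ++attempt) {
        double A[4][4], b[4], d[4];
        for (int a = 0; a < 4; ++a) {
          for (int bb = 0; bb < 4; ++bb) A[a][bb] = JtJ[a][bb];
          A[a][a] += lambda * (JtJ[a][a] > 0 ? JtJ[a][a] : 1.0);
          b[a] = Jtr[a];
        }
        if (!solve4(A, b, d)) { lambda *= 10.0; continue; }
        double pn[4] = {p[0] + d[0], p[1] + d[1], p[2] + d[2], p[3] + d[3]};
        double cn = cost_of(frame, i0, j0, hf, pn, s0);
        if (cn <= cost) {
          double dp = std::max(std::max(std::fabs(d[0]), std::fabs(d[1])),
                               std::max(std::fabs(d[2]) /
                                            std::max(1.0, std::fabs(p[2])),
                                        std::fabs(d[3]) /
                                            std::max(1.0, std::fabs(p[3]))));
          double dc = (cost - cn) / std::max(cost, 1e-300);
          for (int a = 0; a < 4; ++a) p[a] = pn[a];
          cost = cn;
          lambda = std::max(lambda / 10.0, 1e-12);
          stepped = true;
          if (dp < tol || dc < tol) converged = true;
        } else {
          lambda *= 10.0;
        }
      }
      if (!stepped) { converged = cost < 1e-20 ? true : converged; break; }
    }
    out(c, 0) = p[0];
    out(c, 1) = p[1];
    out(c, 2) = p[2];
    out(c, 3) = p[3];
    out(c, 4) = cost;
    out(c, 5) = it;
    out(c, 6) = converged ? 1.0 : 0.0;
  }
  return out;
}

// Hungarian algorithm (Jonker-Volgenant style with potentials) for a square
// cost matrix. Returns, for each row, the 1-based column assigned to it.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j;
  return ans;
}
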