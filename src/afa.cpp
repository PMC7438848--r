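// Adaptive detrending core: overlapped-window polynomial fits stitched into
// a smooth global trend, and the residual fluctuation function over a grid
// of window sizes. Hot path for the channel-difference Hurst networks
// (171 series per epoch), hence compiled.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// design matrix w x p (column-major), abscissa scaled to [-1, 1]
static void buildDesign(int w, int p, std::vector<double> &X) {
  X.assign((size_t)w * p, 0.0);
  for (int i = 0; i < w; ++i) {
    double t = (w == 1) ? 0.0 : -1.0 + 2.0 * i / (w - 1);
    double pw = 1.0;
    for (int j = 0; j < p; ++j) {
      X[(size_t)j * w + i] = pw;
      pw *= t;
    }
  }
}

// C = (X'X)^{-1} X', stored with p rows, column-major: C[a + i*p]
static void pseudoInverse(const std::vector<double> &X, int w, int p,
                          std::vector<double> &C) {
  std::vector<double> G((size_t)p * p, 0.0), I((size_t)p * p, 0.0);
  for (int a = 0; a < p; ++a)
    for (int b = 0; b < p; ++b) {
      double s = 0.0;
      for (int i = 0; i < w; ++i)
        s += X[(size_t)a * w + i] * X[(size_t)b * w + i];
      G[a + b * p] = s;
    }
  for (int a = 0; a < p; ++a) I[a + a * p] = 1.0;
  for (int c = 0; c < p; ++c) {
    int piv = c;
    for (int r = c + 1; r < p; ++r)
      if (std::fabs(G[r + c * p]) > std::fabs(G[piv + c * p])) piv = r;
    if (piv != c)
      for (int k = 0; k < p; ++k) {
        std::swap(G[c + k * p], G[piv + k * p]);
        std::swap(I[c + k * p], I[piv + k * p]);
      }
    double d = G[c + c * p];
    for (int k = 0; k < p; ++k) {
      G[c + k * p] /= d;
      I[c + k * p] /= d;
    }
    for (int r = 0; r < p; ++r) {
      if (r == c) continue;
      double f = G[r + c * p];
      if (f == 0.0) continue;
      for (int k = 0; k < p; ++k) {
        G[r + k * p] -= f * G[c + k * p];
        I[r + k * p] -= f * I[c + k * p];
      }
    }
  }
  C.assign((size_t)p * w, 0.0);
  for (int a = 0; a < p; ++a)
    for (int i = 0; i < w; ++i) {
      double s = 0.0;
      for (int b = 0; b < p; ++b)
        s += I[a + b * p] * X[(size_t)b * w + i];
      C[a + (size_t)i * p] = s;
    }
}

// adjacent windows overlap by (w+1)/2 samples: step (w-1)/2; a final window
// is pinned to end exactly at N (its overlap with the previous window may
// then exceed (w+1)/2, and the crossfade runs over that actual overlap)
static std::vector<int> windowStarts(int N, int w) {
  int step = (w - 1) / 2;
  if (step < 1) step = 1;
  std::vector<int> st;
  for (int s = 0; s + w <= N; s += step) st.push_back(s);
  if (st.empty() || st.back() != N - w) st.push_back(N - w);
  return st;
}

// global trend of u[0..N-1]; linear crossfade over each overlap region
static void trendOne(const double *u, int N, int w, int p,
                     const std::vector<double> &X,
                     const std::vector<double> &C,
                     const std::vector<int> &starts, double *v) {
  std::vector<double> fitted(w);
  double coef[16];
  int prevEnd = -1;
  for (size_t k = 0; k < starts.size(); ++k) {
    int s = starts[k];
    for (int a = 0; a < p; ++a) {
      double acc = 0.0;
      for (int i = 0; i < w; ++i) acc += C[a + (size_t)i * p] * u[s + i];
      coef[a] = acc;
    }
    for (int i = 0; i < w; ++i) {
      double acc = 0.0;
      for (int a = 0; a < p; ++a) acc += X[(size_t)a * w + i] * coef[a];
      fitted[i] = acc;
    }
    if (k == 0) {
      for (int i = 0; i < w; ++i) v[s + i] = fitted[i];
    } else {
      int o = prevEnd - s + 1;
      for (int l = 0; l < o; ++l) {
        double t = (o > 1) ? (double)l / (o - 1) : 1.0;
        v[s + l] = (1.0 - t) * v[s + l] + t * fitted[l];
      }
      for (int i = o; i < w; ++i) v[s + i] = fitted[i];
    }
    prevEnd = s + w - 1;
  }
}

// [[Rcpp::export]]
NumericVector afaTrendCpp(NumericVector u, int w, int order) {
  int N = u.size(), p = order + 1;
  if (w % 2 == 0) stop("window size must be odd");
  if (w > N) stop("window size exceeds series length");
  if (order < 0 || order > 8) stop("unsupported polynomial order");
  std::vector<double> X, C;
  buildDesign(w, p, X);
  pseudoInverse(X, w, p, C);
  std::vector<int> st = windowStarts(N, w);
  NumericVector v(N);
  trendOne(u.begin(), N, w, p, X, C, st, v.begin());
  return v;
}

// Fluctuation function F(w) = rms residual of the global trend, for every
// column of `u` at every window size in wGrid. With profile = true the
// columns are raw series and the mean-removed cumulative-sum profile is
// built here first. Returns a length(wGrid) x ncol(u) matrix.
// [[Rcpp::export]]
NumericMatrix afaFluctCpp(NumericMatrix u, IntegerVector wGrid, int order,
                          bool profile = false) {
  int N = u.nrow(), S = u.ncol(), G = wGrid.size(), p = order + 1;
  if (order < 0 || order > 8) stop("unsupported polynomial order");
  NumericMatrix out(G, S);
  std::vector<double> v(N), X, C;
  std::vector<double> prof;
  if (profile) prof.resize((size_t)N * S);
  const double *base = u.begin();
  if (profile) {
    for (int s = 0; s < S; ++s) {
      const double *col = u.begin() + (size_t)s * N;
      double m = 0.0;
      for (int i = 0; i < N; ++i) m += col[i];
      m /= N;
      double acc = 0.0;
      double *pc = prof.data() + (size_t)s * N;
      for (int i = 0; i < N; ++i) {
        acc += col[i] - m;
        pc[i] = acc;
      }
    }
    base = prof.data();
  }
  for (int g = 0; g < G; ++g) {
    int w = wGrid[g];
    if (w % 2 == 0) stop("window sizes must be odd");
    if (w > N) stop("window size exceeds series length");
    buildDesign(w, p, X);
    pseudoInverse(X, w, p, C);
    std::vector<int> st = windowStarts(N, w);
    for (int s = 0; s < S; ++s) {
      const double *col = base + (size_t)s * N;
      trendOne(col, N, w, p, X, C, st, v.data());
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        double r = col[i] - v[i];
        acc += r * r;
      }
      out(g, s) = std::sqrt(acc / N);
    }
  }
  return out;
}

// max - min of every column
// [[Rcpp::export]]
NumericVector colRangeCpp(NumericMatrix x) {
  int N = x.nrow(), S = x.ncol();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) {
    const double *col = x.begin() + (size_t)s * N;
    double lo = col[0], hi = col[0];
    for (int i = 1; i < N; ++i) {
      if (col[i] < lo) lo = col[i];
      if (col[i] > hi) hi = col[i];
    }
    out[s] = hi - lo;
  }
  return out;
}
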