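#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step integrators for the three model families. Edge lists are
// 2-column 1-based (i, j) with i < j; all graphs are undirected and
// unweighted, so every edge contributes symmetrically.

static inline void kuramoto_rhs(const std::vector<double>& th,
                                const std::vector<double>& omega,
                                const int* ei, const int* ej, int E,
                                double d, std::vector<double>& out) {
  const int N = th.size();
  for (int i = 0; i < N; ++i) out[i] = omega[i];
  for (int e = 0; e < E; ++e) {
    const int i = ei[e] - 1, j = ej[e] - 1;
    const double s = std::sin(th[j] - th[i]);
    out[i] += d * s;
    out[j] -= d * s;
  }
}

// [[Rcpp::export]]
List kuramoto_rk4_cpp(IntegerMatrix edges, NumericVector omega, double d,
                      NumericVector theta0, double dt,
                      int transient_steps, int n_samples, int sample_stride) {
  const int N = omega.size(), E = edges.nrow();
  if (theta0.size() != N) stop("theta0 length mismatch");
  std::vector<int> ei(E), ej(E);
  for (int e = 0; e < E; ++e) { ei[e] = edges(e, 0); ej[e] = edges(e, 1); }
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N);
  const double two_pi = 2.0 * M_PI;
  const std::vector<double> om = as<std::vector<double>>(omega);

  auto step = [&]() {
    kuramoto_rhs(th, om, ei.data(), ej.data(), E, d, k1);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k1[i];
    kuramoto_rhs(tmp, om, ei.data(), ej.data(), E, d, k2);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + 0.5 * dt * k2[i];
    kuramoto_rhs(tmp, om, ei.data(), ej.data(), E, d, k3);
    for (int i = 0; i < N; ++i) tmp[i] = th[i] + dt * k3[i];
    kuramoto_rhs(tmp, om, ei.data(), ej.data(), E, d, k4);
    for (int i = 0; i < N; ++i) {
      th[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      th[i] = std::remainder(th[i], two_pi);
    }
  };

  for (int t = 0; t < transient_steps; ++t) step();

  NumericMatrix theta_out(n_samples, N), freq_out(n_samples, N);
  for (int s = 0; s < n_samples; ++s) {
    kuramoto_rhs(th, om, ei.data(), ej.data(), E, d, k1);
    for (int i = 0; i < N; ++i) {
      theta_out(s, i) = th[i];
      freq_out(s, i) = k1[i];
      if (!std::isfinite(th[i]))
        stop("non-finite phase during integration (dt = %f)", dt);
    }
    if (s < n_samples - 1)
      for (int t = 0; t < sample_stride; ++t) step();
  }
  return List::create(_["theta"] = theta_out, _["freq"] = freq_out,
                      _["final_state"] = NumericVector(th.begin(), th.end()));
}

// [[Rcpp::export]]
List chialvo_cpp(IntegerMatrix edges, NumericVector I, double d,
                 NumericVector x0, NumericVector y0,
                 double a, double b, double c,
                 int transient_iters, int n_iters,
                 double spike_threshold, bool store_series) {
  const int N = I.size(), E = edges.nrow();
  if (x0.size() != N || y0.size() != N) stop("state length mismatch");
  std::vector<int> ei(E), ej(E);
  for (int e = 0; e < E; ++e) { ei[e] = edges(e, 0); ej[e] = edges(e, 1); }
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> xn(N), yn(N), cpl(N);

  auto iterate = [&]() {
    std::fill(cpl.begin(), cpl.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      const int i = ei[e] - 1, j = ej[e] - 1;
      const double diff = x[j] - x[i];
      cpl[i] += diff;
      cpl[j] -= diff;
    }
    for (int i = 0; i < N; ++i) {
      xn[i] = x[i] * x[i] * std::exp(y[i] - x[i]) + I[i] + d * cpl[i];
      yn[i] = a * y[i] - b * x[i] + c;
      if (!std::isfinite(xn[i]) || std::fabs(xn[i]) > 1e6)
        stop("Chialvo iteration diverged (|x| > 1e6)");
    }
    x.swap(xn);
    y.swap(yn);
  };

  for (int t = 0; t < transient_iters; ++t) iterate();

  // on-the-fly strict local maxima of x per node, gated by spike_threshold
  std::vector<std::vector<double>> mx_val(N);
  std::vector<std::vector<int>> mx_idx(N);
  std::vector<double> prev2(N), prev1(N);
  NumericMatrix xs;
  if (store_series) xs = NumericMatrix(n_iters, N);
  for (int t = 0; t < n_iters; ++t) {
    if (store_series)
      for (int i = 0; i < N; ++i) xs(t, i) = x[i];
    if (t >= 2) {
      for (int i = 0; i < N; ++i) {
        if (prev1[i] > prev2[i] && prev1[i] > x[i] && prev1[i] > spike_threshold) {
          mx_val[i].push_back(prev1[i]);
          mx_idx[i].push_back(t);  // 1-based index of the maximum = (t+1) - 1
        }
      }
    }
    for (int i = 0; i < N; ++i) { prev2[i] = prev1[i]; prev1[i] = x[i]; }
    iterate();
  }
  List maxima(N), maxima_t(N);
  for (int i = 0; i < N; ++i) {
    maxima[i] = NumericVector(mx_val[i].begin(), mx_val[i].end());
    maxima_t[i] = IntegerVector(mx_idx[i].begin(), mx_idx[i].end());
  }
  List out = List::create(_["maxima"] = maxima, _["maxima_t"] = maxima_t,
                          _["x_final"] = NumericVector(x.begin(), x.end()),
                          _["y_final"] = NumericVector(y.begin(), y.end()));
  if (store_series) out["x"] = xs;
  return out;
}

static inline void rossler_rhs(const std::vector<double>& s,
                               const std::vector<double>& w,
                               const int* ei, const int* ej, int E,
                               double a, double b, double c, double d,
                               std::vector<double>& out) {
  const int N = w.size();
  for (int i = 0; i < N; ++i) {
    const double x = s[3 * i], y = s[3 * i + 1], z = s[3 * i + 2];
    out[3 * i]     = -w[i] * y - z;
    out[3 * i + 1] = w[i] * x + a * y;
    out[3 * i + 2] = b + z * (x - c);
  }
  for (int e = 0; e < E; ++e) {
    const int i = ei[e] - 1, j = ej[e] - 1;
    const double diff = s[3 * j + 1] - s[3 * i + 1];  // coupling acts on y
    out[3 * i + 1] += d * diff;
    out[3 * j + 1] -= d * diff;
  }
}

// [[Rcpp::export]]
List rossler_rk4_cpp(IntegerMatrix edges, NumericVector w, double d,
                     NumericVector state0, double a, double b, double c,
                     double dt, int transient_steps, int n_steps,
                     int phase_stride, bool store_series, int series_stride) {
  const int N = w.size(), E = edges.nrow();
  if (state0.size() != 3 * N) stop("state0 must have length 3 * N");
  std::vector<int> ei(E), ej(E);
  for (int e = 0; e < E; ++e) { ei[e] = edges(e, 0); ej[e] = edges(e, 1); }
  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> k1(3 * N), k2(3 * N), k3(3 * N), k4(3 * N), tmp(3 * N);
  const std::vector<double> wv = as<std::vector<double>>(w);

  auto step = [&]() {
    rossler_rhs(s, wv, ei.data(), ej.data(), E, a, b, c, d, k1);
    for (int i = 0; i < 3 * N; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    rossler_rhs(tmp, wv, ei.data(), ej.data(), E, a, b, c, d, k2);
    for (int i = 0; i < 3 * N; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    rossler_rhs(tmp, wv, ei.data(), ej.data(), E, a, b, c, d, k3);
    for (int i = 0; i < 3 * N; ++i) tmp[i] = s[i] + dt * k3[i];
    rossler_rhs(tmp, wv, ei.data(), ej.data(), E, a, b, c, d, k4);
    for (int i = 0; i < 3 * N; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  };

  for (int t = 0; t < transient_steps; ++t) {
    step();
    if (t % 500 == 0 && !std::isfinite(s[0]))
      stop("non-finite state during Roessler transient (dt = %f)", dt);
  }

  const int n_phase = n_steps / phase_stride;
  NumericMatrix theta(n_phase, N);
  const int n_series = store_series ? n_steps / series_stride : 0;
  NumericMatrix series;
  if (store_series) series = NumericMatrix(n_series, 3 * N);

  std::vector<std::vector<double>> mn_val(N);
  std::vector<std::vector<int>> mn_idx(N);
  std::vector<double> prev2(N, NA_REAL), prev1(N, NA_REAL);
  int ip = 0, is = 0;
  for (int t = 0; t < n_steps; ++t) {
    // strict local minima of y on the integration grid
    if (t >= 2) {
      for (int i = 0; i < N; ++i) {
        const double yv = s[3 * i + 1];
        if (prev1[i] < prev2[i] && prev1[i] < yv) {
          mn_val[i].push_back(prev1[i]);
          mn_idx[i].push_back(t);
        }
      }
    }
    for (int i = 0; i < N; ++i) { prev2[i] = prev1[i]; prev1[i] = s[3 * i + 1]; }
    if (t % phase_stride == 0 && ip < n_phase) {
      for (int i = 0; i < N; ++i)
        theta(ip, i) = std::atan2(s[3 * i + 1], s[3 * i]);
      ++ip;
    }
    if (store_series && t % series_stride == 0 && is < n_series) {
      for (int i = 0; i < 3 * N; ++i) series(is, i) = s[i];
      ++is;
    }
    step();
    if (t % 200 == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(s[3 * i]))
          stop("non-finite state during Roessler integration (dt = %f)", dt);
    }
  }
  List minima(N), minima_t(N);
  for (int i = 0; i < N; ++i) {
    minima[i] = NumericVector(mn_val[i].begin(), mn_val[i].end());
    minima_t[i] = IntegerVector(mn_idx[i].begin(), mn_idx[i].end());
  }
  List out = List::create(_["minima"] = minima, _["minima_t"] = minima_t,
                          _["theta"] = theta,
                          _["final_state"] = NumericVector(s.begin(), s.end()));
  if (store_series) out["series"] = series;
  return out;
}
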