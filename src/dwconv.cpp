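#include <Rcpp.h>
using namespace Rcpp;

// Depthwise valid convolution over time in flattened layout: X is
// [M x T] with M = N * C rows ordered sample-fastest (rows n + N*(c-1)
// belong to channel c), kernel K is [C x S] (one filter per channel),
// bias b per channel. Channel blocks are contiguous row ranges, so the
// inner loops run over contiguous memory.

// [[Rcpp::export]]
NumericMatrix dwconv_fwd_cpp(const NumericMatrix& X, const NumericMatrix& K,
                             const NumericVector& b, const int N) {
  const int M = X.nrow(), T = X.ncol(), S = K.ncol(), C = K.nrow();
  const int Tout = T - S + 1;
  NumericMatrix Y(M, Tout);
  const double* xp = &X(0, 0);
  double* yp = &Y(0, 0);
  for (int t = 0; t < Tout; ++t) {
    double* ycol = yp + (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double bc = b[c];
      double* yblk = ycol + (size_t)c * N;
      for (int n = 0; n < N; ++n) yblk[n] = bc;
    }
    for (int s = 0; s < S; ++s) {
      const double* xcol = xp + (size_t)(t + s) * M;
      for (int c = 0; c < C; ++c) {
        const double k = K(c, s);
        const double* xblk = xcol + (size_t)c * N;
        double* yblk = ycol + (size_t)c * N;
        for (int n = 0; n < N; ++n) yblk[n] += xblk[n] * k;
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                    const NumericMatrix& K, const int N) {
  const int M = X.nrow(), T = X.ncol(), S = K.ncol(), C = K.nrow();
  const int Tout = dY.ncol();
  NumericMatrix dX(M, T), dK(C, S);
  NumericVector db(C);
  const double* xp = &X(0, 0);
  const double* dyp = &dY(0, 0);
  double* dxp = &dX(0, 0);
  for (int t = 0; t < Tout; ++t) {
    const double* dycol = dyp + (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double* dyblk = dycol + (size_t)c * N;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) acc += dyblk[n];
      db[c] += acc;
    }
    for (int s = 0; s < S; ++s) {
      double* dxcol = dxp + (size_t)(t + s) * M;
      const double* xcol = xp + (size_t)(t + s) * M;
      for (int c = 0; c < C; ++c) {
        const double k = K(c, s);
        const double* dyblk = dycol + (size_t)c * N;
        const double* xblk = xcol + (size_t)c * N;
        double* dxblk = dxcol + (size_t)c * N;
        double acc = 0.0;
        for (int n = 0; n < N; ++n) {
          dxblk[n] += dyblk[n] * k;
          acc += xblk[n] * dyblk[n];
        }
        dK(c, s) += acc;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK, _["db"] = db);
}

// One DWT level as strided (stride-2) correlation over an already padded
// [M x Tp] matrix; windows start at even offsets. Returns approximation
// and detail coefficient matrices [M x nout].

// [[Rcpp::export]]
List dwt_level_fwd_cpp(const NumericMatrix& Xp, const NumericVector& g,
                       const NumericVector& h) {
  const int M = Xp.nrow(), Tp = Xp.ncol(), R = g.size();
  const int nout = (Tp - R) / 2 + 1;
  NumericMatrix A(M, nout), D(M, nout);
  const double* xp = &Xp(0, 0);
  double* ap = &A(0, 0);
  double* dp = &D(0, 0);
  for (int i = 0; i < nout; ++i) {
    double* acol = ap + (size_t)i * M;
    double* dcol = dp + (size_t)i * M;
    for (int r = 0; r < R; ++r) {
      const double* xcol = xp + (size_t)(2 * i + r) * M;
      const double gr = g[r], hr = h[r];
      for (int m = 0; m < M; ++m) {
        acol[m] += xcol[m] * gr;
        dcol[m] += xcol[m] * hr;
      }
    }
  }
  return List::create(_["A"] = A, _["D"] = D);
}

// [[Rcpp::export]]
NumericMatrix dwt_level_bwd_cpp(const NumericMatrix& dA,
                                const NumericMatrix& dD,
                                const NumericVector& g,
                                const NumericVector& h, const int Tp) {
  const int M = dA.nrow(), nout = dA.ncol(), R = g.size();
  NumericMatrix dXp(M, Tp);
  const double* dap = &dA(0, 0);
  const double* ddp = &dD(0, 0);
  double* dxp = &dXp(0, 0);
  for (int i = 0; i < nout; ++i) {
    const double* acol = dap + (size_t)i * M;
    const double* dcol = ddp + (size_t)i * M;
    for (int r = 0; r < R; ++r) {
      double* xcol = dxp + (size_t)(2 * i + r) * M;
      const double gr = g[r], hr = h[r];
      for (int m = 0; m < M; ++m) xcol[m] += acol[m] * gr + dcol[m] * hr;
    }
  }
  return dXp;
}

// Dense 1-D convolution over time with SAME zero padding, flattened
// layout: X [N*C x T] -> Y [N*E x T]; kernel K as a (C, E, S) array.

// [[Rcpp::export]]
NumericMatrix conv1d_fwd_cpp(const NumericMatrix& X, const NumericVector& K,
                             const NumericVector& b, const int N,
                             const int E, const int S) {
  const int T = X.ncol();
  const int C = X.nrow() / N;
  const int pad = (S - 1) / 2;
  NumericMatrix Y(N * E, T);
  const double* xp = &X(0, 0);
  const double* kp = &K[0];
  double* yp = &Y(0, 0);
  for (int t = 0; t < T; ++t) {
    double* ycol = yp + (size_t)t * (N * E);
    for (int e = 0; e < E; ++e) {
      const double be = b[e];
      double* yblk = ycol + (size_t)e * N;
      for (int n = 0; n < N; ++n) yblk[n] = be;
    }
    for (int s = 0; s < S; ++s) {
      const int tx = t + s - pad;
      if (tx < 0 || tx >= T) continue;
      const double* xcol = xp + (size_t)tx * (N * C);
      for (int e = 0; e < E; ++e) {
        double* yblk = ycol + (size_t)e * N;
        for (int c = 0; c < C; ++c) {
          const double k = kp[c + C * e + C * E * s];
          const double* xblk = xcol + (size_t)c * N;
          for (int n = 0; n < N; ++n) yblk[n] += xblk[n] * k;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& X,
                    const NumericVector& K, const int N, const int E,
                    const int S) {
  const int T = X.ncol();
  const int C = X.nrow() / N;
  const int pad = (S - 1) / 2;
  NumericMatrix dX(N * C, T);
  NumericVector dK(C * E * S), db(E);
  const double* xp = &X(0, 0);
  const double* kp = &K[0];
  const double* dyp = &dY(0, 0);
  double* dxp = &dX(0, 0);
  double* dkp = &dK[0];
  for (int t = 0; t < T; ++t) {
    const double* dycol = dyp + (size_t)t * (N * E);
    for (int e = 0; e < E; ++e) {
      const double* dyblk = dycol + (size_t)e * N;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) acc += dyblk[n];
      db[e] += acc;
    }
    for (int s = 0; s < S; ++s) {
      const int tx = t + s - pad;
      if (tx < 0 || tx >= T) continue;
      const double* xcol = xp + (size_t)tx * (N * C);
      double* dxcol = dxp + (size_t)tx * (N * C);
      for (int e = 0; e < E; ++e) {
        const double* dyblk = dycol + (size_t)e * N;
        for (int c = 0; c < C; ++c) {
          const double k = kp[c + C * e + C * E * s];
          const double* xblk = xcol + (size_t)c * N;
          double* dxblk = dxcol + (size_t)c * N;
          double acc = 0.0;
          for (int n = 0; n < N; ++n) {
            dxblk[n] += dyblk[n] * k;
            acc += xblk[n] * dyblk[n];
          }
          dkp[c + C * e + C * E * s] += acc;
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dK"] = dK, _["db"] = db);
}

// ELU (alpha = 1) forward/backward, attribute-preserving.

// [[Rcpp::export]]
NumericVector elu_fwd_cpp(const NumericVector& x) {
  NumericVector y = clone(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (y[i] < 0) y[i] = std::exp(y[i]) - 1.0;
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(const NumericVector& dy, const NumericVector& y,
                          const NumericVector& x) {
  NumericVector g = clone(dy);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (x[i] < 0) g[i] = dy[i] * (y[i] + 1.0);
  return g;
}

// Channel-grouped batch normalization in flattened [M x T] layout
// (statistics per channel over its N rows x T columns).

// [[Rcpp::export]]
List bn_mat_fwd_cpp(const NumericMatrix& X, const NumericVector& gamma,
                    const NumericVector& beta, const NumericVector& mu,
                    const NumericVector& inv_sd, const int N) {
  const int M = X.nrow(), T = X.ncol(), C = M / N;
  NumericMatrix Xhat(M, T), Y(M, T);
  const double* xp = &X(0, 0);
  double* xh = &Xhat(0, 0);
  double* yp = &Y(0, 0);
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double m_ = mu[c], is_ = inv_sd[c], g_ = gamma[c], b_ = beta[c];
      const double* xb = xp + off + (size_t)c * N;
      double* hb = xh + off + (size_t)c * N;
      double* yb = yp + off + (size_t)c * N;
      for (int n = 0; n < N; ++n) {
        hb[n] = (xb[n] - m_) * is_;
        yb[n] = hb[n] * g_ + b_;
      }
    }
  }
  return List::create(_["Xhat"] = Xhat, _["Y"] = Y);
}

// [[Rcpp::export]]
NumericVector bn_stats_cpp(const NumericMatrix& X, const int N) {
  // returns c(mu_1..mu_C, var_1..var_C), biased variance
  const int M = X.nrow(), T = X.ncol(), C = M / N;
  NumericVector out(2 * C);
  const double* xp = &X(0, 0);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double* xb = xp + off + (size_t)c * N;
      double a1 = 0.0, a2 = 0.0;
      for (int n = 0; n < N; ++n) { a1 += xb[n]; a2 += xb[n] * xb[n]; }
      s1[c] += a1; s2[c] += a2;
    }
  }
  const double m = (double)N * T;
  for (int c = 0; c < C; ++c) {
    out[c] = s1[c] / m;
    out[C + c] = s2[c] / m - out[c] * out[c];
  }
  return out;
}

// [[Rcpp::export]]
List bn_mat_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& Xhat,
                    const NumericVector& gamma, const NumericVector& inv_sd,
                    const int N, const bool train) {
  const int M = dY.nrow(), T = dY.ncol(), C = M / N;
  const double m = (double)N * T;
  NumericMatrix dX(M, T);
  NumericVector dgamma(C), dbeta(C);
  const double* dyp = &dY(0, 0);
  const double* xh = &Xhat(0, 0);
  double* dxp = &dX(0, 0);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double* dyb = dyp + off + (size_t)c * N;
      const double* hb = xh + off + (size_t)c * N;
      double a1 = 0.0, a2 = 0.0;
      for (int n = 0; n < N; ++n) {
        a1 += dyb[n];
        a2 += dyb[n] * hb[n];
      }
      dbeta[c] += a1; dgamma[c] += a2;
      s1[c] += a1 * gamma[c]; s2[c] += a2 * gamma[c];
    }
  }
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * M;
    for (int c = 0; c < C; ++c) {
      const double g_ = gamma[c], is_ = inv_sd[c];
      const double sm1 = train ? s1[c] / m : 0.0;
      const double sm2 = train ? s2[c] / m : 0.0;
      const double* dyb = dyp + off + (size_t)c * N;
      const double* hb = xh + off + (size_t)c * N;
      double* dxb = dxp + off + (size_t)c * N;
      for (int n = 0; n < N; ++n) {
        dxb[n] = (dyb[n] * g_ - sm1 - hb[n] * sm2) * is_;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
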