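// Small convolutional network over rasterized landmark images.
// Architecture: conv(32,3x3)+ReLU+maxpool(2x2), conv(32,3x3)+ReLU+maxpool(2x2),
// conv(64,3x3)+ReLU+maxpool(2x2), flatten, dense -> 2 logits.
// Valid (unpadded) convolutions; pooling floors odd dimensions.
// All gradients are exact analytic backprop; training is plain minibatch Adam.
// Determinism: weight init and epoch permutations are supplied by the caller,
// and execution is single-threaded, so identical inputs give identical output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Unfold a (H, W, C) activation cube into a (C*9, Ho*Wo) matrix of 3x3
// patches so convolution becomes a single GEMM. Column j = wo*Ho + ho.
mat im2col3(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const uword Ho = H - 2, Wo = W - 2;
  mat cols(C * 9, Ho * Wo);
  for (uword c = 0; c < C; ++c) {
    for (uword kj = 0; kj < 3; ++kj) {
      for (uword ki = 0; ki < 3; ++ki) {
        const uword r = c * 9 + kj * 3 + ki;
        for (uword wo = 0; wo < Wo; ++wo) {
          const double* src = X.slice_colptr(c, wo + kj) + ki;
          double* dst0 = cols.colptr(wo * Ho) + r;
          // stride over columns of `cols` is its number of rows
          const uword stride = cols.n_rows;
          for (uword ho = 0; ho < Ho; ++ho) {
            *(dst0 + ho * stride) = src[ho];
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add the patch-matrix gradient back onto the input cube.
cube col2im3(const mat& dcols, uword H, uword W, uword C) {
  const uword Ho = H - 2, Wo = W - 2;
  cube dX(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    for (uword kj = 0; kj < 3; ++kj) {
      for (uword ki = 0; ki < 3; ++ki) {
        const uword r = c * 9 + kj * 3 + ki;
        const uword stride = dcols.n_rows;
        for (uword wo = 0; wo < Wo; ++wo) {
          const double* src0 = dcols.colptr(wo * Ho) + r;
          double* dst = dX.slice_colptr(c, wo + kj) + ki;
          for (uword ho = 0; ho < Ho; ++ho) {
            dst[ho] += *(src0 + ho * stride);
          }
        }
      }
    }
  }
  return dX;
}

// (Cout, Ho*Wo) GEMM result -> (Ho, Wo, Cout) cube.
cube rows2cube(const mat& Y, uword Ho, uword Wo) {
  cube out(Ho, Wo, Y.n_rows);
  for (uword c = 0; c < Y.n_rows; ++c) {
    out.slice(c) = reshape(Y.row(c).t(), Ho, Wo);
  }
  return out;
}

mat cube2rows(const cube& X) {
  mat out(X.n_slices, X.n_rows * X.n_cols);
  for (uword c = 0; c < X.n_slices; ++c) {
    out.row(c) = vectorise(X.slice(c)).t();
  }
  return out;
}

// 2x2 max pool, stride 2; odd trailing rows/cols dropped. Records the
// argmax element index within each 2x2 window for backprop routing.
cube maxpool2(const cube& X, ucube& arg) {
  const uword Ho = X.n_rows / 2, Wo = X.n_cols / 2, C = X.n_slices;
  cube out(Ho, Wo, C);
  arg.set_size(Ho, Wo, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < Wo; ++j) {
      for (uword i = 0; i < Ho; ++i) {
        double best = X(2 * i, 2 * j, c);
        uword which = 0;
        const double cand1 = X(2 * i + 1, 2 * j, c);
        if (cand1 > best) { best = cand1; which = 1; }
        const double cand2 = X(2 * i, 2 * j + 1, c);
        if (cand2 > best) { best = cand2; which = 2; }
        const double cand3 = X(2 * i + 1, 2 * j + 1, c);
        if (cand3 > best) { best = cand3; which = 3; }
        out(i, j, c) = best;
        arg(i, j, c) = which;
      }
    }
  }
  return out;
}

cube maxpool2_back(const cube& dY, const ucube& arg, uword H, uword W) {
  cube dX(H, W, dY.n_slices, fill::zeros);
  for (uword c = 0; c < dY.n_slices; ++c) {
    for (uword j = 0; j < dY.n_cols; ++j) {
      for (uword i = 0; i < dY.n_rows; ++i) {
        const uword w = arg(i, j, c);
        dX(2 * i + (w == 1 || w == 3 ? 1 : 0),
           2 * j + (w >= 2 ? 1 : 0), c) += dY(i, j, c);
      }
    }
  }
  return dX;
}

struct Params {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4;
};

Params unpack(const Rcpp::List& p) {
  Params out;
  out.W1 = Rcpp::as<mat>(p["W1"]); out.b1 = Rcpp::as<vec>(p["b1"]);
  out.W2 = Rcpp::as<mat>(p["W2"]); out.b2 = Rcpp::as<vec>(p["b2"]);
  out.W3 = Rcpp::as<mat>(p["W3"]); out.b3 = Rcpp::as<vec>(p["b3"]);
  out.W4 = Rcpp::as<mat>(p["W4"]); out.b4 = Rcpp::as<vec>(p["b4"]);
  return out;
}

Rcpp::List pack(const Params& p) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = p.W1, Rcpp::Named("b1") = p.b1,
    Rcpp::Named("W2") = p.W2, Rcpp::Named("b2") = p.b2,
    Rcpp::Named("W3") = p.W3, Rcpp::Named("b3") = p.b3,
    Rcpp::Named("W4") = p.W4, Rcpp::Named("b4") = p.b4);
}

// Per-sample caches needed for backprop.
struct Caches {
  cube a0;                       // input (H, W, 1)
  mat cols1, cols2, cols3;       // im2col views
  cube z1, z2, z3;               // pre-activation conv outputs
  cube r1, r2, r3;               // post-ReLU
  cube p1, p2, p3;               // post-pool
  ucube arg1, arg2, arg3;        // pool argmax
  vec flat;
  vec logits;
};

vec forward_sample(const Params& P, const mat& x, Caches* C) {
  Caches tmp;
  Caches& cc = C ? *C : tmp;
  cc.a0 = cube(x.n_rows, x.n_cols, 1);
  cc.a0.slice(0) = x;

  cc.cols1 = im2col3(cc.a0);
  mat y1 = P.W1 * cc.cols1;
  y1.each_col() += P.b1;
  cc.z1 = rows2cube(y1, x.n_rows - 2, x.n_cols - 2);
  cc.r1 = clamp(cc.z1, 0.0, datum::inf);
  cc.p1 = maxpool2(cc.r1, cc.arg1);

  cc.cols2 = im2col3(cc.p1);
  mat y2 = P.W2 * cc.cols2;
  y2.each_col() += P.b2;
  cc.z2 = rows2cube(y2, cc.p1.n_rows - 2, cc.p1.n_cols - 2);
  cc.r2 = clamp(cc.z2, 0.0, datum::inf);
  cc.p2 = maxpool2(cc.r2, cc.arg2);

  cc.cols3 = im2col3(cc.p2);
  mat y3 = P.W3 * cc.cols3;
  y3.each_col() += P.b3;
  cc.z3 = rows2cube(y3, cc.p2.n_rows - 2, cc.p2.n_cols - 2);
  cc.r3 = clamp(cc.z3, 0.0, datum::inf);
  cc.p3 = maxpool2(cc.r3, cc.arg3);

  cc.flat = vectorise(cc.p3);
  cc.logits = P.W4 * cc.flat + P.b4;
  return cc.logits;
}

double softmax_ce(const vec& logits, uword y, vec& dlogits) {
  const double m = logits.max();
  vec e = exp(logits - m);
  const double s = accu(e);
  vec p = e / s;
  dlogits = p;
  dlogits(y) -= 1.0;
  return -(logits(y) - m - std::log(s));
}

void backward_sample(const Params& P, const Caches& cc, const vec& dlogits,
                     Params& G) {
  G.W4 += dlogits * cc.flat.t();
  G.b4 += dlogits;
  vec dflat = P.W4.t() * dlogits;

  cube dp3(const_cast<double*>(dflat.memptr()), cc.p3.n_rows, cc.p3.n_cols,
           cc.p3.n_slices, true);
  cube dr3 = maxpool2_back(dp3, cc.arg3, cc.r3.n_rows, cc.r3.n_cols);
  dr3.elem(find(cc.z3 <= 0)).zeros();
  mat dY3 = cube2rows(dr3);
  G.W3 += dY3 * cc.cols3.t();
  G.b3 += sum(dY3, 1);
  cube dp2 = col2im3(P.W3.t() * dY3, cc.p2.n_rows, cc.p2.n_cols,
                     cc.p2.n_slices);

  cube dr2 = maxpool2_back(dp2, cc.arg2, cc.r2.n_rows, cc.r2.n_cols);
  dr2.elem(find(cc.z2 <= 0)).zeros();
  mat dY2 = cube2rows(dr2);
  G.W2 += dY2 * cc.cols2.t();
  G.b2 += sum(dY2, 1);
  cube dp1 = col2im3(P.W2.t() * dY2, cc.p1.n_rows, cc.p1.n_cols,
                     cc.p1.n_slices);

  cube dr1 = maxpool2_back(dp1, cc.arg1, cc.r1.n_rows, cc.r1.n_cols);
  dr1.elem(find(cc.z1 <= 0)).zeros();
  mat dY1 = cube2rows(dr1);
  G.W1 += dY1 * cc.cols1.t();
  G.b1 += sum(dY1, 1);
}

Params zeros_like(const Params& P) {
  Params G;
  G.W1 = zeros<mat>(size(P.W1)); G.b1 = zeros<vec>(P.b1.n_elem);
  G.W2 = zeros<mat>(size(P.W2)); G.b2 = zeros<vec>(P.b2.n_elem);
  G.W3 = zeros<mat>(size(P.W3)); G.b3 = zeros<vec>(P.b3.n_elem);
  G.W4 = zeros<mat>(size(P.W4)); G.b4 = zeros<vec>(P.b4.n_elem);
  return G;
}

}  // namespace

// Logits for a batch of images; X is (H, W, N).
// [[Rcpp::export]]
arma::mat cnn_forward_logits(const Rcpp::List& params, const arma::cube& X) {
  const Params P = unpack(params);
  mat out(X.n_slices, 2);
  for (uword i = 0; i < X.n_slices; ++i) {
    out.row(i) = forward_sample(P, X.slice(i), nullptr).t();
  }
  return out;
}

// Mean cross-entropy loss and exact mean gradients for a batch.
// y is 0/1 (0 = not engaged, 1 = engaged).
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad(const Rcpp::List& params, const arma::cube& X,
                         const arma::uvec& y) {
  const Params P = unpack(params);
  Params G = zeros_like(P);
  double loss = 0.0;
  const uword n = X.n_slices;
  for (uword i = 0; i < n; ++i) {
    Caches cc;
    forward_sample(P, X.slice(i), &cc);
    vec dlogits;
    loss += softmax_ce(cc.logits, y(i), dlogits);
    backward_sample(P, cc, dlogits, G);
  }
  const double inv = 1.0 / static_cast<double>(n);
  G.W1 *= inv; G.b1 *= inv; G.W2 *= inv; G.b2 *= inv;
  G.W3 *= inv; G.b3 *= inv; G.W4 *= inv; G.b4 *= inv;
  return Rcpp::List::create(Rcpp::Named("loss") = loss * inv,
                            Rcpp::Named("grads") = pack(G));
}

// Minibatch Adam over `order` (n x epochs matrix of 1-based permutations,
// generated by the caller so the whole run is reproducible from one seed).
// Returns final parameters plus per-epoch mean loss and training accuracy
// (both measured on the forward passes done during that epoch).
// [[Rcpp::export]]
Rcpp::List cnn_train(const Rcpp::List& params, const arma::cube& X,
                     const arma::uvec& y, const arma::umat& order,
                     int batch_size, double lr, double beta1, double beta2,
                     double eps) {
  Params P = unpack(params);
  Params M = zeros_like(P), V = zeros_like(P);
  const uword n = X.n_slices, n_epochs = order.n_cols;
  vec ep_loss(n_epochs), ep_acc(n_epochs);
  long t = 0;

  for (uword e = 0; e < n_epochs; ++e) {
    double loss_sum = 0.0;
    uword correct = 0;
    uword start = 0;
    while (start < n) {
      const uword stop = std::min(start + static_cast<uword>(batch_size), n);
      Params G = zeros_like(P);
      for (uword k = start; k < stop; ++k) {
        const uword i = order(k, e) - 1;
        Caches cc;
        forward_sample(P, X.slice(i), &cc);
        vec dlogits;
        loss_sum += softmax_ce(cc.logits, y(i), dlogits);
        backward_sample(P, cc, dlogits, G);
        // ties broken toward class 0 (not engaged)
        if ((cc.logits(1) > cc.logits(0) ? 1u : 0u) == y(i)) ++correct;
      }
      const double inv = 1.0 / static_cast<double>(stop - start);
      ++t;
      const double corr = lr * std::sqrt(1.0 - std::pow(beta2, t)) /
                          (1.0 - std::pow(beta1, t));
      auto adam = [&](mat& w, mat& m, mat& v, const mat& g_raw) {
        const mat g = g_raw * inv;
        m = beta1 * m + (1.0 - beta1) * g;
        v = beta2 * v + (1.0 - beta2) * square(g);
        w -= corr * m / (sqrt(v) + eps);
      };
      auto adamv = [&](vec& w, vec& m, vec& v, const vec& g_raw) {
        const vec g = g_raw * inv;
        m = beta1 * m + (1.0 - beta1) * g;
        v = beta2 * v + (1.0 - beta2) * square(g);
        w -= corr * m / (sqrt(v) + eps);
      };
      adam(P.W1, M.W1, V.W1, G.W1); adamv(P.b1, M.b1, V.b1, G.b1);
      adam(P.W2, M.W2, V.W2, G.W2); adamv(P.b2, M.b2, V.b2, G.b2);
      adam(P.W3, M.W3, V.W3, G.W3); adamv(P.b3, M.b3, V.b3, G.b3);
      adam(P.W4, M.W4, V.W4, G.W4); adamv(P.b4, M.b4, V.b4, G.b4);
      start = stop;
    }
    ep_loss(e) = loss_sum / static_cast<double>(n);
    ep_acc(e) = static_cast<double>(correct) / static_cast<double>(n);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(P),
                            Rcpp::Named("loss") = ep_loss,
                            Rcpp::Named("accuracy") = ep_acc);
}
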