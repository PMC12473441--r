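// Shallow two-block CNN for dual-mat pressure frames.
//
// Layout conventions:
//  - a batch of B samples is a (d x B) matrix, d = C*H*H, each channel plane
//    stored column-major (p = col*H + row);
//  - im2col matrices are ((H*H)*B) x (C*9), row index = b*P + p, so 3x3
//    'same' convolutions become one BLAS gemm per layer;
//  - pooling (2x2, stride 2) fires only when the current spatial side is at
//    least 8, which lets the same architecture run on downsampled frames.
// All arithmetic is single precision; determinism comes from the caller
// (initial weights and batch orders are drawn from the R random stream).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Geom {
  int C, H, f1, f2, dunits, K;
  bool pool1, pool2;
  int H2, H3, P, P2, P3, flat;
};

Geom make_geom(int C, int H, int f1, int f2, int dunits, int K) {
  Geom g;
  g.C = C; g.H = H; g.f1 = f1; g.f2 = f2; g.dunits = dunits; g.K = K;
  g.pool1 = H >= 8;
  g.H2 = g.pool1 ? H / 2 : H;
  g.pool2 = g.H2 >= 8;
  g.H3 = g.pool2 ? g.H2 / 2 : g.H2;
  g.P = H * H; g.P2 = g.H2 * g.H2; g.P3 = g.H3 * g.H3;
  g.flat = f2 * g.P3;
  return g;
}

struct Params {
  fmat W1, W2, W3, W4;
  frowvec b1, b2;
  fvec b3, b4;
};

// 3x3 'same'-padding im2col: in (P*B) x C -> out (P*B) x (C*9)
void im2col3(const fmat& in, int H, int B, fmat& out) {
  const int C = in.n_cols, P = H * H;
  out.zeros(in.n_rows, C * 9);
  for (int ch = 0; ch < C; ++ch) {
    const float* src = in.colptr(ch);
    for (int kc = -1; kc <= 1; ++kc) {
      for (int kr = -1; kr <= 1; ++kr) {
        float* dst = out.colptr(ch * 9 + (kc + 1) * 3 + (kr + 1));
        const int r0 = std::max(0, -kr), r1 = std::min(H - 1, H - 1 - kr);
        for (int b = 0; b < B; ++b) {
          const int ob = b * P;
          for (int c = 0; c < H; ++c) {
            const int sc = c + kc;
            if (sc < 0 || sc >= H) continue;
            const float* s = src + ob + sc * H + kr;
            float* d = dst + ob + c * H;
            for (int r = r0; r <= r1; ++r) d[r] = s[r];
          }
        }
      }
    }
  }
}

// transpose of im2col3 (scatter-add)
void col2im3(const fmat& dout, int H, int B, fmat& din) {
  const int C = dout.n_cols / 9, P = H * H;
  din.zeros(dout.n_rows, C);
  for (int ch = 0; ch < C; ++ch) {
    float* dst = din.colptr(ch);
    for (int kc = -1; kc <= 1; ++kc) {
      for (int kr = -1; kr <= 1; ++kr) {
        const float* src = dout.colptr(ch * 9 + (kc + 1) * 3 + (kr + 1));
        const int r0 = std::max(0, -kr), r1 = std::min(H - 1, H - 1 - kr);
        for (int b = 0; b < B; ++b) {
          const int ob = b * P;
          for (int c = 0; c < H; ++c) {
            const int sc = c + kc;
            if (sc < 0 || sc >= H) continue;
            float* d = dst + ob + sc * H + kr;
            const float* s = src + ob + c * H;
            for (int r = r0; r <= r1; ++r) d[r] += s[r];
          }
        }
      }
    }
  }
}

// 2x2 stride-2 max pool: in (P*B) x F with side H -> out (P2*B) x F
void maxpool(const fmat& in, int H, int B, fmat& out) {
  const int F = in.n_cols, H2 = H / 2, P = H * H, P2 = H2 * H2;
  out.set_size(P2 * B, F);
  for (int f = 0; f < F; ++f) {
    const float* src = in.colptr(f);
    float* dst = out.colptr(f);
    for (int b = 0; b < B; ++b) {
      const int ib = b * P, ob = b * P2;
      for (int c2 = 0; c2 < H2; ++c2) {
        const float* s0 = src + ib + (2 * c2) * H;
        const float* s1 = s0 + H;
        float* d = dst + ob + c2 * H2;
        for (int r2 = 0; r2 < H2; ++r2) {
          const int r = 2 * r2;
          d[r2] = std::max(std::max(s0[r], s0[r + 1]),
                           std::max(s1[r], s1[r + 1]));
        }
      }
    }
  }
}

// route each pooled gradient to the first window cell matching the max
// (ties resolved identically in every pass: earliest index wins)
void maxpool_back(const fmat& dout, const fmat& in, const fmat& pooled,
                  int H, int B, fmat& din) {
  const int F = in.n_cols, H2 = H / 2, P = H * H, P2 = H2 * H2;
  din.zeros(in.n_rows, F);
  for (int f = 0; f < F; ++f) {
    const float* src = in.colptr(f);
    const float* pv = pooled.colptr(f);
    const float* s = dout.colptr(f);
    float* d = din.colptr(f);
    for (int b = 0; b < B; ++b) {
      const int ib = b * P, ob = b * P2;
      for (int c2 = 0; c2 < H2; ++c2) {
        for (int r2 = 0; r2 < H2; ++r2) {
          const int o = ob + c2 * H2 + r2;
          const int i00 = ib + (2 * c2) * H + 2 * r2;
          const float v = pv[o];
          int at = i00;
          if (src[i00] != v) {
            if (src[i00 + 1] == v) at = i00 + 1;
            else if (src[i00 + H] == v) at = i00 + H;
            else at = i00 + H + 1;
          }
          d[at] += s[o];
        }
      }
    }
  }
}

// fused bias add + ReLU over a gemm output (columns share one bias entry)
inline void bias_relu(fmat& Z, const frowvec& b) {
  for (uword f = 0; f < Z.n_cols; ++f) {
    float* z = Z.colptr(f);
    const float bf = b(f);
    for (uword i = 0; i < Z.n_rows; ++i) {
      const float v = z[i] + bf;
      z[i] = v > 0.0f ? v : 0.0f;
    }
  }
}

// zero gradient entries where the forward activation was clipped at zero
inline void relu_mask(fmat& dZ, const fmat& Z) {
  const float* z = Z.memptr();
  float* d = dZ.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (z[i] == 0.0f) d[i] = 0.0f;
  }
}

struct Cache {
  fmat A1, Z1, P1, A2, Z2, P2m, Fl, A3, probs;
};

// forward pass over a batch X (d x B); fills cache when train=true
void forward(const Params& p, const Geom& g, const fmat& X, Cache& c,
             bool keep) {
  const int B = X.n_cols;
  // conv1 expects (P*B) x C
  fmat in1(g.P * B, g.C);
  for (int b = 0; b < B; ++b) {
    for (int ch = 0; ch < g.C; ++ch) {
      std::memcpy(in1.colptr(ch) + b * g.P, X.colptr(b) + ch * g.P,
                  sizeof(float) * g.P);
    }
  }
  im2col3(in1, g.H, B, c.A1);
  c.Z1 = c.A1 * p.W1;
  bias_relu(c.Z1, p.b1);
  if (g.pool1) maxpool(c.Z1, g.H, B, c.P1); else c.P1 = c.Z1;

  im2col3(c.P1, g.H2, B, c.A2);
  c.Z2 = c.A2 * p.W2;
  bias_relu(c.Z2, p.b2);
  if (g.pool2) maxpool(c.Z2, g.H2, B, c.P2m); else c.P2m = c.Z2;

  c.Fl.set_size(g.flat, B);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < g.f2; ++f) {
      std::memcpy(c.Fl.colptr(b) + f * g.P3, c.P2m.colptr(f) + b * g.P3,
                  sizeof(float) * g.P3);
    }
  }
  c.A3 = p.W3 * c.Fl;
  c.A3.each_col() += p.b3;
  c.A3.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat Z4 = p.W4 * c.A3;
  Z4.each_col() += p.b4;
  // softmax, numerically stable
  Z4.each_row() -= max(Z4, 0);
  c.probs = exp(Z4);
  c.probs.each_row() /= sum(c.probs, 0);
  if (!keep) { c.A1.reset(); c.A2.reset(); }
}

double batch_loss(const fmat& probs, const ivec& y) {
  double L = 0.0;
  for (uword b = 0; b < probs.n_cols; ++b) {
    L -= std::log(std::max(probs(y(b), b), 1e-30f));
  }
  return L / probs.n_cols;
}

void backward(const Params& p, const Geom& g, const ivec& y, Cache& c,
              Params& grad) {
  const int B = c.probs.n_cols;
  fmat dZ4 = c.probs;
  for (int b = 0; b < B; ++b) dZ4(y(b), b) -= 1.0f;
  dZ4 /= (float)B;

  grad.W4 = dZ4 * c.A3.t();
  grad.b4 = sum(dZ4, 1);
  fmat dA3 = p.W4.t() * dZ4;
  relu_mask(dA3, c.A3);
  grad.W3 = dA3 * c.Fl.t();
  grad.b3 = sum(dA3, 1);
  fmat dFl = p.W3.t() * dA3;

  fmat dP2(g.P3 * B, g.f2);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < g.f2; ++f) {
      std::memcpy(dP2.colptr(f) + b * g.P3, dFl.colptr(b) + f * g.P3,
                  sizeof(float) * g.P3);
    }
  }
  fmat dZ2;
  if (g.pool2) maxpool_back(dP2, c.Z2, c.P2m, g.H2, B, dZ2); else dZ2 = dP2;
  relu_mask(dZ2, c.Z2);
  grad.W2 = c.A2.t() * dZ2;
  grad.b2 = sum(dZ2, 0);
  fmat dA2 = dZ2 * p.W2.t();
  fmat dP1;
  col2im3(dA2, g.H2, B, dP1);
  fmat dZ1;
  if (g.pool1) maxpool_back(dP1, c.Z1, c.P1, g.H, B, dZ1); else dZ1 = dP1;
  relu_mask(dZ1, c.Z1);
  grad.W1 = c.A1.t() * dZ1;
  grad.b1 = sum(dZ1, 0);
}

Params params_from_list(const Rcpp::List& w) {
  Params p;
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
  p.W3 = conv_to<fmat>::from(Rcpp::as<mat>(w["W3"]));
  p.W4 = conv_to<fmat>::from(Rcpp::as<mat>(w["W4"]));
  p.b1 = conv_to<frowvec>::from(Rcpp::as<rowvec>(w["b1"]));
  p.b2 = conv_to<frowvec>::from(Rcpp::as<rowvec>(w["b2"]));
  p.b3 = conv_to<fvec>::from(Rcpp::as<vec>(w["b3"]));
  p.b4 = conv_to<fvec>::from(Rcpp::as<vec>(w["b4"]));
  return p;
}

Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(p.W1),
      Rcpp::Named("b1") = conv_to<rowvec>::from(p.b1),
      Rcpp::Named("W2") = conv_to<mat>::from(p.W2),
      Rcpp::Named("b2") = conv_to<rowvec>::from(p.b2),
      Rcpp::Named("W3") = conv_to<mat>::from(p.W3),
      Rcpp::Named("b3") = conv_to<vec>::from(p.b3),
      Rcpp::Named("W4") = conv_to<mat>::from(p.W4),
      Rcpp::Named("b4") = conv_to<vec>::from(p.b4));
}

// evaluate mean loss and accuracy over a set, in chunks
void eval_set(const Params& p, const Geom& g, const fmat& X, const ivec& y,
              double& loss, double& acc) {
  const int n = X.n_cols, chunk = 128;
  double L = 0.0; int correct = 0;
  Cache c;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    fmat Xb = X.cols(s, e - 1);
    forward(p, g, Xb, c, false);
    for (int b = 0; b < e - s; ++b) {
      L -= std::log(std::max(c.probs(y(s + b), b), 1e-30f));
      if ((int)index_max(c.probs.col(b)) == y(s + b)) ++correct;
    }
  }
  loss = L / n;
  acc = (double)correct / n;
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Params& p) {
    m.W1.zeros(size(p.W1)); v.W1.zeros(size(p.W1));
    m.W2.zeros(size(p.W2)); v.W2.zeros(size(p.W2));
    m.W3.zeros(size(p.W3)); v.W3.zeros(size(p.W3));
    m.W4.zeros(size(p.W4)); v.W4.zeros(size(p.W4));
    m.b1.zeros(size(p.b1)); v.b1.zeros(size(p.b1));
    m.b2.zeros(size(p.b2)); v.b2.zeros(size(p.b2));
    m.b3.zeros(size(p.b3)); v.b3.zeros(size(p.b3));
    m.b4.zeros(size(p.b4)); v.b4.zeros(size(p.b4));
  }
  template <class M>
  void upd1(M& w, M& mm, M& vv, const M& gr, double lr) {
    mm = (float)b1 * mm + (float)(1 - b1) * gr;
    vv = (float)b2 * vv + (float)(1 - b2) * square(gr);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    w -= (float)(lr / c1) * (mm / (sqrt(vv / (float)c2) + (float)eps));
  }
  void step(Params& p, const Params& g, double lr) {
    ++t;
    upd1(p.W1, m.W1, v.W1, g.W1, lr); upd1(p.b1, m.b1, v.b1, g.b1, lr);
    upd1(p.W2, m.W2, v.W2, g.W2, lr); upd1(p.b2, m.b2, v.b2, g.b2, lr);
    upd1(p.W3, m.W3, v.W3, g.W3, lr); upd1(p.b3, m.b3, v.b3, g.b3, lr);
    upd1(p.W4, m.W4, v.W4, g.W4, lr); upd1(p.b4, m.b4, v.b4, g.b4, lr);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::ivec& y,
                         const arma::mat& Xval, const arma::ivec& yval,
                         int C, int H, const Rcpp::List& init,
                         double lr, int batch, int max_epochs, int patience,
                         const arma::imat& perms) {
  Params p = params_from_list(init);
  const int f1 = p.W1.n_cols, f2 = p.W2.n_cols;
  const int dunits = p.W3.n_rows, K = p.W4.n_rows;
  Geom g = make_geom(C, H, f1, f2, dunits, K);
  fmat Xf = conv_to<fmat>::from(X);
  fmat Xvf = conv_to<fmat>::from(Xval);
  const int n = Xf.n_cols;
  Adam opt; opt.init(p);
  Params best = p;
  double best_val = datum::inf, best_acc = -1.0;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  std::vector<double> h_tl, h_ta, h_vl, h_va;
  Cache c; Params grad;
  for (int ep = 0; ep < max_epochs; ++ep) {
    epochs_run = ep + 1;
    double ep_loss = 0.0; long ep_correct = 0;
    for (int s = 0; s < n; s += batch) {
      const int e = std::min(n, s + batch);
      const int B = e - s;
      fmat Xb(Xf.n_rows, B);
      ivec yb(B);
      for (int b = 0; b < B; ++b) {
        const int idx = perms(s + b, ep) - 1;  // perms is 1-based from R
        Xb.col(b) = Xf.col(idx);
        yb(b) = y(idx);
      }
      forward(p, g, Xb, c, true);
      ep_loss += batch_loss(c.probs, yb) * B;
      for (int b = 0; b < B; ++b) {
        if ((int)index_max(c.probs.col(b)) == yb(b)) ++ep_correct;
      }
      backward(p, g, yb, c, grad);
      opt.step(p, grad, lr);
    }
    double vl, va;
    eval_set(p, g, Xvf, yval, vl, va);
    h_tl.push_back(ep_loss / n);
    h_ta.push_back((double)ep_correct / n);
    h_vl.push_back(vl);
    h_va.push_back(va);
    // the patience clock runs on validation loss; the returned weights are
    // those of the best validation *accuracy* epoch, since accuracy is the
    // scoring metric of the whole comparison and the cross-entropy can
    // drift upward (over-confident errors) while accuracy still improves
    if (va > best_acc + 1e-9) {
      best_acc = va; best = p; best_epoch = ep + 1;
    }
    if (vl < best_val - 1e-6) {
      best_val = vl; since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_list(best),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq(1, (int)h_tl.size()),
          Rcpp::Named("train_loss") = h_tl, Rcpp::Named("train_acc") = h_ta,
          Rcpp::Named("val_loss") = h_vl, Rcpp::Named("val_acc") = h_va),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = epochs_run);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const Rcpp::List& weights, const arma::mat& X,
                          int C, int H) {
  Params p = params_from_list(weights);
  Geom g = make_geom(C, H, p.W1.n_cols, p.W2.n_cols, p.W3.n_rows,
                     p.W4.n_rows);
  fmat Xf = conv_to<fmat>::from(X);
  const int n = Xf.n_cols, chunk = 128;
  mat probs(p.W4.n_rows, n);
  Cache c;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    fmat Xb = Xf.cols(s, e - 1);
    forward(p, g, Xb, c, false);
    probs.cols(s, e - 1) = conv_to<mat>::from(c.probs);
  }
  return probs;
}

// loss and exact gradients for one batch; used by the finite-difference
// gradient check in the test suite
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(const Rcpp::List& weights, const arma::mat& X,
                             const arma::ivec& y, int C, int H) {
  Params p = params_from_list(weights);
  Geom g = make_geom(C, H, p.W1.n_cols, p.W2.n_cols, p.W3.n_rows,
                     p.W4.n_rows);
  fmat Xf = conv_to<fmat>::from(X);
  Cache c; Params grad;
  forward(p, g, Xf, c, true);
  const double L = batch_loss(c.probs, y);
  backward(p, g, y, c, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = L,
                            Rcpp::Named("grad") = params_to_list(grad));
}
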