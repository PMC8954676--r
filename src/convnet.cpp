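// 3D convolutional scoring network: forward, backprop and ADAM training.
//
// Tensors are laid out channel-major: a (C, D, D, D) volume is a length
// C*D^3 vector with index c + C*(x + D*(y + D*z)); a batch is a matrix with
// one sample per column. Convolutions are im2col + GEMM (Armadillo/BLAS).
// All randomness (init, shuffling) comes from the R side, so results are a
// pure function of the R seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum LayerKind { CONV = 0, POOL = 1, FLATTEN = 2, DENSE = 3 };

struct Layer {
  int kind;
  int k = 0;        // conv kernel / pool size
  int stride = 1;
  int out_ch = 0;   // conv filters or dense units
  bool relu = false;
  // shape bookkeeping (filled by shape pass)
  int Cin = 0, Din = 0, Cout = 0, Dout = 0;
  int in_dim = 0, out_dim = 0;
};

static std::vector<Layer> parse_layers(const List& layers, int Cin, int D) {
  std::vector<Layer> out;
  int C = Cin, d = D;
  bool flat = false;
  int dim = 0;
  for (int li = 0; li < layers.size(); ++li) {
    List sp = layers[li];
    std::string kind = as<std::string>(sp["kind"]);
    Layer L;
    if (kind == "conv3d") {
      L.kind = CONV;
      L.k = as<int>(sp["kernel"]);
      L.stride = sp.containsElementNamed("stride") ? as<int>(sp["stride"]) : 1;
      L.out_ch = as<int>(sp["filters"]);
      L.relu = as<std::string>(sp["activation"]) == "relu";
      if (flat) stop("conv3d after flatten (layer %d)", li + 1);
      if (L.k > d)
        stop("layer %d: kernel %d exceeds input extent %d", li + 1, L.k, d);
      L.Cin = C; L.Din = d;
      L.Cout = L.out_ch;
      L.Dout = (d - L.k) / L.stride + 1;
      L.in_dim = C * d * d * d;
      L.out_dim = L.Cout * L.Dout * L.Dout * L.Dout;
      C = L.Cout; d = L.Dout;
    } else if (kind == "maxpool") {
      L.kind = POOL;
      L.k = sp.containsElementNamed("size") ? as<int>(sp["size"]) : 2;
      if (flat) stop("maxpool after flatten (layer %d)", li + 1);
      if (L.k > d)
        stop("layer %d: pool size %d exceeds input extent %d", li + 1, L.k, d);
      L.Cin = C; L.Din = d; L.Cout = C; L.Dout = d / L.k;
      L.in_dim = C * d * d * d;
      L.out_dim = C * L.Dout * L.Dout * L.Dout;
      d = L.Dout;
    } else if (kind == "flatten") {
      L.kind = FLATTEN;
      L.in_dim = flat ? dim : C * d * d * d;
      L.out_dim = L.in_dim;
      flat = true; dim = L.out_dim;
    } else if (kind == "dense") {
      L.kind = DENSE;
      L.out_ch = as<int>(sp["units"]);
      L.relu = as<std::string>(sp["activation"]) == "relu";
      L.in_dim = flat ? dim : C * d * d * d;
      L.out_dim = L.out_ch;
      flat = true; dim = L.out_dim;
    } else {
      stop("unknown layer kind '%s'", kind.c_str());
    }
    out.push_back(L);
  }
  return out;
}

// im2col for one channel-major sample: rows indexed c + Cin*(dx + k*(dy + k*dz)),
// columns ox + Dout*(oy + Dout*oz).
static void im2col(const double* x, int Cin, int Din, int k, int stride,
                   int Dout, arma::mat& P) {
  const int K = Cin * k * k * k;
  P.set_size(K, Dout * Dout * Dout);
  for (int oz = 0; oz < Dout; ++oz)
    for (int oy = 0; oy < Dout; ++oy)
      for (int ox = 0; ox < Dout; ++ox) {
        double* col = P.colptr(ox + Dout * (oy + Dout * oz));
        int r = 0;
        for (int dz = 0; dz < k; ++dz)
          for (int dy = 0; dy < k; ++dy)
            for (int dx = 0; dx < k; ++dx) {
              const int ix = ox * stride + dx, iy = oy * stride + dy,
                        iz = oz * stride + dz;
              const double* src = x + Cin * (ix + Din * (iy + Din * iz));
              for (int c = 0; c < Cin; ++c) col[r++] = src[c];
            }
      }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& dP, int Cin, int Din, int k, int stride,
                   int Dout, double* dx) {
  for (int oz = 0; oz < Dout; ++oz)
    for (int oy = 0; oy < Dout; ++oy)
      for (int ox = 0; ox < Dout; ++ox) {
        const double* col = dP.colptr(ox + Dout * (oy + Dout * oz));
        int r = 0;
        for (int dz = 0; dz < k; ++dz)
          for (int dy = 0; dy < k; ++dy)
            for (int dx_ = 0; dx_ < k; ++dx_) {
              const int ix = ox * stride + dx_, iy = oy * stride + dy,
                        iz = oz * stride + dz;
              double* dst = dx + Cin * (ix + Din * (iy + Din * iz));
              for (int c = 0; c < Cin; ++c) dst[c] += col[r++];
            }
      }
}

struct Cache {
  arma::mat out;        // post-activation output of the layer
  arma::umat pool_idx;  // argmax linear index (into input sample) per output
};

// Sparse-input convolution for one sample: binary occupancy grids are
// ~2% occupied, so iterating nonzeros beats im2col+GEMM by an order of
// magnitude. Y must be (Cout x No), pre-zeroed.
static void conv_sparse_forward(const double* x, const Layer& ly,
                                const arma::mat& W, arma::mat& Y) {
  const int Cin = ly.Cin, Din = ly.Din, k = ly.k, st = ly.stride,
            Dout = ly.Dout;
  const int n_in = Cin * Din * Din * Din;
  for (int idx = 0; idx < n_in; ++idx) {
    const double v = x[idx];
    if (v == 0.0) continue;
    const int c = idx % Cin;
    int rest = idx / Cin;
    const int ix = rest % Din; rest /= Din;
    const int iy = rest % Din;
    const int iz = rest / Din;
    for (int dz = 0; dz < k; ++dz) {
      const int tz = iz - dz;
      if (tz < 0 || tz % st || tz / st >= Dout) continue;
      const int oz = tz / st;
      for (int dy = 0; dy < k; ++dy) {
        const int ty = iy - dy;
        if (ty < 0 || ty % st || ty / st >= Dout) continue;
        const int oy = ty / st;
        for (int dx = 0; dx < k; ++dx) {
          const int tx = ix - dx;
          if (tx < 0 || tx % st || tx / st >= Dout) continue;
          const int ox = tx / st;
          const int wcol = c + Cin * (dx + k * (dy + k * dz));
          Y.col(ox + Dout * (oy + Dout * oz)) += v * W.col(wcol);
        }
      }
    }
  }
}

// dW accumulation for the sparse path (same window enumeration).
static void conv_sparse_dw(const double* x, const Layer& ly,
                           const arma::mat& dY, arma::mat& dW) {
  const int Cin = ly.Cin, Din = ly.Din, k = ly.k, st = ly.stride,
            Dout = ly.Dout;
  const int n_in = Cin * Din * Din * Din;
  for (int idx = 0; idx < n_in; ++idx) {
    const double v = x[idx];
    if (v == 0.0) continue;
    const int c = idx % Cin;
    int rest = idx / Cin;
    const int ix = rest % Din; rest /= Din;
    const int iy = rest % Din;
    const int iz = rest / Din;
    for (int dz = 0; dz < k; ++dz) {
      const int tz = iz - dz;
      if (tz < 0 || tz % st || tz / st >= Dout) continue;
      const int oz = tz / st;
      for (int dy = 0; dy < k; ++dy) {
        const int ty = iy - dy;
        if (ty < 0 || ty % st || ty / st >= Dout) continue;
        const int oy = ty / st;
        for (int dx = 0; dx < k; ++dx) {
          const int tx = ix - dx;
          if (tx < 0 || tx % st || tx / st >= Dout) continue;
          const int ox = tx / st;
          const int wcol = c + Cin * (dx + k * (dy + k * dz));
          dW.col(wcol) += v * dY.col(ox + Dout * (oy + Dout * oz));
        }
      }
    }
  }
}

// Fraction of nonzero entries in a column.
static double col_density(const double* x, int n) {
  int nnz = 0;
  for (int i = 0; i < n; ++i) nnz += (x[i] != 0.0);
  return (double)nnz / n;
}

// Forward through all layers. X: in_dim x B. Caches filled when train=true.
static arma::mat forward(const std::vector<Layer>& L, const List& params,
                         const arma::mat& X, std::vector<Cache>* caches) {
  arma::mat cur = X;
  const int B = X.n_cols;
  for (size_t li = 0; li < L.size(); ++li) {
    const Layer& ly = L[li];
    arma::mat next;
    Cache cc;
    if (ly.kind == CONV) {
      List pp = params[li];
      arma::mat W = as<arma::mat>(pp["W"]);   // Cout x Cin*k^3
      arma::vec b = as<arma::vec>(pp["b"]);
      next.set_size(ly.out_dim, B);
      arma::mat P;
      const int No = ly.Dout * ly.Dout * ly.Dout;
      for (int s = 0; s < B; ++s) {
        arma::mat Y;
        if (col_density(cur.colptr(s), ly.in_dim) < 0.08) {
          Y.zeros(ly.Cout, No);
          conv_sparse_forward(cur.colptr(s), ly, W, Y);
        } else {
          im2col(cur.colptr(s), ly.Cin, ly.Din, ly.k, ly.stride, ly.Dout, P);
          Y = W * P;                           // Cout x No
        }
        Y.each_col() += b;
        if (ly.relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
        std::memcpy(next.colptr(s), Y.memptr(),
                    sizeof(double) * (size_t)ly.Cout * No);
      }
    } else if (ly.kind == POOL) {
      const int C = ly.Cin, Din = ly.Din, Dp = ly.Dout, k = ly.k;
      next.set_size(ly.out_dim, B);
      if (caches) cc.pool_idx.set_size(ly.out_dim, B);
      for (int s = 0; s < B; ++s) {
        const double* x = cur.colptr(s);
        double* y = next.colptr(s);
        for (int oz = 0; oz < Dp; ++oz)
          for (int oy = 0; oy < Dp; ++oy)
            for (int ox = 0; ox < Dp; ++ox)
              for (int c = 0; c < C; ++c) {
                double best = -std::numeric_limits<double>::infinity();
                int besti = -1;
                for (int dz = 0; dz < k; ++dz)
                  for (int dy = 0; dy < k; ++dy)
                    for (int dx = 0; dx < k; ++dx) {
                      const int idx = c + C * ((ox * k + dx) +
                                      Din * ((oy * k + dy) + Din * (oz * k + dz)));
                      if (x[idx] > best) { best = x[idx]; besti = idx; }
                    }
                const int oidx = c + C * (ox + Dp * (oy + Dp * oz));
                y[oidx] = best;
                if (caches) cc.pool_idx(oidx, s) = besti;
              }
      }
    } else if (ly.kind == FLATTEN) {
      next = cur;  // layout already flat (channel-major vector)
    } else {  // DENSE
      List pp = params[li];
      arma::mat W = as<arma::mat>(pp["W"]);
      arma::vec b = as<arma::vec>(pp["b"]);
      next = W * cur;
      next.each_col() += b;
      if (ly.relu) next.transform([](double v) { return v > 0 ? v : 0.0; });
    }
    if (caches) {
      cc.out = next;
      (*caches)[li] = std::move(cc);
    }
    cur = std::move(next);
  }
  return cur;
}

// Backward pass; fills grads (same shapes as params) and returns nothing.
// dOut: gradient wrt network output (out_dim x B).
static void backward(const std::vector<Layer>& L, const List& params,
                     const arma::mat& X, const std::vector<Cache>& caches,
                     arma::mat dOut, List& grads) {
  const int B = X.n_cols;
  for (int li = (int)L.size() - 1; li >= 0; --li) {
    const Layer& ly = L[li];
    const arma::mat& input = (li == 0) ? X : caches[li - 1].out;
    if (ly.kind == CONV) {
      List pp = params[li];
      arma::mat W = as<arma::mat>(pp["W"]);
      const arma::mat& out = caches[li].out;
      if (ly.relu) dOut %= arma::conv_to<arma::mat>::from(out > 0);
      const int No = ly.Dout * ly.Dout * ly.Dout;
      arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
      arma::vec db(ly.Cout, arma::fill::zeros);
      const bool need_dx = li > 0;  // no consumer of the input gradient
      arma::mat dX;
      if (need_dx) dX.zeros(ly.in_dim, B);
      arma::mat P;
      for (int s = 0; s < B; ++s) {
        arma::mat dY(const_cast<double*>(dOut.colptr(s)), ly.Cout, No, false, true);
        db += arma::sum(dY, 1);
        if (!need_dx && col_density(input.colptr(s), ly.in_dim) < 0.08) {
          conv_sparse_dw(input.colptr(s), ly, dY, dW);
        } else {
          im2col(input.colptr(s), ly.Cin, ly.Din, ly.k, ly.stride, ly.Dout, P);
          dW += dY * P.t();
          if (need_dx) {
            arma::mat dP = W.t() * dY;        // K x No
            col2im(dP, ly.Cin, ly.Din, ly.k, ly.stride, ly.Dout, dX.colptr(s));
          }
        }
      }
      List g = grads[li];
      g["W"] = dW; g["b"] = db;
      grads[li] = g;
      dOut = std::move(dX);
    } else if (ly.kind == POOL) {
      arma::mat dX(ly.in_dim, B, arma::fill::zeros);
      const arma::umat& idx = caches[li].pool_idx;
      for (int s = 0; s < B; ++s)
        for (int o = 0; o < ly.out_dim; ++o)
          dX(idx(o, s), s) += dOut(o, s);
      dOut = std::move(dX);
    } else if (ly.kind == FLATTEN) {
      // identity
    } else {  // DENSE
      List pp = params[li];
      arma::mat W = as<arma::mat>(pp["W"]);
      const arma::mat& out = caches[li].out;
      if (ly.relu) dOut %= arma::conv_to<arma::mat>::from(out > 0);
      List g = grads[li];
      g["W"] = arma::mat(dOut * input.t());
      g["b"] = arma::vec(arma::sum(dOut, 1));
      grads[li] = g;
      dOut = W.t() * dOut;
    }
  }
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(List layers, List params, arma::mat X, int Cin, int D) {
  std::vector<Layer> L = parse_layers(layers, Cin, D);
  if ((int)X.n_rows != Cin * D * D * D)
    stop("input rows (%d) do not match Cin*D^3 (%d)", (int)X.n_rows,
         Cin * D * D * D);
  return forward(L, params, X, nullptr);
}

// [[Rcpp::export]]
List cnn_shapes_cpp(List layers, int Cin, int D) {
  std::vector<Layer> L = parse_layers(layers, Cin, D);
  IntegerVector in_dim(L.size()), out_dim(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    in_dim[i] = L[i].in_dim; out_dim[i] = L[i].out_dim;
  }
  return List::create(_["in_dim"] = in_dim, _["out_dim"] = out_dim);
}

// Mini-batch ADAM training with MSE loss. `order` is an epochs x N matrix of
// 1-based sample permutations drawn on the R side.
// [[Rcpp::export]]
List cnn_train_cpp(List layers, List params, arma::mat X, arma::vec y,
                   int Cin, int D, int epochs, int batch_size, double lr,
                   IntegerMatrix order, double beta1 = 0.9,
                   double beta2 = 0.999, double eps = 1e-8,
                   double weight_decay = 0.0, double avg_decay = 0.0) {
  std::vector<Layer> L = parse_layers(layers, Cin, D);
  const int N = X.n_cols;
  if ((int)y.n_elem != N) stop("label count mismatch");

  // deep-copy params so the caller's object is untouched; A holds an
  // exponential moving average of the parameters when avg_decay > 0
  List P(params.size()), M(params.size()), V(params.size()), G(params.size()),
       A(params.size());
  for (int i = 0; i < params.size(); ++i) {
    if (L[i].kind == CONV || L[i].kind == DENSE) {
      List pp = params[i];
      arma::mat W = as<arma::mat>(pp["W"]);
      arma::vec b = as<arma::vec>(pp["b"]);
      P[i] = List::create(_["W"] = W, _["b"] = b);
      M[i] = List::create(_["W"] = arma::mat(W.n_rows, W.n_cols, arma::fill::zeros),
                          _["b"] = arma::vec(b.n_elem, arma::fill::zeros));
      V[i] = List::create(_["W"] = arma::mat(W.n_rows, W.n_cols, arma::fill::zeros),
                          _["b"] = arma::vec(b.n_elem, arma::fill::zeros));
      G[i] = List::create(_["W"] = R_NilValue, _["b"] = R_NilValue);
      A[i] = List::create(_["W"] = W, _["b"] = b);
    } else {
      P[i] = List::create(); M[i] = List::create(); V[i] = List::create();
      G[i] = List::create(_["W"] = R_NilValue, _["b"] = R_NilValue);
      A[i] = List::create();
    }
  }

  NumericVector history(epochs);
  long t = 0;
  std::vector<Cache> caches(L.size());
  for (int ep = 0; ep < epochs; ++ep) {
    double sse = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      const int bs = std::min(batch_size, N - start);
      arma::mat Xb(X.n_rows, bs);
      arma::vec yb(bs);
      for (int j = 0; j < bs; ++j) {
        const int src = order(ep, start + j) - 1;
        Xb.col(j) = X.col(src);
        yb(j) = y(src);
      }
      arma::mat pred = forward(L, P, Xb, &caches);
      arma::rowvec diff = pred.row(0) - yb.t();
      const double batch_sse = arma::accu(arma::square(diff));
      if (!std::isfinite(batch_sse))
        stop("NaN/Inf training loss at epoch %d; try a smaller learning rate",
             ep + 1);
      sse += batch_sse;
      arma::mat dOut(1, bs);
      dOut.row(0) = (2.0 / bs) * diff;
      backward(L, P, Xb, caches, dOut, G);
      t += 1;
      const double bc = lr * std::sqrt(1.0 - std::pow(beta2, (double)t)) /
                        (1.0 - std::pow(beta1, (double)t));
      for (size_t i = 0; i < L.size(); ++i) {
        if (L[i].kind != CONV && L[i].kind != DENSE) continue;
        List pp = P[i], mm = M[i], vv = V[i], gg = G[i];
        arma::mat W = as<arma::mat>(pp["W"]), gW = as<arma::mat>(gg["W"]),
                  mW = as<arma::mat>(mm["W"]), vW = as<arma::mat>(vv["W"]);
        arma::vec b = as<arma::vec>(pp["b"]), gb = as<arma::vec>(gg["b"]),
                  mb = as<arma::vec>(mm["b"]), vb = as<arma::vec>(vv["b"]);
        mW = beta1 * mW + (1 - beta1) * gW;
        vW = beta2 * vW + (1 - beta2) * arma::square(gW);
        // decoupled (AdamW-style) weight decay; biases are not decayed
        if (weight_decay > 0) W *= (1.0 - lr * weight_decay);
        W -= bc * mW / (arma::sqrt(vW) + eps);
        mb = beta1 * mb + (1 - beta1) * gb;
        vb = beta2 * vb + (1 - beta2) * arma::square(gb);
        b -= bc * mb / (arma::sqrt(vb) + eps);
        pp["W"] = W; pp["b"] = b; mm["W"] = mW; mm["b"] = mb;
        vv["W"] = vW; vv["b"] = vb;
        P[i] = pp; M[i] = mm; V[i] = vv;
        if (avg_decay > 0) {
          List aa = A[i];
          arma::mat aW = as<arma::mat>(aa["W"]);
          arma::vec ab = as<arma::vec>(aa["b"]);
          aW = avg_decay * aW + (1 - avg_decay) * W;
          ab = avg_decay * ab + (1 - avg_decay) * b;
          aa["W"] = aW; aa["b"] = ab;
          A[i] = aa;
        }
      }
    }
    history[ep] = sse / N;
  }
  return List::create(_["params"] = P, _["history"] = history,
                      _["avg_params"] = avg_decay > 0 ? A : P);
}
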