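// Minimal trainable CNN engine: conv (grouped), batch norm, local response
// norm, leaky/plain ReLU, max pooling, fully-connected, dropout, with
// softmax cross-entropy and YOLOv2-style multi-part detection losses,
// optimised by SGD with momentum.  Activations are stored one column per
// sample, flattened in R array order (h + H*w + H*W*c).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Shape { int h, w, c; int size() const { return h * w * c; } };

struct Layer {
  std::string type;
  // conv / pool
  int out_c = 0, k = 0, stride = 1, pad = 0, groups = 1, pad_extra = 0;
  // lrelu slope, lrn params, dropout prob
  double alpha = 0.01, beta = 0.75, kconst = 2.0;
  int window = 5;
  double p = 0.5;
  int fc_out = 0;
  Shape in, out;
};

std::vector<Layer> parse_spec(const List& spec) {
  std::vector<Layer> layers;
  Shape cur{0, 0, 0};
  for (int i = 0; i < spec.size(); ++i) {
    List ls = spec[i];
    Layer L;
    L.type = as<std::string>(ls["type"]);
    if (L.type == "input") {
      cur.h = as<int>(ls["h"]); cur.w = as<int>(ls["w"]); cur.c = as<int>(ls["c"]);
      continue;
    }
    L.in = cur;
    if (L.type == "conv") {
      L.out_c = as<int>(ls["out_c"]); L.k = as<int>(ls["k"]);
      L.stride = as<int>(ls["stride"]); L.pad = as<int>(ls["pad"]);
      L.groups = ls.containsElementNamed("groups") ? as<int>(ls["groups"]) : 1;
      L.out.h = (cur.h + 2 * L.pad - L.k) / L.stride + 1;
      L.out.w = (cur.w + 2 * L.pad - L.k) / L.stride + 1;
      L.out.c = L.out_c;
    } else if (L.type == "maxpool") {
      L.k = as<int>(ls["k"]); L.stride = as<int>(ls["stride"]);
      L.pad = ls.containsElementNamed("pad") ? as<int>(ls["pad"]) : 0;
      L.pad_extra = ls.containsElementNamed("pad_extra") ? as<int>(ls["pad_extra"]) : 0;
      L.out.h = (cur.h + 2 * L.pad + L.pad_extra - L.k) / L.stride + 1;
      L.out.w = (cur.w + 2 * L.pad + L.pad_extra - L.k) / L.stride + 1;
      L.out.c = cur.c;
    } else if (L.type == "bn" || L.type == "relu") {
      L.out = cur;
    } else if (L.type == "lrelu") {
      L.alpha = ls.containsElementNamed("alpha") ? as<double>(ls["alpha"]) : 0.1;
      L.out = cur;
    } else if (L.type == "lrn") {
      if (ls.containsElementNamed("window")) L.window = as<int>(ls["window"]);
      if (ls.containsElementNamed("alpha")) L.alpha = as<double>(ls["alpha"]);
      if (ls.containsElementNamed("beta")) L.beta = as<double>(ls["beta"]);
      if (ls.containsElementNamed("k")) L.kconst = as<double>(ls["k"]);
      L.out = cur;
    } else if (L.type == "dropout") {
      L.p = as<double>(ls["p"]);
      L.out = cur;
    } else if (L.type == "fc") {
      L.fc_out = as<int>(ls["out"]);
      L.out.h = 1; L.out.w = 1; L.out.c = L.fc_out;
    } else {
      stop("unknown layer type: " + L.type);
    }
    cur = L.out;
    layers.push_back(L);
  }
  return layers;
}

// per-sample im2col transpose: rows = out pixels (oh + Hout*ow), cols = K
void im2col_t(const double* x, const Layer& L, int g, mat& Pt) {
  const int Hin = L.in.h, Win = L.in.w;
  const int Hout = L.out.h, Wout = L.out.w;
  const int cin_g = L.in.c / L.groups;
  for (int cg = 0; cg < cin_g; ++cg) {
    const int c = g * cin_g + cg;
    const double* xc = x + (size_t)c * Hin * Win;
    for (int kx = 0; kx < L.k; ++kx) {
      for (int ky = 0; ky < L.k; ++ky) {
        const int col = cg * L.k * L.k + kx * L.k + ky;
        double* pcol = Pt.colptr(col);
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow * L.stride - L.pad + kx;
          if (iw < 0 || iw >= Win) {
            for (int oh = 0; oh < Hout; ++oh) pcol[oh + Hout * ow] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)iw * Hin;
          for (int oh = 0; oh < Hout; ++oh) {
            const int ih = oh * L.stride - L.pad + ky;
            pcol[oh + Hout * ow] = (ih >= 0 && ih < Hin) ? xcol[ih] : 0.0;
          }
        }
      }
    }
  }
}

void col2im_t(const mat& dPt, const Layer& L, int g, double* dx) {
  const int Hin = L.in.h, Win = L.in.w;
  const int Hout = L.out.h, Wout = L.out.w;
  const int cin_g = L.in.c / L.groups;
  for (int cg = 0; cg < cin_g; ++cg) {
    const int c = g * cin_g + cg;
    double* xc = dx + (size_t)c * Hin * Win;
    for (int kx = 0; kx < L.k; ++kx) {
      for (int ky = 0; ky < L.k; ++ky) {
        const int col = cg * L.k * L.k + kx * L.k + ky;
        const double* pcol = dPt.colptr(col);
        for (int ow = 0; ow < Wout; ++ow) {
          const int iw = ow * L.stride - L.pad + kx;
          if (iw < 0 || iw >= Win) continue;
          double* xcol = xc + (size_t)iw * Hin;
          for (int oh = 0; oh < Hout; ++oh) {
            const int ih = oh * L.stride - L.pad + ky;
            if (ih >= 0 && ih < Hin) xcol[ih] += pcol[oh + Hout * ow];
          }
        }
      }
    }
  }
}

struct Cache {
  arma::Mat<arma::uword> pool_idx;  // flat input index of the max, per output
  mat bn_xhat;
  vec bn_invstd;
  mat mask;            // dropout
  std::vector<mat> lrn_s;  // scale per channel slice (HW x B)
};

struct FwdState {
  std::vector<mat> act;      // act[0] = input, act[l+1] = output of layer l
  std::vector<Cache> cache;
};

void forward(const std::vector<Layer>& layers, const List& params, const mat& X,
             bool training, std::mt19937_64& rng, FwdState& st,
             List* running_update = nullptr) {
  const int B = X.n_cols;
  st.act.assign(layers.size() + 1, mat());
  st.cache.assign(layers.size(), Cache());
  st.act[0] = X;
  for (size_t li = 0; li < layers.size(); ++li) {
    const Layer& L = layers[li];
    const mat& A = st.act[li];
    mat& O = st.act[li + 1];
    Cache& C = st.cache[li];
    if (L.type == "conv") {
      List pl = params[li];
      mat W = as<mat>(pl["W"]);
      vec b = as<vec>(pl["b"]);
      const int Hout = L.out.h, Wout = L.out.w, HW = Hout * Wout;
      const int cout_g = L.out_c / L.groups;
      const int K = (L.in.c / L.groups) * L.k * L.k;
      O.set_size((size_t)HW * L.out_c, B);
      mat Pt(HW, K);
      for (int s = 0; s < B; ++s) {
        for (int g = 0; g < L.groups; ++g) {
          im2col_t(A.colptr(s), L, g, Pt);
          mat Og = Pt * W.rows(g * cout_g, (g + 1) * cout_g - 1).t();  // HW x cout_g
          for (int oc = 0; oc < cout_g; ++oc) {
            const int c = g * cout_g + oc;
            std::memcpy(O.colptr(s) + (size_t)c * HW, Og.colptr(oc),
                        sizeof(double) * HW);
            double* dst = O.colptr(s) + (size_t)c * HW;
            const double bb = b[c];
            for (int i = 0; i < HW; ++i) dst[i] += bb;
          }
        }
      }
    } else if (L.type == "bn") {
      List pl = params[li];
      vec gamma = as<vec>(pl["gamma"]), betav = as<vec>(pl["beta"]);
      const int HW = L.in.h * L.in.w;
      O.set_size(A.n_rows, B);
      C.bn_xhat.set_size(A.n_rows, B);
      C.bn_invstd.set_size(L.in.c);
      vec rm = as<vec>(pl["running_mean"]), rv = as<vec>(pl["running_var"]);
      const double eps = 1e-5;
      for (int c = 0; c < L.in.c; ++c) {
        auto rows_in = A.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1);
        double m, v;
        if (training) {
          m = arma::accu(rows_in) / ((double)HW * B);
          v = arma::accu(arma::square(rows_in - m)) / ((double)HW * B);
          rm[c] = 0.9 * rm[c] + 0.1 * m;
          rv[c] = 0.9 * rv[c] + 0.1 * v;
        } else {
          m = rm[c]; v = rv[c];
        }
        const double inv = 1.0 / std::sqrt(v + eps);
        C.bn_invstd[c] = inv;
        mat xhat = (rows_in - m) * inv;
        C.bn_xhat.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1) = xhat;
        O.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1) =
            gamma[c] * xhat + betav[c];
      }
      if (training && running_update) {
        List pl2 = (*running_update)[li];
        pl2["running_mean"] = NumericVector(rm.begin(), rm.end());
        pl2["running_var"] = NumericVector(rv.begin(), rv.end());
      }
    } else if (L.type == "relu") {
      O = arma::clamp(A, 0.0, arma::datum::inf);
    } else if (L.type == "lrelu") {
      O = A;
      O.transform([&](double x) { return x > 0 ? x : L.alpha * x; });
    } else if (L.type == "lrn") {
      const int HW = L.in.h * L.in.w, Cc = L.in.c, half = L.window / 2;
      O.set_size(A.n_rows, B);
      C.lrn_s.assign(Cc, mat());
      std::vector<mat> sq(Cc);
      for (int c = 0; c < Cc; ++c)
        sq[c] = arma::square(A.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1));
      for (int c = 0; c < Cc; ++c) {
        mat ss(HW, B, arma::fill::zeros);
        for (int j = std::max(0, c - half); j <= std::min(Cc - 1, c + half); ++j)
          ss += sq[j];
        mat s = L.kconst + (L.alpha / L.window) * ss;
        C.lrn_s[c] = s;
        O.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1) =
            A.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1) % arma::pow(s, -L.beta);
      }
    } else if (L.type == "maxpool") {
      const int Hin = L.in.h, Win = L.in.w;
      const int Hout = L.out.h, Wout = L.out.w;
      O.set_size((size_t)Hout * Wout * L.in.c, B);
      C.pool_idx.set_size((size_t)Hout * Wout * L.in.c, B);
      for (int s = 0; s < B; ++s) {
        const double* x = A.colptr(s);
        double* o = O.colptr(s);
        arma::uword* pi = C.pool_idx.colptr(s);
        for (int c = 0; c < L.in.c; ++c) {
          const double* xc = x + (size_t)c * Hin * Win;
          for (int ow = 0; ow < Wout; ++ow) {
            for (int oh = 0; oh < Hout; ++oh) {
              double best = -arma::datum::inf;
              arma::uword bidx = 0;
              for (int kx = 0; kx < L.k; ++kx) {
                const int iw = ow * L.stride - L.pad + kx;
                if (iw < 0 || iw >= Win) continue;
                for (int ky = 0; ky < L.k; ++ky) {
                  const int ih = oh * L.stride - L.pad + ky;
                  if (ih < 0 || ih >= Hin) continue;
                  const double v = xc[ih + (size_t)iw * Hin];
                  if (v > best) { best = v; bidx = (size_t)c * Hin * Win + ih + (size_t)iw * Hin; }
                }
              }
              const size_t oidx = (size_t)c * Hout * Wout + oh + (size_t)ow * Hout;
              o[oidx] = best;
              pi[oidx] = bidx;
            }
          }
        }
      }
    } else if (L.type == "fc") {
      List pl = params[li];
      mat W = as<mat>(pl["W"]);
      vec b = as<vec>(pl["b"]);
      O = W * A;
      O.each_col() += b;
    } else if (L.type == "dropout") {
      if (training && L.p > 0) {
        std::bernoulli_distribution keep(1.0 - L.p);
        C.mask.set_size(A.n_rows, B);
        for (uword j = 0; j < C.mask.n_cols; ++j)
          for (uword i = 0; i < C.mask.n_rows; ++i)
            C.mask(i, j) = keep(rng) ? 1.0 / (1.0 - L.p) : 0.0;
        O = A % C.mask;
      } else {
        O = A;
      }
    }
  }
}

// grads: per-layer List with same shapes as params; dX propagated backwards.
void backward(const std::vector<Layer>& layers, const List& params,
              const FwdState& st, mat& dOut, std::vector<List>& grads,
              bool training) {
  grads.assign(layers.size(), List());
  for (int li = (int)layers.size() - 1; li >= 0; --li) {
    const Layer& L = layers[li];
    const mat& A = st.act[li];
    const Cache& C = st.cache[li];
    const int B = A.n_cols;
    mat dIn;
    if (L.type == "conv") {
      List pl = params[li];
      mat W = as<mat>(pl["W"]);
      const int Hout = L.out.h, Wout = L.out.w, HW = Hout * Wout;
      const int cout_g = L.out_c / L.groups;
      const int K = (L.in.c / L.groups) * L.k * L.k;
      mat dW(arma::size(W), arma::fill::zeros);
      vec db(L.out_c, arma::fill::zeros);
      dIn.zeros(A.n_rows, B);
      mat Pt(HW, K), dOg(HW, cout_g);
      for (int s = 0; s < B; ++s) {
        for (int g = 0; g < L.groups; ++g) {
          im2col_t(A.colptr(s), L, g, Pt);
          for (int oc = 0; oc < cout_g; ++oc) {
            const int c = g * cout_g + oc;
            std::memcpy(dOg.colptr(oc), dOut.colptr(s) + (size_t)c * HW,
                        sizeof(double) * HW);
            db[c] += arma::accu(dOg.col(oc));
          }
          mat Wg = W.rows(g * cout_g, (g + 1) * cout_g - 1);
          dW.rows(g * cout_g, (g + 1) * cout_g - 1) += dOg.t() * Pt;
          mat dPt = dOg * Wg;  // HW x K
          col2im_t(dPt, L, g, dIn.colptr(s));
        }
      }
      grads[li] = List::create(Named("W") = dW, Named("b") = db);
    } else if (L.type == "bn") {
      List pl = params[li];
      vec gamma = as<vec>(pl["gamma"]);
      const int HW = L.in.h * L.in.w;
      vec dgamma(L.in.c), dbeta(L.in.c);
      dIn.set_size(A.n_rows, B);
      const double N = (double)HW * B;
      for (int c = 0; c < L.in.c; ++c) {
        auto rr = arma::span((size_t)c * HW, (size_t)(c + 1) * HW - 1);
        mat dy = dOut.rows(rr.a, rr.b);
        mat xh = C.bn_xhat.rows(rr.a, rr.b);
        const double dg = arma::accu(dy % xh);
        const double dbv = arma::accu(dy);
        dgamma[c] = dg; dbeta[c] = dbv;
        if (training) {
          dIn.rows(rr.a, rr.b) =
              (gamma[c] * C.bn_invstd[c] / N) * (N * dy - dbv - xh * dg);
        } else {
          dIn.rows(rr.a, rr.b) = gamma[c] * C.bn_invstd[c] * dy;
        }
      }
      grads[li] = List::create(Named("gamma") = dgamma, Named("beta") = dbeta);
    } else if (L.type == "relu") {
      dIn = dOut % arma::conv_to<mat>::from(A > 0);
    } else if (L.type == "lrelu") {
      dIn = dOut;
      for (uword i = 0; i < A.n_elem; ++i)
        if (A[i] <= 0) dIn[i] *= L.alpha;
    } else if (L.type == "lrn") {
      const int HW = L.in.h * L.in.w, Cc = L.in.c, half = L.window / 2;
      std::vector<mat> t(Cc);
      for (int c = 0; c < Cc; ++c) {
        auto rr = arma::span((size_t)c * HW, (size_t)(c + 1) * HW - 1);
        t[c] = dOut.rows(rr.a, rr.b) % A.rows(rr.a, rr.b) %
               arma::pow(C.lrn_s[c], -L.beta - 1.0);
      }
      dIn.set_size(A.n_rows, B);
      for (int j = 0; j < Cc; ++j) {
        auto rr = arma::span((size_t)j * HW, (size_t)(j + 1) * HW - 1);
        mat acc(HW, B, arma::fill::zeros);
        for (int i = std::max(0, j - half); i <= std::min(Cc - 1, j + half); ++i)
          acc += t[i];
        dIn.rows(rr.a, rr.b) =
            dOut.rows(rr.a, rr.b) % arma::pow(C.lrn_s[j], -L.beta) -
            (2.0 * L.alpha * L.beta / L.window) * A.rows(rr.a, rr.b) % acc;
      }
    } else if (L.type == "maxpool") {
      dIn.zeros(A.n_rows, B);
      for (int s = 0; s < B; ++s) {
        const arma::uword* pi = C.pool_idx.colptr(s);
        const double* dy = dOut.colptr(s);
        double* dx = dIn.colptr(s);
        const size_t n = (size_t)L.out.h * L.out.w * L.in.c;
        for (size_t i = 0; i < n; ++i) dx[pi[i]] += dy[i];
      }
    } else if (L.type == "fc") {
      List pl = params[li];
      mat W = as<mat>(pl["W"]);
      mat dW = dOut * A.t();
      vec db = arma::sum(dOut, 1);
      dIn = W.t() * dOut;
      grads[li] = List::create(Named("W") = dW, Named("b") = db);
    } else if (L.type == "dropout") {
      dIn = (C.mask.n_elem > 0) ? mat(dOut % C.mask) : dOut;
    }
    dOut = dIn;
  }
}

List init_params(const std::vector<Layer>& layers, int seed) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  List params(layers.size());
  for (size_t li = 0; li < layers.size(); ++li) {
    const Layer& L = layers[li];
    if (L.type == "conv") {
      const int K = (L.in.c / L.groups) * L.k * L.k;
      mat W(L.out_c, K);
      const double sd = std::sqrt(2.0 / K);
      for (uword i = 0; i < W.n_elem; ++i) W[i] = sd * nd(rng);
      params[li] = List::create(Named("W") = W,
                                Named("b") = vec(L.out_c, arma::fill::zeros));
    } else if (L.type == "fc") {
      const int K = L.in.size();
      mat W(L.fc_out, K);
      const double sd = std::sqrt(2.0 / K);
      for (uword i = 0; i < W.n_elem; ++i) W[i] = sd * nd(rng);
      params[li] = List::create(Named("W") = W,
                                Named("b") = vec(L.fc_out, arma::fill::zeros));
    } else if (L.type == "bn") {
      params[li] = List::create(
          Named("gamma") = vec(L.in.c, arma::fill::ones),
          Named("beta") = vec(L.in.c, arma::fill::zeros),
          Named("running_mean") = vec(L.in.c, arma::fill::zeros),
          Named("running_var") = vec(L.in.c, arma::fill::ones));
    } else {
      params[li] = List::create();
    }
  }
  return params;
}

double softmax_loss_grad(const mat& logits, const arma::uvec& y, mat& dlogits,
                         double* acc_out) {
  const int B = logits.n_cols;
  mat P = logits;
  P.each_row() -= arma::max(P, 0);
  P = arma::exp(P);
  P.each_row() /= arma::sum(P, 0);
  double loss = 0.0;
  int correct = 0;
  dlogits = P;
  for (int s = 0; s < B; ++s) {
    loss += -std::log(std::max(P(y[s], s), 1e-12));
    dlogits(y[s], s) -= 1.0;
    if (P.col(s).index_max() == y[s]) ++correct;
  }
  dlogits /= B;
  if (acc_out) *acc_out = (double)correct / B;
  return loss / B;
}

inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// YOLOv2-style loss on the final S x S x (A*(5+C)) map.
// gt: per-sample matrix n x 7 (ci, cj, a, tx, ty, tw, th), 0-based cells;
// boxes: n x 4 (cx, cy, w, h) in grid units for the no-object IoU exemption.
double yolo_loss_grad(const mat& out, const Shape& sh, const List& gt_list,
                      const List& box_list, const mat& anchors, int n_class,
                      mat& dOut) {
  const int B = out.n_cols;
  const int S = sh.h;
  const int A = anchors.n_rows;
  const int F = 5 + n_class;
  const int HW = S * S;
  const double lc = 5.0, ln = 0.5;
  dOut.zeros(arma::size(out));
  double loss = 0.0;
  for (int s = 0; s < B; ++s) {
    const double* o = out.colptr(s);
    double* d = dOut.colptr(s);
    mat gt = as<mat>(gt_list[s]);
    mat gb = as<mat>(box_list[s]);
    // map (ci, cj, a) -> gt row
    std::vector<int> assign((size_t)HW * A, -1);
    for (uword r = 0; r < gt.n_rows; ++r) {
      const int ci = (int)gt(r, 0), cj = (int)gt(r, 1), a = (int)gt(r, 2);
      assign[(size_t)a * HW + ci + S * cj] = (int)r;
    }
    for (int a = 0; a < A; ++a) {
      for (int cj = 0; cj < S; ++cj) {
        for (int ci = 0; ci < S; ++ci) {
          const size_t pix = ci + (size_t)S * cj;
          const size_t base = (size_t)(a * F) * HW + pix;
          const double tx = o[base], ty = o[base + HW], tw = o[base + 2 * HW],
                       th = o[base + 3 * HW], to = o[base + 4 * HW];
          const double sx = sigm(tx), sy = sigm(ty), conf = sigm(to);
          const int r = assign[(size_t)a * HW + pix];
          if (r >= 0) {
            const double txs = gt(r, 3), tys = gt(r, 4), tws = gt(r, 5),
                         ths = gt(r, 6);
            loss += lc * ((sx - txs) * (sx - txs) + (sy - tys) * (sy - tys) +
                          (tw - tws) * (tw - tws) + (th - ths) * (th - ths));
            loss += (conf - 1.0) * (conf - 1.0);
            d[base] += lc * 2.0 * (sx - txs) * sx * (1 - sx);
            d[base + HW] += lc * 2.0 * (sy - tys) * sy * (1 - sy);
            d[base + 2 * HW] += lc * 2.0 * (tw - tws);
            d[base + 3 * HW] += lc * 2.0 * (th - ths);
            d[base + 4 * HW] += 2.0 * (conf - 1.0) * conf * (1 - conf);
            if (n_class > 1) {
              // softmax CE over class channels; class id in col 7 (optional)
              // single-class pipeline never reaches this branch
            }
          } else {
            // skip penalty when the predicted box overlaps any truth well
            double best_iou = 0.0;
            if (gb.n_rows > 0) {
              const double bx = cj + sx, by = ci + sy;
              const double bw = anchors(a, 0) * std::exp(tw);
              const double bh = anchors(a, 1) * std::exp(th);
              for (uword r2 = 0; r2 < gb.n_rows; ++r2) {
                const double ix = std::max(0.0, std::min(bx + bw / 2, gb(r2, 0) + gb(r2, 2) / 2) -
                                                std::max(bx - bw / 2, gb(r2, 0) - gb(r2, 2) / 2));
                const double iy = std::max(0.0, std::min(by + bh / 2, gb(r2, 1) + gb(r2, 3) / 2) -
                                                std::max(by - bh / 2, gb(r2, 1) - gb(r2, 3) / 2));
                const double inter = ix * iy;
                const double uni = bw * bh + gb(r2, 2) * gb(r2, 3) - inter;
                if (uni > 0) best_iou = std::max(best_iou, inter / uni);
              }
            }
            if (best_iou < 0.6) {
              loss += ln * conf * conf;
              d[base + 4 * HW] += ln * 2.0 * conf * conf * (1 - conf);
            }
          }
        }
      }
    }
  }
  dOut /= B;
  return loss / B;
}

void sgdm_step(const std::vector<Layer>& layers, List& params, List& vel,
               const std::vector<List>& grads, double lr, double momentum) {
  for (size_t li = 0; li < layers.size(); ++li) {
    if (grads[li].size() == 0) continue;
    List pl = params[li], vl = vel[li], gl = grads[li];
    CharacterVector nm = gl.names();
    for (int k = 0; k < gl.size(); ++k) {
      std::string name = as<std::string>(nm[k]);
      NumericVector p = pl[name], v = vl[name], g = gl[name];
      for (int i = 0; i < p.size(); ++i) {
        v[i] = momentum * v[i] - lr * g[i];
        p[i] += v[i];
      }
    }
  }
}

List make_velocity(const List& params) {
  List vel(params.size());
  for (int li = 0; li < params.size(); ++li) {
    List pl = params[li];
    List vl(pl.size());
    if (pl.size() > 0) {
      CharacterVector nm = pl.names();
      vl.names() = nm;
      for (int k = 0; k < pl.size(); ++k) {
        NumericVector p = pl[k];
        vl[k] = NumericVector(p.size());
      }
    }
    vel[li] = vl;
  }
  return vel;
}

}  // namespace

// [[Rcpp::export]]
List cpp_nn_init(List spec, int seed) {
  auto layers = parse_spec(spec);
  return init_params(layers, seed);
}

// [[Rcpp::export]]
List cpp_nn_shapes(List spec) {
  auto layers = parse_spec(spec);
  IntegerMatrix sh(layers.size(), 3);
  for (size_t i = 0; i < layers.size(); ++i) {
    sh(i, 0) = layers[i].out.h; sh(i, 1) = layers[i].out.w; sh(i, 2) = layers[i].out.c;
  }
  return List::create(Named("shapes") = sh);
}

// [[Rcpp::export]]
arma::mat cpp_nn_forward(List spec, List params, arma::mat X) {
  auto layers = parse_spec(spec);
  std::mt19937_64 rng(0);
  FwdState st;
  forward(layers, params, X, false, rng, st);
  return st.act.back();
}

// [[Rcpp::export]]
List cpp_nn_loss_grad_softmax(List spec, List params, arma::mat X,
                              IntegerVector y, bool training) {
  auto layers = parse_spec(spec);
  std::mt19937_64 rng(1);
  FwdState st;
  forward(layers, params, X, training, rng, st);
  arma::uvec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i] - 1;
  mat dlog;
  double acc;
  double loss = softmax_loss_grad(st.act.back(), yy, dlog, &acc);
  std::vector<List> grads;
  backward(layers, params, st, dlog, grads, training);
  return List::create(Named("loss") = loss, Named("acc") = acc,
                      Named("grads") = wrap(grads));
}

// [[Rcpp::export]]
List cpp_nn_loss_grad_yolo(List spec, List params, arma::mat X, List gt_list,
                           List box_list, arma::mat anchors, int n_class,
                           bool training) {
  auto layers = parse_spec(spec);
  std::mt19937_64 rng(1);
  FwdState st;
  forward(layers, params, X, training, rng, st);
  Shape sh{layers.back().out.h, layers.back().out.w, layers.back().out.c};
  mat dOut;
  double loss = yolo_loss_grad(st.act.back(), sh, gt_list, box_list, anchors,
                               n_class, dOut);
  std::vector<List> grads;
  backward(layers, params, st, dOut, grads, training);
  return List::create(Named("loss") = loss, Named("grads") = wrap(grads));
}

// [[Rcpp::export]]
List cpp_nn_train_softmax(List spec, List params, arma::mat X, IntegerVector y,
                          arma::mat Xval, IntegerVector yval, int epochs,
                          int batch, NumericVector lr_per_epoch, double momentum,
                          int seed) {
  params = clone(params);
  auto layers = parse_spec(spec);
  std::mt19937_64 rng(seed);
  List vel = make_velocity(params);
  const int N = X.n_cols;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  arma::uvec yy(y.size());
  for (int i = 0; i < y.size(); ++i) yy[i] = y[i] - 1;
  const int nbatch = N / batch;
  NumericMatrix hist(epochs, 5);  // lr, train_loss, train_acc, val_loss, val_acc
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    const double lr = lr_per_epoch[e];
    double eloss = 0.0, eacc = 0.0;
    for (int bi = 0; bi < nbatch; ++bi) {
      arma::uvec cols(batch), yb(batch);
      for (int k = 0; k < batch; ++k) {
        cols[k] = idx[bi * batch + k];
        yb[k] = yy[cols[k]];
      }
      mat Xb = X.cols(cols);
      FwdState st;
      forward(layers, params, Xb, true, rng, st, &params);
      mat dlog;
      double acc;
      double loss = softmax_loss_grad(st.act.back(), yb, dlog, &acc);
      std::vector<List> grads;
      backward(layers, params, st, dlog, grads, true);
      sgdm_step(layers, params, vel, grads, lr, momentum);
      eloss += loss; eacc += acc;
      Rcpp::checkUserInterrupt();
    }
    hist(e, 0) = lr;
    hist(e, 1) = eloss / std::max(1, nbatch);
    hist(e, 2) = eacc / std::max(1, nbatch);
    if (Xval.n_cols > 0) {
      FwdState st;
      forward(layers, params, Xval, false, rng, st);
      arma::uvec yv(yval.size());
      for (int i = 0; i < yval.size(); ++i) yv[i] = yval[i] - 1;
      mat dd;
      double vacc;
      hist(e, 3) = softmax_loss_grad(st.act.back(), yv, dd, &vacc);
      hist(e, 4) = vacc;
    } else {
      hist(e, 3) = NA_REAL; hist(e, 4) = NA_REAL;
    }
  }
  return List::create(Named("params") = params, Named("history") = hist);
}

// [[Rcpp::export]]
List cpp_nn_train_yolo(List spec, List params, arma::mat X, List gt_list,
                       List box_list, arma::mat anchors, int n_class,
                       int epochs, int batch, double lr, double momentum,
                       int seed) {
  params = clone(params);
  auto layers = parse_spec(spec);
  std::mt19937_64 rng(seed);
  List vel = make_velocity(params);
  const int N = X.n_cols;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  const int nbatch = N / batch;
  std::vector<double> trace;
  trace.reserve((size_t)nbatch * epochs);
  Shape sh{layers.back().out.h, layers.back().out.w, layers.back().out.c};
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int bi = 0; bi < nbatch; ++bi) {
      arma::uvec cols(batch);
      List gtb(batch), gbb(batch);
      for (int k = 0; k < batch; ++k) {
        cols[k] = idx[bi * batch + k];
        gtb[k] = gt_list[cols[k]];
        gbb[k] = box_list[cols[k]];
      }
      mat Xb = X.cols(cols);
      FwdState st;
      forward(layers, params, Xb, true, rng, st, &params);
      mat dOut;
      double loss = yolo_loss_grad(st.act.back(), sh, gtb, gbb, anchors,
                                   n_class, dOut);
      std::vector<List> grads;
      backward(layers, params, st, dOut, grads, true);
      sgdm_step(layers, params, vel, grads, lr, momentum);
      trace.push_back(loss);
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(Named("params") = params, Named("loss_trace") = wrap(trace));
}

// [[Rcpp::export]]
arma::mat cpp_resize_bilinear(arma::mat img, int out_h, int out_w) {
  const int H = img.n_rows, W = img.n_cols;
  mat out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double x = (j + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(x);
    double fx = x - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(x0 + 1, W - 1);
    for (int i = 0; i < out_h; ++i) {
      double yy = (i + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(yy);
      double fy = yy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(y0 + 1, H - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0c, x0c) + fx * img(y0c, x1c)) +
                  fy * ((1 - fx) * img(y1c, x0c) + fx * img(y1c, x1c));
    }
  }
  return out;
}
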