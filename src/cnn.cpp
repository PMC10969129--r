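// Compact CNN used as the desk-scale binary image classifier: a stack of
// 3x3 same-padding conv blocks (ReLU + 2x2 max pool), global average
// pooling and a 2-unit softmax head, trained with Adagrad on categorical
// cross-entropy. All randomness (shuffling) comes from a caller-supplied
// seed through a private mt19937 stream so training is reproducible.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::uvec;
using arma::vec;

namespace {

struct Arch {
  int H, W, C;                 // input dims
  std::vector<int> filters;    // conv filters per block
  int k;                       // kernel size (odd)
  double gain;                 // fixed logit gain (softmax temperature^-1)
};

Arch parse_arch(const List& arch) {
  Arch a;
  IntegerVector in = arch["input_size"];
  a.H = in[0]; a.W = in[1]; a.C = in[2];
  IntegerVector f = arch["conv_filters"];
  a.filters = std::vector<int>(f.begin(), f.end());
  a.k = as<int>(arch["kernel"]);
  a.gain = arch.containsElementNamed("logit_gain")
               ? as<double>(arch["logit_gain"]) : 1.0;
  return a;
}

// Weight container mirrored from the R list: conv Wm are (k*k*Cin) x Cout
// (column-major flattening di fastest, then dj, then channel — identical to
// an R array dim c(k, k, Cin, Cout)); dense is Cf x 2.
struct Weights {
  std::vector<mat> Wm;
  std::vector<vec> b;
  mat Wd;
  vec bd;
};

Weights parse_weights(const List& w, const Arch& a) {
  Weights out;
  List conv = w["conv"];
  int cin = a.C;
  for (int l = 0; l < (int)conv.size(); ++l) {
    List layer = conv[l];
    NumericVector Wv = layer["W"];
    int cout_l = a.filters[l];
    mat Wm(Wv.begin(), a.k * a.k * cin, cout_l);  // copies
    out.Wm.push_back(Wm);
    NumericVector bv = layer["b"];
    out.b.push_back(vec(bv.begin(), bv.size()));
    cin = cout_l;
  }
  List dense = w["dense"];
  NumericMatrix Wdv = dense["W"];
  out.Wd = mat(Wdv.begin(), Wdv.nrow(), Wdv.ncol());
  NumericVector bdv = dense["b"];
  out.bd = vec(bdv.begin(), bdv.size());
  return out;
}

List weights_to_list(const Weights& w, const Arch& a) {
  List conv(w.Wm.size());
  int cin = a.C;
  for (size_t l = 0; l < w.Wm.size(); ++l) {
    NumericVector Wv(w.Wm[l].begin(), w.Wm[l].end());
    Wv.attr("dim") = IntegerVector::create(a.k, a.k, cin, a.filters[l]);
    NumericVector bv(w.b[l].begin(), w.b[l].end());
    conv[l] = List::create(_["W"] = Wv, _["b"] = bv);
    cin = a.filters[l];
  }
  NumericMatrix Wd(w.Wd.n_rows, w.Wd.n_cols);
  std::copy(w.Wd.begin(), w.Wd.end(), Wd.begin());
  NumericVector bd(w.bd.begin(), w.bd.end());
  return List::create(_["conv"] = conv,
                      _["dense"] = List::create(_["W"] = Wd, _["b"] = bd));
}

// im2col for same-padding conv: row per pixel (column-major i + H*j),
// column per (di, dj, c) with di fastest.
mat im2col(const cube& A, int k) {
  int H = A.n_rows, W = A.n_cols, C = A.n_slices, pad = (k - 1) / 2;
  mat P(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
          for (int i = i0; i < i1; ++i)
            P(i + H * j, col) = S(i + di - pad, sj);
        }
      }
    }
  }
  return P;
}

void col2im_add(cube& dA, const mat& dP, int k) {
  int H = dA.n_rows, W = dA.n_cols, C = dA.n_slices, pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat& S = dA.slice(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        int col = di + k * dj + k * k * c;
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          int i0 = std::max(0, pad - di), i1 = std::min(H, H + pad - di);
          for (int i = i0; i < i1; ++i)
            S(i + di - pad, sj) += dP(i + H * j, col);
        }
      }
    }
  }
}

mat cube_to_mat(const cube& A) {  // (H*W) x C view copy
  mat M(A.n_rows * A.n_cols, A.n_slices);
  for (arma::uword c = 0; c < A.n_slices; ++c)
    M.col(c) = arma::vectorise(A.slice(c));
  return M;
}

cube mat_to_cube(const mat& M, int H, int W) {
  cube A(H, W, M.n_cols);
  for (arma::uword c = 0; c < M.n_cols; ++c)
    A.slice(c) = arma::reshape(M.col(c), H, W);
  return A;
}

struct BlockCache {
  mat P;        // im2col of the block input
  mat Zr;       // post-ReLU activation, (H*W) x Cout
  arma::umat idx;  // argmax linear index (into pre-pool map) per pooled cell
  int H, W;     // pre-pool dims
};

// One conv block forward; A is replaced by the pooled output.
void block_forward(cube& A, const mat& Wm, const vec& b, int k,
                   BlockCache* cache) {
  int H = A.n_rows, W = A.n_cols;
  mat P = im2col(A, k);
  mat Z = P * Wm;
  Z.each_row() += b.t();
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
  int Cout = Z.n_cols, Hp = H / 2, Wp = W / 2;
  cube Ap(Hp, Wp, Cout);
  arma::umat idx(Hp * Wp, Cout);
  for (int c = 0; c < Cout; ++c) {
    for (int j = 0; j < Wp; ++j) {
      for (int i = 0; i < Hp; ++i) {
        int base_i = 2 * i, base_j = 2 * j;
        double best = -1.0; arma::uword bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            arma::uword lin = (base_i + di) + (arma::uword)H * (base_j + dj);
            double v = Z(lin, c);
            if (v > best) { best = v; bidx = lin; }
          }
        Ap(i, j, c) = best;
        idx(i + Hp * j, c) = bidx;
      }
    }
  }
  if (cache) {
    cache->P = std::move(P);
    cache->Zr = std::move(Z);
    cache->idx = std::move(idx);
    cache->H = H; cache->W = W;
  }
  A = std::move(Ap);
}

vec softmax2(const vec& z) {
  double m = z.max();
  vec e = arma::exp(z - m);
  return e / arma::accu(e);
}

struct ForwardOut {
  vec probs;            // length 2
  vec gap;              // Cf
  std::vector<BlockCache> caches;
  int Hp, Wp;           // pooled dims of last block
};

ForwardOut forward_one(const cube& x, const Weights& w, const Arch& a,
                       bool keep_cache) {
  ForwardOut out;
  cube A = x;
  out.caches.resize(keep_cache ? w.Wm.size() : 0);
  for (size_t l = 0; l < w.Wm.size(); ++l)
    block_forward(A, w.Wm[l], w.b[l], a.k,
                  keep_cache ? &out.caches[l] : nullptr);
  out.Hp = A.n_rows; out.Wp = A.n_cols;
  out.gap = vec(A.n_slices);
  for (arma::uword c = 0; c < A.n_slices; ++c)
    out.gap(c) = arma::accu(A.slice(c)) / (A.n_rows * A.n_cols);
  vec logits = a.gain * (w.Wd.t() * out.gap + w.bd);
  out.probs = softmax2(logits);
  return out;
}

// Backprop from dlogits through the whole net, accumulating into grads.
void backward_one(const ForwardOut& f, const vec& dlogits, const Weights& w,
                  const Arch& a, Weights& g, cube* dInput = nullptr) {
  g.Wd += f.gap * dlogits.t();
  g.bd += dlogits;
  vec dgap = w.Wd * dlogits;
  int nb = (int)w.Wm.size();
  // gradient wrt pooled output of last block
  int Hp = f.Hp, Wp = f.Wp;
  mat dpool(Hp * Wp, dgap.n_elem);
  for (arma::uword c = 0; c < dgap.n_elem; ++c)
    dpool.col(c).fill(dgap(c) / (Hp * Wp));
  for (int l = nb - 1; l >= 0; --l) {
    const BlockCache& cc = f.caches[l];
    int H = cc.H, W = cc.W;
    mat dZ(H * W, cc.Zr.n_cols, arma::fill::zeros);
    for (arma::uword c = 0; c < cc.Zr.n_cols; ++c)
      for (arma::uword p = 0; p < cc.idx.n_rows; ++p)
        dZ(cc.idx(p, c), c) += dpool(p, c);
    // ReLU mask
    dZ %= arma::conv_to<mat>::from(cc.Zr > 0.0);
    g.Wm[l] += cc.P.t() * dZ;
    g.b[l] += arma::sum(dZ, 0).t();
    mat dP = dZ * w.Wm[l].t();
    int Cin = (l == 0) ? a.C : a.filters[l - 1];
    cube dA(H, W, Cin, arma::fill::zeros);
    col2im_add(dA, dP, a.k);
    if (l == 0) {
      if (dInput) *dInput = dA;
    } else {
      dpool = cube_to_mat(dA);
    }
  }
}

Weights zeros_like(const Weights& w) {
  Weights g;
  for (size_t l = 0; l < w.Wm.size(); ++l) {
    g.Wm.push_back(mat(w.Wm[l].n_rows, w.Wm[l].n_cols, arma::fill::zeros));
    g.b.push_back(vec(w.b[l].n_elem, arma::fill::zeros));
  }
  g.Wd = mat(w.Wd.n_rows, w.Wd.n_cols, arma::fill::zeros);
  g.bd = vec(w.bd.n_elem, arma::fill::zeros);
  return g;
}

cube as_cube(SEXP s) {
  NumericVector v(s);
  IntegerVector d = v.attr("dim");
  cube A(v.begin(), d[0], d[1], d[2]);  // copies
  return A;
}

mat bilinear_upsample(const mat& M, int H, int W) {
  int h = M.n_rows, w = M.n_cols;
  mat out(H, W);
  // align-corners-free mapping (pixel centers), standard bilinear
  for (int j = 0; j < W; ++j) {
    double sy = (w == 1) ? 0.0 : ((j + 0.5) * w / W - 0.5);
    int j0 = (int)std::floor(sy);
    double fy = sy - j0;
    int ja = std::min(std::max(j0, 0), w - 1);
    int jb = std::min(std::max(j0 + 1, 0), w - 1);
    for (int i = 0; i < H; ++i) {
      double sx = (h == 1) ? 0.0 : ((i + 0.5) * h / H - 0.5);
      int i0 = (int)std::floor(sx);
      double fx = sx - i0;
      int ia = std::min(std::max(i0, 0), h - 1);
      int ib = std::min(std::max(i0 + 1, 0), h - 1);
      out(i, j) = (1 - fx) * (1 - fy) * M(ia, ja) + fx * (1 - fy) * M(ib, ja)
                + (1 - fx) * fy * M(ia, jb) + fx * fy * M(ib, jb);
    }
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cnn_forward_cpp(List weights, List X, List arch) {
  Arch a = parse_arch(arch);
  Weights w = parse_weights(weights, a);
  int n = X.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    cube x = as_cube(X[i]);
    ForwardOut f = forward_one(x, w, a, false);
    out(i, 0) = f.probs(0);
    out(i, 1) = f.probs(1);
  }
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, List X, IntegerVector y, List arch,
                   int epochs, int batch_size, double lr, int seed) {
  Arch a = parse_arch(arch);
  Weights w = parse_weights(weights, a);
  int n = X.size();
  std::vector<cube> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as_cube(X[i]);

  Weights G = zeros_like(w);  // Adagrad accumulators (fresh per call)
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const double eps = 1e-8;
  NumericVector ep_loss(epochs), ep_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with our own stream (std::shuffle is stdlib-dependent)
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> U(0, i);
      std::swap(order[i], order[U(rng)]);
    }
    double tot_loss = 0.0; int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(n, start + batch_size);
      int bs = stop - start;
      Weights g = zeros_like(w);
      for (int bi = start; bi < stop; ++bi) {
        int i = order[bi];
        ForwardOut f = forward_one(xs[i], w, a, true);
        int cls = y[i];
        double p = std::max(f.probs(cls), 1e-12);
        tot_loss += -std::log(p);
        if ((f.probs(1) > 0.5 ? 1 : 0) == cls) ++correct;
        vec dlogits = f.probs;
        dlogits(cls) -= 1.0;   // softmax + CE gradient
        dlogits *= a.gain;     // chain through the fixed logit gain
        backward_one(f, dlogits, w, a, g);
      }
      // mean gradient over the batch, Adagrad step
      double inv = 1.0 / bs;
      for (size_t l = 0; l < w.Wm.size(); ++l) {
        mat gw = g.Wm[l] * inv;
        G.Wm[l] += arma::square(gw);
        w.Wm[l] -= lr * gw / arma::sqrt(G.Wm[l] + eps);
        vec gb = g.b[l] * inv;
        G.b[l] += arma::square(gb);
        w.b[l] -= lr * gb / arma::sqrt(G.b[l] + eps);
      }
      mat gd = g.Wd * inv;
      G.Wd += arma::square(gd);
      w.Wd -= lr * gd / arma::sqrt(G.Wd + eps);
      vec gbd = g.bd * inv;
      G.bd += arma::square(gbd);
      w.bd -= lr * gbd / arma::sqrt(G.bd + eps);
    }
    ep_loss[ep] = tot_loss / n;
    ep_acc[ep] = (double)correct / n;
  }
  return List::create(_["weights"] = weights_to_list(w, a),
                      _["loss"] = ep_loss, _["accuracy"] = ep_acc);
}

// Grad-CAM on the last conv block's post-ReLU map (pre-pool): channel
// weights are the spatially averaged gradients of the target logit; the
// map is the ReLU'd weighted sum, bilinearly upsampled to input size.
// target_class is 0-based; -1 means the predicted class.
// [[Rcpp::export]]
NumericMatrix cnn_gradcam_cpp(List weights, NumericVector x, List arch,
                              int target_class) {
  Arch a = parse_arch(arch);
  Weights w = parse_weights(weights, a);
  cube xc = as_cube(x);
  ForwardOut f = forward_one(xc, w, a, true);
  int cls = target_class >= 0 ? target_class
                              : (f.probs(1) > f.probs(0) ? 1 : 0);
  // gradient of the raw logit (not the softmax output) wrt the last block
  vec dlogits(2, arma::fill::zeros);
  dlogits(cls) = a.gain;  // raw-logit gradient includes the fixed gain
  vec dgap = w.Wd * dlogits;
  int nb = (int)w.Wm.size();
  const BlockCache& cc = f.caches[nb - 1];
  int Hp = f.Hp, Wp = f.Wp, Cf = a.filters[nb - 1];
  // route dgap through GAP and the max-pool mask back to the conv map
  mat dZ(cc.H * cc.W, Cf, arma::fill::zeros);
  for (int c = 0; c < Cf; ++c) {
    double v = dgap(c) / (Hp * Wp);
    for (arma::uword p = 0; p < cc.idx.n_rows; ++p)
      dZ(cc.idx(p, c), c) += v;
  }
  // dZ is the gradient wrt the post-ReLU map itself (max-pool routing
  // only); the ReLU mask belongs one step further back and is not part of
  // the Grad-CAM channel weights.
  mat cam(cc.H, cc.W, arma::fill::zeros);
  for (int c = 0; c < Cf; ++c) {
    double alpha = arma::mean(dZ.col(c));
    cam += alpha * arma::reshape(cc.Zr.col(c), cc.H, cc.W);
  }
  cam.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat up = bilinear_upsample(cam, a.H, a.W);
  up.transform([](double v) { return v > 0.0 ? v : 0.0; });
  double mx = up.max();
  if (mx > 0) up /= mx;
  NumericMatrix out(a.H, a.W);
  std::copy(up.begin(), up.end(), out.begin());
  return out;
}
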