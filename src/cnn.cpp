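// Minimal convolutional network engine: conv (im2col + GEMM), ReLU,
// max-pooling, dense, inverted dropout, softmax cross-entropy head,
// SGD with momentum. Backpropagation is verified in the test suite by a
// finite-difference gradient check.
//
// Data layout: a batch is a (H*W*C) x n matrix; each column is one image
// flattened column-major over (h, w, c), matching R's as.vector() on an
// array of dim c(H, W, C).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

enum LType { CONV = 0, RELU, POOL, FLATTEN, DENSE, DROPOUT };

struct LayerSpec {
  LType type;
  int out = 0, k = 0, stride = 1, pad = 0;
  double rate = 0.0;
  int Hi = 0, Wi = 0, Ci = 0, Ho = 0, Wo = 0, Co = 0;
  int p = -1;  // index into the parameter list, or -1
};

struct Net {
  int H0, W0, C0;
  std::vector<LayerSpec> ls;
  int nparams = 0;
};

struct Params {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

Net parse_spec(List spec) {
  Net net;
  net.H0 = as<int>(spec["inputSize"]);
  net.W0 = net.H0;
  net.C0 = as<int>(spec["channels"]);
  List layers = spec["layers"];
  int H = net.H0, W = net.W0, C = net.C0;
  bool flat = false;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    std::string t = as<std::string>(l["type"]);
    LayerSpec s;
    s.Hi = H; s.Wi = W; s.Ci = C;
    if (t == "conv") {
      s.type = CONV;
      s.out = as<int>(l["filters"]);
      s.k = as<int>(l["kernel"]);
      s.stride = l.containsElementNamed("stride") ? as<int>(l["stride"]) : 1;
      s.pad = l.containsElementNamed("pad") ? as<int>(l["pad"]) : 0;
      s.Ho = (H + 2 * s.pad - s.k) / s.stride + 1;
      s.Wo = (W + 2 * s.pad - s.k) / s.stride + 1;
      s.Co = s.out;
      if (s.Ho < 1 || s.Wo < 1) stop("convolution output size < 1");
      s.p = net.nparams++;
      H = s.Ho; W = s.Wo; C = s.Co;
    } else if (t == "relu") {
      s.type = RELU; s.Ho = H; s.Wo = W; s.Co = C;
    } else if (t == "pool") {
      s.type = POOL;
      s.k = as<int>(l["size"]);
      s.stride = l.containsElementNamed("stride") ? as<int>(l["stride"]) : s.k;
      s.Ho = (H - s.k) / s.stride + 1;
      s.Wo = (W - s.k) / s.stride + 1;
      s.Co = C;
      if (s.Ho < 1 || s.Wo < 1) stop("pooling output size < 1");
      H = s.Ho; W = s.Wo;
    } else if (t == "flatten") {
      s.type = FLATTEN;
      s.Ho = H * W * C; s.Wo = 1; s.Co = 1;
      H = s.Ho; W = 1; C = 1;
      flat = true;
    } else if (t == "dense") {
      if (!flat && (W != 1 || C != 1)) stop("dense layer before flatten");
      s.type = DENSE;
      s.out = as<int>(l["units"]);
      s.Ho = s.out; s.Wo = 1; s.Co = 1;
      s.p = net.nparams++;
      H = s.out; W = 1; C = 1;
    } else if (t == "dropout") {
      s.type = DROPOUT;
      s.rate = as<double>(l["rate"]);
      s.Ho = H; s.Wo = W; s.Co = C;
    } else {
      stop("unknown layer type: %s", t.c_str());
    }
    net.ls.push_back(s);
  }
  return net;
}

Params params_from_list(List pl) {
  Params p;
  for (int i = 0; i < pl.size(); ++i) {
    List e = pl[i];
    p.W.push_back(as<arma::mat>(e["W"]));
    p.b.push_back(as<arma::vec>(e["b"]));
  }
  return p;
}

List params_to_list(const Params& p) {
  List out(p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i)
    out[i] = List::create(_["W"] = p.W[i], _["b"] = p.b[i]);
  return out;
}

void im2col(const double* x, int H, int W, int C, int k, int stride, int pad,
            int Ho, int Wo, arma::mat& cols) {
  cols.set_size(k * k * C, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = cols.colptr(ho + Ho * wo);
      for (int ci = 0; ci < C; ++ci) {
        for (int kw = 0; kw < k; ++kw) {
          int w = wo * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h = ho * stride - pad + kh;
            dst[kh + k * kw + k * k * ci] =
                (h >= 0 && h < H && w >= 0 && w < W) ? x[h + H * (w + W * ci)]
                                                     : 0.0;
          }
        }
      }
    }
  }
}

void col2im(const arma::mat& cols, int H, int W, int C, int k, int stride,
            int pad, int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = cols.colptr(ho + Ho * wo);
      for (int ci = 0; ci < C; ++ci) {
        for (int kw = 0; kw < k; ++kw) {
          int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            dx[h + H * (w + W * ci)] += src[kh + k * kw + k * k * ci];
          }
        }
      }
    }
  }
}

struct Cache {
  std::vector<arma::mat> act;                  // act[0] = input
  std::vector<std::vector<arma::mat>> cols;    // per conv layer, per image
  std::vector<arma::umat> poolidx;             // per pool layer
  std::vector<arma::mat> dmask;                // per dropout layer
};

// forward pass; if cc != nullptr caches are stored for backprop
arma::mat forward(const Net& net, const Params& P, const arma::mat& X,
                  bool training, std::mt19937* rng, Cache* cc) {
  const arma::uword n = X.n_cols;
  arma::mat cur = X;
  if (cc) {
    cc->act.assign(net.ls.size() + 1, arma::mat());
    cc->cols.assign(net.ls.size(), {});
    cc->poolidx.assign(net.ls.size(), arma::umat());
    cc->dmask.assign(net.ls.size(), arma::mat());
    cc->act[0] = cur;
  }
  for (size_t i = 0; i < net.ls.size(); ++i) {
    const LayerSpec& s = net.ls[i];
    if (s.type == CONV) {
      arma::mat out(s.Ho * s.Wo * s.Co, n);
      arma::mat cols;
      if (cc) cc->cols[i].resize(n);
      for (arma::uword im = 0; im < n; ++im) {
        im2col(cur.colptr(im), s.Hi, s.Wi, s.Ci, s.k, s.stride, s.pad, s.Ho,
               s.Wo, cols);
        arma::mat O = cols.t() * P.W[s.p];        // (HoWo) x Co
        O.each_row() += P.b[s.p].t();
        out.col(im) = arma::vectorise(O);
        if (cc) cc->cols[i][im] = cols;
      }
      cur = std::move(out);
    } else if (s.type == RELU) {
      cur = arma::clamp(cur, 0.0, arma::datum::inf);
    } else if (s.type == POOL) {
      const int Hi = s.Hi, Wi = s.Wi, C = s.Ci, k = s.k, st = s.stride;
      const int Ho = s.Ho, Wo = s.Wo;
      arma::mat out(Ho * Wo * C, n);
      arma::umat idx;
      if (cc) idx.set_size(Ho * Wo * C, n);
      for (arma::uword im = 0; im < n; ++im) {
        const double* x = cur.colptr(im);
        double* o = out.colptr(im);
        for (int ci = 0; ci < C; ++ci) {
          for (int wo = 0; wo < Wo; ++wo) {
            for (int ho = 0; ho < Ho; ++ho) {
              double best = -arma::datum::inf;
              int bidx = 0;
              for (int kw = 0; kw < k; ++kw) {
                int w = wo * st + kw;
                for (int kh = 0; kh < k; ++kh) {
                  int h = ho * st + kh;
                  int ii = h + Hi * (w + Wi * ci);
                  if (x[ii] > best) { best = x[ii]; bidx = ii; }
                }
              }
              int oi = ho + Ho * (wo + Wo * ci);
              o[oi] = best;
              if (cc) idx(oi, im) = (arma::uword)bidx;
            }
          }
        }
      }
      if (cc) cc->poolidx[i] = std::move(idx);
      cur = std::move(out);
    } else if (s.type == FLATTEN) {
      // layout is already flat column-major; nothing to do
    } else if (s.type == DENSE) {
      arma::mat out = P.W[s.p].t() * cur;       // out x n
      out.each_col() += P.b[s.p];
      cur = std::move(out);
    } else if (s.type == DROPOUT) {
      if (training && s.rate > 0.0) {
        double keep = 1.0 - s.rate;
        arma::mat mask(cur.n_rows, cur.n_cols);
        std::uniform_real_distribution<double> U(0.0, 1.0);
        for (arma::uword jj = 0; jj < mask.n_elem; ++jj)
          mask[jj] = (U(*rng) < keep) ? 1.0 / keep : 0.0;
        cur %= mask;
        if (cc) cc->dmask[i] = std::move(mask);
      } else if (cc) {
        cc->dmask[i] = arma::mat();   // identity in eval mode
      }
    }
    if (cc) cc->act[i + 1] = cur;
  }
  return cur;  // logits (numClasses x n)
}

// softmax probabilities column-wise
arma::mat softmax(const arma::mat& Z) {
  arma::mat P = Z;
  P.each_row() -= arma::max(Z, 0);
  P = arma::exp(P);
  P.each_row() /= arma::sum(P, 0);
  return P;
}

void backward(const Net& net, const Params& P, const Cache& cc,
              const arma::mat& dZ, Params& G) {
  arma::mat delta = dZ;
  for (int i = (int)net.ls.size() - 1; i >= 0; --i) {
    const LayerSpec& s = net.ls[i];
    const arma::mat& ain = cc.act[i];
    if (s.type == CONV) {
      const arma::uword n = delta.n_cols;
      arma::mat dW(P.W[s.p].n_rows, P.W[s.p].n_cols, arma::fill::zeros);
      arma::vec db(P.b[s.p].n_elem, arma::fill::zeros);
      arma::mat dprev(ain.n_rows, n, arma::fill::zeros);
      const int HoWo = s.Ho * s.Wo;
      for (arma::uword im = 0; im < n; ++im) {
        arma::mat dO(const_cast<double*>(delta.colptr(im)), HoWo, s.Co, false,
                     true);
        dW += cc.cols[i][im] * dO;
        db += arma::sum(dO, 0).t();
        arma::mat dcols = P.W[s.p] * dO.t();   // (k*k*Ci) x HoWo
        col2im(dcols, s.Hi, s.Wi, s.Ci, s.k, s.stride, s.pad, s.Ho, s.Wo,
               dprev.colptr(im));
      }
      G.W[s.p] = dW;
      G.b[s.p] = db;
      delta = std::move(dprev);
    } else if (s.type == RELU) {
      delta %= arma::conv_to<arma::mat>::from(cc.act[i + 1] > 0.0);
    } else if (s.type == POOL) {
      arma::mat dprev(ain.n_rows, delta.n_cols, arma::fill::zeros);
      const arma::umat& idx = cc.poolidx[i];
      for (arma::uword im = 0; im < delta.n_cols; ++im)
        for (arma::uword oi = 0; oi < idx.n_rows; ++oi)
          dprev(idx(oi, im), im) += delta(oi, im);
      delta = std::move(dprev);
    } else if (s.type == FLATTEN) {
      // no-op
    } else if (s.type == DENSE) {
      G.W[s.p] = ain * delta.t();
      G.b[s.p] = arma::sum(delta, 1);
      delta = P.W[s.p] * delta;
    } else if (s.type == DROPOUT) {
      if (cc.dmask[i].n_elem > 0) delta %= cc.dmask[i];
    }
  }
}

double ce_loss(const arma::mat& probs, const arma::ivec& y) {
  double s = 0.0;
  for (arma::uword j = 0; j < probs.n_cols; ++j)
    s -= std::log(std::max(probs(y[j], j), 1e-12));
  return s / probs.n_cols;
}

int count_correct(const arma::mat& probs, const arma::ivec& y) {
  int c = 0;
  for (arma::uword j = 0; j < probs.n_cols; ++j) {
    arma::uword am = arma::index_max(probs.col(j));
    if ((int)am == y[j]) ++c;
  }
  return c;
}

// chunked eval-mode forward (memory-bounded)
arma::mat predict_probs(const Net& net, const Params& P, const arma::mat& X) {
  const arma::uword n = X.n_cols, chunk = 128;
  arma::mat out;
  for (arma::uword s = 0; s < n; s += chunk) {
    arma::uword e = std::min(n, s + chunk) - 1;
    arma::mat Z = forward(net, P, X.cols(s, e), false, nullptr, nullptr);
    arma::mat Pr = softmax(Z);
    if (out.n_elem == 0) out.set_size(Pr.n_rows, n);
    out.cols(s, e) = Pr;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_cnn_init")]]
List cpp_cnn_init(List spec, int seed) {
  Net net = parse_spec(spec);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> N(0.0, 1.0);
  Params P;
  for (const LayerSpec& s : net.ls) {
    if (s.type == CONV) {
      int fan_in = s.k * s.k * s.Ci;
      arma::mat W(fan_in, s.out);
      double sd = std::sqrt(2.0 / fan_in);
      for (arma::uword j = 0; j < W.n_elem; ++j) W[j] = sd * N(rng);
      P.W.push_back(W);
      P.b.push_back(arma::vec(s.out, arma::fill::zeros));
    } else if (s.type == DENSE) {
      int fan_in = s.Hi;
      arma::mat W(fan_in, s.out);
      double sd = std::sqrt(2.0 / fan_in);
      for (arma::uword j = 0; j < W.n_elem; ++j) W[j] = sd * N(rng);
      P.W.push_back(W);
      P.b.push_back(arma::vec(s.out, arma::fill::zeros));
    }
  }
  return params_to_list(P);
}

// [[Rcpp::export(name = ".cpp_cnn_train")]]
List cpp_cnn_train(List spec, List params, const arma::mat& X,
                   const arma::ivec& y, const arma::mat& Xval,
                   const arma::ivec& yval, int epochs, int batch_size,
                   double lr, double momentum, int seed) {
  Net net = parse_spec(spec);
  Params P = params_from_list(params);
  Params V;  // momentum velocities
  for (size_t i = 0; i < P.W.size(); ++i) {
    V.W.push_back(arma::mat(P.W[i].n_rows, P.W[i].n_cols, arma::fill::zeros));
    V.b.push_back(arma::vec(P.b[i].n_elem, arma::fill::zeros));
  }
  std::mt19937 rng((unsigned)seed);
  const arma::uword n = X.n_cols;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  arma::mat hist(epochs, 4);
  hist.fill(arma::datum::nan);
  const bool has_val = Xval.n_cols > 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int correct = 0;
    for (arma::uword s = 0; s < n; s += (arma::uword)batch_size) {
      arma::uword e = std::min(n, s + (arma::uword)batch_size);
      arma::uvec bidx(e - s);
      arma::ivec by(e - s);
      for (arma::uword j = s; j < e; ++j) {
        bidx[j - s] = order[j];
        by[j - s] = y[order[j]];
      }
      arma::mat Xb = X.cols(bidx);
      Cache cc;
      arma::mat Z = forward(net, P, Xb, true, &rng, &cc);
      arma::mat Pr = softmax(Z);
      loss_sum += ce_loss(Pr, by) * (double)(e - s);
      correct += count_correct(Pr, by);
      arma::mat dZ = Pr;
      for (arma::uword j = 0; j < by.n_elem; ++j) dZ(by[j], j) -= 1.0;
      dZ /= (double)by.n_elem;
      Params G;
      G.W.resize(P.W.size());
      G.b.resize(P.b.size());
      backward(net, P, cc, dZ, G);
      for (size_t i = 0; i < P.W.size(); ++i) {
        V.W[i] = momentum * V.W[i] - lr * G.W[i];
        V.b[i] = momentum * V.b[i] - lr * G.b[i];
        P.W[i] += V.W[i];
        P.b[i] += V.b[i];
      }
    }
    hist(ep, 0) = loss_sum / (double)n;
    hist(ep, 1) = (double)correct / (double)n;
    if (has_val) {
      arma::mat Pv = predict_probs(net, P, Xval);
      hist(ep, 2) = ce_loss(Pv, yval);
      hist(ep, 3) = (double)count_correct(Pv, yval) / (double)yval.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(P), _["history"] = hist);
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
arma::mat cpp_cnn_predict(List spec, List params, const arma::mat& X) {
  Net net = parse_spec(spec);
  Params P = params_from_list(params);
  return predict_probs(net, P, X);
}

// loss and exact gradients in eval configuration (dropout inactive);
// used by the finite-difference gradient check
// [[Rcpp::export(name = ".cpp_cnn_grad")]]
List cpp_cnn_grad(List spec, List params, const arma::mat& X,
                  const arma::ivec& y) {
  Net net = parse_spec(spec);
  Params P = params_from_list(params);
  Cache cc;
  arma::mat Z = forward(net, P, X, false, nullptr, &cc);
  arma::mat Pr = softmax(Z);
  double loss = ce_loss(Pr, y);
  arma::mat dZ = Pr;
  for (arma::uword j = 0; j < y.n_elem; ++j) dZ(y[j], j) -= 1.0;
  dZ /= (double)y.n_elem;
  Params G;
  G.W.resize(P.W.size());
  G.b.resize(P.b.size());
  backward(net, P, cc, dZ, G);
  return List::create(_["loss"] = loss, _["grads"] = params_to_list(G));
}
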