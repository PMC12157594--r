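// Small convolutional genotype classifier.
//
// Input: float32 pileup tensors of shape (rows, cols, 6), channel fastest.
// Architecture: N conv blocks (3x3 kernels, stride-2 downsampling, ReLU)
// followed by one dense ReLU layer with dropout and a softmax over the
// three genotype classes {REF, HET, HOM_ALT}. Trained with class-weighted
// cross-entropy and Adam. All randomness (init, shuffling, dropout) comes
// from one std::mt19937_64 seeded by the caller, so identical inputs and
// seed give identical weights and predictions.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NCLASS = 3;

struct ConvPlan {
  int Hin, Win, Cin, F, Hout, Wout, K, P;
  std::vector<int> idx;  // (kernel*kernel) x P spatial gather map, -1 = pad
};

static ConvPlan make_plan(int Hin, int Win, int Cin, int F,
                          int kernel, int stride, int pad) {
  ConvPlan pl;
  pl.Hin = Hin; pl.Win = Win; pl.Cin = Cin; pl.F = F;
  pl.Hout = (Hin + 2 * pad - kernel) / stride + 1;
  pl.Wout = (Win + 2 * pad - kernel) / stride + 1;
  pl.K = kernel * kernel * Cin;
  pl.P = pl.Hout * pl.Wout;
  pl.idx.assign((size_t)kernel * kernel * pl.P, -1);
  for (int r = 0; r < pl.Hout; ++r) {
    for (int c = 0; c < pl.Wout; ++c) {
      int j = r * pl.Wout + c;
      for (int dr = 0; dr < kernel; ++dr) {
        for (int dc = 0; dc < kernel; ++dc) {
          int rin = r * stride - pad + dr;
          int cin = c * stride - pad + dc;
          int t = dr * kernel + dc;
          if (rin >= 0 && rin < Hin && cin >= 0 && cin < Win)
            pl.idx[(size_t)t * pl.P + j] = rin * Win + cin;
        }
      }
    }
  }
  return pl;
}

struct Net {
  std::vector<ConvPlan> plans;
  std::vector<arma::fmat> Wc;  // F x K
  std::vector<arma::fvec> bc;
  arma::fmat Wd;  // dense x flat
  arma::fvec bd;
  arma::fmat Wo;  // 3 x dense
  arma::fvec bo;
  int kernel, stride, pad, dense, flat;
};

static void build_plans(Net& net, const IntegerVector& dims,
                        const IntegerVector& filters) {
  int H = dims[0], W = dims[1], C = dims[2];
  net.plans.clear();
  for (int l = 0; l < filters.size(); ++l) {
    ConvPlan pl = make_plan(H, W, C, filters[l], net.kernel, net.stride, net.pad);
    net.plans.push_back(pl);
    H = pl.Hout; W = pl.Wout; C = pl.F;
  }
  net.flat = H * W * C;
}

static Net net_from_arch(const List& arch, const IntegerVector& dims) {
  Net net;
  net.kernel = as<int>(arch["kernel"]);
  net.stride = as<int>(arch["stride"]);
  net.pad = as<int>(arch["pad"]);
  net.dense = as<int>(arch["dense"]);
  IntegerVector filters = arch["filters"];
  build_plans(net, dims, filters);
  return net;
}

static void init_weights(Net& net, std::mt19937_64& rng) {
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  auto he = [&](arma::fmat& W, int fan_in) {
    float sd = std::sqrt(2.0f / fan_in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = gauss(rng) * sd;
  };
  net.Wc.clear(); net.bc.clear();
  for (const ConvPlan& pl : net.plans) {
    arma::fmat W(pl.F, pl.K);
    he(W, pl.K);
    net.Wc.push_back(W);
    net.bc.push_back(arma::fvec(pl.F, arma::fill::zeros));
  }
  net.Wd.set_size(net.dense, net.flat); he(net.Wd, net.flat);
  net.bd = arma::fvec(net.dense, arma::fill::zeros);
  net.Wo.set_size(NCLASS, net.dense); he(net.Wo, net.dense);
  net.bo = arma::fvec(NCLASS, arma::fill::zeros);
}

static NumericVector to_r(const arma::fmat& m) {
  NumericVector out(m.n_elem);
  for (arma::uword i = 0; i < m.n_elem; ++i) out[i] = (double)m(i);
  out.attr("dim") = IntegerVector::create(m.n_rows, m.n_cols);
  return out;
}

static arma::fmat from_r(const NumericVector& v, int nr, int nc,
                         const char* what) {
  if ((int)v.size() != nr * nc)
    stop(std::string("checkpoint weight '") + what + "' has " +
         std::to_string(v.size()) + " values; expected " +
         std::to_string(nr) + "x" + std::to_string(nc));
  arma::fmat m(nr, nc);
  for (int i = 0; i < nr * nc; ++i) m(i) = (float)v[i];
  return m;
}

static List weights_to_r(const Net& net) {
  List out;
  for (size_t l = 0; l < net.Wc.size(); ++l) {
    out.push_back(to_r(net.Wc[l]), "Wc" + std::to_string(l + 1));
    out.push_back(to_r(arma::fmat(net.bc[l])), "bc" + std::to_string(l + 1));
  }
  out.push_back(to_r(net.Wd), "Wd");
  out.push_back(to_r(arma::fmat(net.bd)), "bd");
  out.push_back(to_r(net.Wo), "Wo");
  out.push_back(to_r(arma::fmat(net.bo)), "bo");
  return out;
}

static void weights_from_r(Net& net, const List& weights) {
  net.Wc.clear(); net.bc.clear();
  for (size_t l = 0; l < net.plans.size(); ++l) {
    const ConvPlan& pl = net.plans[l];
    std::string wn = "Wc" + std::to_string(l + 1);
    std::string bn = "bc" + std::to_string(l + 1);
    net.Wc.push_back(from_r(weights[wn], pl.F, pl.K, wn.c_str()));
    net.bc.push_back(arma::fvec(from_r(weights[bn], pl.F, 1, bn.c_str())));
  }
  net.Wd = from_r(weights["Wd"], net.dense, net.flat, "Wd");
  net.bd = arma::fvec(from_r(weights["bd"], net.dense, 1, "bd"));
  net.Wo = from_r(weights["Wo"], NCLASS, net.dense, "Wo");
  net.bo = arma::fvec(from_r(weights["bo"], NCLASS, 1, "bo"));
}

// scratch buffers reused across examples
struct Scratch {
  std::vector<arma::fmat> X;    // inputs to each conv layer (+ final map)
  std::vector<arma::fmat> Col;  // im2col matrices
  arma::fvec x, h, p;           // flat, dense hidden, probabilities
  arma::fvec hmask;             // dropout mask applied to h
};

static void im2col(const ConvPlan& pl, const arma::fmat& X, arma::fmat& Col) {
  int kk = pl.K / pl.Cin;
  for (int t = 0; t < kk; ++t) {
    const int* map = &pl.idx[(size_t)t * pl.P];
    for (int j = 0; j < pl.P; ++j) {
      float* dst = Col.colptr(j) + (size_t)t * pl.Cin;
      int s = map[j];
      if (s >= 0) std::memcpy(dst, X.colptr(s), pl.Cin * sizeof(float));
      else std::memset(dst, 0, pl.Cin * sizeof(float));
    }
  }
}

static void col2im_add(const ConvPlan& pl, const arma::fmat& dCol,
                       arma::fmat& dX) {
  int kk = pl.K / pl.Cin;
  for (int t = 0; t < kk; ++t) {
    const int* map = &pl.idx[(size_t)t * pl.P];
    for (int j = 0; j < pl.P; ++j) {
      int s = map[j];
      if (s < 0) continue;
      const float* src = dCol.colptr(j) + (size_t)t * pl.Cin;
      float* dst = dX.colptr(s);
      for (int c = 0; c < pl.Cin; ++c) dst[c] += src[c];
    }
  }
}

static void alloc_scratch(const Net& net, Scratch& s) {
  s.X.resize(net.plans.size() + 1);
  s.Col.resize(net.plans.size());
  for (size_t l = 0; l < net.plans.size(); ++l) {
    const ConvPlan& pl = net.plans[l];
    s.X[l].set_size(pl.Cin, pl.Hin * pl.Win);
    s.Col[l].set_size(pl.K, pl.P);
    s.X[l + 1].set_size(pl.F, pl.P);
  }
}

static void load_example(const RawVector& raw, const ConvPlan& pl0,
                         arma::fmat& X0) {
  size_t need = (size_t)pl0.Cin * pl0.Hin * pl0.Win * 4;
  if ((size_t)raw.size() != need)
    stop("example tensor has " + std::to_string(raw.size()) +
         " bytes; expected " + std::to_string(need) +
         " for shape (" + std::to_string(pl0.Hin) + ", " +
         std::to_string(pl0.Win) + ", " + std::to_string(pl0.Cin) + ")");
  std::memcpy(X0.memptr(), RAW(raw), need);
}

// forward pass; returns probabilities in s.p
static void forward(const Net& net, Scratch& s, bool train, float dropout,
                    std::mt19937_64* rng) {
  for (size_t l = 0; l < net.plans.size(); ++l) {
    const ConvPlan& pl = net.plans[l];
    im2col(pl, s.X[l], s.Col[l]);
    s.X[l + 1] = net.Wc[l] * s.Col[l];
    s.X[l + 1].each_col() += net.bc[l];
    s.X[l + 1].transform([](float v) { return v > 0 ? v : 0; });
  }
  s.x = arma::vectorise(s.X.back());
  s.h = net.Wd * s.x + net.bd;
  s.h.transform([](float v) { return v > 0 ? v : 0; });
  if (train && dropout > 0) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    float keep = 1.0f - dropout;
    s.hmask.set_size(s.h.n_elem);
    for (arma::uword i = 0; i < s.h.n_elem; ++i)
      s.hmask(i) = unif(*rng) < keep ? 1.0f / keep : 0.0f;
    s.h %= s.hmask;
  }
  arma::fvec logits = net.Wo * s.h + net.bo;
  logits -= logits.max();
  s.p = arma::exp(logits);
  s.p /= arma::accu(s.p);
}

struct Grads {
  std::vector<arma::fmat> Wc;
  std::vector<arma::fvec> bc;
  arma::fmat Wd; arma::fvec bd;
  arma::fmat Wo; arma::fvec bo;
  void zero_like(const Net& net) {
    Wc.clear(); bc.clear();
    for (const ConvPlan& pl : net.plans) {
      Wc.push_back(arma::fmat(pl.F, pl.K, arma::fill::zeros));
      bc.push_back(arma::fvec(pl.F, arma::fill::zeros));
    }
    Wd = arma::fmat(net.Wd.n_rows, net.Wd.n_cols, arma::fill::zeros);
    bd = arma::fvec(net.bd.n_elem, arma::fill::zeros);
    Wo = arma::fmat(net.Wo.n_rows, net.Wo.n_cols, arma::fill::zeros);
    bo = arma::fvec(net.bo.n_elem, arma::fill::zeros);
  }
};

// backward pass for one example; gradients accumulate into g.
// Assumes forward() was just called (train mode) on s. `w` is the class
// weight of this example's label.
static void backward(const Net& net, Scratch& s, Grads& g, int label,
                     float w, float dropout) {
  arma::fvec dlogit = s.p;
  dlogit(label) -= 1.0f;
  dlogit *= w;
  g.Wo += dlogit * s.h.t();
  g.bo += dlogit;
  arma::fvec dh = net.Wo.t() * dlogit;
  if (dropout > 0) dh %= s.hmask;
  for (arma::uword i = 0; i < dh.n_elem; ++i)
    if (s.h(i) <= 0) dh(i) = 0;
  g.Wd += dh * s.x.t();
  g.bd += dh;
  arma::fvec dx = net.Wd.t() * dh;
  arma::fmat dX = arma::reshape(dx, s.X.back().n_rows, s.X.back().n_cols);
  for (int l = (int)net.plans.size() - 1; l >= 0; --l) {
    const ConvPlan& pl = net.plans[l];
    // ReLU gate on this layer's output
    const arma::fmat& Y = s.X[l + 1];
    for (arma::uword i = 0; i < dX.n_elem; ++i)
      if (Y(i) <= 0) dX(i) = 0;
    g.Wc[l] += dX * s.Col[l].t();
    g.bc[l] += arma::sum(dX, 1);
    if (l > 0) {
      arma::fmat dCol = net.Wc[l].t() * dX;
      arma::fmat dXprev(pl.Cin, pl.Hin * pl.Win, arma::fill::zeros);
      col2im_add(pl, dCol, dXprev);
      dX = dXprev;
    }
  }
}

struct Adam {
  std::vector<arma::fmat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;
  void init(const std::vector<arma::fmat*>& params) {
    m.clear(); v.clear();
    for (auto* p : params) {
      m.push_back(arma::fmat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(arma::fmat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<arma::fmat*>& params,
            const std::vector<arma::fmat*>& grads, float lr) {
    ++t;
    float corr = std::sqrt(1.0 - std::pow(b2, t)) / (1.0 - std::pow(b1, t));
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = (float)b1 * m[i] + (float)(1 - b1) * (*grads[i]);
      v[i] = (float)b2 * v[i] + (float)(1 - b2) * arma::square(*grads[i]);
      *params[i] -= lr * corr * m[i] / (arma::sqrt(v[i]) + (float)eps);
    }
  }
};

// [[Rcpp::export]]
List cpp_cnn_train(List examples, IntegerVector labels,
                   IntegerVector train_idx, IntegerVector holdout_idx,
                   List arch, List opt, IntegerVector dims) {
  Net net = net_from_arch(arch, dims);
  double lr = as<double>(opt["lr"]);
  int batch = as<int>(opt["batch_size"]);
  int epochs = as<int>(opt["epochs"]);
  int patience = as<int>(opt["patience"]);
  float dropout = (float)as<double>(opt["dropout"]);
  unsigned long seed = (unsigned long)as<double>(opt["seed"]);
  NumericVector cw = opt["class_weights"];
  std::mt19937_64 rng(seed);
  init_weights(net, rng);

  Scratch s;
  alloc_scratch(net, s);

  // Adam over all parameters; biases are carried as 1-column fmats in
  // bias_mats (stable addresses) and copied back into the fvec views
  // after every optimizer step.
  Grads g;
  Adam adam;
  std::vector<arma::fmat*> params;
  g.zero_like(net);
  for (size_t l = 0; l < net.Wc.size(); ++l) params.push_back(&net.Wc[l]);
  params.push_back(&net.Wd); params.push_back(&net.Wo);
  std::vector<arma::fmat> bias_mats;
  bias_mats.reserve(net.bc.size() + 2);
  for (auto& b : net.bc) bias_mats.push_back(arma::fmat(b));
  bias_mats.push_back(arma::fmat(net.bd));
  bias_mats.push_back(arma::fmat(net.bo));
  for (auto& bm : bias_mats) params.push_back(&bm);
  adam.init(params);

  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> ho(holdout_idx.begin(), holdout_idx.end());

  auto eval_set = [&](const std::vector<int>& idx, double& loss,
                      double& acc) {
    loss = 0; acc = 0;
    if (idx.empty()) { loss = NA_REAL; acc = NA_REAL; return; }
    for (int i : idx) {
      load_example(examples[i - 1], net.plans[0], s.X[0]);
      forward(net, s, false, 0, nullptr);
      int y = labels[i - 1];
      loss += -std::log(std::max(s.p(y), 1e-12f));
      if (s.p.index_max() == (arma::uword)y) acc += 1;
    }
    loss /= idx.size(); acc /= idx.size();
  };

  List best_weights;
  double best_loss = R_PosInf;
  int best_epoch = 0, bad_epochs = 0;
  std::vector<double> log_epoch, log_train, log_holdout, log_acc;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0, ep_wsum = 0;
    for (size_t b0 = 0; b0 < tr.size(); b0 += batch) {
      size_t b1 = std::min(b0 + batch, tr.size());
      g.zero_like(net);
      double wsum = 0;
      for (size_t ii = b0; ii < b1; ++ii) {
        int i = tr[ii];
        int y = labels[i - 1];
        float w = (float)cw[y];
        load_example(examples[i - 1], net.plans[0], s.X[0]);
        forward(net, s, true, dropout, &rng);
        ep_loss += w * -std::log(std::max(s.p(y), 1e-12f));
        ep_wsum += w;
        wsum += w;
        backward(net, s, g, y, w, dropout);
      }
      float inv = 1.0f / (float)wsum;
      std::vector<arma::fmat*> gr;
      for (auto& W : g.Wc) { W *= inv; gr.push_back(&W); }
      g.Wd *= inv; gr.push_back(&g.Wd);
      g.Wo *= inv; gr.push_back(&g.Wo);
      std::vector<arma::fmat> gbias;
      gbias.reserve(g.bc.size() + 2);
      for (auto& b : g.bc) gbias.push_back(arma::fmat(b) * inv);
      gbias.push_back(arma::fmat(g.bd) * inv);
      gbias.push_back(arma::fmat(g.bo) * inv);
      for (auto& gb : gbias) gr.push_back(&gb);
      adam.step(params, gr, (float)lr);
      // copy bias fmats back into fvec views
      size_t nb = net.bc.size();
      for (size_t l = 0; l < nb; ++l)
        net.bc[l] = arma::fvec(*params[params.size() - nb - 2 + l]);
      net.bd = arma::fvec(*params[params.size() - 2]);
      net.bo = arma::fvec(*params[params.size() - 1]);
    }
    double ho_loss, ho_acc;
    eval_set(ho, ho_loss, ho_acc);
    log_epoch.push_back(ep);
    log_train.push_back(ep_wsum > 0 ? ep_loss / ep_wsum : NA_REAL);
    log_holdout.push_back(ho_loss);
    log_acc.push_back(ho_acc);
    if (!ho.empty()) {
      if (ho_loss < best_loss - 1e-5) {
        best_loss = ho_loss;
        best_epoch = ep;
        best_weights = weights_to_r(net);
        bad_epochs = 0;
      } else if (++bad_epochs >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }
  if (best_weights.size() == 0) {
    best_weights = weights_to_r(net);
    best_epoch = log_epoch.empty() ? 0 : (int)log_epoch.back();
  }
  return List::create(
    _["weights"] = best_weights,
    _["best_epoch"] = best_epoch,
    _["log"] = DataFrame::create(
      _["epoch"] = wrap(log_epoch), _["train_loss"] = wrap(log_train),
      _["holdout_loss"] = wrap(log_holdout),
      _["holdout_acc"] = wrap(log_acc)));
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List weights, List examples, List arch,
                              IntegerVector dims) {
  Net net = net_from_arch(arch, dims);
  weights_from_r(net, weights);
  Scratch s;
  alloc_scratch(net, s);
  R_xlen_t n = examples.size();
  NumericMatrix out(n, NCLASS);
  for (R_xlen_t i = 0; i < n; ++i) {
    load_example(examples[i], net.plans[0], s.X[0]);
    forward(net, s, false, 0, nullptr);
    for (int k = 0; k < NCLASS; ++k) out(i, k) = (double)s.p(k);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Mean class-weighted cross-entropy and its gradient over a set of
// examples, at fixed weights and no dropout. Used by finite-difference
// gradient tests.
// [[Rcpp::export]]
List cpp_cnn_loss_grad(List weights, List examples, IntegerVector labels,
                       List arch, IntegerVector dims,
                       NumericVector class_weights) {
  Net net = net_from_arch(arch, dims);
  weights_from_r(net, weights);
  Scratch s;
  alloc_scratch(net, s);
  Grads g;
  g.zero_like(net);
  double loss = 0, wsum = 0;
  for (R_xlen_t i = 0; i < examples.size(); ++i) {
    int y = labels[i];
    float w = (float)class_weights[y];
    load_example(examples[i], net.plans[0], s.X[0]);
    forward(net, s, false, 0, nullptr);
    loss += w * -std::log(std::max(s.p(y), 1e-12f));
    wsum += w;
    backward(net, s, g, y, w, 0);
  }
  float inv = 1.0f / (float)wsum;
  List gl;
  for (size_t l = 0; l < g.Wc.size(); ++l) {
    gl.push_back(to_r(g.Wc[l] * inv), "Wc" + std::to_string(l + 1));
    gl.push_back(to_r(arma::fmat(g.bc[l]) * inv), "bc" + std::to_string(l + 1));
  }
  gl.push_back(to_r(g.Wd * inv), "Wd");
  gl.push_back(to_r(arma::fmat(g.bd) * inv), "bd");
  gl.push_back(to_r(g.Wo * inv), "Wo");
  gl.push_back(to_r(arma::fmat(g.bo) * inv), "bo");
  return List::create(_["loss"] = loss / wsum, _["grad"] = gl);
}

// Flat-vector dimensionality of the final conv feature map, given input
// dims and the architecture; lets R validate checkpoints.
// [[Rcpp::export]]
int cpp_cnn_flat_dim(List arch, IntegerVector dims) {
  Net net = net_from_arch(arch, dims);
  return net.flat;
}
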