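// Single-precision network kernels. Parameters cross the R/C++ boundary as
// lists of list(W, b); all heavy linear algebra stays in float (sgemm).
// Conventions shared with the R side:
//  - pair-feature matrices are sample-major: rows s*n .. s*n+n-1 belong to
//    sample s (0-based), neighbours sorted by increasing distance;
//  - `odd` is a 1-based column index vector of features that flip sign under
//    reflection along the focal's body axis;
//  - labels y are 0/1 with 1 = right turn; the logit z is the log-odds of a
//    right turn.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uword;

struct MLP {
  std::vector<fmat> W;
  std::vector<frowvec> b;
  size_t n_layers() const { return W.size(); }
};

static MLP as_mlp(const Rcpp::List& params) {
  MLP net;
  for (R_xlen_t l = 0; l < params.size(); ++l) {
    Rcpp::List layer = params[l];
    net.W.push_back(Rcpp::as<fmat>(layer["W"]));
    net.b.push_back(arma::conv_to<frowvec>::from(Rcpp::as<fvec>(layer["b"])));
  }
  return net;
}

static inline void relu_inplace(fmat& Z) {
  float* p = Z.memptr();
  const uword n = Z.n_elem;
  for (uword i = 0; i < n; ++i)
    p[i] = p[i] > 0.0f ? p[i] : 0.0f;  // branchless, vectorizes
}

// zero the entries of dZ where the cached post-activation output is zero
static inline void relu_mask_inplace(fmat& dZ, const fmat& act) {
  float* p = dZ.memptr();
  const float* a = act.memptr();
  const uword n = dZ.n_elem;
  for (uword i = 0; i < n; ++i)
    p[i] = a[i] > 0.0f ? p[i] : 0.0f;
}

// forward pass; cache[l] is the post-activation output of layer l (cache[0]
// is the input). ReLU after every hidden layer, linear readout. When a
// cache is supplied the activations live only there (cache->back() is the
// network output), avoiding large copies.
static fmat mlp_forward(const MLP& net, const fmat& X,
                        std::vector<fmat>* cache) {
  if (cache) {
    cache->clear();
    cache->reserve(net.n_layers() + 1);
    cache->push_back(X);
    for (size_t l = 0; l < net.n_layers(); ++l) {
      fmat Z = cache->back() * net.W[l];
      Z.each_row() += net.b[l];
      if (l + 1 < net.n_layers()) relu_inplace(Z);
      cache->push_back(std::move(Z));
    }
    return cache->back();
  }
  fmat A = X;
  for (size_t l = 0; l < net.n_layers(); ++l) {
    fmat Z = A * net.W[l];
    Z.each_row() += net.b[l];
    if (l + 1 < net.n_layers()) relu_inplace(Z);
    A = std::move(Z);
  }
  return A;
}

// backward pass through an MLP whose forward cache is given; returns
// parameter gradients and (optionally) the gradient w.r.t. the input.
static void mlp_backward(const MLP& net, const std::vector<fmat>& cache,
                         fmat dOut, std::vector<fmat>* gW,
                         std::vector<frowvec>* gb, fmat* dX) {
  gW->assign(net.n_layers(), fmat());
  gb->assign(net.n_layers(), frowvec());
  for (size_t l = net.n_layers(); l-- > 0;) {
    if (l + 1 < net.n_layers()) {
      // ReLU mask from the stored post-activation output of layer l
      relu_mask_inplace(dOut, cache[l + 1]);
    }
    (*gW)[l] = cache[l].t() * dOut;
    (*gb)[l] = arma::sum(dOut, 0);
    if (l > 0 || dX) dOut = dOut * net.W[l].t();
  }
  if (dX) *dX = dOut;
}

static Rcpp::List grads_to_list(const std::vector<fmat>& gW,
                                const std::vector<frowvec>& gb) {
  Rcpp::List out(gW.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    out[l] = Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::wrap(arma::conv_to<arma::mat>::from(gW[l])),
        Rcpp::Named("b") = Rcpp::wrap(arma::conv_to<arma::vec>::from(gb[l].t())));
  }
  return out;
}

// reflected copy: sign of the `odd` columns flipped
static fmat reflect_cols(const fmat& X, const Rcpp::IntegerVector& odd) {
  fmat XR = X;
  for (R_xlen_t k = 0; k < odd.size(); ++k) XR.col(odd[k] - 1) *= -1.0f;
  return XR;
}

// cross-entropy on logits; fills dz with dL/dz (mean reduction)
static double ce_loss(const fvec& z, const arma::vec& y, fvec* dz) {
  const double m = static_cast<double>(z.n_elem);
  double loss = 0.0;
  if (dz) dz->set_size(z.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) {
    double p = 1.0 / (1.0 + std::exp(-static_cast<double>(z[i])));
    p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    loss -= y[i] > 0.5 ? std::log(p) : std::log(1.0 - p);
    if (dz) (*dz)[i] = static_cast<float>((p - y[i]) / m);
  }
  return loss / m;
}

// ---------------------------------------------------------------------------
// Attention network: z_s = sum_i PiA_i * omega_i with
//   PiA_i = piA(x_i) - piA(x_i*)   (antisymmetrized per neighbour)
//   omega_i = exp(w_i) / sum_j exp(w_j), w_i = wnet(u_i) (symmetric inputs)
// ---------------------------------------------------------------------------

struct AttnFwd {
  fmat Pi;      // n x m per-neighbour antisymmetrized logit
  fmat logW;    // n x m raw weight-net readout (log of the raw weight)
  fmat omega;   // n x m normalized weights (softmax of logW per sample)
  fvec z;       // m
  std::vector<fmat> cache_pi, cache_w;
  fmat Xjoin;
};

static void attn_forward_core(const fmat& Xpair, const fmat& Xw,
                              const Rcpp::IntegerVector& odd, int n,
                              const MLP& pi_net, const MLP& w_net,
                              AttnFwd* f, bool keep_cache) {
  const uword mn = Xpair.n_rows;
  const uword m = mn / n;
  f->Xjoin = arma::join_cols(Xpair, reflect_cols(Xpair, odd));
  fmat out = mlp_forward(pi_net, f->Xjoin, keep_cache ? &f->cache_pi : nullptr);
  fvec o = out.col(0);
  f->Pi = fmat(o.memptr(), n, m);            // first half
  f->Pi -= fmat(o.memptr() + mn, n, m);      // minus reflected half
  fmat wout = mlp_forward(w_net, Xw, keep_cache ? &f->cache_w : nullptr);
  f->logW = fmat(wout.colptr(0), n, m);
  // numerically stable softmax per sample (column)
  f->omega = f->logW;
  f->omega.each_row() -= arma::max(f->omega, 0);
  f->omega = arma::exp(f->omega);
  f->omega.each_row() /= arma::sum(f->omega, 0);
  f->z = arma::sum(f->Pi % f->omega, 0).t();
}

// [[Rcpp::export]]
Rcpp::List cpp_attn_forward(const arma::mat& Xpair, const arma::mat& Xw,
                            Rcpp::IntegerVector odd, int n,
                            Rcpp::List pi_params, Rcpp::List w_params) {
  MLP pi_net = as_mlp(pi_params), w_net = as_mlp(w_params);
  AttnFwd f;
  attn_forward_core(arma::conv_to<fmat>::from(Xpair),
                    arma::conv_to<fmat>::from(Xw), odd, n, pi_net, w_net, &f,
                    false);
  return Rcpp::List::create(
      Rcpp::Named("z") = Rcpp::wrap(arma::conv_to<arma::vec>::from(f.z)),
      Rcpp::Named("pi") = Rcpp::wrap(arma::conv_to<arma::mat>::from(f.Pi)),
      Rcpp::Named("log_w") = Rcpp::wrap(arma::conv_to<arma::mat>::from(f.logW)),
      Rcpp::Named("omega") = Rcpp::wrap(arma::conv_to<arma::mat>::from(f.omega)));
}

// [[Rcpp::export]]
Rcpp::List cpp_attn_grad(const arma::mat& Xpair, const arma::mat& Xw,
                         Rcpp::IntegerVector odd, int n, const arma::vec& y,
                         Rcpp::List pi_params, Rcpp::List w_params) {
  MLP pi_net = as_mlp(pi_params), w_net = as_mlp(w_params);
  AttnFwd f;
  attn_forward_core(arma::conv_to<fmat>::from(Xpair),
                    arma::conv_to<fmat>::from(Xw), odd, n, pi_net, w_net, &f,
                    true);
  fvec dz;
  double loss = ce_loss(f.z, y, &dz);
  const uword m = f.z.n_elem, mn = m * n;
  // dL/dPi_i = dz_s * omega_i ; dL/dlogW_i = dz_s * (Pi_i - z_s) * omega_i
  fmat dPi = f.omega;
  dPi.each_row() %= dz.t();
  fmat dLogW = f.Pi;
  dLogW.each_row() -= f.z.t();
  dLogW %= f.omega;
  dLogW.each_row() %= dz.t();
  // back through pi on the joined (original, reflected) batch
  fmat dOut(2 * mn, 1);
  std::memcpy(dOut.memptr(), dPi.memptr(), mn * sizeof(float));
  fmat negdPi = -dPi;
  std::memcpy(dOut.memptr() + mn, negdPi.memptr(), mn * sizeof(float));
  std::vector<fmat> gWpi, gWw;
  std::vector<frowvec> gbpi, gbw;
  mlp_backward(pi_net, f.cache_pi, dOut, &gWpi, &gbpi, nullptr);
  fmat dWOut(dLogW.memptr(), mn, 1);
  mlp_backward(w_net, f.cache_w, dWOut, &gWw, &gbw, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("g_pi") = grads_to_list(gWpi, gbpi),
                            Rcpp::Named("g_w") = grads_to_list(gWw, gbw));
}

// ---------------------------------------------------------------------------
// Interaction network: z = I(X) - I(X*) with
//   I(X) = Gamma(relu(sum_i piI(x_i))), piI 128-dim embedding
// ---------------------------------------------------------------------------

struct InterFwd {
  fmat E;        // 2mn x 128 embeddings (original stacked over reflected)
  fmat S;        // 2m x 128 per-sample sums
  fmat R;        // relu(S)
  fvec z;        // m
  std::vector<fmat> cache_pi, cache_g;
};

static void inter_forward_core(const fmat& Xpair, const Rcpp::IntegerVector& odd,
                               int n, const MLP& pi_net, const MLP& g_net,
                               InterFwd* f, bool keep_cache) {
  const uword mn = Xpair.n_rows;
  const uword m = mn / n;
  fmat Xjoin = arma::join_cols(Xpair, reflect_cols(Xpair, odd));
  f->E = mlp_forward(pi_net, Xjoin, keep_cache ? &f->cache_pi : nullptr);
  const uword d = f->E.n_cols;
  f->S.zeros(2 * m, d);
  for (uword s = 0; s < 2 * m; ++s)
    f->S.row(s) = arma::sum(f->E.rows(s * n, s * n + n - 1), 0);
  f->R = f->S;
  relu_inplace(f->R);
  fmat out = mlp_forward(g_net, f->R, keep_cache ? &f->cache_g : nullptr);
  f->z = out.col(0).head(m) - out.col(0).tail(m);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_inter_forward(const arma::mat& Xpair,
                                      Rcpp::IntegerVector odd, int n,
                                      Rcpp::List pi_params,
                                      Rcpp::List gamma_params) {
  MLP pi_net = as_mlp(pi_params), g_net = as_mlp(gamma_params);
  InterFwd f;
  inter_forward_core(arma::conv_to<fmat>::from(Xpair), odd, n, pi_net, g_net,
                     &f, false);
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(f.z));
}

// [[Rcpp::export]]
Rcpp::List cpp_inter_grad(const arma::mat& Xpair, Rcpp::IntegerVector odd,
                          int n, const arma::vec& y, Rcpp::List pi_params,
                          Rcpp::List gamma_params) {
  MLP pi_net = as_mlp(pi_params), g_net = as_mlp(gamma_params);
  InterFwd f;
  inter_forward_core(arma::conv_to<fmat>::from(Xpair), odd, n, pi_net, g_net,
                     &f, true);
  fvec dz;
  double loss = ce_loss(f.z, y, &dz);
  const uword m = f.z.n_elem;
  fmat dOut(2 * m, 1);
  dOut.col(0).head(m) = dz;
  dOut.col(0).tail(m) = -dz;
  std::vector<fmat> gWg, gWpi;
  std::vector<frowvec> gbg, gbpi;
  fmat dR;
  mlp_backward(g_net, f.cache_g, dOut, &gWg, &gbg, &dR);
  relu_mask_inplace(dR, f.R);  // relu before Gamma
  // broadcast per-sample gradient to each neighbour embedding row
  fmat dE(f.E.n_rows, f.E.n_cols);
  for (uword s = 0; s < 2 * m; ++s)
    dE.rows(s * n, s * n + n - 1) = arma::repmat(dR.row(s), n, 1);
  mlp_backward(pi_net, f.cache_pi, dE, &gWpi, &gbpi, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("g_pi") = grads_to_list(gWpi, gbpi),
                            Rcpp::Named("g_gamma") = grads_to_list(gWg, gbg));
}

// ---------------------------------------------------------------------------
// Focal-only baseline: z = f(alpha) - f(alpha*) through a plain MLP
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::NumericVector cpp_focal_forward(const arma::mat& X,
                                      Rcpp::IntegerVector odd,
                                      Rcpp::List params) {
  MLP net = as_mlp(params);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat o1 = mlp_forward(net, Xf, nullptr);
  fmat o2 = mlp_forward(net, reflect_cols(Xf, odd), nullptr);
  fvec z = o1.col(0) - o2.col(0);
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(z));
}

// [[Rcpp::export]]
Rcpp::List cpp_focal_grad(const arma::mat& X, Rcpp::IntegerVector odd,
                          const arma::vec& y, Rcpp::List params) {
  MLP net = as_mlp(params);
  fmat Xf = arma::conv_to<fmat>::from(X);
  const uword m = Xf.n_rows;
  fmat Xjoin = arma::join_cols(Xf, reflect_cols(Xf, odd));
  std::vector<fmat> cache;
  fmat out = mlp_forward(net, Xjoin, &cache);
  fvec z = out.col(0).head(m) - out.col(0).tail(m);
  fvec dz;
  double loss = ce_loss(z, y, &dz);
  fmat dOut(2 * m, 1);
  dOut.col(0).head(m) = dz;
  dOut.col(0).tail(m) = -dz;
  std::vector<fmat> gW;
  std::vector<frowvec> gb;
  mlp_backward(net, cache, dOut, &gW, &gb, nullptr);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("g") = grads_to_list(gW, gb));
}

// plain MLP evaluation with per-input antisymmetrization disabled; used by
// the map module to evaluate piA(x) - piA(x*) on dense grids
// [[Rcpp::export]]
Rcpp::NumericVector cpp_pair_logit(const arma::mat& X, Rcpp::IntegerVector odd,
                                   Rcpp::List pi_params) {
  MLP net = as_mlp(pi_params);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat o1 = mlp_forward(net, Xf, nullptr);
  fmat o2 = mlp_forward(net, reflect_cols(Xf, odd), nullptr);
  fvec z = o1.col(0) - o2.col(0);
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(z));
}

// raw weight-net readout (log W) on a feature matrix; used for weight maps
// [[Rcpp::export]]
Rcpp::NumericVector cpp_weight_logit(const arma::mat& Xw, Rcpp::List w_params) {
  MLP net = as_mlp(w_params);
  fmat o = mlp_forward(net, arma::conv_to<fmat>::from(Xw), nullptr);
  fvec v = o.col(0);
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(v));
}
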