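// Fused batch step of the convolutional-recurrent feature extractor.
// The network is small but the activation tensors are not (14 x 128 x 16
// per segment), so the per-batch elementwise work lives here as fused
// explicit loops; matrix products go through BLAS via Armadillo.
// Dropout masks come from a counter-based generator seeded from R's
// RNG, so a single set.seed() in R determines the whole training run.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// xorshift128+ for dropout masks; seeded per batch from R's RNG
struct XorShift128 {
  uint64_t s0, s1;
  explicit XorShift128(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
  }
  inline double next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return (double)((s1 + y) >> 11) * (1.0 / 9007199254740992.0);
  }
};

// conv -> BN -> ReLU -> pool -> dropout for one kernel, writing the
// flattened features for this kernel straight into F
static void block_forward(const arma::mat& Spad, int len, int q,
                          const arma::mat& conv_w, const arma::vec& conv_b,
                          const arma::vec& bn_gamma,
                          const arma::vec& bn_beta,
                          const arma::vec& bn_mean,
                          const arma::vec& bn_var, double eps, bool literal,
                          bool train, double dropout_p, XorShift128* rng,
                          arma::mat* xhat_c, arma::mat* relu_c,
                          arma::mat* mask_c, double* denom_c,
                          double* bn_mu_out, double* bn_var_out,
                          arma::mat& F) {
  const int k = conv_w.n_cols;
  const int m = Spad.n_cols;
  std::vector<double> w(k);
  for (int i = 0; i < k; ++i) w[i] = conv_w(q, i);
  const double* wq = w.data();
  const double bq = conv_b(q);

  arma::mat C(len, m);
  double sum = 0.0, sumsq = 0.0;
  for (int j = 0; j < m; ++j) {
    const double* sp = Spad.colptr(j);
    double* cp = C.colptr(j);
    for (int v = 0; v < len; ++v) {
      double acc = bq;
      const double* z = sp + v;
      for (int i = 0; i < k; ++i) acc += wq[i] * z[i];
      cp[v] = acc;
      sum += acc;
      sumsq += acc * acc;
    }
  }
  const double N = (double)len * m;
  double mu, var;
  if (train) {
    mu = sum / N;
    var = sumsq / N - mu * mu;
    if (var < 0) var = 0;
    *bn_mu_out = mu;
    *bn_var_out = var;
  } else {
    mu = bn_mean(q);
    var = bn_var(q);
  }
  const double denom = literal ? (var + eps) : std::sqrt(var + eps);
  const double gam = bn_gamma(q), bet = bn_beta(q);
  if (denom_c) *denom_c = denom;

  const bool drop = train && dropout_p > 0;
  const double scale = drop ? 1.0 / (1.0 - dropout_p) : 1.0;
  for (int j = 0; j < m; ++j) {
    const double* cp = C.colptr(j);
    double* xh = xhat_c ? xhat_c->colptr(j) : nullptr;
    double* rl = relu_c->colptr(j);
    for (int v = 0; v < len; ++v) {
      const double x = (cp[v] - mu) / denom;
      if (xh) xh[v] = x;
      const double b = gam * x + bet;
      rl[v] = b > 0 ? b : 0;
    }
  }
  // pool + dropout, writing directly into the flattened feature block:
  // F rows for kernel q are q*len*n_channels ... laid out so that the
  // m columns of the len x m activation matrix map to consecutive
  // len-blocks of rows within each segment's column of F
  const int B = (int)F.n_cols;
  const int ch_per_seg = m / B;
  for (int j = 0; j < m; ++j) {
    const int seg = j / ch_per_seg;
    const int ch = j % ch_per_seg;
    double* fcol = F.colptr(seg) + (size_t)q * len * ch_per_seg +
                   (size_t)ch * len;
    const double* rl = relu_c->colptr(j);
    double* mk = drop ? mask_c->colptr(j) : nullptr;
    for (int v = 0; v < len; ++v) {
      double p = (v < len - 1) ? (rl[v] >= rl[v + 1] ? rl[v] : rl[v + 1])
                               : (rl[v] > 0 ? rl[v] : 0);
      if (drop) {
        const double mval = (rng->next() >= dropout_p) ? scale : 0.0;
        mk[v] = mval;
        p *= mval;
      }
      fcol[v] = p;
    }
  }
}

static void lstm_head_forward(const arma::mat& F, const arma::mat& lstm_wx,
                              const arma::vec& lstm_b,
                              const arma::mat& head_w,
                              const arma::vec& head_b, int u,
                              arma::mat* gi_c, arma::mat* gg_c,
                              arma::mat* go_c, arma::mat* cv_c,
                              arma::mat& h, arma::mat& logits) {
  arma::mat Z = lstm_wx * F;
  Z.each_col() += lstm_b;
  arma::mat gi = 1.0 / (1.0 + arma::exp(-Z.rows(0, u - 1)));
  arma::mat gg = arma::tanh(Z.rows(2 * u, 3 * u - 1));
  arma::mat go = 1.0 / (1.0 + arma::exp(-Z.rows(3 * u, 4 * u - 1)));
  arma::mat cvec = gi % gg; // zero initial cell state: forget path drops
  h = go % arma::tanh(cvec);
  logits = head_w * h;
  logits.each_col() += head_b;
  if (gi_c) {
    *gi_c = std::move(gi);
    *gg_c = std::move(gg);
    *go_c = std::move(go);
    *cv_c = std::move(cvec);
  }
}

// [[Rcpp::export(name = ".cpp_crnn_eval")]]
List cpp_crnn_eval(const arma::mat& S, const arma::mat& conv_w,
                   const arma::vec& conv_b, const arma::vec& bn_gamma,
                   const arma::vec& bn_beta, const arma::vec& bn_mean,
                   const arma::vec& bn_var, const arma::mat& lstm_wx,
                   const arma::vec& lstm_b, const arma::mat& head_w,
                   const arma::vec& head_b, int n_channels, double eps,
                   bool literal) {
  const int len = S.n_rows;
  const int nf = conv_w.n_rows;
  const int k = conv_w.n_cols;
  const int m = S.n_cols;
  const int B = m / n_channels;
  arma::mat Spad(len + k - 1, m, arma::fill::zeros);
  Spad.rows(0, len - 1) = S;
  arma::mat F((size_t)len * n_channels * nf, B);
  arma::mat relu(len, m);
  double mu_d, var_d;
  for (int q = 0; q < nf; ++q) {
    block_forward(Spad, len, q, conv_w, conv_b, bn_gamma, bn_beta,
                  bn_mean, bn_var, eps, literal, false, 0.0, nullptr,
                  nullptr, &relu, nullptr, nullptr, &mu_d, &var_d, F);
  }
  const int u = lstm_wx.n_rows / 4;
  arma::mat h, logits;
  lstm_head_forward(F, lstm_wx, lstm_b, head_w, head_b, u, nullptr,
                    nullptr, nullptr, nullptr, h, logits);
  return List::create(_["h"] = h, _["logits"] = logits);
}

// [[Rcpp::export(name = ".cpp_crnn_train_step")]]
List cpp_crnn_train_step(const arma::mat& S, const arma::mat& Y,
                         const arma::mat& conv_w, const arma::vec& conv_b,
                         const arma::vec& bn_gamma,
                         const arma::vec& bn_beta,
                         const arma::mat& lstm_wx, const arma::vec& lstm_b,
                         const arma::mat& head_w, const arma::vec& head_b,
                         int n_channels, double eps, bool literal,
                         double dropout_p) {
  const int len = S.n_rows;
  const int nf = conv_w.n_rows;
  const int k = conv_w.n_cols;
  const int m = S.n_cols;
  const int B = m / n_channels;
  const size_t rows_per_q = (size_t)len * n_channels;
  arma::mat Spad(len + k - 1, m, arma::fill::zeros);
  Spad.rows(0, len - 1) = S;

  // one draw from R's RNG seeds all dropout masks of this batch
  XorShift128 rng((uint64_t)(unif_rand() * 9007199254740992.0));

  std::vector<arma::mat> xhat(nf), relu(nf), mask(nf);
  arma::vec denoms(nf), bn_mu(nf), bn_v(nf);
  arma::mat F(rows_per_q * nf, B);
  const bool drop = dropout_p > 0;
  for (int q = 0; q < nf; ++q) {
    xhat[q].set_size(len, m);
    relu[q].set_size(len, m);
    if (drop) mask[q].set_size(len, m);
    block_forward(Spad, len, q, conv_w, conv_b, bn_gamma, bn_beta,
                  bn_gamma /*unused*/, bn_gamma /*unused*/, eps, literal,
                  true, dropout_p, &rng, &xhat[q], &relu[q],
                  drop ? &mask[q] : nullptr, &denoms(q), &bn_mu(q),
                  &bn_v(q), F);
  }
  const int u = lstm_wx.n_rows / 4;
  arma::mat gi, gg, go, cvec, h, logits;
  lstm_head_forward(F, lstm_wx, lstm_b, head_w, head_b, u, &gi, &gg, &go,
                    &cvec, h, logits);

  // softmax cross-entropy
  arma::mat P = logits;
  P.each_row() -= arma::max(P, 0);
  P = arma::exp(P);
  P.each_row() /= arma::sum(P, 0);
  double loss = 0.0;
  int correct = 0;
  for (int j = 0; j < B; ++j) {
    arma::uword yj = arma::index_max(Y.col(j));
    loss -= std::log(std::max(P(yj, j), 1e-12));
    if (arma::index_max(logits.col(j)) == yj) ++correct;
  }
  loss /= B;

  // ---- backward ----
  arma::mat dL = (P - Y) / (double)B;
  arma::mat g_head_w = dL * h.t();
  arma::vec g_head_b = arma::sum(dL, 1);
  arma::mat dh = head_w.t() * dL;
  arma::mat tc = arma::tanh(cvec);
  arma::mat do_ = dh % tc;
  arma::mat dc = dh % go % (1.0 - arma::square(tc));
  arma::mat dZ(4 * u, B, arma::fill::zeros);
  dZ.rows(0, u - 1) = (dc % gg) % gi % (1.0 - gi);
  dZ.rows(2 * u, 3 * u - 1) = (dc % gi) % (1.0 - arma::square(gg));
  dZ.rows(3 * u, 4 * u - 1) = do_ % go % (1.0 - go);
  arma::mat g_lstm_wx = dZ * F.t();
  arma::vec g_lstm_b = arma::sum(dZ, 1);
  arma::mat dF = lstm_wx.t() * dZ;

  arma::mat g_conv_w(nf, k, arma::fill::zeros);
  arma::vec g_conv_b(nf, arma::fill::zeros);
  arma::vec g_bn_gamma(nf, arma::fill::zeros);
  arma::vec g_bn_beta(nf, arma::fill::zeros);
  arma::mat dC(len, m);
  const int ch_per_seg = n_channels;
  for (int q = 0; q < nf; ++q) {
    const double gam = bn_gamma(q);
    const arma::mat& Rq = relu[q];
    const arma::mat& Xh = xhat[q];
    double s_dg = 0.0, s_db = 0.0, s_dx = 0.0, s_dxxh = 0.0;
    // pool/dropout backward into dC (used as dB buffer first)
    for (int j = 0; j < m; ++j) {
      const int seg = j / ch_per_seg;
      const int ch = j % ch_per_seg;
      const double* dfc = dF.colptr(seg) + (size_t)q * rows_per_q +
                          (size_t)ch * len;
      const double* mk = drop ? mask[q].colptr(j) : nullptr;
      const double* rl = Rq.colptr(j);
      double* dcc = dC.colptr(j);
      for (int v = 0; v < len; ++v) dcc[v] = 0.0;
      for (int v = 0; v < len; ++v) {
        double d = dfc[v];
        if (drop) d *= mk[v];
        if (v < len - 1) {
          if (rl[v] >= rl[v + 1]) dcc[v] += d; else dcc[v + 1] += d;
        } else {
          dcc[v] += d; // zero pad never wins against post-ReLU values
        }
      }
      const double* xh = Xh.colptr(j);
      for (int v = 0; v < len; ++v) {
        double d = (rl[v] > 0) ? dcc[v] : 0.0; // ReLU gate
        dcc[v] = d;
        s_dg += d * xh[v];
        s_db += d;
        s_dxxh += d * gam * xh[v];
        s_dx += d * gam;
      }
    }
    g_bn_gamma(q) = s_dg;
    g_bn_beta(q) = s_db;
    const double N = (double)len * m;
    const double mean_dx = s_dx / N;
    const double mean_dxxh = s_dxxh / N;
    const double denom = denoms(q);
    std::vector<double> gwi(k, 0.0);
    double gb = 0.0;
    for (int j = 0; j < m; ++j) {
      double* dcc = dC.colptr(j);
      const double* xh = Xh.colptr(j);
      const double* sp = Spad.colptr(j);
      for (int v = 0; v < len; ++v) {
        const double dxh = dcc[v] * gam;
        double d;
        if (literal) {
          d = dxh / denom - mean_dx / denom - 2.0 * mean_dxxh * xh[v];
        } else {
          d = (dxh - mean_dx - xh[v] * mean_dxxh) / denom;
        }
        dcc[v] = d;
        gb += d;
        const double* z = sp + v;
        for (int i = 0; i < k; ++i) gwi[i] += d * z[i];
      }
    }
    for (int i = 0; i < k; ++i) g_conv_w(q, i) = gwi[i];
    g_conv_b(q) = gb;
  }

  return List::create(
      _["loss"] = loss, _["n_correct"] = correct,
      _["bn_mean_batch"] = bn_mu, _["bn_var_batch"] = bn_v,
      _["g_conv_w"] = g_conv_w, _["g_conv_b"] = g_conv_b,
      _["g_bn_gamma"] = g_bn_gamma, _["g_bn_beta"] = g_bn_beta,
      _["g_lstm_wx"] = g_lstm_wx, _["g_lstm_b"] = g_lstm_b,
      _["g_head_w"] = g_head_w, _["g_head_b"] = g_head_b);
}

// In-place Adam update; caller owns param/m/v exclusively.
// [[Rcpp::export(name = ".cpp_adam_update")]]
void cpp_adam_update(NumericVector param, NumericVector m, NumericVector v,
                     const NumericVector grad, double lr_t, double b1,
                     double b2, double eps) {
  const R_xlen_t n = param.size();
  double* p = REAL(param);
  double* mp = REAL(m);
  double* vp = REAL(v);
  const double* g = REAL(grad);
  for (R_xlen_t j = 0; j < n; ++j) {
    mp[j] = b1 * mp[j] + (1.0 - b1) * g[j];
    vp[j] = b2 * vp[j] + (1.0 - b2) * g[j] * g[j];
    p[j] -= lr_t * mp[j] / (std::sqrt(vp[j]) + eps);
  }
}
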