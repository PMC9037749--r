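// 1D residual convolutional backbone with time-distributed dense head:
// forward pass, backward pass and a fused training step. Single precision
// internally; im2col + GEMM convolutions. Batch activations are (C x L*B)
// matrices, record b occupying columns [b*L, (b+1)*L). Convolutions are
// 'same' (zero padding, left pad (k-1)/2) and never bleed across records.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

static fmat im2col(const fmat& X, int k, int L, int B, int pad) {
  const int C = X.n_rows;
  fmat out(C * k, (size_t)L * B, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    int t0 = std::max(0, pad - o);
    int t1 = std::min(L, L + pad - o);  // exclusive
    if (t1 <= t0) continue;
    for (int b = 0; b < B; ++b) {
      out.submat(o * C, (size_t)b * L + t0, (o + 1) * C - 1,
                 (size_t)b * L + t1 - 1) =
          X.cols((size_t)b * L + t0 + o - pad, (size_t)b * L + t1 - 1 + o - pad);
    }
  }
  return out;
}

static fmat col2im(const fmat& dXcol, int C, int k, int L, int B, int pad) {
  fmat dX(C, (size_t)L * B, arma::fill::zeros);
  for (int o = 0; o < k; ++o) {
    int t0 = std::max(0, pad - o);
    int t1 = std::min(L, L + pad - o);
    if (t1 <= t0) continue;
    for (int b = 0; b < B; ++b) {
      dX.cols((size_t)b * L + t0 + o - pad, (size_t)b * L + t1 - 1 + o - pad) +=
          dXcol.submat(o * C, (size_t)b * L + t0, (o + 1) * C - 1,
                       (size_t)b * L + t1 - 1);
    }
  }
  return dX;
}

struct BNCache { fmat xhat; fvec invstd; };

// Batch norm over all columns (time x batch) per channel row.
static fmat bn_forward(const fmat& X, const fvec& gamma, const fvec& beta,
                       fvec& run_mean, fvec& run_var, bool training,
                       BNCache* cache) {
  const double n = (double)X.n_cols;
  fvec mean_, var_;
  if (training) {
    mean_ = arma::mean(X, 1);
    fmat centered = X.each_col() - mean_;
    var_ = arma::mean(arma::square(centered), 1);
    run_mean = (1.0f - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mean_;
    // unbiased variance for the running estimate
    float ub = (n > 1) ? (float)(n / (n - 1.0)) : 1.0f;
    run_var = (1.0f - BN_MOMENTUM) * run_var + BN_MOMENTUM * (ub * var_);
    fvec invstd = 1.0f / arma::sqrt(var_ + BN_EPS);
    fmat xhat = centered.each_col() % invstd;
    fmat out = (xhat.each_col() % gamma).each_col() + beta;
    if (cache) { cache->xhat = std::move(xhat); cache->invstd = invstd; }
    return out;
  }
  fvec invstd = 1.0f / arma::sqrt(run_var + BN_EPS);
  fmat xhat = (X.each_col() - run_mean).each_col() % invstd;
  return (xhat.each_col() % gamma).each_col() + beta;
}

static fmat bn_backward(const fmat& dY, const BNCache& cache, const fvec& gamma,
                        fvec& dgamma, fvec& dbeta) {
  const float n = (float)dY.n_cols;
  dgamma = arma::sum(dY % cache.xhat, 1);
  dbeta = arma::sum(dY, 1);
  fmat dxhat = dY.each_col() % gamma;
  fvec s1 = arma::sum(dxhat, 1);
  fvec s2 = arma::sum(dxhat % cache.xhat, 1);
  fmat dX = dxhat * n;
  dX.each_col() -= s1;
  dX -= cache.xhat.each_col() % s2;
  dX.each_col() %= (cache.invstd / n);
  return dX;
}

static fmat maxpool2(const fmat& X, int L, int B, arma::umat& argmax) {
  const int C = X.n_rows, Lp = L / 2;
  fmat out(C, (size_t)Lp * B);
  argmax.set_size(C, (size_t)Lp * B);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < Lp; ++j) {
      size_t c0 = (size_t)b * L + 2 * j, c1 = c0 + 1;
      size_t oc = (size_t)b * Lp + j;
      for (int c = 0; c < C; ++c) {
        if (X(c, c0) >= X(c, c1)) { out(c, oc) = X(c, c0); argmax(c, oc) = c0; }
        else { out(c, oc) = X(c, c1); argmax(c, oc) = c1; }
      }
    }
  }
  return out;
}

static fmat maxpool2_backward(const fmat& dY, const arma::umat& argmax,
                              int C, int L, int B) {
  fmat dX(C, (size_t)L * B, arma::fill::zeros);
  for (size_t j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c) dX(c, argmax(c, j)) += dY(c, j);
  return dX;
}

// Nearest-neighbor upsampling by integer factor with right-edge clamping.
static fmat upsample(const fmat& X, int Lin, int B, int Lout, int factor) {
  const int C = X.n_rows;
  fmat out(C, (size_t)Lout * B);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < Lout; ++j)
      out.col((size_t)b * Lout + j) =
          X.col((size_t)b * Lin + std::min(j / factor, Lin - 1));
  return out;
}

static fmat upsample_backward(const fmat& dY, int Lin, int B, int Lout,
                              int factor) {
  const int C = dY.n_rows;
  fmat dX(C, (size_t)Lin * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < Lout; ++j)
      dX.col((size_t)b * Lin + std::min(j / factor, Lin - 1)) +=
          dY.col((size_t)b * Lout + j);
  return dX;
}

static fmat dropout_mask(int rows, size_t cols, double p) {
  fmat m(rows, cols);
  const float scale = 1.0f / (1.0f - (float)p);
  for (size_t j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      m(i, j) = (R::unif_rand() < p) ? 0.0f : scale;
  return m;
}

static fmat as_f(SEXP x) { return arma::conv_to<fmat>::from(as<arma::mat>(x)); }
static fvec as_fv(SEXP x) { return arma::conv_to<fvec>::from(as<arma::vec>(x)); }

static fmat softmax_cols(const fmat& logits) {
  fmat p = logits.each_row() - arma::max(logits, 0);
  p = arma::exp(p);
  p.each_row() /= arma::sum(p, 0);
  return p;
}

struct ForwardState {
  // everything the backward pass needs, per block
  std::vector<fmat> block_in, h1, a1, drop_mask, a1d, h2, pre_relu_mask, pooled_in;
  std::vector<fmat> in_col, a1d_col;  // cached im2col matrices
  std::vector<BNCache> bn1, bn2;
  std::vector<arma::umat> argmax;
  std::vector<int> lens;
  fmat sig, feat_up, concat_in, probs;
  int L, B, C, k, pool, n_blocks, L_final;
};

static void forward_pass(const List& params, List& bn_state, const fmat& sig,
                         const fmat& feats, int n_blocks, int k, int pool,
                         double dropout, bool training, ForwardState& st) {
  const int L = sig.n_rows, B = sig.n_cols;
  const int pad = (k - 1) / 2;
  st.L = L; st.B = B; st.k = k; st.pool = pool; st.n_blocks = n_blocks;
  st.sig = fmat(1, (size_t)L * B);
  for (int b = 0; b < B; ++b)
    st.sig.cols((size_t)b * L, (size_t)(b + 1) * L - 1) =
        arma::conv_to<fmat>::from(sig.col(b).t());

  fmat W0 = as_f(params["conv0_W"]);
  fvec b0 = as_fv(params["conv0_b"]);
  const int C = W0.n_rows;
  st.C = C;
  st.sig = im2col(st.sig, k, L, B, pad);  // conv0 backward reuses this
  fmat z = W0 * st.sig;
  z.each_col() += b0;

  int Lc = L;
  st.block_in.resize(n_blocks); st.h1.resize(n_blocks); st.a1.resize(n_blocks);
  st.drop_mask.resize(n_blocks); st.a1d.resize(n_blocks); st.h2.resize(n_blocks);
  st.pre_relu_mask.resize(n_blocks); st.pooled_in.resize(n_blocks);
  st.bn1.resize(n_blocks); st.bn2.resize(n_blocks);
  st.argmax.resize(n_blocks); st.lens.resize(n_blocks);
  st.in_col.resize(n_blocks); st.a1d_col.resize(n_blocks);

  for (int i = 0; i < n_blocks; ++i) {
    std::string p = "b" + std::to_string(i + 1) + "_";
    st.lens[i] = Lc;
    st.block_in[i] = z;
    fmat W1 = as_f(params[p + "W1"]); fvec bb1 = as_fv(params[p + "b1"]);
    fmat W2 = as_f(params[p + "W2"]); fvec bb2 = as_fv(params[p + "b2"]);
    fvec g1 = as_fv(params[p + "g1"]), be1 = as_fv(params[p + "be1"]);
    fvec g2 = as_fv(params[p + "g2"]), be2 = as_fv(params[p + "be2"]);
    fvec rm1 = as_fv(bn_state[p + "rm1"]), rv1 = as_fv(bn_state[p + "rv1"]);
    fvec rm2 = as_fv(bn_state[p + "rm2"]), rv2 = as_fv(bn_state[p + "rv2"]);

    st.in_col[i] = im2col(z, k, Lc, B, pad);
    fmat h = W1 * st.in_col[i];
    h.each_col() += bb1;
    st.h1[i] = h;
    h = bn_forward(h, g1, be1, rm1, rv1, training, training ? &st.bn1[i] : nullptr);
    h = arma::clamp(h, 0.0f, arma::datum::inf);  // ReLU
    st.a1[i] = h;
    if (training && dropout > 0) {
      st.drop_mask[i] = dropout_mask(h.n_rows, h.n_cols, dropout);
      h %= st.drop_mask[i];
    }
    st.a1d[i] = h;
    st.a1d_col[i] = im2col(h, k, Lc, B, pad);
    fmat h2 = W2 * st.a1d_col[i];
    h2.each_col() += bb2;
    st.h2[i] = h2;
    h2 = bn_forward(h2, g2, be2, rm2, rv2, training, training ? &st.bn2[i] : nullptr);
    fmat merged = h2 + z;
    st.pre_relu_mask[i] = arma::conv_to<fmat>::from(merged > 0.0f);
    merged = arma::clamp(merged, 0.0f, arma::datum::inf);
    st.pooled_in[i] = merged;
    z = maxpool2(merged, Lc, B, st.argmax[i]);
    Lc /= pool;
    if (training) {
      bn_state[p + "rm1"] = NumericVector(rm1.begin(), rm1.end());
      bn_state[p + "rv1"] = NumericVector(rv1.begin(), rv1.end());
      bn_state[p + "rm2"] = NumericVector(rm2.begin(), rm2.end());
      bn_state[p + "rv2"] = NumericVector(rv2.begin(), rv2.end());
    }
  }
  st.L_final = Lc;
  int factor = 1;
  for (int i = 0; i < n_blocks; ++i) factor *= pool;
  st.feat_up = upsample(z, Lc, B, L, factor);

  st.concat_in = arma::join_cols(st.feat_up, feats);
  fmat Wh = as_f(params["head_W"]);
  fvec bh = as_fv(params["head_b"]);
  fmat logits = Wh * st.concat_in;
  logits.each_col() += bh;
  st.probs = softmax_cols(logits);
}

static List backward_pass(const List& params, const ForwardState& st,
                          const fmat& dprobs) {
  const int L = st.L, B = st.B, C = st.C, k = st.k, pool = st.pool;
  const int pad = (k - 1) / 2;
  List grads;

  // softmax backward: dlogits = P .* (dP - colsum(P .* dP))
  fmat pdp = st.probs % dprobs;
  arma::frowvec s = arma::sum(pdp, 0);
  fmat dlogits = pdp - (st.probs.each_row() % s);

  fmat Wh = as_f(params["head_W"]);
  grads["head_W"] = wrap(arma::conv_to<arma::mat>::from(dlogits * st.concat_in.t()));
  fvec dbh = arma::sum(dlogits, 1);
  grads["head_b"] = NumericVector(dbh.begin(), dbh.end());
  fmat dconcat = Wh.t() * dlogits;
  fmat dfeat_up = dconcat.rows(0, C - 1);  // knowledge rows carry no params

  int factor = 1;
  for (int i = 0; i < st.n_blocks; ++i) factor *= pool;
  fmat dz = upsample_backward(dfeat_up, st.L_final, B, L, factor);

  for (int i = st.n_blocks - 1; i >= 0; --i) {
    std::string p = "b" + std::to_string(i + 1) + "_";
    const int Lc = st.lens[i];
    fmat W1 = as_f(params[p + "W1"]), W2 = as_f(params[p + "W2"]);
    fvec g1 = as_fv(params[p + "g1"]), g2 = as_fv(params[p + "g2"]);

    fmat dmerged = maxpool2_backward(dz, st.argmax[i], C, Lc, B);
    dmerged %= st.pre_relu_mask[i];
    // residual: merged = bn2(conv2(...)) + block_in
    fmat dh2bn = dmerged;  // toward conv2 branch
    fvec dg2, dbe2;
    fmat dh2 = bn_backward(dh2bn, st.bn2[i], g2, dg2, dbe2);
    grads[p + "g2"] = NumericVector(dg2.begin(), dg2.end());
    grads[p + "be2"] = NumericVector(dbe2.begin(), dbe2.end());

    grads[p + "W2"] = wrap(arma::conv_to<arma::mat>::from(dh2 * st.a1d_col[i].t()));
    fvec db2 = arma::sum(dh2, 1);
    grads[p + "b2"] = NumericVector(db2.begin(), db2.end());
    fmat da1d = col2im(W2.t() * dh2, C, k, Lc, B, pad);

    if (st.drop_mask[i].n_elem) da1d %= st.drop_mask[i];
    da1d %= arma::conv_to<fmat>::from(st.a1[i] > 0.0f);  // ReLU backward
    fvec dg1, dbe1;
    fmat dh1 = bn_backward(da1d, st.bn1[i], g1, dg1, dbe1);
    grads[p + "g1"] = NumericVector(dg1.begin(), dg1.end());
    grads[p + "be1"] = NumericVector(dbe1.begin(), dbe1.end());

    grads[p + "W1"] = wrap(arma::conv_to<arma::mat>::from(dh1 * st.in_col[i].t()));
    fvec db1 = arma::sum(dh1, 1);
    grads[p + "b1"] = NumericVector(db1.begin(), db1.end());

    dz = col2im(W1.t() * dh1, C, k, Lc, B, pad) + dmerged;  // + skip path
  }

  grads["conv0_W"] = wrap(arma::conv_to<arma::mat>::from(dz * st.sig.t()));
  fvec db0 = arma::sum(dz, 1);
  grads["conv0_b"] = NumericVector(db0.begin(), db0.end());
  return grads;
}

// [[Rcpp::export]]
List nn_forward_cpp(List params, List bn_state, arma::mat sig, arma::mat feats,
                    int n_blocks, int kernel_len, int pool) {
  ForwardState st;
  forward_pass(params, bn_state, arma::conv_to<fmat>::from(sig),
               arma::conv_to<fmat>::from(feats), n_blocks, kernel_len, pool,
               0.0, false, st);
  return List::create(
      _["probs"] = wrap(arma::conv_to<arma::mat>::from(st.probs)));
}

// Fused training step: forward (training mode), R callback computing the
// loss and its gradient w.r.t. the local probabilities, then backward.
// [[Rcpp::export]]
List nn_train_step_cpp(List params, List bn_state, arma::mat sig,
                       arma::mat feats, Function loss_grad_fn, int n_blocks,
                       int kernel_len, int pool, double dropout) {
  ForwardState st;
  forward_pass(params, bn_state, arma::conv_to<fmat>::from(sig),
               arma::conv_to<fmat>::from(feats), n_blocks, kernel_len, pool,
               dropout, true, st);
  List lg = loss_grad_fn(wrap(arma::conv_to<arma::mat>::from(st.probs)));
  fmat dprobs = as_f(lg["dprobs"]);
  List grads = backward_pass(params, st, dprobs);
  return List::create(_["grads"] = grads, _["loss"] = lg["loss"],
                      _["bn_state"] = bn_state);
}
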