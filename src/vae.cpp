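// Sequence VAE: character embedding -> bidirectional LSTM encoder -> Gaussian
// latent layer -> repeat-vector LSTM decoder -> per-position softmax.
// Forward, loss and analytic backpropagation; all randomness (reparameterization
// noise, recurrent dropout masks) is drawn in R and passed in, so the C++ side
// is a pure function and the whole pipeline is seeded from one master seed.
//
// Parameter list layout (all arma::mat):
//   Emb  (V x E)                  character embedding, V = alphabet + pad
//   Wx_f, Wh_f, b_f               forward-direction encoder LSTM (E x 4H, H x 4H, 1 x 4H)
//   Wx_b, Wh_b, b_b               backward-direction encoder LSTM
//   W_mu (2H x L), b_mu (1 x L)   latent mean head
//   W_lv (2H x L), b_lv (1 x L)   latent log-variance head
//   Wx_d (L x 4H), Wh_d, b_d      decoder LSTM fed the repeated latent vector
//   W_out (H x V), b_out (1 x V)  per-position projection to character logits
// Gate order inside the 4H blocks: input, forget, output, cell candidate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct LstmCache {
  cube i, f, o, g, c, tc, h; // B x H x T, indexed by processing step
  void init(uword B, uword H, uword T) {
    i.set_size(B, H, T); f.set_size(B, H, T); o.set_size(B, H, T);
    g.set_size(B, H, T); c.set_size(B, H, T); tc.set_size(B, H, T);
    h.set_size(B, H, T);
  }
};

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// one LSTM step; mask is the (variational) recurrent dropout mask on h_prev.
// xa is the precomputed input contribution x_t * Wx (input-side GEMMs are
// hoisted out of the time loop and batched — for the repeat-vector decoder
// the single product z * Wx serves every step).
static void lstm_step_pre(const mat& xa, const mat& h_prev, const mat& c_prev,
                          const mat& mask, const mat& Wh,
                          const rowvec& b, uword s, LstmCache& cc) {
  const uword H = Wh.n_rows;
  mat a = xa + (h_prev % mask) * Wh;
  a.each_row() += b;
  cc.i.slice(s) = sigmoid(a.cols(0, H - 1));
  cc.f.slice(s) = sigmoid(a.cols(H, 2 * H - 1));
  cc.o.slice(s) = sigmoid(a.cols(2 * H, 3 * H - 1));
  cc.g.slice(s) = tanh(a.cols(3 * H, 4 * H - 1));
  cc.c.slice(s) = cc.f.slice(s) % c_prev + cc.i.slice(s) % cc.g.slice(s);
  cc.tc.slice(s) = tanh(cc.c.slice(s));
  cc.h.slice(s) = cc.o.slice(s) % cc.tc.slice(s);
}

// backward through one step. dh/dc carry the running gradients; on exit they
// hold gradients wrt h_{s-1} (mask applied) and c_{s-1}. The pre-activation
// gradient is stored in dA (slice s); input-weight gradients and dx are
// batched into single GEMMs by the caller after the loop.
static void lstm_back_step(const mat& h_prev_masked, const mat& c_prev,
                           const mat& mask, const mat& Wh, uword s,
                           const LstmCache& cc, cube& dA,
                           mat& dh, mat& dc, mat& dWh, rowvec& db) {
  const mat& i = cc.i.slice(s); const mat& f = cc.f.slice(s);
  const mat& o = cc.o.slice(s); const mat& g = cc.g.slice(s);
  const mat& tc = cc.tc.slice(s);
  mat do_ = dh % tc;
  dc += dh % o % (1.0 - tc % tc);
  mat di = dc % g;
  mat dg = dc % i;
  mat df = dc % c_prev;
  mat dc_prev = dc % f;
  mat da = join_rows(join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
                     join_rows(do_ % o % (1.0 - o), dg % (1.0 - g % g)));
  dA.slice(s) = da;
  dWh += h_prev_masked.t() * da;
  db += sum(da, 0);
  dh = (da * Wh.t()) % mask;
  dc = dc_prev;
}

// [[Rcpp::export]]
List cpp_vae_loss_grad(const List& W, const IntegerMatrix& Xr,
                       const NumericMatrix& epsR, double kl_weight,
                       const NumericMatrix& mask_fR,
                       const NumericMatrix& mask_bR,
                       const NumericMatrix& mask_dR,
                       bool want_grad) {
  const mat Emb = W["Emb"];
  const mat Wx_f = W["Wx_f"], Wh_f = W["Wh_f"];
  const mat Wx_b = W["Wx_b"], Wh_b = W["Wh_b"];
  const rowvec b_f = as<rowvec>(W["b_f"]), b_b = as<rowvec>(W["b_b"]);
  const mat W_mu = W["W_mu"], W_lv = W["W_lv"];
  const rowvec b_mu = as<rowvec>(W["b_mu"]), b_lv = as<rowvec>(W["b_lv"]);
  const mat Wx_d = W["Wx_d"], Wh_d = W["Wh_d"];
  const rowvec b_d = as<rowvec>(W["b_d"]);
  const mat W_out = W["W_out"];
  const rowvec b_out = as<rowvec>(W["b_out"]);

  const uword B = Xr.nrow(), T = Xr.ncol();
  const uword V = Emb.n_rows, E = Emb.n_cols;
  const uword H = Wh_f.n_rows, L = W_mu.n_cols;

  umat X(B, T);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < T; ++t) {
      int code = Xr(b, t);
      if (code < 0 || (uword)code >= V) stop("code out of range at (%d,%d)", b + 1, t + 1);
      X(b, t) = (uword)code;
    }
  const mat eps = as<mat>(epsR);
  const mat mask_f = as<mat>(mask_fR), mask_b = as<mat>(mask_bR),
            mask_d = as<mat>(mask_dR);

  // embedded inputs, stacked (T*B x E) for one batched input GEMM
  mat xstack(T * B, E);
  for (uword t = 0; t < T; ++t) xstack.rows(t * B, t * B + B - 1) = Emb.rows(X.col(t));
  mat xa_f = xstack * Wx_f; // T*B x 4H, rows [tB, tB+B) belong to step t
  mat xa_b = xstack * Wx_b;

  // encoder, both directions (backward direction processes t = T-1 .. 0)
  LstmCache enc_f, enc_b;
  enc_f.init(B, H, T); enc_b.init(B, H, T);
  mat h0(B, H, fill::zeros), c0(B, H, fill::zeros);
  {
    mat hp = h0, cp = c0;
    for (uword s = 0; s < T; ++s) {
      lstm_step_pre(xa_f.rows(s * B, s * B + B - 1), hp, cp, mask_f, Wh_f,
                    b_f, s, enc_f);
      hp = enc_f.h.slice(s); cp = enc_f.c.slice(s);
    }
  }
  {
    mat hp = h0, cp = c0;
    for (uword s = 0; s < T; ++s) {
      uword t = T - 1 - s;
      lstm_step_pre(xa_b.rows(t * B, t * B + B - 1), hp, cp, mask_b, Wh_b,
                    b_b, s, enc_b);
      hp = enc_b.h.slice(s); cp = enc_b.c.slice(s);
    }
  }
  mat hcat = join_rows(enc_f.h.slice(T - 1), enc_b.h.slice(T - 1)); // B x 2H

  mat mu = hcat * W_mu;  mu.each_row() += b_mu;
  mat lv = hcat * W_lv;  lv.each_row() += b_lv;
  mat sd = exp(0.5 * lv);
  mat z = mu + sd % eps; // B x L

  // decoder: the latent point is the input at every time step, so its input
  // contribution is a single GEMM reused at each step
  LstmCache dec;
  dec.init(B, H, T);
  mat za = z * Wx_d;
  {
    mat hp = h0, cp = c0;
    for (uword s = 0; s < T; ++s) {
      lstm_step_pre(za, hp, cp, mask_d, Wh_d, b_d, s, dec);
      hp = dec.h.slice(s); cp = dec.c.slice(s);
    }
  }

  // per-position softmax cross-entropy; probabilities kept for the backward pass
  cube P(B, V, T);
  double recon = 0.0;
  for (uword s = 0; s < T; ++s) {
    mat logits = dec.h.slice(s) * W_out;
    logits.each_row() += b_out;
    vec m = max(logits, 1);
    logits.each_col() -= m;
    mat ex = exp(logits);
    vec Z = sum(ex, 1);
    P.slice(s) = ex.each_col() / Z;
    for (uword b = 0; b < B; ++b) {
      recon -= logits(b, X(b, s)) - std::log(Z(b));
    }
  }
  recon /= (double)B;

  double kl = 0.5 * accu(square(mu) + exp(lv) - 1.0 - lv) / (double)B;
  double total = recon + kl_weight * kl;

  List out = List::create(_["total"] = total, _["recon"] = recon, _["kl"] = kl);
  if (!want_grad) return out;

  // ---- backward ----
  mat dEmb(V, E, fill::zeros);
  mat dWx_f(size(Wx_f), fill::zeros), dWh_f(size(Wh_f), fill::zeros);
  mat dWx_b(size(Wx_b), fill::zeros), dWh_b(size(Wh_b), fill::zeros);
  rowvec db_f(4 * H, fill::zeros), db_b(4 * H, fill::zeros);
  mat dW_mu(size(W_mu), fill::zeros), dW_lv(size(W_lv), fill::zeros);
  rowvec db_mu(L, fill::zeros), db_lv(L, fill::zeros);
  mat dWx_d(size(Wx_d), fill::zeros), dWh_d(size(Wh_d), fill::zeros);
  rowvec db_d(4 * H, fill::zeros);
  mat dW_out(size(W_out), fill::zeros);
  rowvec db_out(V, fill::zeros);

  // decoder BPTT; pre-activation grads collected, then one GEMM each for the
  // input-weight gradient and the gradient on z
  mat dz(B, L, fill::zeros);
  {
    cube dA(B, 4 * H, T);
    mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
    for (uword s = T; s-- > 0;) {
      mat dlogits = P.slice(s);
      for (uword b = 0; b < B; ++b) dlogits(b, X(b, s)) -= 1.0;
      dlogits /= (double)B;
      dW_out += dec.h.slice(s).t() * dlogits;
      db_out += sum(dlogits, 0);
      dh += dlogits * W_out.t();
      mat h_prev = (s == 0) ? h0 : dec.h.slice(s - 1);
      mat c_prev = (s == 0) ? c0 : dec.c.slice(s - 1);
      lstm_back_step(h_prev % mask_d, c_prev, mask_d, Wh_d, s, dec, dA,
                     dh, dc, dWh_d, db_d);
    }
    mat dA_sum(B, 4 * H, fill::zeros);
    for (uword s = 0; s < T; ++s) dA_sum += dA.slice(s);
    dWx_d = z.t() * dA_sum;
    dz = dA_sum * Wx_d.t();
  }

  // latent heads: reparameterization + KL
  mat dmu = dz + kl_weight * mu / (double)B;
  mat dlv = dz % eps % (0.5 * sd) + kl_weight * 0.5 * (exp(lv) - 1.0) / (double)B;
  dW_mu = hcat.t() * dmu;  db_mu = sum(dmu, 0);
  dW_lv = hcat.t() * dlv;  db_lv = sum(dlv, 0);
  mat dhcat = dmu * W_mu.t() + dlv * W_lv.t(); // B x 2H

  // encoder BPTT, forward direction (gradient enters at final step only);
  // pre-activation grads stacked so dWx and dx are single GEMMs
  mat dxstack(T * B, E, fill::zeros); // accumulated input grads by time step
  {
    cube dA(B, 4 * H, T);
    mat dh = dhcat.cols(0, H - 1), dc(B, H, fill::zeros);
    for (uword s = T; s-- > 0;) {
      mat h_prev = (s == 0) ? h0 : enc_f.h.slice(s - 1);
      mat c_prev = (s == 0) ? c0 : enc_f.c.slice(s - 1);
      lstm_back_step(h_prev % mask_f, c_prev, mask_f, Wh_f, s, enc_f, dA,
                     dh, dc, dWh_f, db_f);
    }
    mat dA_stack(T * B, 4 * H);
    for (uword s = 0; s < T; ++s) dA_stack.rows(s * B, s * B + B - 1) = dA.slice(s);
    dWx_f = xstack.t() * dA_stack;
    dxstack += dA_stack * Wx_f.t();
  }
  // backward direction (processing step s corresponds to input t = T-1-s)
  {
    cube dA(B, 4 * H, T);
    mat dh = dhcat.cols(H, 2 * H - 1), dc(B, H, fill::zeros);
    for (uword s = T; s-- > 0;) {
      mat h_prev = (s == 0) ? h0 : enc_b.h.slice(s - 1);
      mat c_prev = (s == 0) ? c0 : enc_b.c.slice(s - 1);
      lstm_back_step(h_prev % mask_b, c_prev, mask_b, Wh_b, s, enc_b, dA,
                     dh, dc, dWh_b, db_b);
    }
    mat dA_stack(T * B, 4 * H); // reordered to input time t = T-1-s
    for (uword s = 0; s < T; ++s) {
      uword t = T - 1 - s;
      dA_stack.rows(t * B, t * B + B - 1) = dA.slice(s);
    }
    dWx_b = xstack.t() * dA_stack;
    dxstack += dA_stack * Wx_b.t();
  }
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < B; ++b)
      dEmb.row(X(b, t)) += dxstack.row(t * B + b);

  out["grads"] = List::create(
      _["Emb"] = dEmb, _["Wx_f"] = dWx_f, _["Wh_f"] = dWh_f, _["b_f"] = db_f,
      _["Wx_b"] = dWx_b, _["Wh_b"] = dWh_b, _["b_b"] = db_b,
      _["W_mu"] = dW_mu, _["b_mu"] = db_mu, _["W_lv"] = dW_lv, _["b_lv"] = db_lv,
      _["Wx_d"] = dWx_d, _["Wh_d"] = dWh_d, _["b_d"] = db_d,
      _["W_out"] = dW_out, _["b_out"] = db_out);
  return out;
}

// Encoder at inference (dropout off): returns the latent mean and log-variance.
// [[Rcpp::export]]
List cpp_vae_encode(const List& W, const IntegerMatrix& Xr) {
  const mat Emb = W["Emb"];
  const mat Wx_f = W["Wx_f"], Wh_f = W["Wh_f"];
  const mat Wx_b = W["Wx_b"], Wh_b = W["Wh_b"];
  const rowvec b_f = as<rowvec>(W["b_f"]), b_b = as<rowvec>(W["b_b"]);
  const mat W_mu = W["W_mu"], W_lv = W["W_lv"];
  const rowvec b_mu = as<rowvec>(W["b_mu"]), b_lv = as<rowvec>(W["b_lv"]);
  const uword B = Xr.nrow(), T = Xr.ncol(), V = Emb.n_rows, H = Wh_f.n_rows;

  umat X(B, T);
  for (uword b = 0; b < B; ++b)
    for (uword t = 0; t < T; ++t) {
      int code = Xr(b, t);
      if (code < 0 || (uword)code >= V) stop("code out of range");
      X(b, t) = (uword)code;
    }
  const uword E = Emb.n_cols;
  mat xstack(T * B, E);
  for (uword t = 0; t < T; ++t) xstack.rows(t * B, t * B + B - 1) = Emb.rows(X.col(t));
  mat xa_f = xstack * Wx_f;
  mat xa_b = xstack * Wx_b;
  mat ones_mask(B, H, fill::ones);
  mat h0(B, H, fill::zeros), c0(B, H, fill::zeros);
  LstmCache enc_f, enc_b;
  enc_f.init(B, H, T); enc_b.init(B, H, T);
  mat hp = h0, cp = c0;
  for (uword s = 0; s < T; ++s) {
    lstm_step_pre(xa_f.rows(s * B, s * B + B - 1), hp, cp, ones_mask, Wh_f,
                  b_f, s, enc_f);
    hp = enc_f.h.slice(s); cp = enc_f.c.slice(s);
  }
  hp = h0; cp = c0;
  for (uword s = 0; s < T; ++s) {
    uword t = T - 1 - s;
    lstm_step_pre(xa_b.rows(t * B, t * B + B - 1), hp, cp, ones_mask, Wh_b,
                  b_b, s, enc_b);
    hp = enc_b.h.slice(s); cp = enc_b.c.slice(s);
  }
  mat hcat = join_rows(enc_f.h.slice(T - 1), enc_b.h.slice(T - 1));
  mat mu = hcat * W_mu;  mu.each_row() += b_mu;
  mat lv = hcat * W_lv;  lv.each_row() += b_lv;
  return List::create(_["mean"] = mu, _["log_variance"] = lv);
}

// Decoder at inference: repeat each latent point T times through the LSTM and
// project to per-position character distributions. Returns 0-based argmax
// codes (B x T) and, optionally, the full probability array (T x V x B).
// [[Rcpp::export]]
List cpp_vae_decode(const List& W, const NumericMatrix& Zr, int T_out,
                    bool want_probs) {
  const mat Wx_d = W["Wx_d"], Wh_d = W["Wh_d"];
  const rowvec b_d = as<rowvec>(W["b_d"]);
  const mat W_out = W["W_out"];
  const rowvec b_out = as<rowvec>(W["b_out"]);
  const mat z = as<mat>(Zr);
  const uword B = z.n_rows, H = Wh_d.n_rows, V = W_out.n_cols, T = (uword)T_out;

  mat ones_mask(B, H, fill::ones);
  mat hp(B, H, fill::zeros), cp(B, H, fill::zeros);
  LstmCache dec;
  dec.init(B, H, T);
  IntegerMatrix codes((int)B, (int)T);
  cube P;
  if (want_probs) P.set_size(T, V, B);
  mat za = z * Wx_d;
  for (uword s = 0; s < T; ++s) {
    lstm_step_pre(za, hp, cp, ones_mask, Wh_d, b_d, s, dec);
    hp = dec.h.slice(s); cp = dec.c.slice(s);
    mat logits = hp * W_out;
    logits.each_row() += b_out;
    vec m = max(logits, 1);
    logits.each_col() -= m;
    mat ex = exp(logits);
    vec Z = sum(ex, 1);
    mat probs = ex.each_col() / Z;
    for (uword b = 0; b < B; ++b) {
      codes((int)b, (int)s) = (int)index_max(probs.row(b));
      if (want_probs) P.slice(b).row(s) = probs.row(b);
    }
  }
  List out = List::create(_["codes"] = codes);
  if (want_probs) out["probs"] = P;
  return out;
}
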