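// Fast forward/backward core for the sequential variational autoencoder.
// Mirrors the reference R implementation (R/dynamics.R) exactly; the test
// suite asserts bit-level agreement of losses and gradients between the two
// paths and against a numerical-gradient oracle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double LOGVAR_CLAMP = 8.0;
const double LOGRATE_CLAMP = 12.0;

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruParams {
  mat Wx, Wh;
  rowvec b;
};

GruParams gru_from_list(const Rcpp::List& l) {
  GruParams p;
  p.Wx = Rcpp::as<mat>(l["Wx"]);
  p.Wh = Rcpp::as<mat>(l["Wh"]);
  p.b = Rcpp::as<rowvec>(l["b"]);
  return p;
}

struct GruCache {
  mat X, Hprev, r, z, n, Ahn;
};

struct GruGrads {
  mat dWx, dWh;
  rowvec db;
  void init(const GruParams& p) {
    dWx = zeros<mat>(p.Wx.n_rows, p.Wx.n_cols);
    dWh = zeros<mat>(p.Wh.n_rows, p.Wh.n_cols);
    db = zeros<rowvec>(p.b.n_elem);
  }
  Rcpp::List to_list() const {
    return Rcpp::List::create(Rcpp::Named("Wx") = dWx,
                              Rcpp::Named("Wh") = dWh,
                              Rcpp::Named("b") = db);
  }
};

mat gru_step(const GruParams& p, const mat& X, const mat& Hprev,
             GruCache& c) {
  const uword H = Hprev.n_cols;
  mat A = X * p.Wx;
  A.each_row() += p.b;
  mat Ah = Hprev * p.Wh;
  mat r = sigmoid(A.cols(0, H - 1) + Ah.cols(0, H - 1));
  mat z = sigmoid(A.cols(H, 2 * H - 1) + Ah.cols(H, 2 * H - 1));
  mat Ahn = Ah.cols(2 * H, 3 * H - 1);
  mat n = tanh(A.cols(2 * H, 3 * H - 1) + r % Ahn);
  c.X = X; c.Hprev = Hprev; c.r = r; c.z = z; c.n = n; c.Ahn = Ahn;
  return (1.0 - z) % n + z % Hprev;
}

// returns dX, accumulates dHprev into dHprev_out and grads into g
mat gru_step_backward(const GruParams& p, const GruCache& c, const mat& dH,
                      GruGrads& g, mat& dHprev_out) {
  mat dz = dH % (c.Hprev - c.n);
  mat dn = dH % (1.0 - c.z);
  mat dHprev = dH % c.z;
  mat dpre_n = dn % (1.0 - square(c.n));
  mat dr = dpre_n % c.Ahn;
  mat dAh_n = dpre_n % c.r;
  mat dpre_r = dr % c.r % (1.0 - c.r);
  mat dpre_z = dz % c.z % (1.0 - c.z);
  mat dA = join_rows(dpre_r, dpre_z, dpre_n);
  mat dAh = join_rows(dpre_r, dpre_z, dAh_n);
  g.dWx += c.X.t() * dA;
  g.db += sum(dA, 0);
  g.dWh += c.Hprev.t() * dAh;
  dHprev_out = dHprev + dAh * p.Wh.t();
  return dA * p.Wx.t();
}

mat clamp_mask(const mat& x, double lim, mat& mask) {
  mask = conv_to<mat>::from((x > -lim) % (x < lim));
  return clamp(x, -lim, lim);
}

} // namespace

// Full forward pass (and optionally backward) over one batch.
// X: B x n_in x T cube; S: B x n_out x T cube (empty => no loss/grad).
// eps_ic: B x ic_dim; eps_co: B x co_dim x T (zero matrices for
// posterior-mean passes). Returns loss components, optionally per-step
// outputs, and optionally gradients mirroring the parameter list.
// [[Rcpp::export]]
Rcpp::List vae_core(Rcpp::List params, Rcpp::List dims, arma::cube X,
                    arma::cube S, arma::mat eps_ic, arma::cube eps_co,
                    double kl_ic_w, double kl_co_w, double l2_gen,
                    double l2_con, bool want_grad, bool want_outputs) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword E = dims["encoder_dim"];
  const uword G = dims["generator_dim"];
  const uword Fd = dims["factor_dim"];
  const uword cc = dims["co_dim"];
  const uword icd = dims["ic_dim"];
  const uword n_out = dims["n_out"];
  const bool have_S = S.n_elem > 0;

  GruParams enc_f = gru_from_list(params["enc_f"]);
  GruParams enc_b = gru_from_list(params["enc_b"]);
  GruParams gen = gru_from_list(params["gen"]);
  mat W_icm = Rcpp::as<mat>(params["W_icm"]);
  rowvec b_icm = Rcpp::as<rowvec>(params["b_icm"]);
  mat W_icv = Rcpp::as<mat>(params["W_icv"]);
  rowvec b_icv = Rcpp::as<rowvec>(params["b_icv"]);
  mat W_g0 = Rcpp::as<mat>(params["W_g0"]);
  rowvec b_g0 = Rcpp::as<rowvec>(params["b_g0"]);
  mat W_fac = Rcpp::as<mat>(params["W_fac"]);
  mat W_rate = Rcpp::as<mat>(params["W_rate"]);
  rowvec b_rate = Rcpp::as<rowvec>(params["b_rate"]);
  GruParams con;
  mat W_com, W_cov;
  rowvec b_com, b_cov;
  if (cc > 0) {
    con = gru_from_list(params["con"]);
    W_com = Rcpp::as<mat>(params["W_com"]);
    b_com = Rcpp::as<rowvec>(params["b_com"]);
    W_cov = Rcpp::as<mat>(params["W_cov"]);
    b_cov = Rcpp::as<rowvec>(params["b_cov"]);
  }

  // ---- encoder ----
  std::vector<mat> hf(T), hb(T);
  std::vector<GruCache> cf(T), cb(T);
  mat h = zeros<mat>(B, E);
  for (uword t = 0; t < T; ++t) h = hf[t] = gru_step(enc_f, X.slice(t), h, cf[t]);
  h = zeros<mat>(B, E);
  for (uword t = T; t-- > 0;) h = hb[t] = gru_step(enc_b, X.slice(t), h, cb[t]);

  mat icin = join_rows(hf[T - 1], hb[0]);
  mat ic_mean = icin * W_icm;
  ic_mean.each_row() += b_icm;
  mat lv_raw = icin * W_icv;
  lv_raw.each_row() += b_icv;
  mat lv_mask;
  mat lv_ic = clamp_mask(lv_raw, LOGVAR_CLAMP, lv_mask);
  mat ic = ic_mean + exp(0.5 * lv_ic) % eps_ic;
  mat g0_pre = ic * W_g0;
  g0_pre.each_row() += b_g0;
  mat g0 = tanh(g0_pre);
  mat f0 = g0 * W_fac;

  // ---- controller + generator ----
  std::vector<mat> gstate(T), fac(T), logr(T), rmask(T);
  std::vector<GruCache> cgen(T), ccon(T);
  std::vector<mat> cstate(T), co_mean(T), lvco(T), lvco_mask(T), u_all(T);
  mat g_prev = g0, f_prev = f0;
  mat c_prev;
  if (cc > 0) c_prev = zeros<mat>(B, (uword) dims["controller_dim"]);
  double kl_co = 0.0;
  for (uword t = 0; t < T; ++t) {
    mat u;
    if (cc > 0) {
      mat con_in = join_rows(hf[t], hb[t], f_prev);
      c_prev = gru_step(con, con_in, c_prev, ccon[t]);
      cstate[t] = c_prev;
      mat mu = c_prev * W_com;
      mu.each_row() += b_com;
      mat lvr = c_prev * W_cov;
      lvr.each_row() += b_cov;
      mat msk;
      mat lv = clamp_mask(lvr, LOGVAR_CLAMP, msk);
      u = mu + exp(0.5 * lv) % eps_co.slice(t);
      co_mean[t] = mu; lvco[t] = lv; lvco_mask[t] = msk;
      kl_co += 0.5 * accu(square(mu) + exp(lv) - 1.0 - lv);
    } else {
      u = zeros<mat>(B, 0);
    }
    u_all[t] = u;
    g_prev = gru_step(gen, u, g_prev, cgen[t]);
    gstate[t] = g_prev;
    f_prev = g_prev * W_fac;
    fac[t] = f_prev;
    mat lr_raw = f_prev * W_rate;
    lr_raw.each_row() += b_rate;
    mat msk;
    logr[t] = clamp_mask(lr_raw, LOGRATE_CLAMP, msk);
    rmask[t] = msk;
  }

  double kl_ic = 0.5 * accu(square(ic_mean) + exp(lv_ic) - 1.0 - lv_ic);
  double l2 = 0.5 * (l2_gen * accu(square(gen.Wh)) +
                     (cc > 0 ? l2_con * accu(square(con.Wh)) : 0.0));
  double recon = NA_REAL, loss = NA_REAL;
  if (have_S) {
    recon = 0.0;
    for (uword t = 0; t < T; ++t) {
      recon += accu(exp(logr[t]) - S.slice(t) % logr[t] +
                    lgamma(S.slice(t) + 1.0));
    }
    recon /= B;
    loss = recon + kl_ic_w * kl_ic / B + kl_co_w * kl_co / B + l2;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("recon") = recon,
      Rcpp::Named("kl_ic") = kl_ic / B, Rcpp::Named("kl_co") = kl_co / B,
      Rcpp::Named("l2") = l2);

  if (want_outputs) {
    cube logr_c(B, n_out, T), fac_c(B, Fd, T);
    cube co_c(B, cc > 0 ? cc : 1, T, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      logr_c.slice(t) = logr[t];
      fac_c.slice(t) = fac[t];
      if (cc > 0) co_c.slice(t) = co_mean[t];
    }
    out["logr"] = logr_c;
    out["factors"] = fac_c;
    out["co_mean"] = co_c;
    out["ic_mean"] = ic_mean;
    out["ic_logvar"] = lv_ic;
  }

  if (!want_grad) return out;
  if (!have_S) Rcpp::stop("vae_core: gradients require targets");

  // ---- backward ----
  GruGrads g_enc_f, g_enc_b, g_gen, g_con;
  g_enc_f.init(enc_f); g_enc_b.init(enc_b); g_gen.init(gen);
  if (cc > 0) g_con.init(con);
  mat dW_icm = zeros<mat>(W_icm.n_rows, W_icm.n_cols);
  rowvec db_icm = zeros<rowvec>(b_icm.n_elem);
  mat dW_icv = zeros<mat>(W_icv.n_rows, W_icv.n_cols);
  rowvec db_icv = zeros<rowvec>(b_icv.n_elem);
  mat dW_g0 = zeros<mat>(W_g0.n_rows, W_g0.n_cols);
  rowvec db_g0 = zeros<rowvec>(b_g0.n_elem);
  mat dW_fac = zeros<mat>(W_fac.n_rows, W_fac.n_cols);
  mat dW_rate = zeros<mat>(W_rate.n_rows, W_rate.n_cols);
  rowvec db_rate = zeros<rowvec>(b_rate.n_elem);
  mat dW_com, dW_cov;
  rowvec db_com, db_cov;
  if (cc > 0) {
    dW_com = zeros<mat>(W_com.n_rows, W_com.n_cols);
    db_com = zeros<rowvec>(b_com.n_elem);
    dW_cov = zeros<mat>(W_cov.n_rows, W_cov.n_cols);
    db_cov = zeros<rowvec>(b_cov.n_elem);
  }

  std::vector<mat> df(T);
  for (uword t = 0; t < T; ++t) {
    mat dlogr = (exp(logr[t]) - S.slice(t)) / B % rmask[t];
    dW_rate += fac[t].t() * dlogr;
    db_rate += sum(dlogr, 0);
    df[t] = dlogr * W_rate.t();
  }

  mat dg_next = zeros<mat>(B, G);
  mat dc_next;
  if (cc > 0) dc_next = zeros<mat>(B, (uword) dims["controller_dim"]);
  mat dfac_carry = zeros<mat>(B, Fd);
  std::vector<mat> de(T, zeros<mat>(B, 2 * E));

  for (uword t = T; t-- > 0;) {
    mat df_tot = df[t] + dfac_carry;
    dW_fac += gstate[t].t() * df_tot;
    mat dg = df_tot * W_fac.t() + dg_next;
    mat du = gru_step_backward(gen, cgen[t], dg, g_gen, dg_next);
    if (cc > 0) {
      mat dmu = du + kl_co_w * co_mean[t] / B;
      mat dlv = (du % eps_co.slice(t) % (0.5 * exp(0.5 * lvco[t])) +
                 kl_co_w * 0.5 * (exp(lvco[t]) - 1.0) / B) % lvco_mask[t];
      dW_com += cstate[t].t() * dmu;
      db_com += sum(dmu, 0);
      dW_cov += cstate[t].t() * dlv;
      db_cov += sum(dlv, 0);
      mat dc = dmu * W_com.t() + dlv * W_cov.t() + dc_next;
      mat dcin = gru_step_backward(con, ccon[t], dc, g_con, dc_next);
      de[t] += dcin.cols(0, 2 * E - 1);
      dfac_carry = dcin.cols(2 * E, 2 * E + Fd - 1);
    } else {
      dfac_carry.zeros();
    }
  }

  dW_fac += g0.t() * dfac_carry;
  mat dg0 = dfac_carry * W_fac.t() + dg_next;
  mat dg0pre = dg0 % (1.0 - square(g0));
  dW_g0 += ic.t() * dg0pre;
  db_g0 += sum(dg0pre, 0);
  mat dic = dg0pre * W_g0.t();
  mat dmu_ic = dic + kl_ic_w * ic_mean / B;
  mat dlv_ic = (dic % eps_ic % (0.5 * exp(0.5 * lv_ic)) +
                kl_ic_w * 0.5 * (exp(lv_ic) - 1.0) / B) % lv_mask;
  dW_icm += icin.t() * dmu_ic;
  db_icm += sum(dmu_ic, 0);
  dW_icv += icin.t() * dlv_ic;
  db_icv += sum(dlv_ic, 0);
  mat dicin = dmu_ic * W_icm.t() + dlv_ic * W_icv.t();

  mat dh = zeros<mat>(B, E);
  for (uword t = T; t-- > 0;) {
    dh += de[t].cols(0, E - 1);
    if (t == T - 1) dh += dicin.cols(0, E - 1);
    mat dhprev;
    gru_step_backward(enc_f, cf[t], dh, g_enc_f, dhprev);
    dh = dhprev;
  }
  dh = zeros<mat>(B, E);
  for (uword t = 0; t < T; ++t) {
    dh += de[t].cols(E, 2 * E - 1);
    if (t == 0) dh += dicin.cols(E, 2 * E - 1);
    mat dhprev;
    gru_step_backward(enc_b, cb[t], dh, g_enc_b, dhprev);
    dh = dhprev;
  }

  g_gen.dWh += l2_gen * gen.Wh;
  if (cc > 0) g_con.dWh += l2_con * con.Wh;

  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("enc_f") = g_enc_f.to_list(),
      Rcpp::Named("enc_b") = g_enc_b.to_list(),
      Rcpp::Named("W_icm") = dW_icm, Rcpp::Named("b_icm") = db_icm,
      Rcpp::Named("W_icv") = dW_icv, Rcpp::Named("b_icv") = db_icv,
      Rcpp::Named("W_g0") = dW_g0, Rcpp::Named("b_g0") = db_g0,
      Rcpp::Named("gen") = g_gen.to_list(),
      Rcpp::Named("W_fac") = dW_fac,
      Rcpp::Named("W_rate") = dW_rate, Rcpp::Named("b_rate") = db_rate);
  if (cc > 0) {
    grads["con"] = g_con.to_list();
    grads["W_com"] = dW_com;
    grads["b_com"] = db_com;
    grads["W_cov"] = dW_cov;
    grads["b_cov"] = db_cov;
  }
  out["grads"] = grads;
  return out;
}
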