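// Bidirectional LSTM for joint per-frame regression of two physiological
// series (RV, HR) from multichannel ROI input.
//
// Layout conventions:
//   X      : cube (R, B, T)  -- input channels x batch x frames
//   lengths: uvec (B)        -- valid frames per sequence (padding at tail)
//   targets: mat  (T, B)
//   masks  : mat  (T, B) in {0,1}; loss pooled over valid frames
//   dropmask: cube (2H, B, T) -- inverted-dropout keep mask (0 or 1/(1-p))
//
// Gate packing in the 4H dimension: [input; forget; cell; output].
//
// The backward direction consumes each sequence reversed within its own
// valid length, so padding stays at the tail for both directions and
// gradients originating in padded frames are identically zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Reverse each sequence of a (R, B, T) cube within its own length.
static cube reverse_cube(const cube& X, const uvec& lengths) {
  cube Xr(size(X), fill::zeros);
  const uword R = X.n_rows, B = X.n_cols;
  for (uword b = 0; b < B; ++b) {
    uword len = lengths(b);
    for (uword t = 0; t < len; ++t) {
      Xr.subcube(0, b, t, R - 1, b, t) =
        X.subcube(0, b, len - 1 - t, R - 1, b, len - 1 - t);
    }
  }
  return Xr;
}

struct DirCache {
  cube gates;  // (4H, B, T) post-activation [i; f; g; o]
  cube c;      // (H, B, T)
  cube h;      // (H, B, T)
};

// One direction, forward pass over its internal time order.
static void run_direction(const cube& X, const mat& W, const mat& U,
                          const vec& b, DirCache& cache) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  cache.gates.set_size(4 * H, B, T);
  cache.c.set_size(H, B, T);
  cache.h.set_size(H, B, T);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat a = W * X.slice(t) + U * h_prev;
    a.each_col() += b;
    mat gi = sigmoid(a.rows(0, H - 1));
    mat gf = sigmoid(a.rows(H, 2 * H - 1));
    mat gg = tanh(a.rows(2 * H, 3 * H - 1));
    mat go = sigmoid(a.rows(3 * H, 4 * H - 1));
    mat c_t = gf % c_prev + gi % gg;
    mat h_t = go % tanh(c_t);
    cache.gates.slice(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
    cache.c.slice(t) = c_t;
    cache.h.slice(t) = h_t;
    h_prev = h_t;
    c_prev = c_t;
  }
}

// BPTT for one direction. dH: (H, B, T) gradient wrt this direction's
// hidden state in its internal time order. Returns grads for W, U, b.
static void backprop_direction(const cube& X, const mat& W, const mat& U,
                               const DirCache& cache, const cube& dH,
                               mat& dW, mat& dU, vec& db) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  dW.zeros(size(W));
  dU.zeros(size(U));
  db.zeros(4 * H);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat gi = cache.gates.slice(tt).rows(0, H - 1);
    const mat gf = cache.gates.slice(tt).rows(H, 2 * H - 1);
    const mat gg = cache.gates.slice(tt).rows(2 * H, 3 * H - 1);
    const mat go = cache.gates.slice(tt).rows(3 * H, 4 * H - 1);
    const mat c_t = cache.c.slice(tt);
    const mat tc = tanh(c_t);
    mat c_prev = (tt == 0) ? mat(H, B, fill::zeros) : mat(cache.c.slice(tt - 1));
    mat h_prev = (tt == 0) ? mat(H, B, fill::zeros) : mat(cache.h.slice(tt - 1));

    mat dh = dH.slice(tt) + dh_next;
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat da_o = (dh % tc) % go % (1.0 - go);
    mat da_i = (dc % gg) % gi % (1.0 - gi);
    mat da_g = (dc % gi) % (1.0 - gg % gg);
    mat da_f = (dc % c_prev) % gf % (1.0 - gf);
    dc_next = dc % gf;

    mat da = join_cols(join_cols(da_i, da_f), join_cols(da_g, da_o));
    dW += da * X.slice(tt).t();
    dU += da * h_prev.t();
    db += sum(da, 1);
    dh_next = U.t() * da;
  }
}

// [[Rcpp::export(name = ".cpp_bilstm_forward")]]
Rcpp::List cpp_bilstm_forward(const arma::cube& X, const arma::uvec& lengths,
                              const arma::mat& Wf, const arma::mat& Uf,
                              const arma::vec& bf, const arma::mat& Wb,
                              const arma::mat& Ub, const arma::vec& bb,
                              const arma::mat& Wy, const arma::vec& by) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword H = Uf.n_cols;
  DirCache cf, cb;
  run_direction(X, Wf, Uf, bf, cf);
  cube Xr = reverse_cube(X, lengths);
  run_direction(Xr, Wb, Ub, bb, cb);

  mat pred_rv(T, B, fill::zeros), pred_hr(T, B, fill::zeros);
  for (uword b = 0; b < B; ++b) {
    uword len = lengths(b);
    for (uword t = 0; t < len; ++t) {
      vec d(2 * H);
      d.head(H) = cf.h.slice(t).col(b);
      d.tail(H) = cb.h.slice(len - 1 - t).col(b);
      vec y = Wy * d + by;
      pred_rv(t, b) = y(0);
      pred_hr(t, b) = y(1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("rv") = pred_rv,
                            Rcpp::Named("hr") = pred_hr);
}

// [[Rcpp::export(name = ".cpp_bilstm_grad")]]
Rcpp::List cpp_bilstm_grad(const arma::cube& X, const arma::uvec& lengths,
                           const arma::mat& rv, const arma::mat& hr,
                           const arma::mat& mask_rv, const arma::mat& mask_hr,
                           const arma::cube& dropmask,
                           const arma::mat& Wf, const arma::mat& Uf,
                           const arma::vec& bf, const arma::mat& Wb,
                           const arma::mat& Ub, const arma::vec& bb,
                           const arma::mat& Wy, const arma::vec& by) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword H = Uf.n_cols;

  DirCache cf, cb;
  run_direction(X, Wf, Uf, bf, cf);
  cube Xr = reverse_cube(X, lengths);
  run_direction(Xr, Wb, Ub, bb, cb);

  // Assemble dropped concatenated states and head outputs.
  cube D(2 * H, B, T, fill::zeros);  // post-dropout state, original time
  for (uword b = 0; b < B; ++b) {
    uword len = lengths(b);
    for (uword t = 0; t < len; ++t) {
      vec d(2 * H);
      d.head(H) = cf.h.slice(t).col(b);
      d.tail(H) = cb.h.slice(len - 1 - t).col(b);
      vec dm = dropmask.subcube(0, b, t, 2 * H - 1, b, t);
      D.subcube(0, b, t, 2 * H - 1, b, t) = d % dm;
    }
  }
  mat pred_rv(T, B, fill::zeros), pred_hr(T, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat y = Wy * D.slice(t);
    y.each_col() += by;
    pred_rv.row(t) = y.row(0);
    pred_hr.row(t) = y.row(1);
  }

  double n_rv = accu(mask_rv), n_hr = accu(mask_hr);
  if (n_rv < 1 || n_hr < 1) Rcpp::stop("all frames masked");
  mat err_rv = mask_rv % (pred_rv - rv);
  mat err_hr = mask_hr % (pred_hr - hr);
  double loss = accu(square(err_rv)) / n_rv + accu(square(err_hr)) / n_hr;

  // Head gradients and state gradient.
  mat dWy(size(Wy), fill::zeros);
  vec dby(2, fill::zeros);
  cube dHf(H, B, T, fill::zeros);  // forward-dir internal order == original
  cube dHb(H, B, T, fill::zeros);  // backward-dir internal (reversed) order
  mat dY(2, B);
  for (uword t = 0; t < T; ++t) {
    dY.row(0) = 2.0 * err_rv.row(t) / n_rv;
    dY.row(1) = 2.0 * err_hr.row(t) / n_hr;
    dWy += dY * D.slice(t).t();
    dby += sum(dY, 1);
    mat dD = (Wy.t() * dY) % dropmask.slice(t);  // (2H, B)
    for (uword b = 0; b < B; ++b) {
      uword len = lengths(b);
      if (t >= len) continue;
      dHf.subcube(0, b, t, H - 1, b, t) = dD.submat(0, b, H - 1, b);
      dHb.subcube(0, b, len - 1 - t, H - 1, b, len - 1 - t) =
        dD.submat(H, b, 2 * H - 1, b);
    }
  }

  mat dWf, dUf, dWb, dUb;
  vec dbf, dbb;
  backprop_direction(X, Wf, Uf, cf, dHf, dWf, dUf, dbf);
  backprop_direction(Xr, Wb, Ub, cb, dHb, dWb, dUb, dbb);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("rv") = pred_rv, Rcpp::Named("hr") = pred_hr,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wf") = dWf, Rcpp::Named("Uf") = dUf, Rcpp::Named("bf") = dbf,
      Rcpp::Named("Wb") = dWb, Rcpp::Named("Ub") = dUb, Rcpp::Named("bb") = dbb,
      Rcpp::Named("Wy") = dWy, Rcpp::Named("by") = dby));
}
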