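// Compact CNN decoders for epoched MEG: a spatial projection onto k latent
// sources followed by a temporal layer (variant 0 = per-source FIR filters,
// variant 1 = full spatiotemporal / vector-autoregressive mixing), ReLU,
// non-overlapping max-pooling over time, dropout, and a dense softmax head.
// Trained with Adam on binary cross-entropy with an l1 penalty on both
// convolutional layers. All randomness (batch shuffling, dropout) is drawn
// from R's RNG so results are reproducible under set.seed().
//
// Shapes: X is an (n_channels x n_times x n_trials) cube, W (n_channels x k),
// LF filters F (k x l_filt), VAR filters (k x k x l_filt), dense D
// ((k * n_pooled) x 2) with the latent-source index varying fastest, bias (2).
// "Same" temporal padding: pad_left = (l_filt - 1) / 2 (integer division).
// The spatial projection is batched into single GEMMs over concatenated
// trials; the temporal layer runs per trial on small matrices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Mann-Whitney AUC with midrank tie handling; labels in {0,1}.
static double auc_rank(const vec& scores, const ivec& labels) {
  const uword n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double avg = 0.5 * ((i + 1) + (j + 1));
    for (uword m = i; m <= j; ++m) ranks(ord(m)) = avg;
    i = j + 1;
  }
  double n1 = 0, rsum = 0;
  for (uword t = 0; t < n; ++t) {
    if (labels(t) == 1) { n1 += 1.0; rsum += ranks(t); }
  }
  double n0 = n - n1;
  if (n0 == 0 || n1 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n0 * n1);
}

struct Params {
  mat W;        // spatial filters
  mat F_lf;     // LF temporal filters (k x l)
  cube F_var;   // VAR temporal filters (k x k x l)
  mat D;        // dense
  vec b;        // dense bias
  bool is_var;
};

// Per-trial intermediates needed by the backward pass.
struct TrialCache {
  mat Spad;     // padded latent time courses
  mat C;        // pre-activation temporal conv output
  umat amax;    // argmax time index per pooling window
  vec flat;     // flattened pooled output (after dropout scaling if any)
  vec probs;    // softmax probabilities (2)
};

// Forward from precomputed latent time courses S (k x nt).
static void forward_core(const mat& S, const Params& P, int l_filt,
                         int pool, TrialCache& tc, const vec* dropmask,
                         double keep) {
  const int nt = S.n_cols;
  const int k = S.n_rows;
  const int padl = (l_filt - 1) / 2;
  const int np = nt / pool;

  tc.Spad = zeros<mat>(k, nt + l_filt - 1);
  tc.Spad.cols(padl, padl + nt - 1) = S;

  tc.C = zeros<mat>(k, nt);
  if (P.is_var) {
    for (int l = 0; l < l_filt; ++l)
      tc.C += P.F_var.slice(l) * tc.Spad.cols(l, l + nt - 1);
  } else {
    for (int l = 0; l < l_filt; ++l)
      tc.C += tc.Spad.cols(l, l + nt - 1).each_col() % P.F_lf.col(l);
  }

  mat Pm(k, np);
  tc.amax.set_size(k, np);
  for (int u = 0; u < np; ++u) {
    int t0 = u * pool;
    for (int s = 0; s < k; ++s) {
      double best = std::max(tc.C(s, t0), 0.0);
      int bt = t0;
      for (int t = t0 + 1; t < t0 + pool; ++t) {
        double v = std::max(tc.C(s, t), 0.0);
        if (v > best) { best = v; bt = t; }
      }
      Pm(s, u) = best;
      tc.amax(s, u) = bt;
    }
  }
  tc.flat = vectorise(Pm);                    // index s + u*k
  if (dropmask) tc.flat = (tc.flat % (*dropmask)) / keep;

  vec logits = P.D.t() * tc.flat + P.b;
  double mx = logits.max();
  vec ex = exp(logits - mx);
  tc.probs = ex / accu(ex);
}

// Backward through dense, pool, ReLU and the temporal layer; writes the
// gradient w.r.t. the latent time courses into dS (k x nt).
static void backward_core(const Params& P, int l_filt, int pool,
                          const TrialCache& tc, const vec& dlog,
                          const vec* dropmask, double keep,
                          mat& dF_lf, cube& dF_var, mat& dD, vec& db,
                          mat& dS) {
  const int nt = tc.C.n_cols;
  const int k = tc.C.n_rows;
  const int padl = (l_filt - 1) / 2;
  const int np = nt / pool;

  dD += tc.flat * dlog.t();
  db += dlog;
  vec dflat = P.D * dlog;
  if (dropmask) dflat = (dflat % (*dropmask)) / keep;

  mat dR = zeros<mat>(k, nt);
  for (int u = 0; u < np; ++u)
    for (int s = 0; s < k; ++s)
      dR(s, tc.amax(s, u)) += dflat(s + u * k);

  mat dC = dR % conv_to<mat>::from(tc.C > 0);

  mat dSpad = zeros<mat>(k, nt + l_filt - 1);
  if (P.is_var) {
    for (int l = 0; l < l_filt; ++l) {
      dF_var.slice(l) += dC * tc.Spad.cols(l, l + nt - 1).t();
      dSpad.cols(l, l + nt - 1) += P.F_var.slice(l).t() * dC;
    }
  } else {
    for (int l = 0; l < l_filt; ++l) {
      dF_lf.col(l) += sum(dC % tc.Spad.cols(l, l + nt - 1), 1);
      dSpad.cols(l, l + nt - 1) += dC.each_col() % P.F_lf.col(l);
    }
  }
  dS = dSpad.cols(padl, padl + nt - 1);
}

static Params unpack(const arma::mat& W, SEXP Fin, const arma::mat& D,
                     const arma::vec& b, bool is_var) {
  Params P;
  P.W = W; P.D = D; P.b = b; P.is_var = is_var;
  if (is_var) P.F_var = Rcpp::as<arma::cube>(Fin);
  else P.F_lf = Rcpp::as<arma::mat>(Fin);
  return P;
}

// Flatten a set of cube slices into (nch x nt*n) for one batched GEMM.
static mat gather(const cube& X, const std::vector<int>& idx) {
  const uword nch = X.n_rows, nt = X.n_cols, n = idx.size();
  mat Xb(nch, nt * n);
  for (uword j = 0; j < n; ++j)
    Xb.cols(j * nt, (j + 1) * nt - 1) = X.slice(idx[j]);
  return Xb;
}

// Voluntary-class probabilities for every slice of X.
static vec predict_p1(const cube& X, const Params& P, int l_filt, int pool,
                      const mat* Xflat) {
  const uword nt = X.n_cols, ntr = X.n_slices;
  mat Sv = Xflat ? (P.W.t() * (*Xflat)) : mat();
  vec out(ntr);
  TrialCache tc;
  for (uword i = 0; i < ntr; ++i) {
    if (Xflat) {
      forward_core(Sv.cols(i * nt, (i + 1) * nt - 1), P, l_filt, pool, tc,
                   nullptr, 1.0);
    } else {
      mat S = P.W.t() * X.slice(i);
      forward_core(S, P, l_filt, pool, tc, nullptr, 1.0);
    }
    out(i) = tc.probs(1);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::cube& X, const arma::mat& W, SEXP F,
                          const arma::mat& D, const arma::vec& b,
                          bool is_var, int l_filt, int pool) {
  Params P = unpack(W, F, D, b, is_var);
  const uword ntr = X.n_slices, nt = X.n_cols;
  mat probs(ntr, 2);
  TrialCache tc;
  for (uword i = 0; i < ntr; ++i) {
    mat S = P.W.t() * X.slice(i);
    forward_core(S, P, l_filt, pool, tc, nullptr, 1.0);
    probs.row(i) = tc.probs.t();
  }
  return probs;
}

// Full-batch loss and gradients with dropout disabled (used for
// finite-difference verification of the backward pass).
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(const arma::cube& X, const arma::ivec& y,
                        const arma::mat& W, SEXP F, const arma::mat& D,
                        const arma::vec& b, bool is_var, int l_filt,
                        int pool) {
  Params P = unpack(W, F, D, b, is_var);
  const uword ntr = X.n_slices;
  const int k = W.n_cols;

  mat dW = zeros<mat>(W.n_rows, k);
  mat dF_lf; cube dF_var;
  if (is_var) dF_var = zeros<cube>(k, k, l_filt);
  else dF_lf = zeros<mat>(k, l_filt);
  mat dD = zeros<mat>(D.n_rows, 2);
  vec db = zeros<vec>(2);

  double loss = 0.0;
  TrialCache tc;
  mat dS;
  for (uword i = 0; i < ntr; ++i) {
    mat S = P.W.t() * X.slice(i);
    forward_core(S, P, l_filt, pool, tc, nullptr, 1.0);
    loss += -std::log(std::max(tc.probs(y(i)), 1e-300)) / ntr;
    vec dlog = tc.probs;
    dlog(y(i)) -= 1.0;
    dlog /= (double)ntr;
    backward_core(P, l_filt, pool, tc, dlog, nullptr, 1.0,
                  dF_lf, dF_var, dD, db, dS);
    dW += X.slice(i) * dS.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("dW") = dW,
    Rcpp::Named("dF") = is_var ? Rcpp::wrap(dF_var) : Rcpp::wrap(dF_lf),
    Rcpp::Named("dD") = dD,
    Rcpp::Named("db") = db);
}

struct Adam {
  mat mW, vW, mD, vD;  mat mFl, vFl;  cube mFv, vFv;  vec mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const Params& P) {
    mW = zeros<mat>(size(P.W)); vW = mW;
    mD = zeros<mat>(size(P.D)); vD = mD;
    mb = zeros<vec>(2); vb = mb;
    if (P.is_var) { mFv = zeros<cube>(size(P.F_var)); vFv = mFv; }
    else { mFl = zeros<mat>(size(P.F_lf)); vFl = mFl; }
  }
  template <class T>
  void step1(T& w, T& m, T& v, const T& g, double lr, double c1, double c2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// Mini-batch Adam training. Batches cycle through seed-shuffled epochs; the
// validation AUC is recorded after every update (NA when no validation set
// is supplied). Returns final weights and the validation trace.
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::ivec& y,
                         const arma::cube& Xval, const arma::ivec& yval,
                         const arma::mat& W0, SEXP F0, const arma::mat& D0,
                         const arma::vec& b0, bool is_var, int l_filt,
                         int pool, double lr, int batch_size, int n_iter,
                         double dropout_rate, double l1) {
  Rcpp::RNGScope rngscope;
  Params P = unpack(W0, F0, D0, b0, is_var);
  const int n = X.n_slices;
  const int nt = X.n_cols;
  const int k = W0.n_cols;
  const int batch = std::min(batch_size, n);
  const double keep = 1.0 - dropout_rate;
  const bool use_drop = dropout_rate > 0.0;
  const uword nflat = D0.n_rows;
  const bool has_val = Xval.n_slices > 0;

  Adam opt;
  opt.init(P);

  mat Xval_flat;
  if (has_val) {
    std::vector<int> all(Xval.n_slices);
    for (uword i = 0; i < Xval.n_slices; ++i) all[i] = i;
    Xval_flat = gather(Xval, all);
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int pos = n;  // force shuffle on first use

  vec trace(n_iter);
  TrialCache tc;
  vec dropmask(nflat);
  std::vector<int> bidx(batch);
  mat dS;

  for (int it = 0; it < n_iter; ++it) {
    if (pos + batch > n) {
      for (int i = n - 1; i > 0; --i) {  // Fisher-Yates via R RNG
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      pos = 0;
    }
    for (int bi = 0; bi < batch; ++bi) bidx[bi] = order[pos + bi];
    pos += batch;

    mat Xb = gather(X, bidx);
    mat Sb = P.W.t() * Xb;           // one GEMM for the whole batch
    mat dSb(k, Sb.n_cols, fill::zeros);

    mat dF_lf; cube dF_var;
    if (is_var) dF_var = zeros<cube>(k, k, l_filt);
    else dF_lf = zeros<mat>(k, l_filt);
    mat dD = zeros<mat>(size(P.D));
    vec db = zeros<vec>(2);

    for (int bi = 0; bi < batch; ++bi) {
      const vec* mask = nullptr;
      if (use_drop) {
        for (uword m = 0; m < nflat; ++m)
          dropmask(m) = (unif_rand() < keep) ? 1.0 : 0.0;
        mask = &dropmask;
      }
      forward_core(Sb.cols(bi * nt, (bi + 1) * nt - 1), P, l_filt, pool,
                   tc, mask, keep);
      vec dlog = tc.probs;
      dlog(y(bidx[bi])) -= 1.0;
      dlog /= (double)batch;
      backward_core(P, l_filt, pool, tc, dlog, mask, keep,
                    dF_lf, dF_var, dD, db, dS);
      dSb.cols(bi * nt, (bi + 1) * nt - 1) = dS;
    }
    mat dW = Xb * dSb.t();           // one GEMM for the spatial gradient

    if (l1 > 0) {
      dW += l1 * sign(P.W);
      if (is_var) dF_var += l1 * sign(P.F_var);
      else dF_lf += l1 * sign(P.F_lf);
    }

    double c1 = 1.0 - std::pow(opt.b1, it + 1);
    double c2 = 1.0 - std::pow(opt.b2, it + 1);
    opt.step1(P.W, opt.mW, opt.vW, dW, lr, c1, c2);
    if (is_var) opt.step1(P.F_var, opt.mFv, opt.vFv, dF_var, lr, c1, c2);
    else opt.step1(P.F_lf, opt.mFl, opt.vFl, dF_lf, lr, c1, c2);
    opt.step1(P.D, opt.mD, opt.vD, dD, lr, c1, c2);
    opt.step1(P.b, opt.mb, opt.vb, db, lr, c1, c2);

    if (has_val) {
      vec vs = predict_p1(Xval, P, l_filt, pool, &Xval_flat);
      trace(it) = auc_rank(vs, yval);
    } else {
      trace(it) = NA_REAL;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = P.W,
    Rcpp::Named("F") = is_var ? Rcpp::wrap(P.F_var) : Rcpp::wrap(P.F_lf),
    Rcpp::Named("D") = P.D,
    Rcpp::Named("b") = P.b,
    Rcpp::Named("trace") = trace);
}
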