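// Bidirectional LSTM sequence classifier: forward pass, backpropagation
// through time and an RMSprop training loop with per-sequence (variational)
// dropout and early stopping. Weight list layout (all arma::mat):
//   [0] W0 (D x P), [1] b0 (1 x P)                 input perceptron, sigmoid
//   per LSTM layer l = 1..L (6 each):
//     Wf (in x 4H), Uf (H x 4H), bf (1 x 4H)       forward direction
//     Wb, Ub, bb                                   backward direction
//   [2+6L]   Wd (2H x Pd), [3+6L] bd               post perceptron, sigmoid
//   [4+6L]   Wo (Pd x 4),  [5+6L] bo               softmax output
// Gate column order within 4H: input, forget, cell, output.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

typedef std::vector<mat> Weights;

static Weights as_weights(const List& w) {
  Weights out;
  for (int i = 0; i < w.size(); ++i) out.push_back(as<mat>(w[i]));
  return out;
}

static List as_list(const Weights& w, const List& proto) {
  List out(w.size());
  out.names() = proto.names();
  for (size_t i = 0; i < w.size(); ++i) out[i] = w[i];
  return out;
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LayerCache {
  mat I, F, G, O, C, Ct, H;  // gate activations, cell state, tanh(cell), output
};

struct NetCache {
  mat Xd, A0;
  std::vector<LayerCache> fwd, bwd;
  std::vector<mat> concat_drop;  // per layer: dropped [Hf, Hb]
  mat Ad, P;
};

// One direction of one LSTM layer. dir = +1 forward, -1 backward.
static void lstm_dir(const mat& in, const mat& W, const mat& U, const mat& b,
                     const rowvec& rmask, int dir, LayerCache& cc) {
  int T = in.n_rows, H = U.n_rows;
  cc.I.set_size(T, H); cc.F.set_size(T, H); cc.G.set_size(T, H);
  cc.O.set_size(T, H); cc.C.set_size(T, H); cc.Ct.set_size(T, H);
  cc.H.set_size(T, H);
  rowvec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  int t0 = dir > 0 ? 0 : T - 1;
  for (int s = 0; s < T; ++s) {
    int t = t0 + dir * s;
    rowvec z = in.row(t) * W + (h % rmask) * U + b;
    rowvec zi = z.cols(0, H - 1), zf = z.cols(H, 2 * H - 1),
           zg = z.cols(2 * H, 3 * H - 1), zo = z.cols(3 * H, 4 * H - 1);
    rowvec gi = 1.0 / (1.0 + arma::exp(-zi));
    rowvec gf = 1.0 / (1.0 + arma::exp(-zf));
    rowvec gg = arma::tanh(zg);
    rowvec go = 1.0 / (1.0 + arma::exp(-zo));
    c = gf % c + gi % gg;
    rowvec ct = arma::tanh(c);
    h = go % ct;
    cc.I.row(t) = gi; cc.F.row(t) = gf; cc.G.row(t) = gg; cc.O.row(t) = go;
    cc.C.row(t) = c; cc.Ct.row(t) = ct; cc.H.row(t) = h;
  }
}

// BPTT through one direction; returns gradient w.r.t. the layer input and
// accumulates dW, dU, db.
static mat lstm_dir_back(const mat& in, const mat& W, const mat& U,
                         const rowvec& rmask, int dir, const LayerCache& cc,
                         const mat& dH, mat& dW, mat& dU, mat& db) {
  int T = in.n_rows, H = U.n_rows;
  mat dIn(T, in.n_cols, arma::fill::zeros);
  rowvec dh_rec(H, arma::fill::zeros), dc(H, arma::fill::zeros);
  int t0 = dir > 0 ? T - 1 : 0;
  for (int s = 0; s < T; ++s) {
    int t = t0 - dir * s;                      // reverse of forward order
    int tp = t - dir;                          // previous step in time order
    rowvec hprev = (s == T - 1) ? rowvec(H, arma::fill::zeros)
                                : rowvec(cc.H.row(tp));
    rowvec cprev = (s == T - 1) ? rowvec(H, arma::fill::zeros)
                                : rowvec(cc.C.row(tp));
    rowvec dh = rowvec(dH.row(t)) + dh_rec;
    rowvec go = cc.O.row(t), ct = cc.Ct.row(t), gi = cc.I.row(t),
           gf = cc.F.row(t), gg = cc.G.row(t);
    rowvec do_ = dh % ct;
    dc += dh % go % (1.0 - ct % ct);
    rowvec di = dc % gg, df = dc % cprev, dg = dc % gi;
    rowvec dz(4 * H);
    dz.cols(0, H - 1) = di % gi % (1.0 - gi);
    dz.cols(H, 2 * H - 1) = df % gf % (1.0 - gf);
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    dz.cols(3 * H, 4 * H - 1) = do_ % go % (1.0 - go);
    dW += in.row(t).t() * dz;
    dU += (hprev % rmask).t() * dz;
    db += dz;
    dIn.row(t) = dz * W.t();
    dh_rec = (dz * U.t()) % rmask;
    dc = dc % gf;
  }
  return dIn;
}

// Full forward pass. Dropout masks are pre-scaled (inverted dropout); pass
// all-ones masks for inference.
static mat net_forward(const Weights& w, const mat& X, int L, int H,
                       const rowvec& m_in, const std::vector<rowvec>& m_rec_f,
                       const std::vector<rowvec>& m_rec_b,
                       const std::vector<rowvec>& m_out, NetCache* cache) {
  mat Xd = X.each_row() % m_in;
  mat A0 = sigm(Xd * w[0] + arma::repmat(w[1], X.n_rows, 1));
  mat in = A0;
  std::vector<LayerCache> fwd(L), bwd(L);
  std::vector<mat> concat_drop(L);
  for (int l = 0; l < L; ++l) {
    int base = 2 + 6 * l;
    lstm_dir(in, w[base], w[base + 1], w[base + 2], m_rec_f[l], +1, fwd[l]);
    lstm_dir(in, w[base + 3], w[base + 4], w[base + 5], m_rec_b[l], -1, bwd[l]);
    mat cat = arma::join_rows(fwd[l].H, bwd[l].H);
    concat_drop[l] = cat.each_row() % m_out[l];
    in = concat_drop[l];
  }
  int base = 2 + 6 * L;
  mat Ad = sigm(in * w[base] + arma::repmat(w[base + 1], X.n_rows, 1));
  mat logits = Ad * w[base + 2] + arma::repmat(w[base + 3], X.n_rows, 1);
  logits.each_col() -= arma::max(logits, 1);
  mat E = arma::exp(logits);
  mat P = E.each_col() / arma::sum(E, 1);
  if (cache) {
    cache->Xd = Xd; cache->A0 = A0; cache->fwd = fwd; cache->bwd = bwd;
    cache->concat_drop = concat_drop; cache->Ad = Ad; cache->P = P;
  }
  return P;
}

static double soft_ce(const mat& Y, const mat& P) {
  mat Pc = arma::clamp(P, 1e-7, 1.0 - 1e-7);
  return -arma::accu(Y % arma::log(Pc)) / Y.n_rows;
}

// Backward pass; accumulates per-weight gradients (scaled by `scale`).
static void net_backward(const Weights& w, const mat& Y, int L, int H,
                         const rowvec& m_in,
                         const std::vector<rowvec>& m_rec_f,
                         const std::vector<rowvec>& m_rec_b,
                         const std::vector<rowvec>& m_out,
                         const NetCache& cc, Weights& grad, double scale) {
  int T = Y.n_rows;
  int base = 2 + 6 * L;
  mat dlogits = (cc.P - Y) * (scale / T);
  grad[base + 2] += cc.Ad.t() * dlogits;
  grad[base + 3] += arma::sum(dlogits, 0);
  mat dAd = dlogits * w[base + 2].t();
  mat dZd = dAd % cc.Ad % (1.0 - cc.Ad);
  grad[base] += cc.concat_drop[L - 1].t() * dZd;
  grad[base + 1] += arma::sum(dZd, 0);
  mat dIn = dZd * w[base].t();  // grad w.r.t. dropped concat of top layer
  for (int l = L - 1; l >= 0; --l) {
    mat dCat = dIn.each_row() % m_out[l];
    mat dHf = dCat.cols(0, H - 1), dHb = dCat.cols(H, 2 * H - 1);
    const mat& lin = (l == 0) ? cc.A0 : cc.concat_drop[l - 1];
    int b = 2 + 6 * l;
    mat dInF = lstm_dir_back(lin, w[b], w[b + 1], m_rec_f[l], +1, cc.fwd[l],
                             dHf, grad[b], grad[b + 1], grad[b + 2]);
    mat dInB = lstm_dir_back(lin, w[b + 3], w[b + 4], m_rec_b[l], -1,
                             cc.bwd[l], dHb, grad[b + 3], grad[b + 4],
                             grad[b + 5]);
    dIn = dInF + dInB;
  }
  mat dZ0 = dIn % cc.A0 % (1.0 - cc.A0);
  grad[0] += cc.Xd.t() * dZ0;
  grad[1] += arma::sum(dZ0, 0);
}

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(List weights, arma::mat X, int n_layers, int units) {
  Weights w = as_weights(weights);
  rowvec m_in(X.n_cols, arma::fill::ones);
  std::vector<rowvec> mf(n_layers, rowvec(units, arma::fill::ones));
  std::vector<rowvec> mo(n_layers, rowvec(2 * units, arma::fill::ones));
  return net_forward(w, X, n_layers, units, m_in, mf, mf, mo, nullptr);
}

static rowvec draw_mask(std::mt19937& rng, int n, double p_drop) {
  rowvec m(n, arma::fill::ones);
  if (p_drop <= 0) return m;
  std::uniform_real_distribution<double> un(0.0, 1.0);
  for (int i = 0; i < n; ++i)
    m[i] = un(rng) < p_drop ? 0.0 : 1.0 / (1.0 - p_drop);
  return m;
}

// [[Rcpp::export]]
List lstm_train_cpp(List weights, List Xs, List Ys, IntegerVector train_idx,
                    IntegerVector val_idx, int n_layers, int units,
                    double lr, double rho, double eps, int max_passes,
                    int patience, int batch_size, double p_in, double p_out,
                    double p_rec, double clipnorm, int seed, bool verbose) {
  Weights w = as_weights(weights);
  int nw = w.size(), L = n_layers, H = units;
  Weights vcache(nw), grad(nw);
  for (int i = 0; i < nw; ++i) {
    vcache[i] = mat(w[i].n_rows, w[i].n_cols, arma::fill::zeros);
    grad[i] = vcache[i];
  }
  std::vector<mat> X, Y;
  for (int i = 0; i < Xs.size(); ++i) {
    X.push_back(as<mat>(Xs[i]));
    Y.push_back(as<mat>(Ys[i]));
  }
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  std::mt19937 rng(seed);
  rowvec ones_in(X[0].n_cols, arma::fill::ones);
  std::vector<rowvec> ones_rec(L, rowvec(H, arma::fill::ones));
  std::vector<rowvec> ones_out(L, rowvec(2 * H, arma::fill::ones));

  Weights best = w;
  double best_val = std::numeric_limits<double>::infinity();
  int best_pass = -1, since_best = 0;
  std::vector<double> hist_train, hist_val;

  for (int pass = 0; pass < max_passes; ++pass) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double train_loss = 0.0;
    size_t done = 0;
    while (done < tr.size()) {
      size_t bend = std::min(done + (size_t)batch_size, tr.size());
      int nb = bend - done;
      for (int i = 0; i < nw; ++i) grad[i].zeros();
      for (size_t q = done; q < bend; ++q) {
        int night = tr[q];
        rowvec m_in = draw_mask(rng, X[night].n_cols, p_in);
        std::vector<rowvec> mrf(L), mrb(L), mout(L);
        for (int l = 0; l < L; ++l) {
          mrf[l] = draw_mask(rng, H, p_rec);
          mrb[l] = draw_mask(rng, H, p_rec);
          mout[l] = draw_mask(rng, 2 * H, p_out);
        }
        NetCache cc;
        net_forward(w, X[night], L, H, m_in, mrf, mrb, mout, &cc);
        train_loss += soft_ce(Y[night], cc.P);
        net_backward(w, Y[night], L, H, m_in, mrf, mrb, mout, cc, grad,
                     1.0 / nb);
      }
      // global-norm gradient clip, then RMSprop
      double gn2 = 0.0;
      for (int i = 0; i < nw; ++i) gn2 += arma::accu(grad[i] % grad[i]);
      double gn = std::sqrt(gn2);
      double gscale = (clipnorm > 0 && gn > clipnorm) ? clipnorm / gn : 1.0;
      for (int i = 0; i < nw; ++i) {
        mat g = grad[i] * gscale;
        vcache[i] = rho * vcache[i] + (1.0 - rho) * (g % g);
        w[i] -= lr * g / (arma::sqrt(vcache[i]) + eps);
      }
      done = bend;
    }
    train_loss /= tr.size();
    double val_loss = 0.0;
    for (size_t q = 0; q < va.size(); ++q) {
      mat P = net_forward(w, X[va[q]], L, H, ones_in, ones_rec, ones_rec,
                          ones_out, nullptr);
      val_loss += soft_ce(Y[va[q]], P);
    }
    val_loss /= std::max((size_t)1, va.size());
    hist_train.push_back(train_loss);
    hist_val.push_back(val_loss);
    if (!std::isfinite(train_loss) || !std::isfinite(val_loss))
      stop("non-finite loss at pass %d", pass + 1);
    if (val_loss < best_val - 1e-12) {
      best_val = val_loss; best = w; best_pass = pass; since_best = 0;
    } else if (++since_best >= patience) break;
    if (verbose && (pass % 10 == 0))
      Rcpp::Rcout << "pass " << pass + 1 << " train " << train_loss
                  << " val " << val_loss << "\n";
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = as_list(best, weights),
                      _["best_pass"] = best_pass + 1,
                      _["best_val_loss"] = best_val,
                      _["train_loss"] = hist_train,
                      _["val_loss"] = hist_val);
}

// Loss and exact gradients for one sequence without dropout; used by the
// finite-difference gradient tests.
// [[Rcpp::export]]
List lstm_lossgrad_cpp(List weights, arma::mat X, arma::mat Y, int n_layers,
                       int units) {
  Weights w = as_weights(weights);
  int nw = w.size();
  Weights grad(nw);
  for (int i = 0; i < nw; ++i)
    grad[i] = mat(w[i].n_rows, w[i].n_cols, arma::fill::zeros);
  rowvec m_in(X.n_cols, arma::fill::ones);
  std::vector<rowvec> mr(n_layers, rowvec(units, arma::fill::ones));
  std::vector<rowvec> mo(n_layers, rowvec(2 * units, arma::fill::ones));
  NetCache cc;
  net_forward(w, X, n_layers, units, m_in, mr, mr, mo, &cc);
  net_backward(w, Y, n_layers, units, m_in, mr, mr, mo, cc, grad, 1.0);
  return List::create(_["loss"] = soft_ce(Y, cc.P),
                      _["grad"] = as_list(grad, weights));
}
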