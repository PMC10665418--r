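// GE2E d-vector encoder: stacked LSTM -> linear projection -> L2 norm,
// with analytic backpropagation through the GE2E similarity/loss.
//
// Layout conventions:
//   X            : cube (B x D x T), B rows ordered speaker-major
//                  (row r = j*M + i for speaker j, utterance i, 0-based)
//   W[l]         : (D_l x 4H) input weights, gate blocks [i | f | g | o]
//   U[l]         : (H x 4H) recurrent weights
//   b[l]         : (4H) gate biases
//   P, pb        : (H x E) projection and (E) bias
// The embedding is the L2-normalized projection of the top layer's hidden
// state at the final frame.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::cube;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Params {
  std::vector<mat> W, U;
  std::vector<vec> b;
  mat P;
  vec pb;
};

static Params unpack(const List& params) {
  Params p;
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  for (int l = 0; l < Wl.size(); ++l) {
    p.W.push_back(as<mat>(Wl[l]));
    p.U.push_back(as<mat>(Ul[l]));
    p.b.push_back(as<vec>(bl[l]));
  }
  p.P = as<mat>(params["P"]);
  p.pb = as<vec>(params["pb"]);
  return p;
}

struct Cache {
  // per layer: gate activations and cell states, each (B x H x T)
  std::vector<cube> I, F, G, O, C, Th;
  // inputs[l] is the input cube of layer l; inputs[L] is the top layer output
  std::vector<cube> inputs;
};

// Forward pass; returns top-layer hidden state at the final frame (B x H).
static mat lstm_forward(const cube& X, const Params& p, Cache* cache) {
  const int L = (int)p.W.size();
  const int B = X.n_rows, T = X.n_slices;
  cube cur = X;
  mat h_last;
  for (int l = 0; l < L; ++l) {
    const int H = p.U[l].n_rows;
    mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
    cube out(B, H, T);
    cube cI, cF, cG, cO, cC, cTh;
    if (cache) {
      cI.set_size(B, H, T); cF.set_size(B, H, T); cG.set_size(B, H, T);
      cO.set_size(B, H, T); cC.set_size(B, H, T); cTh.set_size(B, H, T);
    }
    for (int t = 0; t < T; ++t) {
      mat Z = cur.slice(t) * p.W[l] + h * p.U[l];
      Z.each_row() += p.b[l].t();
      mat gi = sigm(Z.cols(0, H - 1));
      mat gf = sigm(Z.cols(H, 2 * H - 1));
      mat gg = arma::tanh(Z.cols(2 * H, 3 * H - 1));
      mat go = sigm(Z.cols(3 * H, 4 * H - 1));
      c = gf % c + gi % gg;
      mat th = arma::tanh(c);
      h = go % th;
      out.slice(t) = h;
      if (cache) {
        cI.slice(t) = gi; cF.slice(t) = gf; cG.slice(t) = gg;
        cO.slice(t) = go; cC.slice(t) = c;  cTh.slice(t) = th;
      }
    }
    if (cache) {
      cache->inputs.push_back(cur);
      cache->I.push_back(cI); cache->F.push_back(cF); cache->G.push_back(cG);
      cache->O.push_back(cO); cache->C.push_back(cC); cache->Th.push_back(cTh);
    }
    cur = out;
    h_last = h;
  }
  if (cache) cache->inputs.push_back(cur);
  return h_last;
}

// Backward through time for all layers. dh_top_last is dL/d h_top(T).
static void lstm_backward(const Cache& cache, const Params& p,
                          const mat& dh_top_last,
                          std::vector<mat>& dW, std::vector<mat>& dU,
                          std::vector<vec>& db) {
  const int L = (int)p.W.size();
  const int B = cache.inputs[0].n_rows, T = cache.inputs[0].n_slices;
  const int Htop = p.U[L - 1].n_rows;
  cube dExt(B, Htop, T, arma::fill::zeros);
  dExt.slice(T - 1) = dh_top_last;
  for (int l = L - 1; l >= 0; --l) {
    const int H = p.U[l].n_rows;
    const int D = p.W[l].n_rows;
    dW[l].zeros(D, 4 * H); dU[l].zeros(H, 4 * H); db[l].zeros(4 * H);
    cube dX(B, D, T, arma::fill::zeros);
    mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dh = dExt.slice(t) + dh_next;
      const mat& gi = cache.I[l].slice(t);
      const mat& gf = cache.F[l].slice(t);
      const mat& gg = cache.G[l].slice(t);
      const mat& go = cache.O[l].slice(t);
      const mat& th = cache.Th[l].slice(t);
      mat dct = dh % go % (1.0 - th % th) + dc_next;
      mat cprev = (t == 0) ? mat(B, H, arma::fill::zeros)
                           : mat(cache.C[l].slice(t - 1));
      mat hprev = (t == 0) ? mat(B, H, arma::fill::zeros)
                           : mat(cache.inputs[l + 1].slice(t - 1));
      mat dzi = (dct % gg) % gi % (1.0 - gi);
      mat dzf = (dct % cprev) % gf % (1.0 - gf);
      mat dzg = (dct % gi) % (1.0 - gg % gg);
      mat dzo = (dh % th) % go % (1.0 - go);
      mat dZ = arma::join_rows(arma::join_rows(dzi, dzf),
                               arma::join_rows(dzg, dzo));
      dW[l] += cache.inputs[l].slice(t).t() * dZ;
      dU[l] += hprev.t() * dZ;
      db[l] += arma::sum(dZ, 0).t();
      dh_next = dZ * p.U[l].t();
      dc_next = dct % gf;
      dX.slice(t) = dZ * p.W[l].t();
    }
    dExt = dX;
  }
}

// Project + L2-normalize final hidden states. Returns embeddings; stores raw
// projection norms in `nrm` for the backward pass.
static mat project_normalize(const mat& h_last, const Params& p, vec& nrm) {
  mat U = h_last * p.P;
  U.each_row() += p.pb.t();
  nrm = arma::sqrt(arma::sum(arma::square(U), 1));
  nrm.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
  mat E = U;
  E.each_col() /= nrm;
  return E;
}

// GE2E loss on embeddings grouped speaker-major (N speakers x M utterances):
//   S[r,k] = w * cos(e_r, c_k) + b, with the leave-one-out centroid when
//   k equals the speaker of row r; L = mean_r(-S[r,j_r] + logsumexp_k S[r,k]).
// Fills dE (B x E), dw, dbias when want_grad.
static double ge2e_emb_loss(const mat& E, int N, int M, double w, double b,
                            bool want_grad, mat& dE, double& dw, double& dbias) {
  const int B = N * M;
  const int Edim = E.n_cols;
  vec enorm = arma::sqrt(arma::sum(arma::square(E), 1));
  mat Csum(N, Edim, arma::fill::zeros);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < M; ++i) Csum.row(j) += E.row(j * M + i);

  // centroid vectors and norms per (row, target): full centroids except on
  // the diagonal, where the probe is left out
  mat S(B, N), Cos(B, N);
  std::vector<std::vector<arma::rowvec>> cvecs(B, std::vector<arma::rowvec>(N));
  for (int r = 0; r < B; ++r) {
    int j = r / M;
    for (int k = 0; k < N; ++k) {
      arma::rowvec c;
      if (k == j) c = (Csum.row(j) - E.row(r)) / (double)(M - 1);
      else        c = Csum.row(k) / (double)M;
      double cn = std::max(arma::norm(c, 2), 1e-12);
      double cs = arma::dot(E.row(r), c) / (enorm(r) * cn);
      Cos(r, k) = cs;
      S(r, k) = w * cs + b;
      cvecs[r][k] = c;
    }
  }

  // stable log-sum-exp and loss
  double loss = 0.0;
  mat Pr(B, N);
  for (int r = 0; r < B; ++r) {
    int j = r / M;
    double mx = S.row(r).max();
    arma::rowvec ex = arma::exp(S.row(r) - mx);
    double se = arma::accu(ex);
    loss += -S(r, j) + mx + std::log(se);
    Pr.row(r) = ex / se;
  }
  loss /= (double)B;
  if (!want_grad) return loss;

  dE.zeros(B, Edim);
  dw = 0.0; dbias = 0.0;
  for (int r = 0; r < B; ++r) {
    int j = r / M;
    for (int k = 0; k < N; ++k) {
      double g0 = (Pr(r, k) - (k == j ? 1.0 : 0.0)) / (double)B; // dL/dS[r,k]
      dw += g0 * Cos(r, k);
      dbias += g0;
      double gc = g0 * w; // dL/dcos
      const arma::rowvec& c = cvecs[r][k];
      double cn = std::max(arma::norm(c, 2), 1e-12);
      double en = enorm(r);
      // d cos / d e_r and d cos / d c
      arma::rowvec dcos_de = c / (en * cn) - Cos(r, k) * E.row(r) / (en * en);
      arma::rowvec dcos_dc = E.row(r) / (en * cn) - Cos(r, k) * c / (cn * cn);
      dE.row(r) += gc * dcos_de;
      if (k == j) {
        // leave-one-out centroid: mean of speaker j's other utterances
        for (int i2 = 0; i2 < M; ++i2) {
          int r2 = j * M + i2;
          if (r2 != r) dE.row(r2) += gc * dcos_dc / (double)(M - 1);
        }
      } else {
        for (int i2 = 0; i2 < M; ++i2)
          dE.row(k * M + i2) += gc * dcos_dc / (double)M;
      }
    }
  }
  return loss;
}

// [[Rcpp::export]]
arma::mat cpp_encode(const arma::cube& X, const List& params) {
  Params p = unpack(params);
  mat h_last = lstm_forward(X, p, nullptr);
  vec nrm;
  return project_normalize(h_last, p, nrm);
}

// [[Rcpp::export]]
List cpp_emb_loss_grad(const arma::mat& E, int N, int M, double w, double b) {
  mat dE;
  double dw = 0.0, dbias = 0.0;
  double loss = ge2e_emb_loss(E, N, M, w, b, true, dE, dw, dbias);
  return List::create(_["loss"] = loss, _["dE"] = dE,
                      _["dw"] = dw, _["db"] = dbias);
}

// [[Rcpp::export]]
List cpp_loss_grad(const arma::cube& X, const List& params,
                   int N, int M, double w, double b) {
  Params p = unpack(params);
  const int L = (int)p.W.size();
  Cache cache;
  mat h_last = lstm_forward(X, p, &cache);
  vec nrm;
  mat E = project_normalize(h_last, p, nrm);

  mat dE;
  double dw = 0.0, dbias = 0.0;
  double loss = ge2e_emb_loss(E, N, M, w, b, true, dE, dw, dbias);

  // back through L2 normalization: u -> u/|u|
  mat dUraw(dE.n_rows, dE.n_cols);
  for (arma::uword r = 0; r < dE.n_rows; ++r) {
    double proj = arma::dot(dE.row(r), E.row(r));
    dUraw.row(r) = (dE.row(r) - proj * E.row(r)) / nrm(r);
  }
  mat dP = h_last.t() * dUraw;
  vec dpb = arma::sum(dUraw, 0).t();
  mat dh = dUraw * p.P.t();

  std::vector<mat> dW(L), dU(L);
  std::vector<vec> dbv(L);
  lstm_backward(cache, p, dh, dW, dU, dbv);

  List dWl(L), dUl(L), dbl(L);
  for (int l = 0; l < L; ++l) {
    dWl[l] = dW[l]; dUl[l] = dU[l]; dbl[l] = dbv[l];
  }
  return List::create(
      _["loss"] = loss, _["embeddings"] = E,
      _["dW"] = dWl, _["dU"] = dUl, _["db"] = dbl,
      _["dP"] = dP, _["dpb"] = dpb, _["dw"] = dw, _["dbias"] = dbias);
}
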