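// Minimal self-attention reconstruction network: forward pass and
// full-batch RMSprop training with hand-derived gradients.
//
// Architecture (per sample, n neurons, d_model = 2):
//   M  = Wemb with row i scaled by the input x_i          (n x d)
//   Q  = M WQ,  K = M WK,  V = M WV                       (n x d)
//   A  = row-softmax(Q K^T / sqrt(d_k))                   (n x n)
//   R2 = A V                                              (n x d)
//   u_i = R2(i,) . Wunemb(i,)                             (n)
//   y  = Wff^T u + b                                      (P = 4900)
// Loss: mean squared error over pixels, averaged over samples.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Params {
  mat Wemb, WQ, WK, WV, Wunemb, Wff;
  rowvec bff;
  double dk;
};

static Params unpack(const Rcpp::List& p) {
  Params w;
  w.Wemb = Rcpp::as<mat>(p["Wemb"]);
  w.WQ = Rcpp::as<mat>(p["WQ"]);
  w.WK = Rcpp::as<mat>(p["WK"]);
  w.WV = Rcpp::as<mat>(p["WV"]);
  w.Wunemb = Rcpp::as<mat>(p["Wunemb"]);
  w.Wff = Rcpp::as<mat>(p["Wff"]);
  w.bff = Rcpp::as<rowvec>(p["bff"]);
  w.dk = Rcpp::as<double>(p["dk"]);
  return w;
}

static Rcpp::List pack(const Params& w) {
  return Rcpp::List::create(
    Rcpp::Named("Wemb") = w.Wemb, Rcpp::Named("WQ") = w.WQ,
    Rcpp::Named("WK") = w.WK, Rcpp::Named("WV") = w.WV,
    Rcpp::Named("Wunemb") = w.Wunemb, Rcpp::Named("Wff") = w.Wff,
    Rcpp::Named("bff") = w.bff, Rcpp::Named("dk") = w.dk);
}

// row-softmax with max subtraction
static mat row_softmax(const mat& S) {
  mat E = exp(S.each_col() - max(S, 1));
  return E.each_col() / sum(E, 1);
}

// attention-stage forward for one sample; returns u and fills caches
static vec attn_forward(const Params& w, const vec& x,
                        mat& M, mat& Q, mat& K, mat& V, mat& A, mat& R2) {
  M = w.Wemb.each_col() % x;
  Q = M * w.WQ; K = M * w.WK; V = M * w.WV;
  A = row_softmax(Q * K.t() / std::sqrt(w.dk));
  R2 = A * V;
  return sum(R2 % w.Wunemb, 1);
}

// batch of u vectors (S x n)
static mat u_batch(const Params& w, const mat& X) {
  mat U(X.n_rows, w.Wemb.n_rows);
  mat M, Q, K, V, A, R2;
  for (uword s = 0; s < X.n_rows; ++s)
    U.row(s) = attn_forward(w, X.row(s).t(), M, Q, K, V, A, R2).t();
  return U;
}

// [[Rcpp::export]]
arma::mat recon_forward_cpp(Rcpp::List params, arma::mat X) {
  Params w = unpack(params);
  mat Y = u_batch(w, X) * w.Wff;
  Y.each_row() += w.bff;
  return Y;
}

// [[Rcpp::export]]
arma::mat recon_attention_cpp(Rcpp::List params, arma::vec x) {
  Params w = unpack(params);
  mat M, Q, K, V, A, R2;
  attn_forward(w, x, M, Q, K, V, A, R2);
  return A;
}

// [[Rcpp::export]]
Rcpp::List recon_train_cpp(Rcpp::List params, arma::mat Xtr, arma::mat Ttr,
                           arma::mat Xval, arma::mat Tval, int epochs,
                           double lr, double rho, double eps = 1e-8) {
  Params w = unpack(params);
  const uword S = Xtr.n_rows, n = w.Wemb.n_rows, P = w.Wff.n_cols;
  std::vector<mat> cM(S), cQ(S), cK(S), cV(S), cA(S), cR2(S);
  vec train_loss(epochs), val_loss(epochs);

  // RMSprop accumulators
  mat vWemb(size(w.Wemb), fill::zeros), vWQ(size(w.WQ), fill::zeros),
      vWK(size(w.WK), fill::zeros), vWV(size(w.WV), fill::zeros),
      vWun(size(w.Wunemb), fill::zeros), vWff(size(w.Wff), fill::zeros);
  rowvec vb(P, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    // ---- forward (training set), caching per-sample intermediates
    mat U(S, n);
    for (uword s = 0; s < S; ++s)
      U.row(s) = attn_forward(w, Xtr.row(s).t(), cM[s], cQ[s], cK[s],
                              cV[s], cA[s], cR2[s]).t();
    mat Y = U * w.Wff;
    Y.each_row() += w.bff;
    mat D = Y - Ttr;
    double loss = accu(square(D)) / (double)(S * P);
    train_loss(ep) = loss;
    if (!std::isfinite(loss))
      Rcpp::stop("training diverged (loss is not finite) at epoch %d", ep + 1);

    // ---- backward
    mat DY = (2.0 / (double)(S * P)) * D;          // S x P
    mat gWff = U.t() * DY;                         // n x P
    rowvec gb = sum(DY, 0);
    mat DU = DY * w.Wff.t();                       // S x n

    mat gWemb(size(w.Wemb), fill::zeros), gWQ(size(w.WQ), fill::zeros),
        gWK(size(w.WK), fill::zeros), gWV(size(w.WV), fill::zeros),
        gWun(size(w.Wunemb), fill::zeros);
    double sdk = std::sqrt(w.dk);
    for (uword s = 0; s < S; ++s) {
      vec du = DU.row(s).t();
      mat dR2 = w.Wunemb.each_col() % du;
      gWun += cR2[s].each_col() % du;
      mat dA = dR2 * cV[s].t();                    // n x n
      mat dV = cA[s].t() * dR2;
      mat dS(n, n);
      for (uword i = 0; i < n; ++i) {
        rowvec a = cA[s].row(i);
        rowvec da = dA.row(i);
        dS.row(i) = a % (da - dot(da, a));
      }
      mat dQ = dS * cK[s] / sdk;
      mat dK = dS.t() * cQ[s] / sdk;
      mat dM = dQ * w.WQ.t() + dK * w.WK.t() + dV * w.WV.t();
      gWQ += cM[s].t() * dQ;
      gWK += cM[s].t() * dK;
      gWV += cM[s].t() * dV;
      gWemb += dM.each_col() % Xtr.row(s).t();
    }

    // ---- RMSprop updates
    auto step = [&](mat& W, mat& V2, const mat& G) {
      V2 = rho * V2 + (1.0 - rho) * square(G);
      W -= lr * G / (sqrt(V2) + eps);
    };
    step(w.Wff, vWff, gWff);
    vb = rho * vb + (1.0 - rho) * square(gb);
    w.bff -= lr * gb / (sqrt(vb) + eps);
    step(w.Wemb, vWemb, gWemb);
    step(w.WQ, vWQ, gWQ);
    step(w.WK, vWK, gWK);
    step(w.WV, vWV, gWV);
    step(w.Wunemb, vWun, gWun);

    // ---- validation loss after the update
    if (Xval.n_rows > 0) {
      mat Yv = u_batch(w, Xval) * w.Wff;
      Yv.each_row() += w.bff;
      val_loss(ep) = accu(square(Yv - Tval)) / (double)(Xval.n_rows * P);
    } else {
      val_loss(ep) = datum::nan;
    }
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(w),
                            Rcpp::Named("train_loss") = train_loss,
                            Rcpp::Named("val_loss") = val_loss);
}
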