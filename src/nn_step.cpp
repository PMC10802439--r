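// Compiled hot path for GNN training: full forward/backward of the
// response (f_r) and perturbagen-discovery (f_p) modules on a packed
// sample batch. The aggregation operator A is the sample-level sparse
// block-diagonal matrix built in R (row-normalized for mean aggregation).
// Feature rows are sample-major: row (s-1)*n + i is node i of sample s.
// Conventions (clipping, loss scaling) mirror the R reference
// implementations in R/nn-internal.R and R/train.R exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double CLIP = 1e-12;

struct GnnPars {
  arma::mat pos;                   // n x d positional table
  std::vector<arma::mat> Wself, Wnei;
  std::vector<arma::vec> b;
  arma::mat V1; arma::vec c1;
  arma::rowvec V2; double c2;
  int K;
};

static GnnPars unpackCommon(const List& par, int K) {
  GnnPars p;
  p.K = K;
  p.pos = as<arma::mat>(par["pos"]);
  for (int k = 1; k <= K; ++k) {
    p.Wself.push_back(as<arma::mat>(par["Wself" + std::to_string(k)]));
    p.Wnei.push_back(as<arma::mat>(par["Wnei" + std::to_string(k)]));
    p.b.push_back(as<arma::vec>(par["b" + std::to_string(k)]));
  }
  p.V1 = as<arma::mat>(par["V1"]);
  p.c1 = as<arma::vec>(par["c1"]);
  p.V2 = as<arma::rowvec>(par["V2"]);
  p.c2 = as<double>(par["c2"]);
  return p;
}

struct FwdCache {
  std::vector<arma::mat> H;   // K+1 layer activations (H[0] = features)
  std::vector<arma::mat> M;   // aggregated messages per layer
  arma::mat P1, Hd;           // head pre-activation and hidden
  arma::vec out;              // per-node head output (length S*n)
};

static void stackForward(const GnnPars& p, const arma::sp_mat& A,
                         arma::mat&& H0, FwdCache& fc) {
  fc.H.resize(p.K + 1);
  fc.M.resize(p.K);
  fc.H[0] = std::move(H0);
  for (int k = 0; k < p.K; ++k) {
    fc.M[k] = A * fc.H[k];
    arma::mat P = fc.H[k] * p.Wself[k].t() + fc.M[k] * p.Wnei[k].t();
    P.each_row() += p.b[k].t();
    fc.H[k + 1] = arma::clamp(P, 0.0, arma::datum::inf);
  }
  fc.P1 = fc.H[p.K] * p.V1.t();
  fc.P1.each_row() += p.c1.t();
  fc.Hd = arma::clamp(fc.P1, 0.0, arma::datum::inf);
  fc.out = fc.Hd * p.V2.t() + p.c2;
}

// Backward through head + stack; fills `grads` (when wanted) and returns
// dL/dH0. ReLU masks recovered from the cached activations.
static arma::mat stackBackward(const GnnPars& p, const arma::sp_mat& A,
                               const FwdCache& fc, const arma::vec& dOut,
                               bool wantGrads, List& grads) {
  if (wantGrads) {
    grads["V2"] = arma::mat(dOut.t() * fc.Hd);
    grads["c2"] = arma::accu(dOut);
  }
  arma::mat dP1 = dOut * p.V2;           // N x h
  dP1.elem(arma::find(fc.P1 <= 0)).zeros();
  if (wantGrads) {
    grads["V1"] = arma::mat(dP1.t() * fc.H[p.K]);
    grads["c1"] = arma::vec(arma::sum(dP1, 0).t());
  }
  arma::mat dH = dP1 * p.V1;
  arma::sp_mat At = A.t();
  for (int k = p.K - 1; k >= 0; --k) {
    arma::mat dP = dH;
    dP.elem(arma::find(fc.H[k + 1] <= 0)).zeros();
    if (wantGrads) {
      grads["Wself" + std::to_string(k + 1)] = arma::mat(dP.t() * fc.H[k]);
      grads["Wnei" + std::to_string(k + 1)] = arma::mat(dP.t() * fc.M[k]);
      grads["b" + std::to_string(k + 1)] = arma::vec(arma::sum(dP, 0).t());
    }
    dH = dP * p.Wself[k] + At * (dP * p.Wnei[k]);
  }
  return dH;
}

// Gather a per-node table (rows indexed by idx, 0-based) into N feature rows.
static arma::mat gather(const arma::mat& tab, const arma::uvec& idx) {
  return tab.rows(idx);
}

// Scatter-add N gradient rows back into a table with `rows` rows.
static arma::mat scatter(const arma::mat& g, const arma::uvec& idx,
                         arma::uword rows) {
  arma::mat out(rows, g.n_cols, arma::fill::zeros);
  for (arma::uword r = 0; r < g.n_rows; ++r) out.row(idx[r]) += g.row(r);
  return out;
}

static double ceLoss(const arma::vec& pred, const arma::vec& target) {
  arma::vec p = arma::clamp(pred, CLIP, 1.0 - CLIP);
  return -arma::accu(target % arma::log(p) +
                     (1.0 - target) % arma::log(1.0 - p)) / p.n_elem;
}

// One f_r supervised step: embedding gather, forward, continuous-target CE,
// full backward. iIdx/bins are 1-based (R indices); fv are the hard flags.
// [[Rcpp::export(name = ".frStepCpp")]]
List frStepCpp(const arma::sp_mat& A, const arma::uvec& iIdx,
               const arma::uvec& bins, const arma::vec& fv,
               const List& par, int K, int B, const arma::vec& target,
               bool wantGrad, bool returnPred) {
  GnnPars p = unpackCommon(par, K);
  arma::mat flag0 = as<arma::mat>(par["flag0"]);
  arma::mat flag1 = as<arma::mat>(par["flag1"]);
  arma::mat binTab = as<arma::mat>(par["bin"]);
  arma::uvec i0 = iIdx - 1;
  arma::uvec bIdx = (iIdx - 1) * B + (bins - 1);
  arma::mat F0 = gather(flag0, i0), F1 = gather(flag1, i0);
  arma::mat H0 = arma::join_rows(
      F0.each_col() % (1.0 - fv) + F1.each_col() % fv,
      gather(binTab, bIdx), gather(p.pos, i0));
  FwdCache fc;
  stackForward(p, A, std::move(H0), fc);
  arma::vec pred = 1.0 / (1.0 + arma::exp(-fc.out));
  double loss = ceLoss(pred, target);
  List res = List::create(Named("loss") = loss);
  if (returnPred) res["pred"] = pred;
  if (wantGrad) {
    List grads;
    arma::vec dOut = (pred - target) / (double)pred.n_elem;
    arma::mat dH0 = stackBackward(p, A, fc, dOut, true, grads);
    int d = p.pos.n_cols;
    arma::mat g1 = dH0.cols(0, d - 1);
    grads["flag0"] = scatter(g1.each_col() % (1.0 - fv), i0, flag0.n_rows);
    grads["flag1"] = scatter(g1.each_col() % fv, i0, flag1.n_rows);
    grads["bin"] = scatter(dH0.cols(d, 2 * d - 1), bIdx, binTab.n_rows);
    grads["pos"] = scatter(dH0.cols(2 * d, 3 * d - 1), i0, p.pos.n_rows);
    res["grads"] = grads;
  }
  return res;
}

// One f_p step: discovery forward, supervision CE on the scores, optional
// cycle term through the frozen f_r (soft flags = sigmoid(scores), intact
// graph), and the full backward into f_p's parameters.
// mode: 0 = super, 1 = cycle, 2 = supercycle.
// [[Rcpp::export(name = ".fpStepCpp")]]
List fpStepCpp(const arma::sp_mat& A, const arma::uvec& iIdx,
               const arma::uvec& binsD, const arma::uvec& binsT,
               const List& parFp, const List& parFr, int K, int Kfr, int B,
               const arma::vec& yInd, const arma::vec& wts,
               const arma::vec& xd, const arma::vec& xt, int mode,
               bool wantGrad, bool returnScores) {
  GnnPars p = unpackCommon(parFp, K);
  arma::mat binD = as<arma::mat>(parFp["bin"]);
  arma::mat binT = as<arma::mat>(parFp["binT"]);
  arma::uvec i0 = iIdx - 1;
  arma::uvec bD = (iIdx - 1) * B + (binsD - 1);
  arma::uvec bT = (iIdx - 1) * B + (binsT - 1);
  arma::mat H0 = arma::join_rows(gather(binD, bD), gather(binT, bT),
                                 gather(p.pos, i0));
  FwdCache fc;
  stackForward(p, A, std::move(H0), fc);
  arma::vec scores = fc.out;
  arma::vec sig = 1.0 / (1.0 + arma::exp(-scores));
  double N = (double)scores.n_elem;
  double supLoss = NA_REAL, cycLoss = NA_REAL;
  arma::vec dScores(scores.n_elem, arma::fill::zeros);
  if (mode != 1) {
    arma::vec ps = arma::clamp(sig, CLIP, 1.0 - CLIP);
    supLoss = -arma::accu(wts % (yInd % arma::log(ps) +
                                 (1.0 - yInd) % arma::log(1.0 - ps))) / N;
    if (wantGrad) dScores += wts % (sig - yInd) / N;
  }
  if (mode != 0) {
    // frozen response pass with soft flags on the intact graph
    GnnPars pr = unpackCommon(parFr, Kfr);
    arma::mat flag0 = as<arma::mat>(parFr["flag0"]);
    arma::mat flag1 = as<arma::mat>(parFr["flag1"]);
    arma::mat binR = as<arma::mat>(parFr["bin"]);
    arma::mat F0 = gather(flag0, i0), F1 = gather(flag1, i0);
    arma::mat H0r = arma::join_rows(
        F0.each_col() % (1.0 - sig) + F1.each_col() % sig,
        gather(binR, bD), gather(pr.pos, i0));
    FwdCache fr;
    stackForward(pr, A, std::move(H0r), fr);
    arma::vec pred = 1.0 / (1.0 + arma::exp(-fr.out));
    cycLoss = ceLoss(pred, xt);
    if (wantGrad) {
      List noGrads;
      arma::vec dOutR = (pred - xt) / N;
      arma::mat dH0r = stackBackward(pr, A, fr, dOutR, false, noGrads);
      int dr = pr.pos.n_cols;
      arma::vec dFlags = arma::sum(dH0r.cols(0, dr - 1) % (F1 - F0), 1);
      dScores += dFlags % sig % (1.0 - sig);
    }
  }
  double loss = (mode == 0 ? supLoss : (mode == 1 ? cycLoss
                 : supLoss + cycLoss));
  List res = List::create(Named("loss") = loss,
                          Named("supervision") = supLoss,
                          Named("cycle") = cycLoss);
  if (returnScores) res["scores"] = scores;
  if (wantGrad) {
    List grads;
    arma::mat dH0 = stackBackward(p, A, fc, dScores, true, grads);
    int d = p.pos.n_cols;
    grads["bin"] = scatter(dH0.cols(0, d - 1), bD, binD.n_rows);
    grads["binT"] = scatter(dH0.cols(d, 2 * d - 1), bT, binT.n_rows);
    grads["pos"] = scatter(dH0.cols(2 * d, 3 * d - 1), i0, p.pos.n_rows);
    res["grads"] = grads;
  }
  return res;
}
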