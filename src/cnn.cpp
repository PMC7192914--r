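// Compact 1-D convolutional network for sequence-to-activity regression:
// [conv(same) -> batchnorm -> ReLU -> maxpool/2] x nb -> [dense -> batchnorm
// -> ReLU] x nf -> dense(n_out), trained with Adam on Huber loss.
// Parameters travel as a flat R list of matrices; see R/cnn.R for layout.
#include <RcppArmadillo.h>
typedef arma::fmat FM;
typedef arma::fvec FV;
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.9;

struct Net {
  int nb, K, C, nfc, nout, frame;
  std::vector<int> fcu;
  std::vector<int> Lin, Lp, Cin; // per conv block
  int flat;
};

static Net parse_net(const List& cfg) {
  Net nt;
  nt.nb    = as<int>(cfg["n_blocks"]);
  nt.K     = as<int>(cfg["kernel"]);
  nt.C     = as<int>(cfg["channels"]);
  nt.nout  = as<int>(cfg["n_out"]);
  nt.frame = as<int>(cfg["frame"]);
  IntegerVector fc = cfg["fc"];
  nt.nfc = fc.size();
  for (int i = 0; i < nt.nfc; ++i) nt.fcu.push_back(fc[i]);
  int L = nt.frame;
  for (int b = 0; b < nt.nb; ++b) {
    nt.Cin.push_back(b == 0 ? 4 : nt.C);
    nt.Lin.push_back(L);      // 'same' convolution keeps length
    L = L / 2;                // pool width 2, stride 2, drop odd tail
    nt.Lp.push_back(L);
    if (L < 1) stop("input frame too short for this many conv blocks");
  }
  nt.flat = nt.C * nt.Lp[nt.nb - 1];
  return nt;
}

static std::vector<FM> as_params(const List& L) {
  std::vector<FM> P;
  for (int i = 0; i < L.size(); ++i)
    P.push_back(conv_to<FM>::from(as<arma::mat>(L[i])));
  return P;
}

static List wrap_params(const std::vector<FM>& P) {
  List L(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    L[i] = conv_to<arma::mat>::from(P[i]);
  return L;
}

// param list layout: per conv block {W, gamma, beta, rmean, rvar},
// per fc layer the same five, then {W_out, b_out}
static inline int blk(int b) { return 5 * b; }

struct Cache {
  std::vector<FM> CI, Zh, Act, Pmask, Pool;
  std::vector<FV> istd;
  std::vector<FM> fIn, fZh, fAct;
  std::vector<FV> fistd;
  FM Dlast;
};

static void bn_forward(const FM& Z, FM& gamma, FM& beta, FM& rmean,
                       FM& rvar, bool train, FM& Y, FM& Zh, FV& istd) {
  if (train) {
    FV mu = mean(Z, 1);
    FM Zc = Z.each_col() - mu;
    FV va = mean(square(Zc), 1);
    istd = 1.0 / sqrt(va + BN_EPS);
    Zh = Zc.each_col() % istd;
    rmean.col(0) = BN_MOM * rmean.col(0) + (1 - BN_MOM) * mu;
    rvar.col(0)  = BN_MOM * rvar.col(0)  + (1 - BN_MOM) * va;
  } else {
    istd = 1.0 / sqrt(rvar.col(0) + BN_EPS);
    Zh = (Z.each_col() - rmean.col(0)).each_col() % istd;
  }
  Y = Zh.each_col() % gamma.col(0);
  Y.each_col() += beta.col(0);
}

// standard batchnorm backward (training statistics)
static FM bn_backward(const FM& dY, const FM& Zh, const FV& istd,
                       const FM& gamma, bool train_stats,
                       FM& dgamma, FM& dbeta) {
  dgamma = sum(dY % Zh, 1);
  dbeta  = sum(dY, 1);
  FM dZh = dY.each_col() % gamma.col(0);
  if (!train_stats) return dZh.each_col() % istd;
  FV m1 = mean(dZh, 1);
  FV m2 = mean(dZh % Zh, 1);
  FM dZ = dZh.each_col() - m1;
  dZ -= Zh.each_col() % m2;
  return dZ.each_col() % istd;
}

// forward pass on a batch; X is (4 x frame*B) with columns grouped by item
static FM net_forward(std::vector<FM>& P, const Net& nt, const FM& X,
                       int B, bool train, Cache* cc) {
  const int K = nt.K, padl = (K - 1) / 2;
  FM A = X;
  for (int b = 0; b < nt.nb; ++b) {
    const int Cin = nt.Cin[b], L = nt.Lin[b], Lp = nt.Lp[b];
    const int Lpad = L + K - 1;
    FM Ap(Cin, Lpad * B, fill::zeros);
    for (int i = 0; i < B; ++i)
      Ap.cols(i * Lpad + padl, i * Lpad + padl + L - 1) =
        A.cols(i * L, i * L + L - 1);
    FM CI(Cin * K, L * B);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < B; ++i)
        CI.submat(k * Cin, i * L, (k + 1) * Cin - 1, i * L + L - 1) =
          Ap.cols(i * Lpad + k, i * Lpad + k + L - 1);
    FM Z = P[blk(b)] * CI;
    FM Y, Zh; FV istd;
    bn_forward(Z, P[blk(b) + 1], P[blk(b) + 2], P[blk(b) + 3], P[blk(b) + 4],
               train, Y, Zh, istd);
    FM Act = Y;
    Act.elem(find(Act < 0)).zeros();
    uvec ev = regspace<uvec>(0, 2, 2 * Lp - 2);
    FM Pool(nt.C, Lp * B), Pmask(nt.C, Lp * B);
    for (int i = 0; i < B; ++i) {
      FM s1 = Act.cols(ev + i * L);
      FM s2 = Act.cols(ev + 1 + i * L);
      Pool.cols(i * Lp, (i + 1) * Lp - 1) = arma::max(s1, s2);
      Pmask.cols(i * Lp, (i + 1) * Lp - 1) = conv_to<FM>::from(s1 >= s2);
    }
    if (cc) {
      cc->CI.push_back(std::move(CI));
      cc->Zh.push_back(std::move(Zh));
      cc->istd.push_back(std::move(istd));
      cc->Act.push_back(std::move(Act));
      cc->Pmask.push_back(std::move(Pmask));
      cc->Pool.push_back(Pool);
    }
    A = std::move(Pool);
  }
  // flatten per item
  const int Lf = nt.Lp[nt.nb - 1];
  FM D(nt.flat, B);
  for (int i = 0; i < B; ++i)
    D.col(i) = vectorise(A.cols(i * Lf, (i + 1) * Lf - 1));
  for (int f = 0; f < nt.nfc; ++f) {
    const int off = 5 * (nt.nb + f);
    if (cc) cc->fIn.push_back(D);
    FM Z = P[off] * D;
    FM Y, Zh; FV istd;
    bn_forward(Z, P[off + 1], P[off + 2], P[off + 3], P[off + 4],
               train, Y, Zh, istd);
    FM Act = Y;
    Act.elem(find(Act < 0)).zeros();
    if (cc) {
      cc->fZh.push_back(std::move(Zh));
      cc->fistd.push_back(std::move(istd));
      cc->fAct.push_back(Act);
    }
    D = std::move(Act);
  }
  if (cc) cc->Dlast = D;
  const int oo = 5 * (nt.nb + nt.nfc);
  FM yhat = P[oo] * D;
  yhat.each_col() += P[oo + 1].col(0);
  return yhat;
}

// backward from output-gradient G to parameter grads (and optionally dX)
static void net_backward(std::vector<FM>& P, const Net& nt, const Cache& cc,
                         const FM& G, int B, bool train_stats,
                         std::vector<FM>* grads, FM* dX) {
  const int K = nt.K, padl = (K - 1) / 2;
  const int oo = 5 * (nt.nb + nt.nfc);
  if (grads) {
    (*grads)[oo]     = G * cc.Dlast.t();
    (*grads)[oo + 1] = sum(G, 1);
  }
  FM dD = P[oo].t() * G;
  for (int f = nt.nfc - 1; f >= 0; --f) {
    const int off = 5 * (nt.nb + f);
    FM dY = dD % sign(cc.fAct[f]);
    FM dgamma, dbeta;
    FM dZ = bn_backward(dY, cc.fZh[f], cc.fistd[f], P[off + 1],
                         train_stats, dgamma, dbeta);
    if (grads) {
      (*grads)[off]     = dZ * cc.fIn[f].t();
      (*grads)[off + 1] = dgamma;
      (*grads)[off + 2] = dbeta;
    }
    dD = P[off].t() * dZ;
  }
  // unflatten
  const int Lf = nt.Lp[nt.nb - 1];
  FM dPool(nt.C, Lf * B);
  for (int i = 0; i < B; ++i)
    dPool.cols(i * Lf, (i + 1) * Lf - 1) = reshape(dD.col(i), nt.C, Lf);
  for (int b = nt.nb - 1; b >= 0; --b) {
    const int Cin = nt.Cin[b], L = nt.Lin[b], Lp = nt.Lp[b];
    const int Lpad = L + K - 1;
    uvec ev = regspace<uvec>(0, 2, 2 * Lp - 2);
    FM dAct(nt.C, L * B, fill::zeros);
    for (int i = 0; i < B; ++i) {
      FM dp = dPool.cols(i * Lp, (i + 1) * Lp - 1);
      FM mk = cc.Pmask[b].cols(i * Lp, (i + 1) * Lp - 1);
      dAct.cols(ev + i * L) = dp % mk;
      dAct.cols(ev + 1 + i * L) = dp % (1.0 - mk);
    }
    FM dY = dAct % sign(cc.Act[b]);
    FM dgamma, dbeta;
    FM dZ = bn_backward(dY, cc.Zh[b], cc.istd[b], P[blk(b) + 1],
                         train_stats, dgamma, dbeta);
    if (grads) {
      (*grads)[blk(b)]     = dZ * cc.CI[b].t();
      (*grads)[blk(b) + 1] = dgamma;
      (*grads)[blk(b) + 2] = dbeta;
    }
    if (b == 0 && !dX) break;
    FM dCI = P[blk(b)].t() * dZ;
    FM dAp(Cin, Lpad * B, fill::zeros);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < B; ++i)
        dAp.cols(i * Lpad + k, i * Lpad + k + L - 1) +=
          dCI.submat(k * Cin, i * L, (k + 1) * Cin - 1, i * L + L - 1);
    FM dA(Cin, L * B);
    for (int i = 0; i < B; ++i)
      dA.cols(i * L, i * L + L - 1) =
        dAp.cols(i * Lpad + padl, i * Lpad + padl + L - 1);
    if (b == 0) { *dX = dA; break; }
    dPool = std::move(dA);
  }
}

static FM cube_as_mat(const arma::cube& X) {
  const arma::mat m(X.memptr(), X.n_rows, X.n_cols * X.n_slices);
  return conv_to<FM>::from(m);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List params, List cfg, const arma::cube& X) {
  Net nt = parse_net(cfg);
  std::vector<FM> P = as_params(params);
  FM Xm = cube_as_mat(X);
  int B = X.n_slices;
  return conv_to<arma::mat>::from(net_forward(P, nt, Xm, B, false, nullptr));
}

// [[Rcpp::export]]
List cnn_train_epoch_cpp(List params, List m_in, List v_in, int step, List cfg,
                         const arma::cube& X, const arma::mat& Yin,
                         IntegerVector order, int batch_size, double lr,
                         double delta, double l2) {
  Net nt = parse_net(cfg);
  std::vector<FM> P = as_params(params), M = as_params(m_in),
                   V = as_params(v_in);
  const int N = X.n_slices, F = nt.frame;
  FM Xm = cube_as_mat(X);
  const FM Y = conv_to<FM>::from(Yin);
  const int np = P.size();
  const int oo = 5 * (nt.nb + nt.nfc);
  // trainable entries: W/gamma/beta in each block, output W and b
  std::vector<bool> trainable(np, false), decay(np, false);
  for (int g = 0; g < nt.nb + nt.nfc; ++g) {
    trainable[5 * g] = trainable[5 * g + 1] = trainable[5 * g + 2] = true;
    decay[5 * g] = true; // L2 on weights only, not on the output layer
  }
  trainable[oo] = trainable[oo + 1] = true;

  double loss_sum = 0; int nb_batches = 0;
  for (int start = 0; start < N; start += batch_size) {
    int B = std::min(batch_size, N - start);
    if (B < 2) break; // batchnorm needs >= 2 examples
    FM Xb(4, F * B);
    FM Yb(nt.nout, B);
    for (int j = 0; j < B; ++j) {
      int idx = order[start + j];
      Xb.cols(j * F, (j + 1) * F - 1) = Xm.cols(idx * F, (idx + 1) * F - 1);
      Yb.col(j) = Y.col(idx);
    }
    Cache cc;
    FM yhat = net_forward(P, nt, Xb, B, true, &cc);
    FM R = yhat - Yb;
    // Huber loss and gradient
    FM absR = abs(R);
    FM hub = 0.5 * square(R);
    uvec big = find(absR > delta);
    hub.elem(big) = delta * (absR.elem(big) - 0.5 * delta);
    loss_sum += accu(hub) / (B * nt.nout);
    ++nb_batches;
    FM G = clamp(R, (float)-delta, (float)delta) / (B * nt.nout);
    std::vector<FM> grads(np);
    net_backward(P, nt, cc, G, B, true, &grads, nullptr);
    ++step;
    double c1 = 1 - std::pow(0.9, step), c2 = 1 - std::pow(0.999, step);
    for (int p = 0; p < np; ++p) {
      if (!trainable[p]) continue;
      FM g = grads[p];
      if (g.n_cols != P[p].n_cols || g.n_rows != P[p].n_rows)
        g.reshape(P[p].n_rows, P[p].n_cols);
      if (decay[p]) g += l2 * P[p];
      M[p] = 0.9 * M[p] + 0.1 * g;
      V[p] = 0.999 * V[p] + 0.001 * square(g);
      P[p] -= lr * (M[p] / c1) / (sqrt(V[p] / c2) + 1e-8);
    }
  }
  return List::create(_["params"] = wrap_params(P), _["m"] = wrap_params(M),
                      _["v"] = wrap_params(V), _["step"] = step,
                      _["loss"] = loss_sum / std::max(nb_batches, 1));
}

// training-mode loss and parameter gradients on one batch (used by the
// gradient-correctness tests)
// [[Rcpp::export]]
List cnn_loss_grads_cpp(List params, List cfg, const arma::cube& X,
                        const arma::mat& Yin, double delta) {
  Net nt = parse_net(cfg);
  std::vector<FM> P = as_params(params);
  const int B = X.n_slices;
  FM Xm = cube_as_mat(X);
  const FM Yb = conv_to<FM>::from(Yin);
  Cache cc;
  FM yhat = net_forward(P, nt, Xm, B, true, &cc);
  FM R = yhat - Yb;
  FM absR = abs(R);
  FM hub = 0.5 * square(R);
  uvec big = find(absR > delta);
  hub.elem(big) = delta * (absR.elem(big) - 0.5 * delta);
  double loss = accu(hub) / (B * nt.nout);
  FM G = clamp(R, (float)-delta, (float)delta) / (B * nt.nout);
  std::vector<FM> grads(P.size());
  net_backward(P, nt, cc, G, B, true, &grads, nullptr);
  return List::create(_["loss"] = loss, _["grads"] = wrap_params(grads));
}

// gradient of sum_j outw[j] * output_j with respect to the one-hot input,
// evaluated with frozen (running) batchnorm statistics
// [[Rcpp::export]]
arma::cube cnn_input_grad_cpp(List params, List cfg, const arma::cube& X,
                              const arma::vec& outw) {
  Net nt = parse_net(cfg);
  std::vector<FM> P = as_params(params);
  const int B = X.n_slices, F = nt.frame;
  FM Xm = cube_as_mat(X);
  Cache cc;
  net_forward(P, nt, Xm, B, false, &cc);
  FM G(nt.nout, B);
  G.each_col() = conv_to<FV>::from(outw);
  FM dX;
  net_backward(P, nt, cc, G, B, false, nullptr, &dX);
  cube out(4, F, B);
  for (int i = 0; i < B; ++i)
    out.slice(i) =
      conv_to<arma::mat>::from(dX.cols(i * F, (i + 1) * F - 1));
  return out;
}
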