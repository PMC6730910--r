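// Compiled core of the EEG2Code convolutional network.
//
// Layout fixed by the architecture: input windows are T=150 samples x
// C=32 channels. Layer 1 applies 16 spatial kernels of size 1x32 (a matrix
// product over the channel axis), layer 2 applies 8 temporal kernels of
// size 64x1 with zero padding preserving T, each convolution followed by
// batch normalisation and a rectifier; two temporal max-pools (size 2,
// stride 2) reduce T to 37, and a dense head (dropout 0.5, 128 rectified
// units, 2-way softmax) emits the class probabilities.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const int T_WIN = 150;
const int N_CH = 32;
const int N_SPAT = 16;  // spatial kernels (layer 1)
const int N_TEMP = 8;   // temporal kernels (layer 2)
const int K_TEMP = 64;  // temporal kernel length
const int PAD_L = 31;   // left zero padding ("same", even kernel)
const int T_P1 = T_WIN / 2;      // 75
const int T_P2 = T_P1 / 2;       // 37 (final odd element dropped)
const int N_FLAT = T_P2 * N_TEMP; // 296
const double BN_EPS = 1e-5;

// im2col for the temporal convolution: rows = output time, cols = tap *
// input feature. Zeros outside the window.
void im2col_time(const arma::mat& a, arma::mat& m) {
  m.zeros();
  for (int k = 0; k < K_TEMP; ++k) {
    int o = k - PAD_L;
    int t1 = std::max(0, -o);
    int t2 = std::min(T_WIN - 1, T_WIN - 1 - o);
    if (t1 > t2) continue;
    m.submat(t1, k * N_SPAT, t2, k * N_SPAT + N_SPAT - 1) =
      a.rows(t1 + o, t2 + o);
  }
}

void col2im_time(const arma::mat& dm, arma::mat& da) {
  da.zeros();
  for (int k = 0; k < K_TEMP; ++k) {
    int o = k - PAD_L;
    int t1 = std::max(0, -o);
    int t2 = std::min(T_WIN - 1, T_WIN - 1 - o);
    if (t1 > t2) continue;
    da.rows(t1 + o, t2 + o) +=
      dm.submat(t1, k * N_SPAT, t2, k * N_SPAT + N_SPAT - 1);
  }
}

struct Params {
  arma::mat W1; arma::vec b1, g1, be1;
  arma::mat W2; arma::vec b2, g2, be2;
  arma::mat W3; arma::vec b3;
  arma::mat W4; arma::vec b4;
};

Params unpack(const List& p) {
  Params q;
  q.W1 = as<arma::mat>(p["W1"]); q.b1 = as<arma::vec>(p["b1"]);
  q.g1 = as<arma::vec>(p["g1"]); q.be1 = as<arma::vec>(p["be1"]);
  q.W2 = as<arma::mat>(p["W2"]); q.b2 = as<arma::vec>(p["b2"]);
  q.g2 = as<arma::vec>(p["g2"]); q.be2 = as<arma::vec>(p["be2"]);
  q.W3 = as<arma::mat>(p["W3"]); q.b3 = as<arma::vec>(p["b3"]);
  q.W4 = as<arma::mat>(p["W4"]); q.b4 = as<arma::vec>(p["b4"]);
  return q;
}

} // namespace

// One training step on a batch: forward pass with batch statistics,
// cross-entropy loss, full backward pass. Returns loss, batch accuracy,
// gradients and the batch-normalisation statistics (for the running
// averages kept on the R side). `dropout_mask` is N_FLAT x B with entries
// 0 or 1/(1-rate) (inverted dropout), generated from R's RNG.
// [[Rcpp::export]]
List cnn_train_batch(const arma::cube& X, const arma::ivec& y,
                     const List& params, const arma::mat& dropout_mask) {
  const int B = X.n_slices;
  Params q = unpack(params);
  const int N1 = T_WIN * B;

  // ---- forward ----
  arma::cube H1(T_WIN, N_SPAT, B), C2(T_WIN, N_TEMP, B);
  arma::mat M(T_WIN, K_TEMP * N_SPAT);

  for (int b = 0; b < B; ++b) {
    H1.slice(b) = X.slice(b) * q.W1;
    H1.slice(b).each_row() += q.b1.t();
  }
  // BN1 statistics over time x batch per spatial feature
  arma::vec m1(N_SPAT), v1(N_SPAT);
  for (int f = 0; f < N_SPAT; ++f) {
    double s = 0, ss = 0;
    for (int b = 0; b < B; ++b) {
      const arma::vec col = H1.slice(b).col(f);
      s += arma::accu(col); ss += arma::dot(col, col);
    }
    m1(f) = s / N1;
    v1(f) = ss / N1 - m1(f) * m1(f);
  }
  arma::vec is1 = 1.0 / arma::sqrt(v1 + BN_EPS);
  arma::cube X1h(T_WIN, N_SPAT, B), A1(T_WIN, N_SPAT, B);
  for (int b = 0; b < B; ++b) {
    X1h.slice(b) = H1.slice(b);
    X1h.slice(b).each_row() -= m1.t();
    X1h.slice(b).each_row() %= is1.t();
    arma::mat z = X1h.slice(b);
    z.each_row() %= q.g1.t();
    z.each_row() += q.be1.t();
    A1.slice(b) = arma::clamp(z, 0.0, arma::datum::inf);
  }

  for (int b = 0; b < B; ++b) {
    im2col_time(A1.slice(b), M);
    C2.slice(b) = M * q.W2;
    C2.slice(b).each_row() += q.b2.t();
  }
  arma::vec m2(N_TEMP), v2(N_TEMP);
  for (int f = 0; f < N_TEMP; ++f) {
    double s = 0, ss = 0;
    for (int b = 0; b < B; ++b) {
      const arma::vec col = C2.slice(b).col(f);
      s += arma::accu(col); ss += arma::dot(col, col);
    }
    m2(f) = s / N1;
    v2(f) = ss / N1 - m2(f) * m2(f);
  }
  arma::vec is2 = 1.0 / arma::sqrt(v2 + BN_EPS);
  arma::cube X2h(T_WIN, N_TEMP, B), A2(T_WIN, N_TEMP, B);
  for (int b = 0; b < B; ++b) {
    X2h.slice(b) = C2.slice(b);
    X2h.slice(b).each_row() -= m2.t();
    X2h.slice(b).each_row() %= is2.t();
    arma::mat z = X2h.slice(b);
    z.each_row() %= q.g2.t();
    z.each_row() += q.be2.t();
    A2.slice(b) = arma::clamp(z, 0.0, arma::datum::inf);
  }

  // two temporal max-pools, argmax kept for backprop
  arma::cube P2(T_P2, N_TEMP, B);
  arma::ucube argm(T_P2, N_TEMP, B);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < N_TEMP; ++f) {
      for (int t = 0; t < T_P2; ++t) {
        int base = 4 * t; // pool of pool: 4 candidate samples
        // first pool pairs (base,base+1) and (base+2,base+3), then max of the two
        double best = A2(base, f, b); int bi = base;
        for (int j = 1; j < 4; ++j) {
          if (A2(base + j, f, b) > best) { best = A2(base + j, f, b); bi = base + j; }
        }
        P2(t, f, b) = best;
        argm(t, f, b) = bi;
      }
    }
  }

  // flatten (time-major within each temporal feature), dropout, dense head
  arma::mat F(N_FLAT, B);
  for (int b = 0; b < B; ++b) {
    F.col(b) = arma::vectorise(P2.slice(b));
  }
  arma::mat Fd = F % dropout_mask;
  arma::mat Z3 = q.W3.t() * Fd;
  Z3.each_col() += q.b3;
  arma::mat A3 = arma::clamp(Z3, 0.0, arma::datum::inf);
  arma::mat Z4 = q.W4.t() * A3;
  Z4.each_col() += q.b4;
  arma::mat P(2, B);
  for (int b = 0; b < B; ++b) {
    double mx = Z4.col(b).max();
    arma::vec e = arma::exp(Z4.col(b) - mx);
    P.col(b) = e / arma::accu(e);
  }

  double loss = 0; int correct = 0;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(P(y(b), b), 1e-12));
    if ((P(1, b) >= P(0, b) ? 1 : 0) == y(b)) ++correct;
  }
  loss /= B;

  // ---- backward ----
  arma::mat dZ4 = P;
  for (int b = 0; b < B; ++b) dZ4(y(b), b) -= 1.0;
  dZ4 /= B;
  arma::mat dW4 = A3 * dZ4.t();
  arma::vec db4 = arma::sum(dZ4, 1);
  arma::mat dA3 = q.W4 * dZ4;
  arma::mat dZ3 = dA3 % arma::conv_to<arma::mat>::from(Z3 > 0);
  arma::mat dW3 = Fd * dZ3.t();
  arma::vec db3 = arma::sum(dZ3, 1);
  arma::mat dF = (q.W3 * dZ3) % dropout_mask;

  // unpool into dA2
  arma::cube dA2(T_WIN, N_TEMP, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat dP2 = arma::reshape(dF.col(b), T_P2, N_TEMP);
    for (int f = 0; f < N_TEMP; ++f) {
      for (int t = 0; t < T_P2; ++t) {
        dA2(argm(t, f, b), f, b) += dP2(t, f);
      }
    }
  }

  // BN2 + ReLU backward
  arma::mat dg2(N_TEMP, 1, arma::fill::zeros), dbe2(N_TEMP, 1, arma::fill::zeros);
  arma::cube dC2(T_WIN, N_TEMP, B);
  {
    arma::vec s_dxh(N_TEMP, arma::fill::zeros), s_dxh_xh(N_TEMP, arma::fill::zeros);
    arma::cube dXh(T_WIN, N_TEMP, B);
    for (int b = 0; b < B; ++b) {
      arma::mat dz = dA2.slice(b) % arma::conv_to<arma::mat>::from(A2.slice(b) > 0);
      dg2.col(0) += arma::sum(dz % X2h.slice(b), 0).t();
      dbe2.col(0) += arma::sum(dz, 0).t();
      arma::mat dxh = dz;
      dxh.each_row() %= q.g2.t();
      dXh.slice(b) = dxh;
      s_dxh += arma::sum(dxh, 0).t();
      s_dxh_xh += arma::sum(dxh % X2h.slice(b), 0).t();
    }
    for (int b = 0; b < B; ++b) {
      arma::mat t1 = dXh.slice(b) * double(N1);
      t1.each_row() -= s_dxh.t();
      arma::mat t2 = X2h.slice(b);
      t2.each_row() %= s_dxh_xh.t();
      arma::mat dx = (t1 - t2) / double(N1);
      dx.each_row() %= is2.t();
      dC2.slice(b) = dx;
    }
  }

  // conv2 backward
  arma::mat dW2(K_TEMP * N_SPAT, N_TEMP, arma::fill::zeros);
  arma::vec db2(N_TEMP, arma::fill::zeros);
  arma::cube dA1(T_WIN, N_SPAT, B);
  {
    arma::mat dM(T_WIN, K_TEMP * N_SPAT), da(T_WIN, N_SPAT);
    for (int b = 0; b < B; ++b) {
      im2col_time(A1.slice(b), M);
      dW2 += M.t() * dC2.slice(b);
      db2 += arma::sum(dC2.slice(b), 0).t();
      dM = dC2.slice(b) * q.W2.t();
      col2im_time(dM, da);
      dA1.slice(b) = da;
    }
  }

  // BN1 + ReLU backward
  arma::mat dg1(N_SPAT, 1, arma::fill::zeros), dbe1(N_SPAT, 1, arma::fill::zeros);
  arma::mat dW1(N_CH, N_SPAT, arma::fill::zeros);
  arma::vec db1(N_SPAT, arma::fill::zeros);
  {
    arma::vec s_dxh(N_SPAT, arma::fill::zeros), s_dxh_xh(N_SPAT, arma::fill::zeros);
    arma::cube dXh(T_WIN, N_SPAT, B);
    for (int b = 0; b < B; ++b) {
      arma::mat dz = dA1.slice(b) % arma::conv_to<arma::mat>::from(A1.slice(b) > 0);
      dg1.col(0) += arma::sum(dz % X1h.slice(b), 0).t();
      dbe1.col(0) += arma::sum(dz, 0).t();
      arma::mat dxh = dz;
      dxh.each_row() %= q.g1.t();
      dXh.slice(b) = dxh;
      s_dxh += arma::sum(dxh, 0).t();
      s_dxh_xh += arma::sum(dxh % X1h.slice(b), 0).t();
    }
    for (int b = 0; b < B; ++b) {
      arma::mat t1 = dXh.slice(b) * double(N1);
      t1.each_row() -= s_dxh.t();
      arma::mat t2 = X1h.slice(b);
      t2.each_row() %= s_dxh_xh.t();
      arma::mat dH1 = (t1 - t2) / double(N1);
      dH1.each_row() %= is1.t();
      dW1 += X.slice(b).t() * dH1;
      db1 += arma::sum(dH1, 0).t();
    }
  }

  return List::create(
    _["loss"] = loss,
    _["acc"] = double(correct) / B,
    _["grads"] = List::create(
      _["W1"] = dW1, _["b1"] = db1, _["g1"] = dg1.col(0), _["be1"] = dbe1.col(0),
      _["W2"] = dW2, _["b2"] = db2, _["g2"] = dg2.col(0), _["be2"] = dbe2.col(0),
      _["W3"] = dW3, _["b3"] = db3, _["W4"] = dW4, _["b4"] = db4),
    _["bn1_mean"] = m1, _["bn1_var"] = v1,
    _["bn2_mean"] = m2, _["bn2_var"] = v2);
}

// Inference pass: batch normalisation uses the running statistics, dropout
// is off. Returns the probability of class 1 for every window.
// [[Rcpp::export]]
arma::vec cnn_predict_batch(const arma::cube& X, const List& params,
                            const arma::vec& rm1, const arma::vec& rv1,
                            const arma::vec& rm2, const arma::vec& rv2) {
  const int B = X.n_slices;
  Params q = unpack(params);
  arma::vec is1 = 1.0 / arma::sqrt(rv1 + BN_EPS);
  arma::vec is2 = 1.0 / arma::sqrt(rv2 + BN_EPS);
  arma::vec out(B);
  arma::mat M(T_WIN, K_TEMP * N_SPAT);
  for (int b = 0; b < B; ++b) {
    arma::mat h1 = X.slice(b) * q.W1;
    h1.each_row() += q.b1.t();
    h1.each_row() -= rm1.t();
    h1.each_row() %= (is1 % q.g1).t();
    h1.each_row() += q.be1.t();
    h1 = arma::clamp(h1, 0.0, arma::datum::inf);
    im2col_time(h1, M);
    arma::mat c2 = M * q.W2;
    c2.each_row() += q.b2.t();
    c2.each_row() -= rm2.t();
    c2.each_row() %= (is2 % q.g2).t();
    c2.each_row() += q.be2.t();
    c2 = arma::clamp(c2, 0.0, arma::datum::inf);
    arma::vec f(N_FLAT);
    for (int ff = 0; ff < N_TEMP; ++ff) {
      for (int t = 0; t < T_P2; ++t) {
        int base = 4 * t;
        double best = c2(base, ff);
        for (int j = 1; j < 4; ++j) best = std::max(best, c2(base + j, ff));
        f(ff * T_P2 + t) = best;
      }
    }
    arma::vec z3 = q.W3.t() * f + q.b3;
    z3 = arma::clamp(z3, 0.0, arma::datum::inf);
    arma::vec z4 = q.W4.t() * z3 + q.b4;
    double mx = z4.max();
    arma::vec e = arma::exp(z4 - mx);
    out(b) = e(1) / arma::accu(e);
  }
  return out;
}
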