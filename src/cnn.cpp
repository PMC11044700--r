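// Shallow 3-stage convolutional classifier for 120x120 laminar-interface
// frames. Fixed topology: [conv 3x3 pad 1 -> relu -> maxpool 2x2] x 3,
// dense -> relu, dense -> softmax(2). Layer widths are inferred from the
// weight shapes so the R side owns the architecture config.
//
// Images enter as an H x W x N cube of raw intensities; each image is
// standardised (zero mean, unit sd) internally, which makes predictions
// exactly invariant to affine intensity rescaling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// X: C x (H*W) feature maps, spatial index s = r*W + c (row-major spatial).
// out: (9*C) x (H*W), patch row index = k*C + ch with k = (dr+1)*3 + (dc+1).
void im2col3(const mat& X, int H, int W, mat& out) {
  const int C = X.n_rows;
  out.zeros(9 * C, H * W);
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int k = (dr + 1) * 3 + (dc + 1);
      for (int r = 0; r < H; ++r) {
        const int rr = r + dr;
        if (rr < 0 || rr >= H) continue;
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        if (c0 >= c1) continue;
        // columns c0..c1-1 of row r pull from source columns c0+dc..c1-1+dc
        out.submat(k * C, r * W + c0, k * C + C - 1, r * W + c1 - 1) =
          X.submat(0, rr * W + c0 + dc, C - 1, rr * W + c1 - 1 + dc);
      }
    }
  }
}

// Accumulate the transpose of im2col3: dcol (9C x HW) -> dX (C x HW).
void col2im3(const mat& dcol, int H, int W, mat& dX) {
  const int C = dX.n_rows;
  dX.zeros();
  for (int dr = -1; dr <= 1; ++dr) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int k = (dr + 1) * 3 + (dc + 1);
      for (int r = 0; r < H; ++r) {
        const int rr = r + dr;
        if (rr < 0 || rr >= H) continue;
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        if (c0 >= c1) continue;
        dX.submat(0, rr * W + c0 + dc, C - 1, rr * W + c1 - 1 + dc) +=
          dcol.submat(k * C, r * W + c0, k * C + C - 1, r * W + c1 - 1);
      }
    }
  }
}

// 2x2 max pool. A: C x (H*W) -> P: C x (H/2 * W/2); idx records the argmax
// spatial index into A for backprop.
void maxpool2(const mat& A, int H, int W, mat& P, umat& idx) {
  const int C = A.n_rows, H2 = H / 2, W2 = W / 2;
  P.set_size(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (int r2 = 0; r2 < H2; ++r2) {
    for (int c2 = 0; c2 < W2; ++c2) {
      const int s2 = r2 * W2 + c2;
      const int s00 = (2 * r2) * W + 2 * c2;
      const int cand[4] = {s00, s00 + 1, s00 + W, s00 + W + 1};
      for (int ch = 0; ch < C; ++ch) {
        double best = A(ch, cand[0]);
        int bi = cand[0];
        for (int j = 1; j < 4; ++j) {
          if (A(ch, cand[j]) > best) { best = A(ch, cand[j]); bi = cand[j]; }
        }
        P(ch, s2) = best;
        idx(ch, s2) = bi;
      }
    }
  }
}

void unpool2(const mat& dP, const umat& idx, int H, int W, mat& dA) {
  const int C = dP.n_rows;
  dA.zeros(C, H * W);
  for (uword s2 = 0; s2 < dP.n_cols; ++s2)
    for (int ch = 0; ch < C; ++ch)
      dA(ch, idx(ch, s2)) += dP(ch, s2);
}

struct Net {
  mat W1, W2, W3, W4, W5;
  vec b1, b2, b3, b4, b5;
};

Net unpackNet(const Rcpp::List& w) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<vec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<vec>(w["b2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]); n.b3 = Rcpp::as<vec>(w["b3"]);
  n.W4 = Rcpp::as<mat>(w["W4"]); n.b4 = Rcpp::as<vec>(w["b4"]);
  n.W5 = Rcpp::as<mat>(w["W5"]); n.b5 = Rcpp::as<vec>(w["b5"]);
  return n;
}

// Standardise one image (row-major spatial vector expected by im2col3).
rowvec standardise(const mat& img) {
  // img: H x W (column-major R matrix); flatten row-major: s = r*W + c
  const int H = img.n_rows, W = img.n_cols;
  rowvec x(H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      x(r * W + c) = img(r, c);
  double m = mean(x), s = stddev(x, 1);
  if (s < 1e-12) return rowvec(H * W, fill::zeros);
  return (x - m) / s;
}

struct Cache {
  mat col1, col2, col3, Z1, Z2, Z3, P1, P2, P3;
  umat i1, i2, i3;
  vec f, Z4, A4, p;
};

// Forward for one image; fills cache when training.
vec forwardOne(const Net& n, const mat& img, int H, int W, Cache* cc) {
  Cache local;
  Cache& c = cc ? *cc : local;
  mat X0(1, H * W);
  X0.row(0) = standardise(img);
  im2col3(X0, H, W, c.col1);
  c.Z1 = n.W1 * c.col1;
  c.Z1.each_col() += n.b1;
  mat A1 = clamp(c.Z1, 0.0, datum::inf);
  maxpool2(A1, H, W, c.P1, c.i1);
  const int H1 = H / 2, W1 = W / 2;
  im2col3(c.P1, H1, W1, c.col2);
  c.Z2 = n.W2 * c.col2;
  c.Z2.each_col() += n.b2;
  mat A2 = clamp(c.Z2, 0.0, datum::inf);
  maxpool2(A2, H1, W1, c.P2, c.i2);
  const int H2 = H1 / 2, W2 = W1 / 2;
  im2col3(c.P2, H2, W2, c.col3);
  c.Z3 = n.W3 * c.col3;
  c.Z3.each_col() += n.b3;
  mat A3 = clamp(c.Z3, 0.0, datum::inf);
  maxpool2(A3, H2, W2, c.P3, c.i3);
  c.f = vectorise(c.P3);
  c.Z4 = n.W4 * c.f + n.b4;
  c.A4 = clamp(c.Z4, 0.0, datum::inf);
  vec z5 = n.W5 * c.A4 + n.b5;
  z5 -= z5.max();
  vec e = exp(z5);
  c.p = e / accu(e);
  return c.p;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward")]]
arma::mat cnn_forward_cpp(Rcpp::List weights, arma::cube images) {
  Net n = unpackNet(weights);
  const int H = images.n_rows, W = images.n_cols, N = images.n_slices;
  mat out(N, 2);
  for (int i = 0; i < N; ++i) {
    vec p = forwardOne(n, images.slice(i), H, W, nullptr);
    out(i, 0) = p(0);
    out(i, 1) = p(1);
  }
  return out;
}

// Mini-batch Adam on softmax cross-entropy. `order` is an n x epochs matrix
// of 1-based shuffled indices generated on the R side so all randomness
// stays in R's RNG. Returns the updated weights plus the per-epoch mean loss.
// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, arma::cube images,
                         arma::ivec labels, arma::imat order,
                         int batch_size, double lr) {
  Net n = unpackNet(weights);
  const int H = images.n_rows, W = images.n_cols;
  const int nobs = order.n_rows, epochs = order.n_cols;
  const double b1m = 0.9, b2m = 0.999, eps = 1e-8;

  std::vector<mat*> Ws = {&n.W1, &n.W2, &n.W3, &n.W4, &n.W5};
  std::vector<vec*> bs = {&n.b1, &n.b2, &n.b3, &n.b4, &n.b5};
  std::vector<mat> mW, vW, gW;
  std::vector<vec> mb, vb, gb;
  for (size_t j = 0; j < Ws.size(); ++j) {
    mW.push_back(zeros<mat>(size(*Ws[j])));
    vW.push_back(zeros<mat>(size(*Ws[j])));
    gW.push_back(zeros<mat>(size(*Ws[j])));
    mb.push_back(zeros<vec>(size(*bs[j])));
    vb.push_back(zeros<vec>(size(*bs[j])));
    gb.push_back(zeros<vec>(size(*bs[j])));
  }

  vec epoch_loss(epochs, fill::zeros);
  long tstep = 0;
  Cache c;
  const int H1 = H / 2, W1 = W / 2, H2 = H / 4, W2 = W / 4;

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    for (int start = 0; start < nobs; start += batch_size) {
      const int stop = std::min(start + batch_size, nobs);
      const int bsz = stop - start;
      for (auto& g : gW) g.zeros();
      for (auto& g : gb) g.zeros();

      for (int ii = start; ii < stop; ++ii) {
        const int i = order(ii, ep) - 1;
        vec p = forwardOne(n, images.slice(i), H, W, &c);
        const int y = labels(i);
        loss_sum += -std::log(std::max(p(y), 1e-12));

        vec d5 = p;
        d5(y) -= 1.0;
        gW[4] += d5 * c.A4.t();
        gb[4] += d5;
        vec dA4 = n.W5.t() * d5;
        vec dZ4 = dA4 % conv_to<vec>::from(c.Z4 > 0);
        gW[3] += dZ4 * c.f.t();
        gb[3] += dZ4;
        vec df = n.W4.t() * dZ4;
        mat dP3 = reshape(df, c.P3.n_rows, c.P3.n_cols);
        mat dA3;
        unpool2(dP3, c.i3, H2, W2, dA3);
        mat dZ3 = dA3 % conv_to<mat>::from(c.Z3 > 0);
        gW[2] += dZ3 * c.col3.t();
        gb[2] += sum(dZ3, 1);
        mat dcol3 = n.W3.t() * dZ3;
        mat dP2(c.P2.n_rows, c.P2.n_cols);
        col2im3(dcol3, H2, W2, dP2);
        mat dA2;
        unpool2(dP2, c.i2, H1, W1, dA2);
        mat dZ2 = dA2 % conv_to<mat>::from(c.Z2 > 0);
        gW[1] += dZ2 * c.col2.t();
        gb[1] += sum(dZ2, 1);
        mat dcol2 = n.W2.t() * dZ2;
        mat dP1(c.P1.n_rows, c.P1.n_cols);
        col2im3(dcol2, H1, W1, dP1);
        mat dA1;
        unpool2(dP1, c.i1, H, W, dA1);
        mat dZ1 = dA1 % conv_to<mat>::from(c.Z1 > 0);
        gW[0] += dZ1 * c.col1.t();
        gb[0] += sum(dZ1, 1);
      }

      ++tstep;
      const double corr = std::sqrt(1.0 - std::pow(b2m, tstep)) /
                          (1.0 - std::pow(b1m, tstep));
      for (size_t j = 0; j < Ws.size(); ++j) {
        mat g = gW[j] / bsz;
        mW[j] = b1m * mW[j] + (1 - b1m) * g;
        vW[j] = b2m * vW[j] + (1 - b2m) * square(g);
        *Ws[j] -= lr * corr * mW[j] / (sqrt(vW[j]) + eps);
        vec gv = gb[j] / bsz;
        mb[j] = b1m * mb[j] + (1 - b1m) * gv;
        vb[j] = b2m * vb[j] + (1 - b2m) * square(gv);
        *bs[j] -= lr * corr * mb[j] / (sqrt(vb[j]) + eps);
      }
    }
    epoch_loss(ep) = loss_sum / nobs;
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = Rcpp::List::create(
      Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
      Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
      Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
      Rcpp::Named("W4") = n.W4, Rcpp::Named("b4") = n.b4,
      Rcpp::Named("W5") = n.W5, Rcpp::Named("b5") = n.b5),
    Rcpp::Named("epoch_loss") = epoch_loss);
}
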