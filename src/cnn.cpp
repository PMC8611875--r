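#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolutional encoder over token streams. Each segment is a stream of
// k-mer tokens (1..V, 0 = masked). Because every row of the embedded
// matrix is one of V embedding rows, a convolution of width w reduces to
// summing w token-indexed lookup tables P_j = (E W_j)^T (F x V), which
// keeps training cheap: only the max-pooled positions receive gradient.
//
// Architecture: parallel conv layers (one per width) -> global max pool ->
// concat -> dense(h1, ReLU) -> dense(h2, ReLU) -> dense(C) -> SoftMax.
// The first dense layer (h1) is the node-feature encoding.

static void glorot_fill(arma::mat &m) {
  double s = std::sqrt(6.0 / (m.n_rows + m.n_cols));
  for (arma::uword i = 0; i < m.n_elem; ++i)
    m(i) = (unif_rand() * 2.0 - 1.0) * s;
}

// max-pooled conv features for one segment.
// Pt[w][j] is F x V; h0 is the concatenated pooled vector; amax (optional)
// records the argmax position per (width, filter).
static void conv_h0(const int *t, int T,
                    const std::vector<int> &widths,
                    const std::vector<std::vector<arma::mat>> &Pt,
                    const std::vector<arma::vec> &bc,
                    arma::vec &h0, std::vector<arma::ivec> *amax) {
  int off = 0;
  for (size_t wi = 0; wi < widths.size(); ++wi) {
    int w = widths[wi];
    int F = Pt[wi][0].n_rows;
    int npos = T - w + 1;
    arma::mat Z(F, npos);
    Z.each_col() = bc[wi];
    for (int j = 0; j < w; ++j) {
      const arma::mat &P = Pt[wi][j];
      const double *p = P.memptr();
      double *z = Z.memptr();
      for (int i = 0; i < npos; ++i) {
        int tok = t[i + j];
        if (tok <= 0) continue;
        const double *pc = p + (size_t)(tok - 1) * F;
        double *zc = z + (size_t)i * F;
        for (int f = 0; f < F; ++f) zc[f] += pc[f];
      }
    }
    for (int f = 0; f < F; ++f) {
      double best = Z(f, 0); int bi = 0;
      for (int i = 1; i < npos; ++i)
        if (Z(f, i) > best) { best = Z(f, i); bi = i; }
      h0(off + f) = best;
      if (amax) (*amax)[wi](f) = bi;
    }
    off += F;
  }
}

static std::vector<std::vector<arma::mat>> conv_tables(
    const arma::mat &E, const std::vector<arma::mat> &Wc,
    const std::vector<int> &widths, int d) {
  std::vector<std::vector<arma::mat>> Pt(widths.size());
  for (size_t wi = 0; wi < widths.size(); ++wi) {
    Pt[wi].resize(widths[wi]);
    for (int j = 0; j < widths[wi]; ++j)
      Pt[wi][j] = (E * Wc[wi].rows(j * d, (j + 1) * d - 1)).t();
  }
  return Pt;
}

struct Adam {
  arma::mat m, v;
  void init(const arma::mat &p) { m.zeros(p.n_rows, p.n_cols); v.zeros(p.n_rows, p.n_cols); }
  void step(arma::mat &p, const arma::mat &g, double lr, int t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    double c1 = 1.0 - std::pow(0.9, t), c2 = 1.0 - std::pow(0.999, t);
    p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
  }
};

// [[Rcpp::export]]
List cpp_cnn_train(IntegerMatrix segs, IntegerVector labels, NumericMatrix E_,
                   IntegerVector widths_, int nfilt, int h1, int h2, int C,
                   int epochs, int batch, double lr) {
  int n = segs.nrow(), T = segs.ncol();
  arma::mat E(E_.begin(), E_.nrow(), E_.ncol());
  int d = E.n_cols, V = E.n_rows;
  std::vector<int> widths(widths_.begin(), widths_.end());
  int nw = widths.size();
  for (int w : widths)
    if (T - w + 1 < 1) stop("segment too short for convolution width");
  int D0 = nw * nfilt;

  std::vector<arma::mat> Wc(nw);
  std::vector<arma::vec> bc(nw);
  for (int wi = 0; wi < nw; ++wi) {
    Wc[wi].set_size(widths[wi] * d, nfilt);
    glorot_fill(Wc[wi]);
    bc[wi].zeros(nfilt);
  }
  arma::mat W0(D0, h1), W1(h1, h2), W2(h2, C);
  glorot_fill(W0); glorot_fill(W1); glorot_fill(W2);
  arma::vec b0(h1, arma::fill::zeros), b1(h2, arma::fill::zeros), b2(C, arma::fill::zeros);

  std::vector<Adam> opt(3 + 2 * nw);
  opt[0].init(W0); opt[1].init(W1); opt[2].init(W2);
  std::vector<Adam> optb(3);
  optb[0].init(b0); optb[1].init(b1); optb[2].init(b2);
  for (int wi = 0; wi < nw; ++wi) { opt[3 + wi].init(Wc[wi]); opt[3 + nw + wi].init(bc[wi]); }

  // token matrix by rows for fast per-segment access
  std::vector<std::vector<int>> tok(n, std::vector<int>(T));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < T; ++j) tok[i][j] = segs(i, j);

  NumericVector epoch_loss(epochs);
  int tstep = 0;
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // seeded Fisher-Yates shuffle (R RNG)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double celoss = 0.0;
    for (int start = 0; start < n; start += batch) {
      int bs = std::min(batch, n - start);
      auto Pt = conv_tables(E, Wc, widths, d);
      std::vector<std::vector<arma::mat>> dPt(nw);
      for (int wi = 0; wi < nw; ++wi) {
        dPt[wi].resize(widths[wi]);
        for (int j = 0; j < widths[wi]; ++j) dPt[wi][j].zeros(nfilt, V);
      }
      std::vector<arma::vec> dbc(nw);
      for (int wi = 0; wi < nw; ++wi) dbc[wi].zeros(nfilt);
      arma::mat dW0(D0, h1, arma::fill::zeros), dW1(h1, h2, arma::fill::zeros),
        dW2(h2, C, arma::fill::zeros);
      arma::vec db0(h1, arma::fill::zeros), db1(h2, arma::fill::zeros),
        db2(C, arma::fill::zeros);

      arma::vec h0(D0);
      std::vector<arma::ivec> amax(nw);
      for (int wi = 0; wi < nw; ++wi) amax[wi].set_size(nfilt);

      for (int bi = 0; bi < bs; ++bi) {
        int s = perm[start + bi];
        conv_h0(tok[s].data(), T, widths, Pt, bc, h0, &amax);
        arma::vec z1 = W0.t() * h0 + b0, a1 = arma::clamp(z1, 0.0, arma::datum::inf);
        arma::vec z2 = W1.t() * a1 + b1, a2 = arma::clamp(z2, 0.0, arma::datum::inf);
        arma::vec z3 = W2.t() * a2 + b2;
        z3 -= z3.max();
        arma::vec p = arma::exp(z3);
        p /= arma::accu(p);
        int y = labels[s] - 1;
        celoss -= std::log(std::max(p(y), 1e-300));

        arma::vec dz3 = p; dz3(y) -= 1.0;
        dW2 += a2 * dz3.t(); db2 += dz3;
        arma::vec dz2 = (W2 * dz3) % arma::conv_to<arma::vec>::from(z2 > 0);
        dW1 += a1 * dz2.t(); db1 += dz2;
        arma::vec dz1 = (W1 * dz2) % arma::conv_to<arma::vec>::from(z1 > 0);
        dW0 += h0 * dz1.t(); db0 += dz1;
        arma::vec dh0 = W0 * dz1;

        int off = 0;
        for (int wi = 0; wi < nw; ++wi) {
          int w = widths[wi];
          for (int f = 0; f < nfilt; ++f) {
            double g = dh0(off + f);
            if (g == 0.0) continue;
            int istar = amax[wi](f);
            for (int j = 0; j < w; ++j) {
              int tk = tok[s][istar + j];
              if (tk > 0) dPt[wi][j](f, tk - 1) += g;
            }
            dbc[wi](f) += g;
          }
          off += nfilt;
        }
      }

      double inv = 1.0 / bs;
      ++tstep;
      for (int wi = 0; wi < nw; ++wi) {
        arma::mat dWc(widths[wi] * d, nfilt);
        for (int j = 0; j < widths[wi]; ++j)
          dWc.rows(j * d, (j + 1) * d - 1) = E.t() * dPt[wi][j].t();
        opt[3 + wi].step(Wc[wi], dWc * inv, lr, tstep);
        arma::mat bcm(bc[wi]);
        opt[3 + nw + wi].step(bcm, arma::mat(dbc[wi] * inv), lr, tstep);
        bc[wi] = bcm.col(0);
      }
      opt[0].step(W0, dW0 * inv, lr, tstep);
      opt[1].step(W1, dW1 * inv, lr, tstep);
      opt[2].step(W2, dW2 * inv, lr, tstep);
      arma::mat b0m(b0), b1m(b1), b2m(b2);
      optb[0].step(b0m, arma::mat(db0 * inv), lr, tstep);
      optb[1].step(b1m, arma::mat(db1 * inv), lr, tstep);
      optb[2].step(b2m, arma::mat(db2 * inv), lr, tstep);
      b0 = b0m.col(0); b1 = b1m.col(0); b2 = b2m.col(0);
    }
    epoch_loss[ep] = celoss / n;
    Rcpp::checkUserInterrupt();
  }

  List conv_w(nw), conv_b(nw);
  for (int wi = 0; wi < nw; ++wi) {
    conv_w[wi] = wrap(Wc[wi]);
    conv_b[wi] = wrap(bc[wi]);
  }
  return List::create(_["conv_w"] = conv_w, _["conv_b"] = conv_b,
                      _["w0"] = wrap(W0), _["b0"] = wrap(b0),
                      _["w1"] = wrap(W1), _["b1"] = wrap(b1),
                      _["w2"] = wrap(W2), _["b2"] = wrap(b2),
                      _["epoch_loss"] = epoch_loss);
}

static void unpack(const List &model, const arma::mat &E, int d,
                   std::vector<int> &widths,
                   std::vector<arma::mat> &Wc, std::vector<arma::vec> &bc,
                   std::vector<std::vector<arma::mat>> &Pt) {
  List cw = model["conv_w"], cb = model["conv_b"];
  int nw = cw.size();
  Wc.resize(nw); bc.resize(nw); widths.resize(nw);
  for (int wi = 0; wi < nw; ++wi) {
    NumericMatrix w = cw[wi];
    Wc[wi] = arma::mat(w.begin(), w.nrow(), w.ncol());
    NumericVector b = cb[wi];
    bc[wi] = arma::vec(b.begin(), b.size());
    widths[wi] = w.nrow() / d;
  }
  Pt = conv_tables(E, Wc, widths, d);
}

// first-dense-layer (encoding mode) outputs, one row per segment
// [[Rcpp::export]]
NumericMatrix cpp_cnn_first_dense(IntegerMatrix segs, NumericMatrix E_, List model) {
  arma::mat E(E_.begin(), E_.nrow(), E_.ncol());
  int d = E.n_cols;
  std::vector<int> widths;
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  std::vector<std::vector<arma::mat>> Pt;
  unpack(model, E, d, widths, Wc, bc, Pt);
  NumericMatrix W0_ = model["w0"]; NumericVector b0_ = model["b0"];
  arma::mat W0(W0_.begin(), W0_.nrow(), W0_.ncol());
  arma::vec b0(b0_.begin(), b0_.size());

  int n = segs.nrow(), T = segs.ncol();
  arma::vec h0(W0.n_rows);
  NumericMatrix out(n, W0.n_cols);
  std::vector<int> t(T);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < T; ++j) t[j] = segs(i, j);
    conv_h0(t.data(), T, widths, Pt, bc, h0, nullptr);
    arma::vec a1 = arma::clamp(W0.t() * h0 + b0, 0.0, arma::datum::inf);
    for (arma::uword q = 0; q < a1.n_elem; ++q) out(i, q) = a1(q);
  }
  return out;
}

// train-mode SoftMax outputs, one row per segment
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(IntegerMatrix segs, NumericMatrix E_, List model) {
  arma::mat E(E_.begin(), E_.nrow(), E_.ncol());
  int d = E.n_cols;
  std::vector<int> widths;
  std::vector<arma::mat> Wc;
  std::vector<arma::vec> bc;
  std::vector<std::vector<arma::mat>> Pt;
  unpack(model, E, d, widths, Wc, bc, Pt);
  NumericMatrix W0_ = model["w0"], W1_ = model["w1"], W2_ = model["w2"];
  NumericVector b0_ = model["b0"], b1_ = model["b1"], b2_ = model["b2"];
  arma::mat W0(W0_.begin(), W0_.nrow(), W0_.ncol());
  arma::mat W1(W1_.begin(), W1_.nrow(), W1_.ncol());
  arma::mat W2(W2_.begin(), W2_.nrow(), W2_.ncol());
  arma::vec b0(b0_.begin(), b0_.size()), b1(b1_.begin(), b1_.size()), b2(b2_.begin(), b2_.size());

  int n = segs.nrow(), T = segs.ncol();
  arma::vec h0(W0.n_rows);
  NumericMatrix out(n, W2.n_cols);
  std::vector<int> t(T);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < T; ++j) t[j] = segs(i, j);
    conv_h0(t.data(), T, widths, Pt, bc, h0, nullptr);
    arma::vec a1 = arma::clamp(W0.t() * h0 + b0, 0.0, arma::datum::inf);
    arma::vec a2 = arma::clamp(W1.t() * a1 + b1, 0.0, arma::datum::inf);
    arma::vec z3 = W2.t() * a2 + b2;
    z3 -= z3.max();
    arma::vec p = arma::exp(z3);
    p /= arma::accu(p);
    for (arma::uword q = 0; q < p.n_elem; ++q) out(i, q) = p(q);
  }
  return out;
}
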