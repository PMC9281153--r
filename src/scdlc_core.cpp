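// Core numerics for the scDLC classifier: batched forward pass through
// fc1 (shared per-timestep ReLU embedding) -> two stacked LSTM layers ->
// fc2 -> softmax, analytic backpropagation through time, and the
// mini-batch gradient-descent training loop with global-norm clipping
// and exponential learning-rate decay.
//
// Everything is templated on the element type so the same code runs in
// double (gradient checks, equivalence tests) and float (training speed).
// Matrix products go through BLAS via Armadillo; the per-timestep gate
// arithmetic is fused into single raw loops to avoid small-matrix
// temporaries, which dominate the cost otherwise.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic RNG (splitmix64). Self-contained so dropout masks and batch
// shuffles are bit-reproducible for a given seed regardless of the C++
// standard library in use.
// ---------------------------------------------------------------------------
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

static void fisher_yates(std::vector<int>& idx, SplitMix& rng) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

// exact transcendentals in double; expf-based in float (training path)
static inline double sigmoid_e(double z) { return 1.0 / (1.0 + std::exp(-z)); }
static inline float sigmoid_e(float z) { return 1.0f / (1.0f + expf(-z)); }
static inline double tanh_e(double z) { return std::tanh(z); }
static inline float tanh_e(float z) { return 2.0f / (1.0f + expf(-2.0f * z)) - 1.0f; }

// ---------------------------------------------------------------------------
// Parameter containers. Gate rows are stacked in the fixed order
// [forget; input; candidate; output], each block of `hidden` rows, and the
// weight acting on the concatenation [h_{t-1}, x_t] is split into the
// recurrent part Wh (columns for h) and the input part Wx (columns for x).
// ---------------------------------------------------------------------------
template <typename eT>
struct LstmLayer {
  arma::Mat<eT> Wh;  // 4H x H
  arma::Mat<eT> Wx;  // 4H x D
  arma::Col<eT> b;   // 4H
};

template <typename eT>
struct ScdlcPar {
  arma::Col<eT> fc1_w;   // vectorised fc1 weight (column-major)
  arma::uword fc1_cols = 1;  // 1 = per-gene scalar embedding; p = dense
  arma::Col<eT> fc1_b;
  LstmLayer<eT> l1, l2;
  arma::Mat<eT> fc2_W;   // M x H
  arma::Col<eT> fc2_b;   // M
  int H() const { return static_cast<int>(l1.Wh.n_cols); }
};

template <typename eT>
static arma::Mat<eT> as_mat(SEXP x) {
  NumericMatrix m(x);
  arma::mat d(m.begin(), m.nrow(), m.ncol(), false, true);
  return arma::conv_to<arma::Mat<eT>>::from(d);
}

template <typename eT>
static arma::Col<eT> as_col(SEXP x) {
  NumericVector v(x);
  arma::vec d(v.begin(), v.size(), false, true);
  return arma::conv_to<arma::Col<eT>>::from(d);
}

template <typename eT>
static LstmLayer<eT> unpack_layer(const List& p, const std::string& pre) {
  arma::Mat<eT> Wf = as_mat<eT>(p[pre + "_Wf"]);
  arma::Mat<eT> Wi = as_mat<eT>(p[pre + "_Wi"]);
  arma::Mat<eT> Wc = as_mat<eT>(p[pre + "_Wc"]);
  arma::Mat<eT> Wo = as_mat<eT>(p[pre + "_Wo"]);
  const arma::uword H = Wf.n_rows;
  arma::Mat<eT> W = arma::join_cols(arma::join_cols(Wf, Wi), arma::join_cols(Wc, Wo));
  LstmLayer<eT> L;
  L.Wh = W.cols(0, H - 1);
  L.Wx = W.cols(H, W.n_cols - 1);
  arma::Col<eT> bf = as_col<eT>(p[pre + "_bf"]);
  arma::Col<eT> bi = as_col<eT>(p[pre + "_bi"]);
  arma::Col<eT> bc = as_col<eT>(p[pre + "_bc"]);
  arma::Col<eT> bo = as_col<eT>(p[pre + "_bo"]);
  L.b = arma::join_cols(arma::join_cols(bf, bi), arma::join_cols(bc, bo));
  return L;
}

template <typename eT>
static ScdlcPar<eT> unpack_params(const List& p) {
  ScdlcPar<eT> P;
  arma::Mat<eT> f1 = as_mat<eT>(p["fc1_W"]);
  P.fc1_w = arma::vectorise(f1);
  P.fc1_cols = f1.n_cols;
  P.fc1_b = as_col<eT>(p["fc1_b"]);
  P.l1 = unpack_layer<eT>(p, "lstm1");
  P.l2 = unpack_layer<eT>(p, "lstm2");
  P.fc2_W = as_mat<eT>(p["fc2_W"]);
  P.fc2_b = as_col<eT>(p["fc2_b"]);
  return P;
}

template <typename eT>
static List pack_layer_named(const LstmLayer<eT>& L, const std::string& pre) {
  const arma::uword H = L.Wh.n_rows / 4;
  arma::Mat<eT> W = arma::join_rows(L.Wh, L.Wx);
  List out;
  const char* gates[4] = {"f", "i", "c", "o"};
  for (int g = 0; g < 4; ++g) {
    arma::uword r0 = g * H, r1 = (g + 1) * H - 1;
    out[pre + "_W" + gates[g]] =
        wrap(arma::conv_to<arma::mat>::from(arma::Mat<eT>(W.rows(r0, r1))));
    out[pre + "_b" + gates[g]] =
        wrap(arma::conv_to<arma::vec>::from(arma::Col<eT>(L.b.subvec(r0, r1))));
  }
  return out;
}

template <typename eT>
static List pack_params(const ScdlcPar<eT>& P) {
  List out;
  arma::Mat<eT> f1(const_cast<eT*>(P.fc1_w.memptr()),
                   P.fc1_w.n_elem / P.fc1_cols, P.fc1_cols, false, true);
  out["fc1_W"] = wrap(arma::conv_to<arma::mat>::from(f1));
  out["fc1_b"] = wrap(arma::conv_to<arma::vec>::from(P.fc1_b));
  List l1 = pack_layer_named(P.l1, "lstm1");
  List l2 = pack_layer_named(P.l2, "lstm2");
  CharacterVector n1 = l1.names(), n2 = l2.names();
  for (int i = 0; i < l1.size(); ++i) out[std::string(n1[i])] = l1[i];
  for (int i = 0; i < l2.size(); ++i) out[std::string(n2[i])] = l2[i];
  out["fc2_W"] = wrap(arma::conv_to<arma::mat>::from(P.fc2_W));
  out["fc2_b"] = wrap(arma::conv_to<arma::vec>::from(P.fc2_b));
  return out;
}

// ---------------------------------------------------------------------------
// Forward / backward
// ---------------------------------------------------------------------------
template <typename eT>
struct LayerCache {
  arma::Cube<eT> G;      // gate activations [f; i; ctilde; o], 4H x B x T
  arma::Cube<eT> C;      // cell states, H x B x T
  arma::Cube<eT> tC;     // tanh(C_t)
  arma::Cube<eT> hprev;  // hidden state entering each step
  arma::Cube<eT> mask;   // dropout mask (pre-scaled), H x B x T
  arma::Cube<eT> X;      // layer input, D x B x T
};

// Forward through one LSTM layer over the whole sequence.
// X: D x B x T. Output hdrop: H x B x T (post-dropout when training).
template <typename eT>
static void lstm_layer_forward(const LstmLayer<eT>& L, const arma::Cube<eT>& X,
                               bool training, eT keep, bool variational,
                               SplitMix& rng, bool keep_cache,
                               LayerCache<eT>* cache, arma::Cube<eT>& hdrop) {
  const arma::uword D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const arma::uword H = L.Wh.n_cols;
  arma::Mat<eT> Xmat(const_cast<eT*>(X.memptr()), D, B * T, false, true);
  arma::Mat<eT> Zx = L.Wx * Xmat;  // 4H x (B*T), all timesteps at once

  hdrop.set_size(H, B, T);
  if (keep_cache) {
    cache->G.set_size(4 * H, B, T);
    cache->C.set_size(H, B, T);
    cache->tC.set_size(H, B, T);
    cache->hprev.set_size(H, B, T);
    cache->mask.set_size(H, B, T);
    cache->X = X;
  }
  const bool drop = training && keep < 1;
  const eT inv_keep = drop ? 1 / keep : eT(1);
  // variational dropout: one mask per unit and sample, shared by all
  // timesteps of the sequence
  arma::Mat<eT> vmask;
  if (drop && variational) {
    vmask.set_size(H, B);
    for (arma::uword k = 0; k < vmask.n_elem; ++k)
      vmask(k) = rng.unif() < keep ? inv_keep : eT(0);
  }
  arma::Mat<eT> h(H, B, arma::fill::zeros), C(H, B, arma::fill::zeros);
  arma::Mat<eT> Z(4 * H, B);
  const eT* bp = L.b.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    if (keep_cache) cache->hprev.slice(t) = h;
    Z = Zx.cols(t * B, t * B + B - 1);
    Z += L.Wh * h;
    eT* zp = Z.memptr();
    eT* Cp = C.memptr();
    eT* hp = h.memptr();
    eT* op = hdrop.slice_memptr(t);
    eT* gp = keep_cache ? cache->G.slice_memptr(t) : nullptr;
    eT* cp = keep_cache ? cache->C.slice_memptr(t) : nullptr;
    eT* tp = keep_cache ? cache->tC.slice_memptr(t) : nullptr;
    eT* mp = keep_cache ? cache->mask.slice_memptr(t) : nullptr;
    for (arma::uword col = 0; col < B; ++col) {
      eT* z = zp + col * 4 * H;
      eT* Cc = Cp + col * H;
      eT* hc = hp + col * H;
      eT* oc = op + col * H;
      for (arma::uword j = 0; j < H; ++j) {
        eT f = sigmoid_e(z[j] + bp[j]);
        eT i = sigmoid_e(z[H + j] + bp[H + j]);
        eT g = tanh_e(z[2 * H + j] + bp[2 * H + j]);
        eT o = sigmoid_e(z[3 * H + j] + bp[3 * H + j]);
        eT Cn = f * Cc[j] + i * g;
        eT tCn = tanh_e(Cn);
        eT hn = o * tCn;
        Cc[j] = Cn;
        hc[j] = hn;
        eT m = 1;
        if (drop)
          m = variational ? vmask(j, col)
                          : (rng.unif() < keep ? inv_keep : eT(0));
        oc[j] = hn * m;
        if (keep_cache) {
          eT* g4 = gp + col * 4 * H;
          g4[j] = f; g4[H + j] = i; g4[2 * H + j] = g; g4[3 * H + j] = o;
          cp[col * H + j] = Cn;
          tp[col * H + j] = tCn;
          mp[col * H + j] = m;
        }
      }
    }
  }
}

// Backward through one LSTM layer. dHdrop holds gradients w.r.t. the
// (post-dropout) outputs. Accumulates weight gradients into G, returns the
// gradient w.r.t. the layer input in dX.
template <typename eT>
static void lstm_layer_backward(const LstmLayer<eT>& L, const LayerCache<eT>& c,
                                const arma::Cube<eT>& dHdrop, LstmLayer<eT>& G,
                                arma::Cube<eT>& dX) {
  const arma::uword D = c.X.n_rows, B = c.X.n_cols, T = c.X.n_slices;
  const arma::uword H = L.Wh.n_cols;
  arma::Cube<eT> dZ(4 * H, B, T);
  arma::Mat<eT> dh_rec(H, B, arma::fill::zeros);
  arma::Mat<eT> dC_next(H, B, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    const eT* dhd = dHdrop.slice_memptr(tt);
    const eT* mp = c.mask.slice_memptr(tt);
    const eT* gp = c.G.slice_memptr(tt);
    const eT* tp = c.tC.slice_memptr(tt);
    const eT* cprev = tt > 0 ? c.C.slice_memptr(tt - 1) : nullptr;
    eT* dzp = dZ.slice_memptr(tt);
    eT* dhr = dh_rec.memptr();
    eT* dCn = dC_next.memptr();
    for (arma::uword col = 0; col < B; ++col) {
      const eT* g4 = gp + col * 4 * H;
      eT* dz = dzp + col * 4 * H;
      for (arma::uword j = 0; j < H; ++j) {
        const arma::uword k = col * H + j;
        eT dh = dhd[k] * mp[k] + dhr[k];
        eT f = g4[j], i = g4[H + j], g = g4[2 * H + j], o = g4[3 * H + j];
        eT tC = tp[k];
        eT dO = dh * tC;
        eT dC = dCn[k] + dh * o * (1 - tC * tC);
        eT Cprev = cprev ? cprev[k] : eT(0);
        dz[j] = dC * Cprev * f * (1 - f);          // forget gate
        dz[H + j] = dC * g * i * (1 - i);          // input gate
        dz[2 * H + j] = dC * i * (1 - g * g);      // candidate
        dz[3 * H + j] = dO * o * (1 - o);          // output gate
        dCn[k] = dC * f;
      }
    }
    dh_rec = L.Wh.t() * dZ.slice(tt);
  }
  arma::Mat<eT> dZmat(dZ.memptr(), 4 * H, B * T, false, true);
  arma::Mat<eT> Xmat(const_cast<eT*>(c.X.memptr()), D, B * T, false, true);
  arma::Mat<eT> Hmat(const_cast<eT*>(c.hprev.memptr()), H, B * T, false, true);
  G.Wx += dZmat * Xmat.t();
  G.Wh += dZmat * Hmat.t();
  G.b += arma::sum(dZmat, 1);
  dX.set_size(D, B, T);
  arma::Mat<eT> dXmat(dX.memptr(), D, B * T, false, true);
  dXmat = L.Wx.t() * dZmat;
}

template <typename eT>
struct ModelCache {
  arma::Cube<eT> A;   // fc1 activations, H1 x B x T
  LayerCache<eT> c1, c2;
  arma::Cube<eT> h1;  // layer-1 outputs (post dropout)
  arma::Cube<eT> h2;  // layer-2 outputs (post dropout)
  arma::Mat<eT> probs;  // M x B
};

// Full forward. X: p x B (columns = cells). In per-gene mode (fc1 weight
// has a single column) every ranked gene is one timestep and fc1 embeds
// its scalar expression; in dense mode (fc1 weight has p columns) fc1 maps
// the whole expression vector to seq_len * embed_dim values that are
// reshaped into a seq_len-step sequence. embed_dim equals the input size
// of the first LSTM layer.
template <typename eT>
static void model_forward(const ScdlcPar<eT>& P, const arma::Mat<eT>& X,
                          bool training, eT keep, bool variational,
                          bool drop_readout, SplitMix& rng, bool keep_cache,
                          ModelCache<eT>& mc) {
  const arma::uword B = X.n_cols;
  const bool dense = P.fc1_cols > 1;
  const arma::uword D1 = P.l1.Wx.n_cols;       // LSTM-1 input size
  if (dense) {
    const arma::uword E = P.fc1_w.n_elem / P.fc1_cols;  // rows of fc1_W
    const arma::uword T = E / D1;
    arma::Mat<eT> W(const_cast<eT*>(P.fc1_w.memptr()), E, P.fc1_cols,
                    false, true);
    arma::Mat<eT> A = W * X;
    A.each_col() += P.fc1_b;
    A.for_each([](eT& v) { if (v < 0) v = 0; });
    mc.A.set_size(D1, B, T);
    for (arma::uword t = 0; t < T; ++t)
      mc.A.slice(t) = A.rows(t * D1, (t + 1) * D1 - 1);
  } else {
  const arma::uword T = X.n_rows;
  const arma::uword H1 = P.fc1_w.n_elem;
  mc.A.set_size(H1, B, T);
  const eT* wp = P.fc1_w.memptr();
  const eT* bp = P.fc1_b.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    eT* ap = mc.A.slice_memptr(t);
    for (arma::uword col = 0; col < B; ++col) {
      const eT x = X(t, col);
      eT* a = ap + col * H1;
      for (arma::uword j = 0; j < H1; ++j) {
        eT v = wp[j] * x + bp[j];
        a[j] = v > 0 ? v : eT(0);
      }
    }
  }
  }
  lstm_layer_forward(P.l1, mc.A, training, keep, variational, rng, keep_cache,
                     &mc.c1, mc.h1);
  // the second layer's outputs feed only the fc2 readout; dropping them is
  // optional (drop_readout) and off by default
  lstm_layer_forward(P.l2, mc.h1, training && drop_readout, keep, variational,
                     rng, keep_cache, &mc.c2, mc.h2);
  arma::Mat<eT> logits = P.fc2_W * mc.h2.slice(mc.h2.n_slices - 1);
  logits.each_col() += P.fc2_b;
  logits.each_row() -= arma::max(logits, 0);
  arma::Mat<eT> e = arma::exp(logits);
  arma::Row<eT> denom = arma::sum(e, 0);
  e.each_row() /= denom;
  mc.probs = e;
}

// Mean cross-entropy with probability floor.
template <typename eT>
static double ce_loss(const arma::Mat<eT>& probs, const IntegerVector& y) {
  const arma::uword B = probs.n_cols;
  double L = 0;
  for (arma::uword j = 0; j < B; ++j) {
    double p = static_cast<double>(probs(y[j] - 1, j));
    if (p < 1e-12) p = 1e-12;
    L -= std::log(p);
  }
  return L / static_cast<double>(B);
}

template <typename eT>
static ScdlcPar<eT> zero_like(const ScdlcPar<eT>& P) {
  ScdlcPar<eT> G;
  G.fc1_w.zeros(P.fc1_w.n_elem);
  G.fc1_cols = P.fc1_cols;
  G.fc1_b.zeros(P.fc1_b.n_elem);
  G.l1.Wh.zeros(arma::size(P.l1.Wh)); G.l1.Wx.zeros(arma::size(P.l1.Wx));
  G.l1.b.zeros(P.l1.b.n_elem);
  G.l2.Wh.zeros(arma::size(P.l2.Wh)); G.l2.Wx.zeros(arma::size(P.l2.Wx));
  G.l2.b.zeros(P.l2.b.n_elem);
  G.fc2_W.zeros(arma::size(P.fc2_W));
  G.fc2_b.zeros(P.fc2_b.n_elem);
  return G;
}

// loss + gradients for one batch; gradients written into G (zeroed here).
template <typename eT>
static double model_backward(const ScdlcPar<eT>& P, const arma::Mat<eT>& X,
                             const IntegerVector& y, bool training, eT keep,
                             bool variational, bool drop_readout,
                             SplitMix& rng, ScdlcPar<eT>& G) {
  const arma::uword B = X.n_cols;
  ModelCache<eT> mc;
  model_forward(P, X, training, keep, variational, drop_readout, rng, true, mc);
  const arma::uword T = mc.A.n_slices;
  double loss = ce_loss(mc.probs, y);
  G = zero_like(P);
  arma::Mat<eT> dlog = mc.probs;  // softmax + cross-entropy combined
  for (arma::uword j = 0; j < B; ++j) dlog(y[j] - 1, j) -= 1;
  dlog /= static_cast<eT>(B);
  G.fc2_W = dlog * mc.h2.slice(T - 1).t();
  G.fc2_b = arma::sum(dlog, 1);
  arma::Cube<eT> dH2(P.H(), B, T, arma::fill::zeros);
  dH2.slice(T - 1) = P.fc2_W.t() * dlog;
  arma::Cube<eT> dH1, dA;
  lstm_layer_backward(P.l2, mc.c2, dH2, G.l2, dH1);
  lstm_layer_backward(P.l1, mc.c1, dH1, G.l1, dA);
  if (P.fc1_cols > 1) {
    const arma::uword D1 = P.l1.Wx.n_cols;
    const arma::uword E = P.fc1_w.n_elem / P.fc1_cols;
    arma::Mat<eT> dAmat(E, B);
    for (arma::uword t = 0; t < T; ++t)
      dAmat.rows(t * D1, (t + 1) * D1 - 1) = dA.slice(t);
    // ReLU mask from the cached activations
    for (arma::uword t = 0; t < T; ++t) {
      const eT* ap = mc.A.slice_memptr(t);
      eT* dp = dAmat.memptr();
      for (arma::uword col = 0; col < B; ++col)
        for (arma::uword j = 0; j < D1; ++j)
          if (ap[col * D1 + j] <= 0) dp[(t * D1 + j) + col * E] = 0;
    }
    arma::Mat<eT> gW = dAmat * X.t();
    G.fc1_w = arma::vectorise(gW);
    G.fc1_b = arma::sum(dAmat, 1);
  } else {
  const arma::uword H1 = P.fc1_w.n_elem;
  eT* gw = G.fc1_w.memptr();
  eT* gb = G.fc1_b.memptr();
  for (arma::uword t = 0; t < T; ++t) {
    const eT* ap = mc.A.slice_memptr(t);
    const eT* dp = dA.slice_memptr(t);
    for (arma::uword col = 0; col < B; ++col) {
      const eT x = X(t, col);
      const eT* a = ap + col * H1;
      const eT* d = dp + col * H1;
      for (arma::uword j = 0; j < H1; ++j) {
        if (a[j] > 0) {
          gw[j] += d[j] * x;
          gb[j] += d[j];
        }
      }
    }
  }
  }
  return loss;
}

template <typename eT>
static double global_sq_norm(const ScdlcPar<eT>& G) {
  double s = 0;
  auto add = [&s](const eT* p, arma::uword n) {
    for (arma::uword k = 0; k < n; ++k)
      s += static_cast<double>(p[k]) * static_cast<double>(p[k]);
  };
  add(G.fc1_w.memptr(), G.fc1_w.n_elem);
  add(G.fc1_b.memptr(), G.fc1_b.n_elem);
  const LstmLayer<eT>* Ls[2] = {&G.l1, &G.l2};
  for (int k = 0; k < 2; ++k) {
    add(Ls[k]->Wh.memptr(), Ls[k]->Wh.n_elem);
    add(Ls[k]->Wx.memptr(), Ls[k]->Wx.n_elem);
    add(Ls[k]->b.memptr(), Ls[k]->b.n_elem);
  }
  add(G.fc2_W.memptr(), G.fc2_W.n_elem);
  add(G.fc2_b.memptr(), G.fc2_b.n_elem);
  return s;
}

template <typename eT>
static void scale_params(ScdlcPar<eT>& G, eT a) {
  G.fc1_w *= a; G.fc1_b *= a;
  G.l1.Wh *= a; G.l1.Wx *= a; G.l1.b *= a;
  G.l2.Wh *= a; G.l2.Wx *= a; G.l2.b *= a;
  G.fc2_W *= a; G.fc2_b *= a;
}

template <typename eT>
static void axpy_params(ScdlcPar<eT>& P, const ScdlcPar<eT>& G, eT a) {
  P.fc1_w += a * G.fc1_w; P.fc1_b += a * G.fc1_b;
  P.l1.Wh += a * G.l1.Wh; P.l1.Wx += a * G.l1.Wx; P.l1.b += a * G.l1.b;
  P.l2.Wh += a * G.l2.Wh; P.l2.Wx += a * G.l2.Wx; P.l2.b += a * G.l2.b;
  P.fc2_W += a * G.fc2_W; P.fc2_b += a * G.fc2_b;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

template <typename eT>
static NumericMatrix forward_impl(const List& params, const NumericMatrix& X,
                                  double keep_prob, bool training,
                                  bool variational, bool drop_readout,
                                  double seed) {
  ScdlcPar<eT> P = unpack_params<eT>(params);
  arma::Mat<eT> Xe = as_mat<eT>(X);
  SplitMix rng(static_cast<uint64_t>(seed));
  ModelCache<eT> mc;
  model_forward(P, Xe, training, static_cast<eT>(keep_prob), variational,
                drop_readout, rng, false, mc);
  return wrap(arma::conv_to<arma::mat>::from(mc.probs));
}

// [[Rcpp::export(name = ".cpp_forward")]]
NumericMatrix cpp_forward(List params, NumericMatrix X, double keep_prob,
                          bool training, bool variational, bool drop_readout,
                          double seed, bool single) {
  if (single)
    return forward_impl<float>(params, X, keep_prob, training, variational,
                               drop_readout, seed);
  return forward_impl<double>(params, X, keep_prob, training, variational,
                              drop_readout, seed);
}

template <typename eT>
static List loss_grads_impl(const List& params, const NumericMatrix& X,
                            const IntegerVector& y, double keep_prob,
                            bool training, bool variational,
                            bool drop_readout, double seed) {
  ScdlcPar<eT> P = unpack_params<eT>(params);
  arma::Mat<eT> Xe = as_mat<eT>(X);
  SplitMix rng(static_cast<uint64_t>(seed));
  ScdlcPar<eT> G;
  double loss = model_backward(P, Xe, y, training, static_cast<eT>(keep_prob),
                               variational, drop_readout, rng, G);
  return List::create(_["loss"] = loss, _["grads"] = pack_params(G));
}

// [[Rcpp::export(name = ".cpp_loss_grads")]]
List cpp_loss_grads(List params, NumericMatrix X, IntegerVector y,
                    double keep_prob, bool training, bool variational,
                    bool drop_readout, double seed, bool single) {
  if (single)
    return loss_grads_impl<float>(params, X, y, keep_prob, training,
                                  variational, drop_readout, seed);
  return loss_grads_impl<double>(params, X, y, keep_prob, training,
                                 variational, drop_readout, seed);
}

template <typename eT>
static List train_impl(const List& params, const NumericMatrix& X,
                       const IntegerVector& y, int batch_size, int epochs,
                       double max_lr, double min_lr, double grad_clip,
                       double keep_prob, bool variational, bool drop_readout,
                       double total_steps_r, double seed) {
  ScdlcPar<eT> P = unpack_params<eT>(params);
  arma::Mat<eT> Xall = as_mat<eT>(X);
  const int n = static_cast<int>(Xall.n_cols);
  SplitMix rng(static_cast<uint64_t>(seed));
  const double r = total_steps_r > 0 ? std::log(max_lr / min_lr) / total_steps_r : 0.0;
  const int steps_per_epoch = (n + batch_size - 1) / batch_size;
  const int total_updates = epochs * steps_per_epoch;
  std::vector<double> losses, lrs, gnorms;
  std::vector<int> epoch_log;
  losses.reserve(total_updates); lrs.reserve(total_updates);
  gnorms.reserve(total_updates); epoch_log.reserve(total_updates);
  std::vector<int> perm(n);
  long s = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int k = 0; k < n; ++k) perm[k] = k;
    fisher_yates(perm, rng);
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int bn = std::min(batch_size, n - b0);
      arma::Mat<eT> Xb(Xall.n_rows, bn);
      IntegerVector yb(bn);
      for (int j = 0; j < bn; ++j) {
        Xb.col(j) = Xall.col(perm[b0 + j]);
        yb[j] = y[perm[b0 + j]];
      }
      ScdlcPar<eT> G;
      double loss = model_backward(P, Xb, yb, true,
                                   static_cast<eT>(keep_prob), variational,
                                   drop_readout, rng, G);
      if (!std::isfinite(loss))
        stop("training aborted: non-finite loss at step %d (epoch %d)",
             static_cast<int>(s), ep + 1);
      double gn = std::sqrt(global_sq_norm(G));
      if (std::isfinite(grad_clip) && gn > grad_clip)
        scale_params(G, static_cast<eT>(grad_clip / gn));
      double lr = max_lr * std::exp(-r * static_cast<double>(s));
      if (lr < min_lr) lr = min_lr;
      axpy_params(P, G, static_cast<eT>(-lr));
      losses.push_back(loss); lrs.push_back(lr); gnorms.push_back(gn);
      epoch_log.push_back(ep + 1);
      ++s;
    }
  }
  return List::create(
      _["params"] = pack_params(P), _["loss"] = wrap(losses),
      _["lr"] = wrap(lrs), _["grad_norm"] = wrap(gnorms),
      _["epoch"] = wrap(epoch_log), _["steps"] = static_cast<double>(s),
      _["decay_rate"] = r);
}

// [[Rcpp::export(name = ".cpp_train")]]
List cpp_train(List params, NumericMatrix X, IntegerVector y, int batch_size,
               int epochs, double max_lr, double min_lr, double grad_clip,
               double keep_prob, bool variational, bool drop_readout,
               double total_steps_r, double seed, bool single) {
  if (single)
    return train_impl<float>(params, X, y, batch_size, epochs, max_lr, min_lr,
                             grad_clip, keep_prob, variational, drop_readout,
                             total_steps_r, seed);
  return train_impl<double>(params, X, y, batch_size, epochs, max_lr, min_lr,
                            grad_clip, keep_prob, variational, drop_readout,
                            total_steps_r, seed);
}
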