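// Bidirectional GRU classifier over hybrid (token, signal) windows.
//
// Architecture: token embedding lookup (V x d, trained jointly), the scalar
// per-bp signal appended to each embedding vector (d+1 inputs per position),
// one GRU layer per reading direction (h units each), concatenation of the
// two final hidden states (2h), dropout, then a single sigmoid output.
// Loss is binary cross-entropy, optimized with Adam.  Everything runs in
// single precision on the CPU; all randomness (initialization, shuffling,
// dropout) comes from one std::mt19937 seeded from the config, so training
// is bit-reproducible for a fixed seed.
//
// GRU cell (per direction), with x_t the input column and h the previous
// state:
//   z = sigmoid(W_z x + U_z h + b_z)
//   r = sigmoid(W_r x + U_r h + b_r)
//   n = tanh(W_n x + r o (U_n h + b_n))
//   h' = (1 - z) o n + z o h
// All activations are stored features-by-samples (column at t*B + b for
// window b of the batch at position t) so per-step reads and writes are
// contiguous and every cross-step reduction is a single sgemm.

#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define PEAKTX_HAVE_SSE 1
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

namespace {

// Backpropagation through 1000 timesteps drives gradient magnitudes below
// the normalized float range; without flush-to-zero, the resulting
// subnormals make every BLAS call on those buffers orders of magnitude
// slower.  Values below ~1e-38 are numerical noise here, so flushing them
// is free accuracy-wise.  The previous FP environment is restored on exit.
struct FlushDenormals {
#ifdef PEAKTX_HAVE_SSE
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

struct GruDir {
  fmat W;   // 3h x (d+1): rows are the z, r, n gate blocks
  fmat U;   // 3h x h
  fvec bx;  // 3h
  fvec bh;  // 3h
};

struct Net {
  fmat Emb;  // d x V, one column per token
  GruDir fw, bw;
  fvec wout;  // 2h
  float bout;
  int d, h, V;
};

// Fast float exp: round-to-nearest base-2 range reduction plus a 5th-order
// polynomial on the residual; relative error ~1e-7, branch-free, and far
// cheaper than libm expf in the per-timestep gate activations.
inline float fast_expf(float x) {
  x = std::max(-87.0f, std::min(88.0f, x));
  const float n = std::floor(x * 1.44269504f + 0.5f);
  const float r = x - n * 0.693147181f;
  const float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.166666667f +
                  r * (0.0416666667f + r * 0.00833333333f))));
  int32_t ei = ((int32_t)n + 127) << 23;
  float s;
  std::memcpy(&s, &ei, sizeof(s));
  return p * s;
}

// Contiguous array kernels; simple loops so the compiler can vectorize.
inline void sigmoid_add(const float* a, const float* b, float* out, int n) {
  for (int i = 0; i < n; ++i)
    out[i] = 1.0f / (1.0f + fast_expf(-(a[i] + b[i])));
}

inline void tanh_gated(const float* g, const float* r, const float* an,
                       float* out, int n) {
  for (int i = 0; i < n; ++i) {
    const float e = fast_expf(2.0f * (g[i] + r[i] * an[i]));
    out[i] = (e - 1.0f) / (e + 1.0f);
  }
}

// Mann-Whitney AUC with ties counted half.
double auc_score(const std::vector<double>& s, const std::vector<int>& y) {
  const size_t n = s.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return s[a] < s[b]; });
  std::vector<double> rank(n);
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double avg = 0.5 * (double)(i + j) + 1.0;  // average 1-based rank
    for (size_t k = i; k <= j; ++k) rank[ord[k]] = avg;
    i = j + 1;
  }
  double sum_pos = 0.0;
  size_t n1 = 0;
  for (size_t k = 0; k < n; ++k)
    if (y[k] == 1) { sum_pos += rank[k]; ++n1; }
  size_t n0 = n - n1;
  if (n1 == 0 || n0 == 0) Rcpp::stop("AUC undefined for single-class labels");
  return (sum_pos - 0.5 * n1 * (n1 + 1.0)) / ((double)n1 * (double)n0);
}

// Assemble the (d+1 x T*B) input matrix for a batch: the embedding column
// of each token with the signal scalar appended.
void build_inputs(const Net& net, const IntegerMatrix& tokens,
                  const fmat& signal, const std::vector<int>& idx,
                  fmat& X) {
  const int T = tokens.nrow();
  const int B = (int)idx.size();
  const int d = net.d;
  X.set_size(d + 1, (uword)T * B);
  for (int t = 0; t < T; ++t) {
    for (int b = 0; b < B; ++b) {
      const int col = idx[b];
      const uword out = (uword)t * B + b;
      X.submat(0, out, d - 1, out) = net.Emb.col(tokens(t, col));
      X(d, out) = signal(t, col);
    }
  }
}

// Per-step activations kept for backpropagation through time, stored as
// 3h x T*B (gates) and h x T*B blocks at columns [t*B, (t+1)*B).
struct DirStore {
  fmat Z, R, N, An, Hprev;
};

fmat run_dir(const GruDir& dir, const fmat& X, int T, int B, int h,
             bool forward, DirStore* store) {
  fmat G = dir.W * X;          // 3h x T*B input projections, one gemm
  G.each_col() += dir.bx;
  fmat H(h, B, fill::zeros);
  fmat Ah(3 * h, B);
  std::vector<float> zbuf(h), rbuf(h), nbuf(h);
  if (store) {
    store->Z.set_size(h, (uword)T * B);
    store->R.set_size(h, (uword)T * B);
    store->N.set_size(h, (uword)T * B);
    store->An.set_size(h, (uword)T * B);
    store->Hprev.set_size(h, (uword)T * B);
  }
  for (int k = 0; k < T; ++k) {
    const int t = forward ? k : (T - 1 - k);
    const uword c0 = (uword)t * B;
    Ah = dir.U * H;
    Ah.each_col() += dir.bh;
    // gate update in contiguous vectorizable passes, one window at a time
    for (int b = 0; b < B; ++b) {
      const float* g = G.colptr(c0 + b);
      const float* ah = Ah.colptr(b);
      float* hc = H.colptr(b);
      float* z = store ? store->Z.colptr(c0 + b) : zbuf.data();
      float* r = store ? store->R.colptr(c0 + b) : rbuf.data();
      float* nn = store ? store->N.colptr(c0 + b) : nbuf.data();
      sigmoid_add(g, ah, z, h);
      sigmoid_add(g + h, ah + h, r, h);
      tanh_gated(g + 2 * h, r, ah + 2 * h, nn, h);
      if (store) {
        std::memcpy(store->An.colptr(c0 + b), ah + 2 * h,
                    h * sizeof(float));
        std::memcpy(store->Hprev.colptr(c0 + b), hc, h * sizeof(float));
      }
      for (int i = 0; i < h; ++i)
        hc[i] = (1.0f - z[i]) * nn[i] + z[i] * hc[i];
    }
  }
  return H;
}

struct DirGrads {
  fmat dW, dU;
  fvec dbx, dbh;
};

// BPTT through one direction; accumulates the input gradient into dX.
void backward_dir(const GruDir& dir, const DirStore& st, const fmat& X,
                  fmat dh, int T, int B, int h, bool forward,
                  fmat& dX, DirGrads& g) {
  fmat dG(3 * h, (uword)T * B);   // input-side pre-activation grads
  fmat dAh(3 * h, (uword)T * B);  // recurrent-side grads
  std::vector<float> dnp_buf(h);
  for (int k = T - 1; k >= 0; --k) {
    const int t = forward ? k : (T - 1 - k);
    const uword c0 = (uword)t * B, c1 = (uword)t * B + B - 1;
    // per-window gate gradients in contiguous vectorizable passes; the
    // recurrent gemm below adds the carried-state contribution
    for (int b = 0; b < B; ++b) {
      const float* z = st.Z.colptr(c0 + b);
      const float* r = st.R.colptr(c0 + b);
      const float* nn = st.N.colptr(c0 + b);
      const float* an = st.An.colptr(c0 + b);
      const float* hp = st.Hprev.colptr(c0 + b);
      float* dhc = dh.colptr(b);
      float* dac = dAh.colptr(c0 + b);
      float* dgc = dG.colptr(c0 + b);
      float* dnp = dnp_buf.data();
      for (int i = 0; i < h; ++i)
        dnp[i] = dhc[i] * (1.0f - z[i]) * (1.0f - nn[i] * nn[i]);
      for (int i = 0; i < h; ++i)
        dgc[i] = dac[i] = dhc[i] * (hp[i] - nn[i]) * z[i] * (1.0f - z[i]);
      for (int i = 0; i < h; ++i)
        dgc[h + i] = dac[h + i] = dnp[i] * an[i] * r[i] * (1.0f - r[i]);
      for (int i = 0; i < h; ++i) {
        dac[2 * h + i] = dnp[i] * r[i];
        dgc[2 * h + i] = dnp[i];
      }
      for (int i = 0; i < h; ++i) dhc[i] *= z[i];
    }
    dh += dir.U.t() * dAh.cols(c0, c1);
  }
  g.dW = dG * X.t();
  g.dU = dAh * st.Hprev.t();
  g.dbx = sum(dG, 1);
  g.dbh = sum(dAh, 1);
  dX += dir.W.t() * dG;
}

// One Adam moment pair per parameter tensor.
struct Adam {
  std::vector<fmat> m, v;
  int t = 0;
  float lr, b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  void init(const std::vector<fmat*>& params, float lr_) {
    lr = lr_;
    for (const fmat* p : params) {
      m.emplace_back(size(*p), fill::zeros);
      v.emplace_back(size(*p), fill::zeros);
    }
  }
  void step(std::vector<fmat*> params, const std::vector<fmat*>& grads) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0f - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0f - b2) * square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

fmat as_fmat(const NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = 0; i < x.nrow(); ++i) out(i, j) = (float)x(i, j);
  return out;
}

NumericMatrix as_rmat(const fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  for (uword j = 0; j < x.n_cols; ++j)
    for (uword i = 0; i < x.n_rows; ++i) out(i, j) = x(i, j);
  return out;
}

std::vector<double> predict_net(const Net& net, const IntegerMatrix& tokens,
                                const fmat& signal, int batch_size) {
  const int n = tokens.ncol();
  const int T = tokens.nrow();
  const int h = net.h;
  std::vector<double> out(n);
  for (int lo = 0; lo < n; lo += batch_size) {
    const int hi = std::min(lo + batch_size, n);
    std::vector<int> idx(hi - lo);
    for (int i = lo; i < hi; ++i) idx[i - lo] = i;
    fmat X;
    build_inputs(net, tokens, signal, idx, X);
    fmat Hf = run_dir(net.fw, X, T, (int)idx.size(), h, true, nullptr);
    fmat Hb = run_dir(net.bw, X, T, (int)idx.size(), h, false, nullptr);
    fmat C = join_cols(Hf, Hb);  // 2h x B
    frowvec logit = net.wout.t() * C + net.bout;
    for (size_t b = 0; b < idx.size(); ++b)
      out[lo + b] = 1.0 / (1.0 + std::exp(-(double)logit(b)));
  }
  return out;
}

// Glorot-uniform input weights, orthogonal recurrent weights per gate and
// zero biases, with +1 on the update-gate bias so the initial network
// carries state across the long window (the recurrent-net analogue of the
// LSTM forget-bias trick; without it, gradients from mid-window positions
// cannot reach the final states through 500+ steps).
void init_dir(GruDir& dir, int in, int h, std::mt19937& rng) {
  const float k = std::sqrt(6.0f / (float)(in + h));
  std::uniform_real_distribution<float> unif(-k, k);
  std::normal_distribution<float> norm(0.0f, 1.0f);
  dir.W.set_size(3 * h, in);
  for (uword i = 0; i < dir.W.n_elem; ++i) dir.W(i) = unif(rng);
  dir.U.set_size(3 * h, h);
  for (int gate = 0; gate < 3; ++gate) {
    fmat A(h, h);
    for (uword i = 0; i < A.n_elem; ++i) A(i) = norm(rng);
    fmat Q, Rm;
    qr_econ(Q, Rm, A);
    // sign-fix so the factorization (hence the init) is unique
    for (int j = 0; j < h; ++j)
      if (Rm(j, j) < 0) Q.col(j) *= -1.0f;
    dir.U.rows(gate * h, gate * h + h - 1) = Q;
  }
  dir.bx.zeros(3 * h);
  dir.bh.zeros(3 * h);
  dir.bx.subvec(0, h - 1).fill(1.0f);  // update-gate carry bias
}

List net_to_list(const Net& net) {
  return List::create(
      Rcpp::Named("Emb") = as_rmat(net.Emb),
      Rcpp::Named("W_fwd") = as_rmat(net.fw.W),
      Rcpp::Named("U_fwd") = as_rmat(net.fw.U),
      Rcpp::Named("bx_fwd") = as_rmat(fmat(net.fw.bx)),
      Rcpp::Named("bh_fwd") = as_rmat(fmat(net.fw.bh)),
      Rcpp::Named("W_rev") = as_rmat(net.bw.W),
      Rcpp::Named("U_rev") = as_rmat(net.bw.U),
      Rcpp::Named("bx_rev") = as_rmat(fmat(net.bw.bx)),
      Rcpp::Named("bh_rev") = as_rmat(fmat(net.bw.bh)),
      Rcpp::Named("w_out") = as_rmat(fmat(net.wout)),
      Rcpp::Named("b_out") = (double)net.bout,
      Rcpp::Named("embedding_dim") = net.d,
      Rcpp::Named("hidden_size") = net.h,
      Rcpp::Named("vocab_size") = net.V);
}

Net net_from_list(const List& p) {
  Net net;
  net.d = Rcpp::as<int>(p["embedding_dim"]);
  net.h = Rcpp::as<int>(p["hidden_size"]);
  net.V = Rcpp::as<int>(p["vocab_size"]);
  net.Emb = as_fmat(p["Emb"]);
  net.fw.W = as_fmat(p["W_fwd"]);
  net.fw.U = as_fmat(p["U_fwd"]);
  net.fw.bx = vectorise(as_fmat(p["bx_fwd"]));
  net.fw.bh = vectorise(as_fmat(p["bh_fwd"]));
  net.bw.W = as_fmat(p["W_rev"]);
  net.bw.U = as_fmat(p["U_rev"]);
  net.bw.bx = vectorise(as_fmat(p["bx_rev"]));
  net.bw.bh = vectorise(as_fmat(p["bh_rev"]));
  net.wout = vectorise(as_fmat(p["w_out"]));
  net.bout = (float)Rcpp::as<double>(p["b_out"]);
  return net;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_gru_train(IntegerMatrix tokens, NumericMatrix signal,
                         IntegerVector labels, IntegerMatrix vtokens,
                         NumericMatrix vsignal, IntegerVector vlabels,
                         Rcpp::List cfg) {
  const int d = Rcpp::as<int>(cfg["embedding_dim"]);
  const int h = Rcpp::as<int>(cfg["hidden_size"]);
  const int V = Rcpp::as<int>(cfg["vocab_size"]);
  const float dropout = (float)Rcpp::as<double>(cfg["dropout"]);
  const float lr = (float)Rcpp::as<double>(cfg["learning_rate"]);
  const int max_epochs = Rcpp::as<int>(cfg["max_epochs"]);
  const int batch_size = Rcpp::as<int>(cfg["batch_size"]);
  const int patience = Rcpp::as<int>(cfg["early_stop_patience"]);
  const unsigned seed = (unsigned)Rcpp::as<int>(cfg["seed"]);
  const bool verbose = cfg.containsElementNamed("verbose") ?
      Rcpp::as<bool>(cfg["verbose"]) : false;

  FlushDenormals ftz;
  const int n = tokens.ncol();
  const int T = tokens.nrow();
  std::mt19937 rng(seed);

  Net net;
  net.d = d; net.h = h; net.V = V;
  {
    std::uniform_real_distribution<float> eunif(-0.1f, 0.1f);
    net.Emb.set_size(d, V);
    for (uword i = 0; i < net.Emb.n_elem; ++i) net.Emb(i) = eunif(rng);
    init_dir(net.fw, d + 1, h, rng);
    init_dir(net.bw, d + 1, h, rng);
    const float k = 1.0f / std::sqrt((float)(2 * h));
    std::uniform_real_distribution<float> ounif(-k, k);
    net.wout.set_size(2 * h);
    for (int i = 0; i < 2 * h; ++i) net.wout(i) = ounif(rng);
    net.bout = ounif(rng);
  }

  fmat sig = as_fmat(signal);
  fmat vsig = as_fmat(vsignal);
  std::vector<int> vlab(vlabels.begin(), vlabels.end());

  // Adam over all tensors; vectors wrapped as single-column matrices.
  fmat bxf(net.fw.bx), bhf(net.fw.bh), bxr(net.bw.bx), bhr(net.bw.bh);
  fmat wo(net.wout), bo(1, 1);
  bo(0, 0) = net.bout;
  auto sync_net = [&]() {
    net.fw.bx = bxf.col(0); net.fw.bh = bhf.col(0);
    net.bw.bx = bxr.col(0); net.bw.bh = bhr.col(0);
    net.wout = wo.col(0); net.bout = bo(0, 0);
  };
  std::vector<fmat*> params = {&net.Emb, &net.fw.W, &net.fw.U, &bxf, &bhf,
                               &net.bw.W, &net.bw.U, &bxr, &bhr, &wo, &bo};
  Adam adam;
  adam.init(params, lr);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uniform_real_distribution<float> du(0.0f, 1.0f);

  std::vector<double> ep_loss, ep_auc;
  List best_params = net_to_list(net);
  double best_auc = -1.0;
  int best_epoch = 0, stall = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double total_loss = 0.0;
    int n_batches = 0;
    for (int lo = 0; lo < n; lo += batch_size) {
      const int hi = std::min(lo + batch_size, n);
      const int B = hi - lo;
      std::vector<int> idx(order.begin() + lo, order.begin() + hi);
      fmat X;
      build_inputs(net, tokens, sig, idx, X);
      DirStore stf, stb;
      fmat Hf = run_dir(net.fw, X, T, B, h, true, &stf);
      fmat Hb = run_dir(net.bw, X, T, B, h, false, &stb);
      fmat C = join_cols(Hf, Hb);  // 2h x B
      fmat mask(2 * h, B, fill::ones);
      if (dropout > 0.0f) {
        for (uword i = 0; i < mask.n_elem; ++i)
          mask(i) = du(rng) < dropout ? 0.0f : 1.0f / (1.0f - dropout);
        C %= mask;
      }
      fvec logit = (net.wout.t() * C).t() + net.bout;
      fvec p = 1.0f / (1.0f + exp(-logit));
      fvec y(B);
      for (int b = 0; b < B; ++b) y(b) = (float)labels[idx[b]];
      fvec pc = clamp(p, 1e-7f, 1.0f - 1e-7f);
      double loss = -mean(conv_to<vec>::from(
          y % log(pc) + (1.0f - y) % log(1.0f - pc)));
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
      total_loss += loss;
      ++n_batches;

      fvec dlogit = (p - y) / (float)B;
      fmat dwo = C * dlogit;                 // 2h x 1
      fmat dbo(1, 1);
      dbo(0, 0) = accu(dlogit);
      fmat dC = net.wout * dlogit.t();       // 2h x B
      if (dropout > 0.0f) dC %= mask;
      fmat dX(size(X), fill::zeros);
      DirGrads gf, gb;
      backward_dir(net.fw, stf, X, dC.rows(0, h - 1), T, B, h, true, dX, gf);
      backward_dir(net.bw, stb, X, dC.rows(h, 2 * h - 1), T, B, h, false,
                   dX, gb);
      fmat dEmb(d, V, fill::zeros);
      for (int t = 0; t < T; ++t)
        for (int b = 0; b < B; ++b)
          dEmb.col(tokens(t, idx[b])) +=
              dX.submat(0, (uword)t * B + b, d - 1, (uword)t * B + b);
      fmat gbxf(gf.dbx), gbhf(gf.dbh), gbxr(gb.dbx), gbhr(gb.dbh);
      std::vector<fmat*> grads = {&dEmb, &gf.dW, &gf.dU, &gbxf, &gbhf,
                                  &gb.dW, &gb.dU, &gbxr, &gbhr, &dwo, &dbo};
      adam.step(params, grads);
      sync_net();
      if ((n_batches & 7) == 0) Rcpp::checkUserInterrupt();
    }
    std::vector<double> vp = predict_net(net, vtokens, vsig, batch_size);
    double vauc = auc_score(vp, vlab);
    ep_loss.push_back(total_loss / n_batches);
    ep_auc.push_back(vauc);
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch << ": loss "
                  << total_loss / n_batches << ", val AUC " << vauc << "\n";
    if (vauc > best_auc + 1e-6) {
      best_auc = vauc;
      best_epoch = epoch;
      best_params = net_to_list(net);
      stall = 0;
    } else {
      if (vauc >= best_auc - 1e-9) {
        // AUC tie: keep the longer-trained parameters -- ranking is equal
        // but the probabilities keep calibrating as the loss drops
        best_epoch = epoch;
        best_params = net_to_list(net);
      }
      if (++stall >= patience) break;
    }
  }

  return List::create(
      Rcpp::Named("params") = best_params,
      Rcpp::Named("loss") = NumericVector(ep_loss.begin(), ep_loss.end()),
      Rcpp::Named("val_auc") = NumericVector(ep_auc.begin(), ep_auc.end()),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_auc") = best_auc);
}

// [[Rcpp::export]]
NumericVector cpp_gru_predict(Rcpp::List params, IntegerMatrix tokens,
                              NumericMatrix signal, int batch_size) {
  FlushDenormals ftz;
  Net net = net_from_list(params);
  fmat sig = as_fmat(signal);
  std::vector<double> p = predict_net(net, tokens, sig, batch_size);
  return NumericVector(p.begin(), p.end());
}
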