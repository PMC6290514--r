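// Skip-gram-with-negative-sampling training core for the joint
// code+word embedding model.  All randomness is driven by a local
// xorshift128+ generator seeded from a single integer, so identical
// seeds give byte-identical results independent of R's RNG state.
//
// Matrices are passed transposed (T x n_tokens) so that each token's
// vector is a contiguous column.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into two nonzero state words
    for (int i = 0; i < 2; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      z ^= z >> 31;
      if (i == 0) s0 = z | 1ULL; else s1 = z | 1ULL;
    }
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// rng streams derived from one user seed; constants only decorrelate
const uint64_t STREAM_INIT = 0, STREAM_SHUFFLE = 1, STREAM_NEG = 2;

inline uint64_t stream_seed(int seed, uint64_t stream) {
  return (uint64_t)(uint32_t)seed * 0x100000001b3ULL + stream;
}

inline double sigmoid(double x) {
  if (x >= 0) { double z = std::exp(-x); return 1.0 / (1.0 + z); }
  double z = std::exp(x); return z / (1.0 + z);
}

// draw index in [0, m) from the distribution whose cumulative sums are
// in cum (cum[m-1] == 1); binary search keeps draws O(log m)
inline int sample_cum(const std::vector<double>& cum, Rng& rng) {
  double u = rng.unif();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

void shuffle_epoch(std::vector<int>& idx, Rng& rng) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

// note-boundary segments: words[i] < 0 marks a boundary sentinel
std::vector<int> segments(const IntegerVector& words) {
  std::vector<int> seg(words.size());
  int s = 0;
  for (int i = 0; i < words.size(); ++i) {
    if (words[i] < 0) ++s;
    seg[i] = s;
  }
  return seg;
}

struct PairSink {
  bool record;
  std::vector<int> tgt, ctx;
  void emit(int t, int c) { if (record) { tgt.push_back(t); ctx.push_back(c); } }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_visit_schedule(int n_visits, int epochs, int seed) {
  Rng rng(stream_seed(seed, STREAM_SHUFFLE));
  IntegerVector out((R_xlen_t)n_visits * epochs);
  std::vector<int> idx(n_visits);
  R_xlen_t k = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n_visits; ++i) idx[i] = i;
    shuffle_epoch(idx, rng);
    for (int i = 0; i < n_visits; ++i) out[k++] = idx[i] + 1; // 1-based
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_init_vectors(int dim, int n_tokens, int seed) {
  Rng rng(stream_seed(seed, STREAM_INIT));
  NumericMatrix V(dim, n_tokens);
  double half = 0.5 / dim;
  for (int j = 0; j < n_tokens; ++j)
    for (int d = 0; d < dim; ++d)
      V(d, j) = (rng.unif() * 2.0 - 1.0) * half;
  return V;
}

// One simultaneous gradient-ascent step on a (target, context,
// negatives) triple: every sigmoid is evaluated at the current point,
// then all rows move at once.  Exposed for cross-checking the R
// reference implementation; the trainer below inlines the same math.
// [[Rcpp::export]]
void cpp_pair_update(NumericMatrix V, NumericMatrix U, int target, int context,
                     IntegerVector negatives, double lr) {
  int T = V.nrow();
  double* vt = &V(0, target - 1);
  double* uc = &U(0, context - 1);
  int K = negatives.size();
  double dot = 0;
  for (int d = 0; d < T; ++d) dot += vt[d] * uc[d];
  if (!std::isfinite(dot)) stop("non-finite dot product in update");
  double gpos = lr * (1.0 - sigmoid(dot));
  std::vector<double> acc(T);
  for (int d = 0; d < T; ++d) acc[d] = gpos * uc[d];
  std::vector<double> gneg(K);
  for (int k = 0; k < K; ++k) {
    double* un = &U(0, negatives[k] - 1);
    double dn = 0;
    for (int d = 0; d < T; ++d) dn += vt[d] * un[d];
    if (!std::isfinite(dn)) stop("non-finite dot product in update");
    gneg[k] = -lr * sigmoid(dn);
    for (int d = 0; d < T; ++d) acc[d] += gneg[k] * un[d];
  }
  for (int d = 0; d < T; ++d) uc[d] += gpos * vt[d];
  for (int k = 0; k < K; ++k) {
    double* un = &U(0, negatives[k] - 1);
    for (int d = 0; d < T; ++d) un[d] += gneg[k] * vt[d];
  }
  for (int d = 0; d < T; ++d) vt[d] += acc[d];
}

// Full training loop.  code_sets / word_seqs hold 0-based global token
// ids per visit (word ids in [0, n_words), code ids in [n_words,
// n_tokens); negative word ids in word_seqs are note-boundary
// sentinels).  word_cum / code_cum are cumulative noise probabilities
// over the word / code id blocks.  V and U (dim x n_tokens) are
// updated in place.  mode: 0 = joint, 1 = words_only, 2 = codes_only.
// [[Rcpp::export]]
List cpp_train(List code_sets, List word_seqs, NumericMatrix V, NumericMatrix U,
               int n_words, NumericVector word_cum, NumericVector code_cum,
               int mode, int epochs, int window, int negatives,
               double lr0, double lr_final, bool linear_decay, int seed,
               bool record_pairs) {
  int n_visits = code_sets.size();
  if (word_seqs.size() != n_visits) stop("code_sets and word_seqs length mismatch");
  int T = V.nrow();
  bool do_codes = (mode == 0 || mode == 2);
  bool do_words = (mode == 0 || mode == 1);
  bool joint = (mode == 0);

  std::vector<std::vector<int>> codes(n_visits), words(n_visits), seg(n_visits);
  for (int v = 0; v < n_visits; ++v) {
    IntegerVector cs = code_sets[v], ws = word_seqs[v];
    codes[v].assign(cs.begin(), cs.end());
    words[v].assign(ws.begin(), ws.end());
    IntegerVector wv(ws);
    seg[v] = segments(wv);
  }

  // total scheduled (target, context) pairs, for the linear lr decay
  double total_pairs = 0;
  for (int v = 0; v < n_visits; ++v) {
    double nc = (double)codes[v].size();
    double nw = 0;
    for (size_t i = 0; i < words[v].size(); ++i) if (words[v][i] >= 0) nw += 1;
    if (do_codes) {
      total_pairs += nc * (nc - 1);
      if (joint) total_pairs += nc * nw;
    }
    if (do_words) {
      for (size_t i = 0; i < words[v].size(); ++i) {
        if (words[v][i] < 0) continue;
        int lo = std::max((int)i - window, 0);
        int hi = std::min((int)i + window, (int)words[v].size() - 1);
        for (int j = lo; j <= hi; ++j)
          if (j != (int)i && words[v][j] >= 0 && seg[v][j] == seg[v][i]) total_pairs += 1;
        if (joint) total_pairs += nc;
      }
    }
  }
  total_pairs *= epochs;

  std::vector<double> wcum(word_cum.begin(), word_cum.end());
  std::vector<double> ccum(code_cum.begin(), code_cum.end());
  Rng rng_shuf(stream_seed(seed, STREAM_SHUFFLE));
  Rng rng_neg(stream_seed(seed, STREAM_NEG));
  PairSink sink; sink.record = record_pairs;

  std::vector<double> acc(T), gneg(negatives > 0 ? negatives : 1);
  std::vector<int> negid(negatives > 0 ? negatives : 1);
  double processed = 0;
  double lr = lr0;

  bool do_sgd = !record_pairs; // recording runs only enumerate the stream

  // positive (t, c) plus K negatives from c's namespace
  auto sgd_pair = [&](int t, int c) {
    sink.emit(t + 1, c + 1);
    if (total_pairs > 0 && linear_decay) {
      double f = processed / total_pairs;
      lr = lr0 + (lr_final - lr0) * f;
    }
    processed += 1;
    if (!do_sgd) return;
    bool cw = c < n_words; // context namespace: word or code
    const std::vector<double>& cum = cw ? wcum : ccum;
    int base = cw ? 0 : n_words;
    double* vt = &V(0, t);
    double* uc = &U(0, c);
    double dot = 0;
    for (int d = 0; d < T; ++d) dot += vt[d] * uc[d];
    if (!std::isfinite(dot))
      stop("non-finite update encountered (target id %d); try a smaller learning rate", t + 1);
    double gpos = lr * (1.0 - sigmoid(dot));
    for (int d = 0; d < T; ++d) acc[d] = gpos * uc[d];
    for (int k = 0; k < negatives; ++k) {
      negid[k] = base + sample_cum(cum, rng_neg);
      double* un = &U(0, negid[k]);
      double dn = 0;
      for (int d = 0; d < T; ++d) dn += vt[d] * un[d];
      if (!std::isfinite(dn))
        stop("non-finite update encountered (negative id %d); try a smaller learning rate", negid[k] + 1);
      gneg[k] = -lr * sigmoid(dn);
      for (int d = 0; d < T; ++d) acc[d] += gneg[k] * un[d];
    }
    for (int d = 0; d < T; ++d) uc[d] += gpos * vt[d];
    for (int k = 0; k < negatives; ++k) {
      double* un = &U(0, negid[k]);
      for (int d = 0; d < T; ++d) un[d] += gneg[k] * vt[d];
    }
    for (int d = 0; d < T; ++d) vt[d] += acc[d];
  };

  std::vector<int> order(n_visits);
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < n_visits; ++i) order[i] = i;
    shuffle_epoch(order, rng_shuf);
    for (int oi = 0; oi < n_visits; ++oi) {
      int v = order[oi];
      const std::vector<int>& D = codes[v];
      const std::vector<int>& N = words[v];
      int nc = (int)D.size(), nw = (int)N.size();
      if (do_codes) {
        for (int i = 0; i < nc; ++i) {
          for (int j = 0; j < nc; ++j) if (j != i) sgd_pair(D[i], D[j]);
          if (joint)
            for (int j = 0; j < nw; ++j) if (N[j] >= 0) sgd_pair(D[i], N[j]);
        }
      }
      if (do_words) {
        for (int i = 0; i < nw; ++i) {
          if (N[i] < 0) continue;
          int lo = std::max(i - window, 0);
          int hi = std::min(i + window, nw - 1);
          for (int j = lo; j <= hi; ++j)
            if (j != i && N[j] >= 0 && seg[v][j] == seg[v][i]) sgd_pair(N[i], N[j]);
          if (joint)
            for (int j = 0; j < nc; ++j) sgd_pair(N[i], D[j]);
        }
      }
      if ((oi & 0x3ff) == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(_["n_pairs"] = processed, _["final_lr"] = lr);
  if (record_pairs) {
    IntegerMatrix P((int)sink.tgt.size(), 2);
    for (int i = 0; i < (int)sink.tgt.size(); ++i) { P(i, 0) = sink.tgt[i]; P(i, 1) = sink.ctx[i]; }
    out["pairs"] = P;
  }
  return out;
}
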