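#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xorshift64* PRNG: deterministic, platform-independent, independent of R's
// global RNG stream.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// Truncated random walks: gamma passes; each pass shuffles the vertex order
// and starts one walk per vertex. Walks take uniform steps among neighbours
// and truncate at isolated vertices. adj holds 1-based neighbour indices.
// [[Rcpp::export]]
List cpp_generate_corpus(List adj, int gamma, int t, double seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nbr[i].assign(v.begin(), v.end());
  }
  XorShift rng((uint64_t)seed);
  List out(n * gamma);
  int k = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int pass = 0; pass < gamma; ++pass) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int i = 0; i < n; ++i) {
      int cur = order[i];
      std::vector<int> walk;
      walk.push_back(cur + 1);
      for (int step = 1; step < t; ++step) {
        const std::vector<int> &nb = nbr[cur];
        if (nb.empty()) break;
        cur = nb[rng.below((int)nb.size())] - 1;
        walk.push_back(cur + 1);
      }
      out[k++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

// word2vec-style precomputed sigmoid over [-6, 6]
#define EXP_TABLE_SIZE 1000
#define MAX_EXP 6.0f
static float exp_table[EXP_TABLE_SIZE];
static bool exp_table_ready = false;
static void init_exp_table() {
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    float x = (i / (float)EXP_TABLE_SIZE * 2.0f - 1.0f) * MAX_EXP;
    exp_table[i] = 1.0f / (1.0f + std::exp(-x));
  }
  exp_table_ready = true;
}
static inline float sigmoid(float x) {
  if (x >= MAX_EXP) return 1.0f;
  if (x <= -MAX_EXP) return 0.0f;
  return exp_table[(int)((x + MAX_EXP) * (EXP_TABLE_SIZE / (2.0f * MAX_EXP)))];
}

// Skip-gram with negative sampling over a walk corpus (1-based node ids).
// Single-threaded and deterministic under the seed. Returns the input
// embedding matrix (n_nodes x d); the attribute "trained" flags nodes whose
// vector was ever updated by a centre-context pair.
// [[Rcpp::export]]
NumericMatrix cpp_train_sgns(List walks, int n_nodes, int d, int window,
                             int epochs, int negative, double alpha0,
                             double seed) {
  int n_walks = walks.size();
  std::vector<std::vector<int>> ws(n_walks);
  std::vector<double> freq(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < n_walks; ++i) {
    IntegerVector v = walks[i];
    ws[i].assign(v.begin(), v.end());
    for (int x : ws[i]) { freq[x - 1] += 1.0; ++total_tokens; }
  }
  XorShift rng((uint64_t)seed);

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 17;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int i = 0; i < n_nodes; ++i) z += std::pow(freq[i], 0.75);
  if (z <= 0) stop("empty corpus");
  {
    int i = 0;
    double cum = std::pow(freq[0], 0.75) / z;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((a + 1.0) / table_size > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(freq[i], 0.75) / z;
      }
    }
  }

  if (!exp_table_ready) init_exp_table();
  std::vector<float> syn0((size_t)n_nodes * d), syn1((size_t)n_nodes * d, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / d);
  std::vector<int> touched(n_nodes, 0);
  std::vector<float> neu1e(d);

  long long processed = 0;
  const long long total = (long long)epochs * total_tokens;
  double alpha = alpha0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < n_walks; ++wi) {
      const std::vector<int> &walk = ws[wi];
      int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        ++processed;
        alpha = alpha0 * (1.0 - (double)processed / (double)(total + 1));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        int center = walk[pos] - 1;
        int lo = pos - window < 0 ? 0 : pos - window;
        int hi = pos + window >= len ? len - 1 : pos + window;
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int context = walk[cpos] - 1;
          float *v_in = &syn0[(size_t)context * d];
          std::fill(neu1e.begin(), neu1e.end(), 0.0f);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; float label;
            if (neg == 0) { target = center; label = 1.0f; }
            else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0f;
            }
            float *v_out = &syn1[(size_t)target * d];
            float dot = 0.0f;
            for (int j = 0; j < d; ++j) dot += v_in[j] * v_out[j];
            float g = (label - sigmoid(dot)) * (float)alpha;
            for (int j = 0; j < d; ++j) neu1e[j] += g * v_out[j];
            for (int j = 0; j < d; ++j) v_out[j] += g * v_in[j];
          }
          for (int j = 0; j < d; ++j) v_in[j] += neu1e[j];
          touched[context] = 1;
          touched[center] = 1;
        }
      }
    }
  }

  NumericMatrix out(n_nodes, d);
  for (int i = 0; i < n_nodes; ++i)
    for (int j = 0; j < d; ++j)
      out(i, j) = (double)syn0[(size_t)i * d + j];
  out.attr("trained") = IntegerVector(touched.begin(), touched.end());
  return out;
}
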