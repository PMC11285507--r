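#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Uniform integer in [0, k). Uses R's RNG so set.seed() governs everything.
static inline int runif_int(int k) {
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

// Adjacency is passed as CSR: offsets (length n+1) into neighbors, 0-based.

// Meeting times of two synchronous walkers from independent uniform starts.
// Returns the first step at which the walkers co-occupy a vertex (0 when the
// starts coincide) or NA when no meeting occurs within smax steps.
// With lazy = true each walker independently stays put with probability 1/2
// (breaks the parity obstruction on bipartite graphs).
// [[Rcpp::export]]
IntegerVector cpp_meeting_times(IntegerVector offsets, IntegerVector neighbors,
                                int n_vertices, int n_real, int smax,
                                bool lazy) {
  IntegerVector out(n_real);
  const int *off = offsets.begin();
  const int *nbr = neighbors.begin();
  for (int i = 0; i < n_real; ++i) {
    if ((i & 0xFF) == 0) checkUserInterrupt();
    int a = runif_int(n_vertices), b = runif_int(n_vertices);
    int res = NA_INTEGER;
    if (a == b) {
      res = 0;
    } else {
      for (int t = 1; t <= smax; ++t) {
        if (!lazy || unif_rand() < 0.5)
          a = nbr[off[a] + runif_int(off[a + 1] - off[a])];
        if (!lazy || unif_rand() < 0.5)
          b = nbr[off[b] + runif_int(off[b + 1] - off[b])];
        if (a == b) { res = t; break; }
      }
    }
    out[i] = res;
  }
  return out;
}

// Two r-halting walks from independent uniform starts: returns the meeting
// step when the walks meet strictly before either halts, else -1 (a walk
// halted first). tmax is a safety cap (expected duration is ~1/(2r)); runs
// exceeding it return NA.
// [[Rcpp::export]]
IntegerVector cpp_halting_meet_times(IntegerVector offsets,
                                     IntegerVector neighbors, int n_vertices,
                                     double r, int n_real, int tmax) {
  IntegerVector out(n_real);
  const int *off = offsets.begin();
  const int *nbr = neighbors.begin();
  for (int i = 0; i < n_real; ++i) {
    if ((i & 0xFF) == 0) checkUserInterrupt();
    int a = runif_int(n_vertices), b = runif_int(n_vertices);
    int res = NA_INTEGER;
    if (a == b) {
      res = 0;
    } else {
      for (int t = 1; t <= tmax; ++t) {
        bool halt1 = unif_rand() < r;
        bool halt2 = unif_rand() < r;
        if (halt1 || halt2) { res = -1; break; }
        a = nbr[off[a] + runif_int(off[a + 1] - off[a])];
        b = nbr[off[b] + runif_int(off[b + 1] - off[b])];
        if (a == b) { res = t; break; }
      }
    }
    out[i] = res;
  }
  return out;
}

static double simpson_from_counts(std::unordered_map<double, int> &counts,
                                  int n) {
  double sumsq = 0.0;
  for (auto &kv : counts) {
    double p = (double)kv.second / n;
    sumsq += p * p;
  }
  return 1.0 - sumsq;
}

// One replicate of the synchronous voter model with innovation.
// labels: current meme per vertex (doubles used as exact integers; safe far
// beyond any reachable label count). With probability r a vertex invents a
// fresh label (monotone counter next_label), otherwise it copies the time-t
// label of a uniformly chosen neighbour; updates are double-buffered.
// Returns D(t) for t = 1..n_steps, the final labels and the counter.
// [[Rcpp::export]]
List cpp_voter_run(IntegerVector offsets, IntegerVector neighbors,
                   int n_vertices, NumericVector labels, double next_label,
                   double r, int n_steps) {
  const int *off = offsets.begin();
  const int *nbr = neighbors.begin();
  std::vector<double> cur(labels.begin(), labels.end());
  std::vector<double> nxt(n_vertices);
  NumericVector d(n_steps);
  std::unordered_map<double, int> counts;
  for (int t = 0; t < n_steps; ++t) {
    if ((t & 0x3F) == 0) checkUserInterrupt();
    for (int v = 0; v < n_vertices; ++v) {
      if (r > 0.0 && unif_rand() < r) {
        nxt[v] = next_label;
        next_label += 1.0;
      } else {
        nxt[v] = cur[nbr[off[v] + runif_int(off[v + 1] - off[v])]];
      }
    }
    std::swap(cur, nxt);
    counts.clear();
    for (int v = 0; v < n_vertices; ++v) counts[cur[v]] += 1;
    d[t] = simpson_from_counts(counts, n_vertices);
  }
  return List::create(_["d_series"] = d,
                      _["labels"] = NumericVector(cur.begin(), cur.end()),
                      _["next_label"] = next_label);
}
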