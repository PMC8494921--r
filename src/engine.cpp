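#include <Rcpp.h>
using namespace Rcpp;

// Uniform index in {0, ..., n-1} from a single unif_rand() call.
// Mirrors the R-level draw_index() exactly so both engines consume the
// same RNG stream.
static inline int draw_index(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;  // guard against u == 1 fixups
  return k;
}

// Uniform over the n-1 indices other than i (0-based).
static inline int draw_other(int i, int n) {
  int j = draw_index(n - 1);
  if (j >= i) ++j;
  return j;
}

// Gaussian-offset model selection on a circular line of n agents:
// continuous N(0, sigma) offset, rounded half-away-from-zero, zero
// offsets (and wrap-around self hits) redrawn.
static inline int draw_ring(int i, int n, double sigma) {
  for (int tries = 0; tries < 100000; ++tries) {
    double z = norm_rand() * sigma;
    double r = std::floor(std::fabs(z) + 0.5);
    int k = (z < 0.0) ? -(int)r : (int)r;
    if (k == 0) continue;
    int j = ((i + k) % n + n) % n;
    if (j == i) continue;  // offset a nonzero multiple of n
    return j;
  }
  stop("structured model selection: offset rejection cap exceeded");
}

// Sequential simulation engine. Agents update one at a time in order
// (fixed 0..N-1, or reshuffled each step), each seeing the current,
// possibly already-updated holdings of the others. Draws are lazy:
// only the branch taken consumes random numbers, in the documented
// order (branch uniform; [model]; [innovation]; [roulette]; error
// uniform; [error replacement]).
//
// learner: 0 = copier, 1 = innovator, 2 = maintainer.
// sigma <= 0 means unstructured (uniform over the other agents).
// Returns an (n_steps + 1) x N matrix of 0-based variant ids, row t
// holding the population state after time step t (row 0 = initial).
// [[Rcpp::export]]
IntegerMatrix sim_engine_cpp(IntegerVector payoffs, IntegerVector init,
                             double b, int learner, double e,
                             double sigma, int n_steps, bool shuffle) {
  const int n = init.size();
  const int pool = payoffs.size();
  if (n < 1) stop("empty population");
  IntegerMatrix out(n_steps + 1, n);
  std::vector<int> v(init.begin(), init.end());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) {
    if (v[i] < 0 || v[i] >= pool) stop("variant id out of pool range");
    ord[i] = i;
    out(0, i) = v[i];
  }
  for (int t = 1; t <= n_steps; ++t) {
    if (shuffle) {  // Fisher-Yates via draw_index, matching the R engine
      for (int i = 0; i < n; ++i) ord[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = draw_index(i + 1);
        std::swap(ord[i], ord[j]);
      }
    }
    for (int a = 0; a < n; ++a) {
      const int i = ord[a];
      int chosen;
      if (unif_rand() < b) {
        // critical: roulette over (own, model, innovated), masses add
        int m = (sigma > 0.0) ? draw_ring(i, n, sigma) : draw_other(i, n);
        int innov = draw_index(pool);
        double ps = payoffs[v[i]], pm = payoffs[v[m]], pn = payoffs[innov];
        double u = unif_rand() * (ps + pm + pn);
        if (u < ps) chosen = v[i];
        else if (u < ps + pm) chosen = v[m];
        else chosen = innov;
      } else if (learner == 0) {
        int m = (sigma > 0.0) ? draw_ring(i, n, sigma) : draw_other(i, n);
        chosen = v[m];
      } else if (learner == 1) {
        chosen = draw_index(pool);
      } else {
        chosen = v[i];
      }
      if (unif_rand() < e) chosen = draw_index(pool);
      v[i] = chosen;
    }
    for (int i = 0; i < n; ++i) out(t, i) = v[i];
  }
  return out;
}

// Mean number of distinct models a fixed focal agent accesses over
// n_steps Gaussian-offset draws on an n_agents ring, averaged over
// n_reps replicates.
// [[Rcpp::export]]
double neighbourhood_size_cpp(int n_agents, double sigma, int n_steps,
                              int n_reps) {
  double total = 0.0;
  std::vector<char> seen(n_agents);
  for (int r = 0; r < n_reps; ++r) {
    std::fill(seen.begin(), seen.end(), 0);
    int distinct = 0;
    for (int s = 0; s < n_steps; ++s) {
      int j = draw_ring(0, n_agents, sigma);
      if (!seen[j]) { seen[j] = 1; ++distinct; }
    }
    total += distinct;
  }
  return total / n_reps;
}
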