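#include <Rcpp.h>
#include <vector>
#include <array>
#include <climits>
#include <functional>
using namespace Rcpp;

// Maximum bipartite matching (Kuhn's augmenting paths) on a biadjacency
// matrix with rows = left side, cols = right side.
// [[Rcpp::export]]
List bip_max_matching_cpp(LogicalMatrix adj) {
  int n = adj.nrow(), m = adj.ncol();
  std::vector<int> matchL(n, -1), matchR(m, -1);
  std::vector<char> used(m);
  std::function<bool(int)> aug = [&](int u) -> bool {
    for (int v = 0; v < m; ++v) {
      if (adj(u, v) && !used[v]) {
        used[v] = 1;
        if (matchR[v] < 0 || aug(matchR[v])) {
          matchL[u] = v;
          matchR[v] = u;
          return true;
        }
      }
    }
    return false;
  };
  int size = 0;
  for (int u = 0; u < n; ++u) {
    std::fill(used.begin(), used.end(), 0);
    if (aug(u)) ++size;
  }
  IntegerVector mL(n), mR(m);
  for (int u = 0; u < n; ++u) mL[u] = matchL[u] + 1;  // 0 = unmatched
  for (int v = 0; v < m; ++v) mR[v] = matchR[v] + 1;
  return List::create(_["size"] = size, _["match_left"] = mL,
                      _["match_right"] = mR);
}

// Permanent of a square matrix by Ryser's inclusion-exclusion formula.
// Practical for n <= 16 (guarded in R).
// [[Rcpp::export]]
double permanent_cpp(NumericMatrix mat) {
  int n = mat.nrow();
  if (n != mat.ncol()) stop("matrix must be square");
  if (n == 0) return 1.0;
  if (n > 20) stop("permanent limited to n <= 20");
  double total = 0.0;
  unsigned long nsub = 1UL << n;
  std::vector<double> rowsum(n);
  for (unsigned long s = 1; s < nsub; ++s) {
    int popcount = 0;
    for (int i = 0; i < n; ++i) rowsum[i] = 0.0;
    for (int j = 0; j < n; ++j) {
      if (s & (1UL << j)) {
        ++popcount;
        for (int i = 0; i < n; ++i) rowsum[i] += mat(i, j);
      }
    }
    double prod = 1.0;
    for (int i = 0; i < n; ++i) prod *= rowsum[i];
    double sign = ((n - popcount) % 2 == 0) ? 1.0 : -1.0;
    total += sign * prod;
  }
  return total;
}

// ---------------------------------------------------------------------------
// Capping-set enumeration.
//
// A capped consistent decomposition is evaluated for every perfect matching
// ("capping-set") of the cap vertices allowed by the cap-edge set.  The
// uncapped decomposition is summarised as a list of path objects: real paths
// of the decomposition plus dummy adjacencies (zero-length paths).  Each cap
// vertex is one end of exactly one path object.  Chaining paths via a
// capping-set yields cycles; for each cycle we need its number of indel runs
// l (maximal blocks of same-genome indel edges in cyclic order) and its
// run cost Lambda(l) = 0 if l = 0, ceil((l+1)/2) otherwise.  The cost
// contribution of a capping-set is  sum(Lambda) - (#cycles formed); the DCJ-
// indel operation count then is |O| + p + (cost of the uncapped cycles) +
// (this contribution), assembled on the R side.
// ---------------------------------------------------------------------------

static inline int lambda_cost(const std::vector<int> &labels) {
  // labels: genome tags (1/2) of indel edges along the cycle, in order
  // (consecutive duplicates may be present).  Count cyclic maximal blocks.
  int k = labels.size();
  if (k == 0) return 0;
  int blocks = 0;
  for (int i = 0; i < k; ++i) {
    if (labels[i] != labels[(i + k - 1) % k]) ++blocks;
  }
  if (blocks == 0) blocks = 1;  // all labels equal
  return (blocks + 2) / 2;      // ceil((blocks + 1) / 2)
}

struct CapEnum {
  int p2;                          // caps per side
  const LogicalMatrix &allowed;
  std::vector<int> cap_path;       // per global cap (0..2*p2-1): path id
  std::vector<int> cap_slot;       // end slot 0/1
  std::vector<std::array<int, 2> > end_cap;  // path id -> global caps
  std::vector<std::vector<int> > runs;       // path id -> run labels end0->end1
  std::vector<bool> real_path;
  std::vector<int> match;          // A cap -> B cap (0..p2-1)
  std::vector<char> usedB;
  double n_match = 0.0;
  double max_enum;
  int best_cost = INT_MAX;
  double n_best = 0.0;
  int max_real_at_best = 0;        // max real paths absorbed into one cycle,
                                   // over min-cost capping-sets
  std::vector<int> best_match;

  CapEnum(const LogicalMatrix &allowed_) : allowed(allowed_) {}

  void evaluate() {
    std::vector<char> seen(2 * p2, 0);
    int cost = 0;
    int max_real = 0;
    for (int s = 0; s < 2 * p2; ++s) {
      if (seen[s]) continue;
      // walk the chained cycle through path objects and cap edges
      std::vector<int> labels;
      int nreal = 0;
      int cur = s;
      do {
        int pid = cap_path[cur];
        int slot = cap_slot[cur];
        const std::vector<int> &r = runs[pid];
        if (slot == 0) {
          labels.insert(labels.end(), r.begin(), r.end());
        } else {
          labels.insert(labels.end(), r.rbegin(), r.rend());
        }
        if (real_path[pid]) ++nreal;
        int other = end_cap[pid][1 - slot];
        seen[cur] = seen[other] = 1;
        // follow the cap edge of the capping-set
        if (other < p2)
          cur = p2 + match[other];
        else
          cur = revmatch[other - p2];
      } while (cur != s);
      cost += lambda_cost(labels) - 1;  // -1: one new cycle formed
      if (nreal > max_real) max_real = nreal;
    }
    n_match += 1.0;
    if (cost < best_cost) {
      best_cost = cost;
      n_best = 1.0;
      max_real_at_best = max_real;
      best_match = match;
    } else if (cost == best_cost) {
      n_best += 1.0;
      // among equally optimal capping-sets, prefer the one that merges
      // the fewest paths into any single cycle: the reported statistic is
      // what an optimal capping NEEDS to merge, not what ties allow
      if (max_real < max_real_at_best) {
        max_real_at_best = max_real;
        best_match = match;
      }
    }
  }

  std::vector<int> revmatch;  // B cap -> A cap

  void recurse(int a) {
    if (n_match >= max_enum)
      stop("capping-set enumeration exceeds limit (%.0f)", max_enum);
    if (a == p2) {
      evaluate();
      return;
    }
    for (int b = 0; b < p2; ++b) {
      if (!usedB[b] && allowed(a, b)) {
        usedB[b] = 1;
        match[a] = b;
        revmatch[b] = a;
        recurse(a + 1);
        usedB[b] = 0;
      }
    }
  }
};

// allowed: p2 x p2 logical (A caps x B caps).
// cap_path_a/cap_slot_a: per A cap, 1-based path id and slot (1/2);
// likewise for B caps.  path_runs: list of integer vectors (labels 1=A, 2=B)
// ordered from slot-1 end to slot-2 end.  path_real: real decomposition path
// (TRUE) or dummy adjacency (FALSE).
// [[Rcpp::export]]
List cap_enum_cpp(LogicalMatrix allowed, IntegerVector cap_path_a,
                  IntegerVector cap_slot_a, IntegerVector cap_path_b,
                  IntegerVector cap_slot_b, List path_runs,
                  LogicalVector path_real, double max_enum = 1e7) {
  int p2 = allowed.nrow();
  if (allowed.ncol() != p2) stop("allowed matrix must be square");
  if (cap_path_a.size() != p2 || cap_path_b.size() != p2)
    stop("cap assignments must have one entry per cap vertex");
  CapEnum ce(allowed);
  ce.p2 = p2;
  ce.max_enum = max_enum;
  int npaths = path_runs.size();
  ce.runs.resize(npaths);
  ce.real_path.resize(npaths);
  ce.end_cap.assign(npaths, {{-1, -1}});
  for (int i = 0; i < npaths; ++i) {
    IntegerVector r = path_runs[i];
    ce.runs[i] = std::vector<int>(r.begin(), r.end());
    ce.real_path[i] = path_real[i];
  }
  ce.cap_path.resize(2 * p2);
  ce.cap_slot.resize(2 * p2);
  for (int c = 0; c < p2; ++c) {
    int pid = cap_path_a[c] - 1, slot = cap_slot_a[c] - 1;
    if (pid < 0 || pid >= npaths || slot < 0 || slot > 1)
      stop("bad cap assignment (A side)");
    ce.cap_path[c] = pid;
    ce.cap_slot[c] = slot;
    ce.end_cap[pid][slot] = c;
  }
  for (int c = 0; c < p2; ++c) {
    int pid = cap_path_b[c] - 1, slot = cap_slot_b[c] - 1;
    if (pid < 0 || pid >= npaths || slot < 0 || slot > 1)
      stop("bad cap assignment (B side)");
    ce.cap_path[p2 + c] = pid;
    ce.cap_slot[p2 + c] = slot;
    ce.end_cap[pid][slot] = p2 + c;
  }
  for (int i = 0; i < npaths; ++i)
    if (ce.end_cap[i][0] < 0 || ce.end_cap[i][1] < 0)
      stop("path %d has an end not attached to any cap", i + 1);
  ce.match.assign(p2, -1);
  ce.revmatch.assign(p2, -1);
  ce.usedB.assign(p2, 0);
  ce.recurse(0);
  if (ce.n_match == 0.0) {
    return List::create(_["valid"] = false, _["n_capping_sets"] = 0.0);
  }
  IntegerVector bm(p2);
  for (int i = 0; i < p2; ++i) bm[i] = ce.best_match[i] + 1;
  return List::create(
      _["valid"] = true, _["min_cost"] = ce.best_cost,
      _["n_capping_sets"] = ce.n_match, _["n_optimal"] = ce.n_best,
      _["max_paths_single_cycle"] = ce.max_real_at_best,
      _["best_matching"] = bm);
}

// Run cost of a closed cycle given its cyclic indel-edge labels (exported
// for the R-side evaluation of uncapped cycles).
// [[Rcpp::export]]
int cycle_run_cost_cpp(IntegerVector labels) {
  std::vector<int> l(labels.begin(), labels.end());
  return lambda_cost(l);
}
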