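#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive maximization of Newman weighted modularity over all set
// partitions of the nodes, enumerated as restricted growth strings with
// incremental Q updates. Q = sum_g [ In_g/(2m) - (S_g/(2m))^2 ] with
// In_g the (ordered-pair) within-group weight and S_g the group's summed
// strength; identical to the igraph/Newman convention.

namespace {

struct Search {
  int n;
  const NumericMatrix &A;
  std::vector<double> k;       // node strengths
  double two_m;
  std::vector<int> assign;     // current membership
  std::vector<double> S;       // per-group strength sums
  std::vector<std::vector<int>> members;
  double bestQ;
  std::vector<int> best;

  Search(const NumericMatrix &A_) : A(A_) {
    n = A.nrow();
    k.resize(n);
    two_m = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += A(i, j);
      k[i] = s;
      two_m += s;
    }
    assign.assign(n, -1);
    bestQ = -1e18;
  }

  void run() {
    if (two_m <= 0) {   // no edges: any partition has Q = 0
      bestQ = 0.0;
      best.resize(n);
      for (int i = 0; i < n; ++i) best[i] = i + 1;
      return;
    }
    recurse(0, 0, 0.0);
  }

  void recurse(int i, int ngroups, double Q) {
    if (i == n) {
      if (Q > bestQ + 1e-15) {
        bestQ = Q;
        best = assign;
      }
      return;
    }
    for (int g = 0; g <= ngroups; ++g) {
      double link = 0.0;
      if (g < ngroups)
        for (int v : members[g]) link += A(i, v);
      double Sg = (g < ngroups) ? S[g] : 0.0;
      double dQ = 2.0 * link / two_m -
                  (2.0 * Sg * k[i] + k[i] * k[i]) / (two_m * two_m);
      if (g == ngroups) {
        members.push_back({i});
        S.push_back(k[i]);
      } else {
        members[g].push_back(i);
        S[g] += k[i];
      }
      assign[i] = g;
      recurse(i + 1, g == ngroups ? ngroups + 1 : ngroups, Q + dQ);
      if (g == ngroups) {
        members.pop_back();
        S.pop_back();
      } else {
        members[g].pop_back();
        S[g] -= k[i];
      }
      assign[i] = -1;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List exact_partition_cpp(NumericMatrix A) {
  if (A.nrow() != A.ncol()) stop("adjacency matrix must be square");
  if (A.nrow() > 13) stop("exhaustive search gated at 13 nodes");
  Search s(A);
  s.run();
  IntegerVector memb(s.n);
  for (int i = 0; i < s.n; ++i) memb[i] = s.best[i] + 1;
  return List::create(_["membership"] = memb,
                      _["modularity"] = s.bestQ);
}
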