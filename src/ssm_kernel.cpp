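// Fused kernel for SSM enumeration on a gene pair: extended-Hamming distance
// matrix over PreSSM node keys, then pivoting Bron-Kerbosch maximal-clique
// enumeration with the two-gene spanning filter.
//
// Extended sequences are closed under the Klein four-group
// {id, complement, reverse, reverse-complement}; each transform is a
// position-wise bijection (possibly after index reversal), so Hamming
// distance is invariant under applying the same transform to both words.
// Hence min over all 16 member pairs equals min over the 4 transforms of one
// representative against a fixed representative of the other class, and four
// comparisons per node pair suffice.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return c;
  }
}

// the four members of the extended class of w (with duplicates possible)
static std::vector<std::string> four_transforms(const std::string& w) {
  const size_t n = w.size();
  std::string c(n, ' '), r(n, ' '), rc(n, ' ');
  for (size_t i = 0; i < n; ++i) {
    c[i]  = comp_base(w[i]);
    r[i]  = w[n - 1 - i];
    rc[i] = comp_base(w[n - 1 - i]);
  }
  std::vector<std::string> out;
  out.reserve(4);
  out.push_back(w);
  out.push_back(c);
  out.push_back(r);
  out.push_back(rc);
  return out;
}

static inline int hamming(const std::string& a, const std::string& b) {
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

// min over the four transforms of a's members against b's representative;
// early exit once the running minimum cannot improve
static inline int ext_dist(const std::vector<std::string>& a_members,
                           const std::string& b_rep) {
  int best = (int) b_rep.size() + 1;
  for (size_t t = 0; t < a_members.size(); ++t) {
    int d = hamming(a_members[t], b_rep);
    if (d < best) best = d;
    if (best == 0) return 0;
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix ext_dist_matrix_cpp(CharacterVector keys) {
  const int n = keys.size();
  std::vector<std::vector<std::string> > members(n);
  std::vector<std::string> rep(n);
  for (int i = 0; i < n; ++i) {
    rep[i] = as<std::string>(keys[i]);
    members[i] = four_transforms(rep[i]);
  }
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = ext_dist(members[i], rep[j]);
  return D;
}

namespace {

struct BKState {
  const std::vector<std::vector<char> >* adj;
  const std::vector<char>* in1;
  const std::vector<char>* in2;
  bool collect;
  long count;
  std::vector<std::vector<int> > cliques;
};

// classic Bron-Kerbosch with pivoting; P and X kept in ascending node order
// so enumeration (and therefore any collected output) is deterministic
void bron_kerbosch(std::vector<int>& R, std::vector<int>& P, std::vector<int>& X,
                   BKState& st) {
  if (P.empty() && X.empty()) {
    bool has1 = false, has2 = false;
    for (size_t i = 0; i < R.size(); ++i) {
      if ((*st.in1)[R[i]]) has1 = true;
      if ((*st.in2)[R[i]]) has2 = true;
    }
    if (has1 && has2) {
      ++st.count;
      if (st.collect) {
        std::vector<int> cl(R);
        std::sort(cl.begin(), cl.end());
        st.cliques.push_back(cl);
      }
    }
    return;
  }
  // pivot: vertex of P union X with most neighbours in P
  int pivot = -1, best = -1;
  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<int>& S = pass == 0 ? P : X;
    for (size_t i = 0; i < S.size(); ++i) {
      int u = S[i], deg = 0;
      for (size_t j = 0; j < P.size(); ++j)
        if ((*st.adj)[u][P[j]]) ++deg;
      if (deg > best) { best = deg; pivot = u; }
    }
  }
  std::vector<int> candidates;
  for (size_t i = 0; i < P.size(); ++i)
    if (pivot < 0 || !(*st.adj)[pivot][P[i]])
      candidates.push_back(P[i]);
  for (size_t c = 0; c < candidates.size(); ++c) {
    int v = candidates[c];
    std::vector<int> P2, X2;
    for (size_t i = 0; i < P.size(); ++i)
      if ((*st.adj)[v][P[i]]) P2.push_back(P[i]);
    for (size_t i = 0; i < X.size(); ++i)
      if ((*st.adj)[v][X[i]]) X2.push_back(X[i]);
    R.push_back(v);
    bron_kerbosch(R, P2, X2, st);
    R.pop_back();
    // move v from P to X
    P.erase(std::find(P.begin(), P.end(), v));
    std::vector<int>::iterator pos = std::lower_bound(X.begin(), X.end(), v);
    X.insert(pos, v);
  }
}

void run_bk(const std::vector<std::vector<char> >& adj,
            const std::vector<char>& in1, const std::vector<char>& in2,
            bool collect, BKState& st) {
  const int n = (int) adj.size();
  st.adj = &adj; st.in1 = &in1; st.in2 = &in2;
  st.collect = collect; st.count = 0;
  std::vector<int> R, P(n), X;
  for (int i = 0; i < n; ++i) P[i] = i;
  bron_kerbosch(R, P, X, st);
}

} // namespace

// Enumerate the spanning maximal cliques for one (l, d) type.
// keys: canonical node keys (equal length); in1/in2: node occurs in gene 1/2.
// Returns a list of 1-based, ascending integer index vectors, ordered by the
// enumeration order of the deterministic pivoting search, then sorted
// lexicographically by key sequence on the R side.
// [[Rcpp::export]]
List ssm_cliques_cpp(CharacterVector keys, LogicalVector in1, LogicalVector in2,
                     int d) {
  const int n = keys.size();
  if (n == 0) return List::create();
  std::vector<std::vector<std::string> > members(n);
  std::vector<std::string> rep(n);
  for (int i = 0; i < n; ++i) {
    rep[i] = as<std::string>(keys[i]);
    members[i] = four_transforms(rep[i]);
  }
  std::vector<std::vector<char> > adj(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (ext_dist(members[i], rep[j]) <= d) adj[i][j] = adj[j][i] = 1;
  std::vector<char> g1(n), g2(n);
  for (int i = 0; i < n; ++i) { g1[i] = in1[i] ? 1 : 0; g2[i] = in2[i] ? 1 : 0; }
  BKState st;
  run_bk(adj, g1, g2, true, st);
  List out(st.cliques.size());
  for (size_t k = 0; k < st.cliques.size(); ++k) {
    IntegerVector iv(st.cliques[k].size());
    for (size_t i = 0; i < st.cliques[k].size(); ++i) iv[i] = st.cliques[k][i] + 1;
    out[k] = iv;
  }
  return out;
}

// Count spanning maximal cliques for several distance thresholds at once,
// reusing one distance matrix (the bulk path for null sampling and scans).
// [[Rcpp::export]]
IntegerVector ssm_counts_multi_cpp(CharacterVector keys, LogicalVector in1,
                                   LogicalVector in2, IntegerVector ds) {
  const int n = keys.size();
  IntegerVector out(ds.size());
  if (n == 0) return out;
  std::vector<std::vector<std::string> > members(n);
  std::vector<std::string> rep(n);
  for (int i = 0; i < n; ++i) {
    rep[i] = as<std::string>(keys[i]);
    members[i] = four_transforms(rep[i]);
  }
  std::vector<std::vector<int> > D(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D[i][j] = D[j][i] = ext_dist(members[i], rep[j]);
  std::vector<char> g1(n), g2(n);
  for (int i = 0; i < n; ++i) { g1[i] = in1[i] ? 1 : 0; g2[i] = in2[i] ? 1 : 0; }
  for (int k = 0; k < ds.size(); ++k) {
    const int d = ds[k];
    std::vector<std::vector<char> > adj(n, std::vector<char>(n, 0));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (D[i][j] <= d) adj[i][j] = adj[j][i] = 1;
    BKState st;
    run_bk(adj, g1, g2, false, st);
    out[k] = (int) st.count;
  }
  return out;
}
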