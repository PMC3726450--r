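#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
using namespace Rcpp;

// Nested-structure MFE dynamic programme over a simple base-pair energy
// model. Energy of a structure = sum of pair scores + bulge_penalty per
// unpaired base interrupting a stem region: an unpaired base pays the
// penalty iff its closest enclosing pair encloses at least one other pair
// (i.e. it sits in a bulge/internal/multibranch loop). Hairpin-loop bases
// and exterior bases are free.
//
// Tables:
//   W(i,j): best energy of [i,j] in exterior context
//   C(i,j): best energy of [i,j] enclosed, containing >= 1 pair
//           (every unpaired base in the region costs P)
//   V(i,j): best energy of [i,j] given i pairs with j;
//           V = score(i,j) + min(0 [hairpin loop], C(i+1,j-1))
// A pair (i,j) requires j - i - 1 >= min_loop and a negative score entry.
//
// Traceback is deterministic: pairing the 5'-most base is preferred over
// leaving it unpaired, and the smallest pairing partner is preferred.

static inline int idx(int i, int j, int n) { return i * n + j; }

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector seq_code, IntegerMatrix pair_score,
             int min_loop, int bulge_penalty) {
  const int n = seq_code.size();
  const int INF = 100000000;
  const int P = bulge_penalty;
  std::string db(n, '.');
  if (n == 0)
    return List::create(_["energy"] = 0, _["dotbracket"] = db);

  std::vector<int> W((size_t)n * n, 0), C((size_t)n * n, INF),
      V((size_t)n * n, INF);
  auto sc = [&](int i, int j) { return pair_score(seq_code[i], seq_code[j]); };
  // rest of an enclosed region after a closed pair: either structured (C)
  // or all unpaired at P each
  auto rest_enclosed = [&](int x, int j) {
    if (x > j) return 0;
    int all_unp = P * (j - x + 1);
    int c = C[idx(x, j, n)];
    return c < all_unp ? c : all_unp;
  };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // V(i,j)
      if (sc(i, j) < 0) {
        int inner = 0; // hairpin loop: inner bases free
        if (i + 1 <= j - 1 && C[idx(i + 1, j - 1, n)] < inner)
          inner = C[idx(i + 1, j - 1, n)];
        V[idx(i, j, n)] = sc(i, j) + inner;
      }
      // W(i,j)
      int wbest = W[idx(i + 1, j, n)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V[idx(i, k, n)] >= INF) continue;
        int rest = (k + 1 <= j) ? W[idx(k + 1, j, n)] : 0;
        int cand = V[idx(i, k, n)] + rest;
        if (cand < wbest) wbest = cand;
      }
      W[idx(i, j, n)] = wbest;
      // C(i,j)
      int cbest = INF;
      if (C[idx(i + 1, j, n)] < INF) cbest = C[idx(i + 1, j, n)] + P;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V[idx(i, k, n)] >= INF) continue;
        int cand = V[idx(i, k, n)] + rest_enclosed(k + 1, j);
        if (cand < cbest) cbest = cand;
      }
      C[idx(i, j, n)] = cbest;
    }
  }

  // Traceback over (i, j, state): 0=W, 1=C, 2=V, 3=all-unpaired enclosed
  std::vector<std::array<int, 3>> stack;
  if (n > 1) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto st = stack.back();
    stack.pop_back();
    int i = st[0], j = st[1], state = st[2];
    if (i > j || state == 3) continue;
    if (state == 2) { // V: i pairs j
      db[i] = '(';
      db[j] = ')';
      if (i + 1 <= j - 1) {
        int inner = C[idx(i + 1, j - 1, n)];
        if (inner < 0 &&
            V[idx(i, j, n)] == sc(i, j) + inner)
          stack.push_back({i + 1, j - 1, 1});
        // else hairpin loop: all inner unpaired
      }
      continue;
    }
    if (state == 0) { // W
      int target = W[idx(i, j, n)];
      if (i == j) continue;
      bool done = false;
      for (int k = i + min_loop + 1; k <= j && !done; ++k) {
        if (V[idx(i, k, n)] >= INF) continue;
        int rest = (k + 1 <= j) ? W[idx(k + 1, j, n)] : 0;
        if (V[idx(i, k, n)] + rest == target) {
          stack.push_back({i, k, 2});
          if (k + 1 <= j) stack.push_back({k + 1, j, 0});
          done = true;
        }
      }
      if (!done) stack.push_back({i + 1, j, 0});
      continue;
    }
    // state == 1: C
    {
      int target = C[idx(i, j, n)];
      bool done = false;
      for (int k = i + min_loop + 1; k <= j && !done; ++k) {
        if (V[idx(i, k, n)] >= INF) continue;
        int all_unp = (k + 1 <= j) ? P * (j - k) : 0;
        int cr = (k + 1 <= j) ? C[idx(k + 1, j, n)] : INF;
        int rest = (k + 1 > j) ? 0 : (cr < all_unp ? cr : all_unp);
        if (V[idx(i, k, n)] + rest == target) {
          stack.push_back({i, k, 2});
          if (k + 1 <= j) {
            if (cr < INF && cr <= all_unp && V[idx(i, k, n)] + cr == target)
              stack.push_back({k + 1, j, 1});
            // else: remainder all unpaired, nothing to mark
          }
          done = true;
        }
      }
      if (!done && C[idx(i + 1, j, n)] < INF &&
          C[idx(i + 1, j, n)] + P == target) {
        stack.push_back({i + 1, j, 1});
      }
      continue;
    }
  }
  int energy = (n > 1) ? W[idx(0, n - 1, n)] : 0;
  return List::create(_["energy"] = energy, _["dotbracket"] = db);
}
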