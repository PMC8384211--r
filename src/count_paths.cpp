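#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Depth-first enumeration of pseudo-Hamiltonian paths on the 60-position
// lattice: paths of 30 distinct positions, consecutive positions related
// by a move in `moves`, visiting exactly one member of each mutual
// exclusion pair. Pruning: never extend onto an occupied position or onto
// the exclusion partner of an occupied position. With that pruning every
// completed 30-step path automatically covers all 30 pairs.
//
// move_maps: 60 x 9 (1-based targets), exclusion: length 60 (1-based),
// moves: subset of 1..9, start: 1-based start position. All positions are
// symmetry-equivalent, so a fixed start enumerates one representative
// (the 5'-anchored move sequence) per symmetry class of directed paths.

namespace {

struct Dfs {
  int nm;
  int perm[9][60];
  int excl[60];
  const int *mv;
  long long count = 0;
  double nodes = 0;
  double node_limit;
  bool complete = true;
  bool enumerate;
  long long path_limit;
  std::vector<int> seq;              // current move labels (1-based)
  std::vector<std::vector<int>> out; // stored move sequences

  void run(int p, int depth, uint64_t occ) {
    if (depth == 30) {
      ++count;
      if (enumerate && (long long)out.size() < path_limit) out.push_back(seq);
      return;
    }
    for (int i = 0; i < nm; ++i) {
      int q = perm[mv[i] - 1][p];
      uint64_t bad = (1ULL << q) | (1ULL << excl[q]);
      if (occ & bad) continue;
      if (++nodes > node_limit) { complete = false; return; }
      seq.push_back(mv[i]);
      run(q, depth + 1, occ | (1ULL << q));
      seq.pop_back();
      if (!complete) return;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_count_paths(IntegerMatrix move_maps, IntegerVector exclusion,
                     IntegerVector moves, int start, bool enumerate,
                     double node_limit, double path_limit) {
  if (move_maps.nrow() != 60 || move_maps.ncol() != 9)
    stop("move_maps must be 60 x 9");
  Dfs d;
  d.nm = moves.size();
  std::vector<int> mv(moves.begin(), moves.end());
  std::sort(mv.begin(), mv.end());
  d.mv = mv.data();
  for (int k = 0; k < 9; ++k)
    for (int p = 0; p < 60; ++p) d.perm[k][p] = move_maps(p, k) - 1;
  for (int p = 0; p < 60; ++p) d.excl[p] = exclusion[p] - 1;
  d.node_limit = node_limit;
  d.enumerate = enumerate;
  d.path_limit = (long long)path_limit;
  d.seq.reserve(29);

  int s = start - 1;
  d.run(s, 1, 1ULL << s);

  List res = List::create(_["count"] = (double)d.count,
                          _["nodes"] = d.nodes,
                          _["complete"] = d.complete);
  if (enumerate) {
    IntegerMatrix pm(d.out.size(), 29);
    for (size_t i = 0; i < d.out.size(); ++i)
      for (int j = 0; j < 29; ++j) pm(i, j) = d.out[i][j];
    res["paths"] = pm;
  }
  return res;
}
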