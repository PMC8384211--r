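#include <Rcpp.h>
#include <random>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gillespie simulation of packaging-signal-mediated co-assembly.
//
// Each of n_rna RNAs carries 30 packaging signals (PSs) with binding free
// energies dg(ps, rna). Reactions:
//   bind      free PS + free CP -> CP:PS, propensity k_bind*free_cp/cp_ref
//             per free PS (uniform over free PSs);
//   unbind    CP:PS -> free PS + CP, propensity k_bind*exp(dg/rt)
//             (detailed balance against bind);
//   nucleate  two sequence-adjacent CP:PS place onto the lattice at the
//             canonical position and its image under a contact move
//             (1, 3 or 4) of the move set;
//   elongate  the CP:PS immediately 5' or 3' of the in-shell interval
//             places at a move image of the interval end, provided the
//             target is not blocked and touches the partial shell through
//             a contact edge;
//   detach    a terminal in-shell CP:PS leaves the shell (stays CP-bound).
//
// Shell occupancy: placing a path CP at q also fills the mutual-exclusion
// partner position excl(q) with a plain (non-path) coat protein, the
// quasi-static image of the 30 non-path CPs of the T=1 shell. A position
// is blocked iff it is in this filled set, which enforces both single
// occupancy and the mutual-exclusion rule; contact counts are taken
// against the filled set, so the growing rim is contact-connected.
//
// Attachment propensity per eligible placement is k_attach *
// exp(-phi*dg_cs*c/rt) and detachment of a terminal breaking c contacts
// k_attach * exp((1-phi)*dg_cs*c/rt): a transition-state split of the
// contact energy (ratio exp(-dg_cs*c/rt) independent of phi), so phi
// shifts kinetics, not equilibrium.
//
// An RNA is complete when all 30 PSs are in-shell; completed capsids are
// inert. The run stops at t_max, at quiescence (no shell-composition
// change within q_window), or when total propensity is zero.

namespace {

struct Fenwick {
  int n;
  std::vector<double> tree, val;
  void init(int n_) {
    n = n_;
    tree.assign(n + 1, 0.0);
    val.assign(n, 0.0);
  }
  void set(int i, double v) {
    double d = v - val[i];
    val[i] = v;
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
  }
  double total() const {
    double s = 0;
    for (int j = n; j > 0; j -= j & (-j)) s += tree[j];
    return s;
  }
  void rebuild() {
    std::vector<double> v = val;
    init(n);
    for (int i = 0; i < n; ++i) set(i, v[i]);
  }
  // smallest i with prefix sum > u
  int find(double u) const {
    int pos = 0, mask = 1;
    while ((mask << 1) <= n) mask <<= 1;
    for (; mask; mask >>= 1) {
      int next = pos + mask;
      if (next <= n && tree[next] <= u) { u -= tree[next]; pos = next; }
    }
    return pos < n ? pos : n - 1;
  }
};

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() {  // in (0, 1)
    double u = (g() >> 11) * (1.0 / 9007199254740992.0);
    return u > 0 ? u : 5e-324;
  }
};

struct Action {
  int type = -1;  // 0 unbind, 1 nucleate, 2 elong5, 3 elong3, 4 det_lo, 5 det_hi
  int ps = -1, target = -1, move = -1;
};

struct Engine {
  int n_rna, n_ps = 30;
  int perm[9][60], excl[60], cn[60][3];
  std::vector<int> moves, cmoves;
  std::vector<double> u_rate;          // n_rna*30 unbind rates
  std::vector<int8_t> st;              // n_rna*30: 0 free 1 bound 2 shell
  std::vector<int> pos;                // n_rna*30
  std::vector<int> lo, hi;             // interval, -1 when empty
  std::vector<uint64_t> occ, fill;  // path CPs; path + partner CPs
  std::vector<int8_t> complete;
  std::vector<double> t_complete;
  double k_bind, k_attach, k_nuc, dg_cs, rt, cp_ref, phi;
  bool fill_contacts, require_contact;
  double free_cp, cp_total0;
  double w_att[4], w_det[4];   // contact-count weights, c = 0..3
  Fenwick fp, ffree;
  double t = 0, last_shell = 0;
  long long n_bind = 0, n_unbind = 0, n_nuc = 0, n_att = 0, n_det = 0;
  int n_cap = 0;
  bool debug;
  std::vector<double> log;   // t, rna, type, ps, target, c per shell event
  long long log_max = 0;
  void log_ev(double t, int r, int type, int ps, int tgt, int c) {
    if ((long long)log.size() >= log_max * 6) return;
    log.push_back(t); log.push_back(r + 1); log.push_back(type);
    log.push_back(ps + 1); log.push_back(tgt + 1); log.push_back(c);
  }

  int contacts(int r, int p) const {
    uint64_t set = fill_contacts ? fill[r] : occ[r];
    int c = 0;
    for (int j = 0; j < 3; ++j)
      if (set >> cn[p][j] & 1ULL) ++c;
    return c;
  }

  // Walk the sub-events of RNA r; if pick >= 0 select the event at
  // cumulative propensity pick, else just return the total.
  double rna_prop(int r, double pick, Action &act) {
    double s = 0;
    if (complete[r]) return 0;
    const int8_t *S = &st[r * 30];
    const double *U = &u_rate[r * 30];
    for (int i = 0; i < 30; ++i)
      if (S[i] == 1) {
        s += U[i];
        if (pick >= 0 && pick < s) { act = {0, i, -1, -1}; return s; }
      }
    if (lo[r] < 0) {
      if (!cmoves.empty()) {
        double w = k_nuc / cmoves.size();
        for (int i = 0; i < 29; ++i)
          if (S[i] == 1 && S[i + 1] == 1)
            for (size_t m = 0; m < cmoves.size(); ++m) {
              s += w;
              if (pick >= 0 && pick < s) { act = {1, i, -1, cmoves[m]}; return s; }
            }
      }
      return s;
    }
    const int *P = &pos[r * 30];
    int L = lo[r], H = hi[r];
    // elongation, 5' then 3'
    for (int side = 0; side < 2; ++side) {
      int nb = side == 0 ? L - 1 : H + 1;
      if (nb < 0 || nb > 29 || S[nb] != 1) continue;
      int src = side == 0 ? P[L] : P[H];
      for (size_t m = 0; m < moves.size(); ++m) {
        int q = perm[moves[m] - 1][src];
        if (fill[r] >> q & 1ULL) continue;   // occupied or partner-blocked
        int c = contacts(r, q);
        if (require_contact && c == 0) continue;  // must touch the shell
        s += k_attach * w_att[c];
        if (pick >= 0 && pick < s) { act = {2 + side, nb, q, -1}; return s; }
      }
    }
    // detachment of terminal units (the unit's own contact is not counted)
    s += k_attach * w_det[contacts(r, P[L])];
    if (pick >= 0 && pick < s) { act = {4, L, -1, -1}; return s; }
    if (H > L) {
      s += k_attach * w_det[contacts(r, P[H])];
      if (pick >= 0 && pick < s) { act = {5, H, -1, -1}; return s; }
    }
    return s;
  }

  void refresh(int r) {
    Action a;
    fp.set(r, rna_prop(r, -1, a));
  }

  void validate(int r) {
    const int8_t *S = &st[r * 30];
    const int *P = &pos[r * 30];
    for (int i = 0; i < 30; ++i) {
      bool in = lo[r] >= 0 && i >= lo[r] && i <= hi[r];
      if ((S[i] == 2) != in) stop("invariant: interval contiguity violated");
    }
    if (lo[r] >= 0)
      for (int i = lo[r]; i <= hi[r]; ++i) {
        if (occ[r] >> excl[P[i]] & 1ULL)
          stop("invariant: exclusion pair doubly occupied");
        uint64_t f = 0;
        for (int j = lo[r]; j <= hi[r]; ++j)
          f |= (1ULL << P[j]) | (1ULL << excl[P[j]]);
        if (f != fill[r]) stop("invariant: filled set inconsistent");
        if (i > lo[r]) {
          bool ok = false;
          for (size_t m = 0; m < moves.size(); ++m)
            if (perm[moves[m] - 1][P[i - 1]] == P[i]) ok = true;
          if (!ok) stop("invariant: consecutive shell positions not move-related");
        }
      }
    double held = 0;
    for (int rr = 0; rr < n_rna; ++rr)
      for (int i = 0; i < 30; ++i) held += st[rr * 30 + i] >= 1;
    if (std::abs(free_cp + held - cp_total0) > 0.5)
      stop("invariant: CP conservation violated");
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_run_assembly(IntegerMatrix move_maps, IntegerVector exclusion,
                      IntegerMatrix contact_edges, IntegerVector moves_in,
                      NumericMatrix dg, double dg_cs, double rt,
                      double k_bind, double k_attach, double k_nuc,
                      double phi,
                      bool fill_contacts, bool require_contact,
                      double cp_total,
                      double cp_ref, double t_max, double q_window,
                      double seed, bool debug, double log_events = 0) {
  Engine E;
  E.n_rna = dg.ncol();
  if (dg.nrow() != 30) stop("dg must have 30 rows");
  for (int k = 0; k < 9; ++k)
    for (int p = 0; p < 60; ++p) E.perm[k][p] = move_maps(p, k) - 1;
  for (int p = 0; p < 60; ++p) E.excl[p] = exclusion[p] - 1;
  {
    std::vector<int> deg(60, 0);
    for (int e = 0; e < contact_edges.nrow(); ++e) {
      int a = contact_edges(e, 0) - 1, b = contact_edges(e, 1) - 1;
      if (deg[a] > 2 || deg[b] > 2) stop("contact graph not 3-regular");
      E.cn[a][deg[a]++] = b;
      E.cn[b][deg[b]++] = a;
    }
  }
  E.moves.assign(moves_in.begin(), moves_in.end());
  std::sort(E.moves.begin(), E.moves.end());
  for (int m : E.moves)
    if (m == 1 || m == 3 || m == 4) E.cmoves.push_back(m);
  E.k_bind = k_bind; E.k_attach = k_attach; E.k_nuc = k_nuc;
  E.dg_cs = dg_cs; E.rt = rt;
  E.phi = phi;
  E.fill_contacts = fill_contacts; E.require_contact = require_contact;
  E.cp_ref = cp_ref; E.free_cp = cp_total; E.cp_total0 = cp_total;
  E.debug = debug;
  E.log_max = (long long)log_events;
  for (int c = 0; c < 4; ++c) {
    E.w_att[c] = std::exp(-phi * dg_cs * c / rt);
    E.w_det[c] = std::exp((1 - phi) * dg_cs * c / rt);
  }

  int n = E.n_rna;
  E.u_rate.resize(n * 30);
  for (int r = 0; r < n; ++r)
    for (int i = 0; i < 30; ++i)
      E.u_rate[r * 30 + i] = k_bind * std::exp(dg(i, r) / rt);
  E.st.assign(n * 30, 0);
  E.pos.assign(n * 30, -1);
  E.lo.assign(n, -1); E.hi.assign(n, -1);
  E.occ.assign(n, 0);
  E.fill.assign(n, 0);
  E.complete.assign(n, 0);
  E.t_complete.assign(n, NA_REAL);
  E.fp.init(n);
  E.ffree.init(n);
  for (int r = 0; r < n; ++r) E.ffree.set(r, 30.0);

  Rng rng((uint64_t)seed);
  bool quiescent = false, hit_tmax = false;
  long long n_events = 0;

  while (true) {
    double Rb = E.free_cp > 0 ? k_bind * E.free_cp / cp_ref * E.ffree.total() : 0;
    double Pr = E.fp.total();
    double tot = Rb + Pr;
    if (tot <= 1e-300) { quiescent = true; break; }
    E.t += -std::log(rng.unif()) / tot;
    if (E.t > t_max) { hit_tmax = true; break; }
    if (E.t - E.last_shell > q_window) { quiescent = true; break; }
    if (++n_events % 2000000 == 0) {
      E.fp.rebuild(); E.ffree.rebuild();
      Rcpp::checkUserInterrupt();
    }
    if (rng.unif() * tot < Rb) {
      // bind a uniformly random free PS
      int r = E.ffree.find(rng.unif() * E.ffree.total());
      int k = (int)(rng.unif() * E.ffree.val[r]);
      int i = -1;
      for (int j = 0; j < 30; ++j)
        if (E.st[r * 30 + j] == 0 && k-- == 0) { i = j; break; }
      if (i < 0) continue;  // fp slack; resample
      E.st[r * 30 + i] = 1;
      E.free_cp -= 1;
      E.ffree.set(r, E.ffree.val[r] - 1);
      E.refresh(r);
      ++E.n_bind;
    } else {
      int r = E.fp.find(rng.unif() * Pr);
      Action a;
      double p = E.fp.val[r];
      if (p <= 0) continue;
      E.rna_prop(r, rng.unif() * p, a);
      if (a.type < 0) continue;
      int8_t *S = &E.st[r * 30];
      int *P = &E.pos[r * 30];
      switch (a.type) {
      case 0:  // unbind
        S[a.ps] = 0;
        E.free_cp += 1;
        E.ffree.set(r, E.ffree.val[r] + 1);
        ++E.n_unbind;
        break;
      case 1:  // nucleate PS pair (ps, ps+1) at (0, move(0))
        P[a.ps] = 0; P[a.ps + 1] = E.perm[a.move - 1][0];
        S[a.ps] = S[a.ps + 1] = 2;
        E.occ[r] = (1ULL << 0) | (1ULL << P[a.ps + 1]);
        E.fill[r] = E.occ[r] | (1ULL << E.excl[0]) |
                    (1ULL << E.excl[P[a.ps + 1]]);
        E.lo[r] = a.ps; E.hi[r] = a.ps + 1;
        E.last_shell = E.t;
        ++E.n_nuc;
        E.log_ev(E.t, r, 1, a.ps, P[a.ps + 1], 1);
        break;
      case 2:  // elongate 5'
        E.lo[r] = a.ps; P[a.ps] = a.target; S[a.ps] = 2;
        E.occ[r] |= 1ULL << a.target;
        E.fill[r] |= (1ULL << a.target) | (1ULL << E.excl[a.target]);
        E.last_shell = E.t;
        ++E.n_att;
        E.log_ev(E.t, r, 2, a.ps, a.target, E.contacts(r, a.target) - 0);
        break;
      case 3:  // elongate 3'
        E.hi[r] = a.ps; P[a.ps] = a.target; S[a.ps] = 2;
        E.occ[r] |= 1ULL << a.target;
        E.fill[r] |= (1ULL << a.target) | (1ULL << E.excl[a.target]);
        E.last_shell = E.t;
        ++E.n_att;
        E.log_ev(E.t, r, 3, a.ps, a.target, E.contacts(r, a.target) - 0);
        break;
      case 4: case 5:  // detach terminal (stays CP-bound)
        S[a.ps] = 1;
        E.occ[r] &= ~(1ULL << P[a.ps]);
        E.fill[r] &= ~((1ULL << P[a.ps]) | (1ULL << E.excl[P[a.ps]]));
        if (E.lo[r] == E.hi[r]) { E.lo[r] = E.hi[r] = -1; }
        else if (a.type == 4) E.lo[r] = a.ps + 1;
        else E.hi[r] = a.ps - 1;
        E.last_shell = E.t;
        ++E.n_det;
        E.log_ev(E.t, r, 4, a.ps, P[a.ps], 0);
        break;
      }
      if (E.lo[r] == 0 && E.hi[r] == 29) {
        E.complete[r] = 1;
        E.t_complete[r] = E.t;
        ++E.n_cap;
        E.ffree.set(r, 0);
      }
      E.refresh(r);
      if (debug && a.type >= 1) E.validate(r);
    }
  }

  IntegerMatrix allpos(n, 30);
  IntegerVector lo_out(n), hi_out(n);
  for (int r = 0; r < n; ++r) {
    lo_out[r] = E.lo[r] >= 0 ? E.lo[r] + 1 : NA_INTEGER;
    hi_out[r] = E.lo[r] >= 0 ? E.hi[r] + 1 : NA_INTEGER;
    for (int i = 0; i < 30; ++i)
      allpos(r, i) = E.st[r * 30 + i] == 2 ? E.pos[r * 30 + i] + 1 : NA_INTEGER;
  }
  IntegerMatrix paths(E.n_cap, 30);
  NumericVector tcap(E.n_cap);
  IntegerVector status(n);
  int row = 0;
  for (int r = 0; r < n; ++r) {
    int sz = E.lo[r] >= 0 ? E.hi[r] - E.lo[r] + 1 : 0;
    status[r] = E.complete[r] ? 2 : (sz > 0 ? 1 : 0);
    if (E.complete[r]) {
      for (int i = 0; i < 30; ++i) paths(row, i) = E.pos[r * 30 + i] + 1;
      tcap[row] = E.t_complete[r];
      ++row;
    }
  }
  return List::create(
    _["n_cap"] = E.n_cap,
    _["paths"] = paths,
    _["t_complete"] = tcap,
    _["status"] = status,
    _["t_end"] = E.t,
    _["quiescent"] = quiescent,
    _["shell_pos"] = allpos,
    _["lo"] = lo_out,
    _["hi"] = hi_out,
    _["hit_tmax"] = hit_tmax,
    _["free_cp"] = E.free_cp,
    _["log"] = E.log,
    _["events"] = NumericVector::create(
      _["bind"] = (double)E.n_bind, _["unbind"] = (double)E.n_unbind,
      _["nucleate"] = (double)E.n_nuc, _["attach"] = (double)E.n_att,
      _["detach"] = (double)E.n_det));
}
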