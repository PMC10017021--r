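// Matrix-product-operator compiler and two-site DMRG contraction kernels.
//
// The quantum-chemistry Hamiltonian is compiled into an exact sparse MPO
// over spatial-orbital sites (local dimension 4, basis |0>, |dn>, |up>,
// |updn> with |updn> = a+_up a+_dn |0>). Channels crossing each bond
// follow the normal/complementary-operator normal form: identity,
// completed, single a+/a per spin-orbital mode, pair channels (two
// creators / two annihilators / mixed), and await-single channels for the
// final operator of a two-body term. Jordan-Wigner parity is handled by
// parity pass-through operators and the rule that the emitted local
// operator is multiplied by the parity matrix when the cumulative count
// of placed fermionic operators through the site is odd.
#include <RcppArmadillo.h>
#include <map>
#include <tuple>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

typedef arma::mat::fixed<4, 4> M4;

M4 op_a_up() {
  M4 m; m.zeros();
  m(0, 2) = 1; m(1, 3) = 1;
  return m;
}
M4 op_a_dn() {
  M4 m; m.zeros();
  m(0, 1) = 1; m(2, 3) = -1;
  return m;
}
M4 op_parity() {
  M4 m; m.zeros();
  m(0, 0) = 1; m(1, 1) = -1; m(2, 2) = -1; m(3, 3) = 1;
  return m;
}

struct Op { int mode; bool dag; };

struct MpoBuilder {
  int k;          // spatial sites
  int n;          // modes = 2k
  int OFF_D, OFF_E, OFF_A, OFF_B, OFF_C, OFF_NA, OFF_NC, W_all;
  // per-site entry maps: (from, to) -> matrix
  std::vector<std::map<std::pair<int, int>, arma::mat>> unit, inject;
  M4 aup, adn, par;

  MpoBuilder(int k_) : k(k_), n(2 * k_) {
    OFF_D = 2;
    OFF_E = OFF_D + n;
    OFF_A = OFF_E + n;
    int npair = n * (n - 1) / 2;
    OFF_B = OFF_A + npair;
    OFF_C = OFF_B + npair;
    OFF_NA = OFF_C + n * n;
    OFF_NC = OFF_NA + n;
    W_all = OFF_NC + n;
    unit.resize(k);
    inject.resize(k);
    aup = op_a_up(); adn = op_a_dn(); par = op_parity();
  }
  int pidx(int P, int Q) const { // 1-based modes, P < Q
    return (Q - 1) * (Q - 2) / 2 + (P - 1);
  }
  int site_of(int mode) const { return (mode - 1) / 2; } // 0-based site
  M4 local(int mode, bool dag) const {
    M4 m = (mode % 2 == 1) ? aup : adn; // odd mode = up
    if (dag) return M4(m.t());
    return m;
  }
  // channel of a placed-op set
  int channel(const std::vector<Op>& placed,
              const std::vector<Op>& remaining) const {
    size_t np = placed.size();
    if (np == 0) return 0;
    if (remaining.empty()) return 1;
    if (np == 1)
      return placed[0].dag ? OFF_D + placed[0].mode - 1
                           : OFF_E + placed[0].mode - 1;
    if (np == 2) {
      bool d0 = placed[0].dag, d1 = placed[1].dag;
      int m0 = placed[0].mode, m1 = placed[1].mode;
      if (d0 && d1)
        return OFF_A + pidx(std::min(m0, m1), std::max(m0, m1));
      if (!d0 && !d1)
        return OFF_B + pidx(std::min(m0, m1), std::max(m0, m1));
      int P = d0 ? m0 : m1, R = d0 ? m1 : m0;
      return OFF_C + (P - 1) * n + (R - 1);
    }
    // np == 3: await the single remaining operator
    const Op& rem = remaining[0];
    return rem.dag ? OFF_NC + rem.mode - 1 : OFF_NA + rem.mode - 1;
  }

  void add_term(double coeff, std::vector<Op> ops) {
    if (coeff == 0.0) return;
    // stable sort by site; parity of the permutation
    int m = ops.size();
    int sign = 1;
    for (int i = 1; i < m; ++i) { // insertion sort counting swaps
      Op key = ops[i];
      int j = i - 1;
      while (j >= 0 && site_of(ops[j].mode) > site_of(key.mode)) {
        ops[j + 1] = ops[j];
        sign = -sign;
        --j;
      }
      ops[j + 1] = key;
    }
    coeff *= sign;
    // group by site and walk
    std::vector<Op> placed;
    bool injected = false;
    int i = 0;
    int from = 0;
    while (i < m) {
      int s = site_of(ops[i].mode);
      arma::mat loc = arma::eye(4, 4);
      int cnt = 0;
      while (i < m && site_of(ops[i].mode) == s) {
        loc = loc * local(ops[i].mode, ops[i].dag);
        placed.push_back(ops[i]);
        ++i; ++cnt;
      }
      if (placed.size() % 2 == 1) loc = loc * par;
      std::vector<Op> remaining(ops.begin() + i, ops.end());
      int to = channel(placed, remaining);
      bool is_info_loss = (to == 1 || to >= OFF_NA);
      auto key = std::make_pair(from, to);
      if (is_info_loss && !injected) {
        auto it = inject[s].find(key);
        if (it == inject[s].end()) inject[s][key] = coeff * loc;
        else it->second += coeff * loc;
        injected = true;
      } else {
        auto it = unit[s].find(key);
        if (it == unit[s].end()) unit[s][key] = loc;
      }
      from = to;
    }
  }
};

} // namespace

// Build the Hamiltonian MPO from spatial-orbital integrals (already
// permuted into chain order). h: k x k, eri: k^4 flat chemist (pq|rs).
// Returns per-site sparse entries plus per-bond active channel lists.
// [[Rcpp::export(name = ".cpp_build_mpo")]]
List cpp_build_mpo(int k, arma::mat h, NumericVector eri) {
  MpoBuilder B(k);
  int n = 2 * k;
  auto spat = [&](int mode) { return (mode - 1) / 2; }; // 0-based orbital
  auto spin = [&](int mode) { return (mode - 1) % 2; };
  const double* V = eri.begin();
  auto eri_at = [&](int p, int q, int r, int s) { // 0-based spatial
    return V[p + k * (q + k * (r + (size_t)k * s))];
  };
  // <PQ|RS> over modes (physicist) = (pr|qs) delta(sP,sR) delta(sQ,sS)
  auto Vmode = [&](int P, int Q, int R, int S) {
    double v = 0.0;
    if (spin(P) == spin(R) && spin(Q) == spin(S))
      v = eri_at(spat(P), spat(R), spat(Q), spat(S));
    return v;
  };
  // one-electron terms
  for (int P = 1; P <= n; ++P)
    for (int Q = 1; Q <= n; ++Q) {
      if (spin(P) != spin(Q)) continue;
      double t = h(spat(P), spat(Q));
      if (t != 0.0)
        B.add_term(t, {{P, true}, {Q, false}});
    }
  // two-electron: sum_{P<Q, R<S} G a+_P a+_Q a_S a_R,
  // G = <PQ|RS> - <PQ|SR>
  for (int P = 1; P <= n; ++P)
    for (int Q = P + 1; Q <= n; ++Q)
      for (int R = 1; R <= n; ++R)
        for (int S = R + 1; S <= n; ++S) {
          double G = Vmode(P, Q, R, S) - Vmode(P, Q, S, R);
          if (G != 0.0)
            B.add_term(G, {{P, true}, {Q, true}, {S, false}, {R, false}});
        }
  // merge entries, reachability pruning
  std::vector<std::map<std::pair<int, int>, arma::mat>> ent(k);
  for (int s = 0; s < k; ++s) {
    ent[s] = B.unit[s];
    for (auto& kv : B.inject[s]) {
      auto it = ent[s].find(kv.first);
      if (it == ent[s].end()) ent[s][kv.first] = kv.second;
      else it->second += kv.second;
    }
  }
  int W = B.W_all;
  std::vector<std::vector<bool>> fwd(k + 1, std::vector<bool>(W, false));
  fwd[0][0] = true;
  for (int s = 0; s < k; ++s) {
    fwd[s + 1] = fwd[s]; // pass-through
    for (auto& kv : ent[s])
      if (fwd[s][kv.first.first]) fwd[s + 1][kv.first.second] = true;
  }
  std::vector<std::vector<bool>> bwd(k + 1, std::vector<bool>(W, false));
  bwd[k][1] = true;
  for (int s = k - 1; s >= 0; --s) {
    bwd[s] = bwd[s + 1];
    for (auto& kv : ent[s])
      if (bwd[s + 1][kv.first.second]) bwd[s][kv.first.first] = true;
  }
  M4 par = op_parity();
  // parity of each channel (odd op count -> parity pass-through)
  auto chan_parity = [&](int c) {
    if (c >= B.OFF_D && c < B.OFF_A) return 1;      // singles
    if (c >= B.OFF_NA) return 1;                    // await singles
    return 0;
  };
  List sites(k);
  List bonds(k + 1);
  for (int b = 0; b <= k; ++b) {
    std::vector<int> act;
    for (int c = 0; c < W; ++c)
      if (fwd[b][c] && bwd[b][c]) act.push_back(c);
    IntegerVector av(act.size());
    for (size_t i = 0; i < act.size(); ++i) av[i] = act[i];
    bonds[b] = av;
  }
  for (int s = 0; s < k; ++s) {
    std::vector<int> from, to;
    std::vector<arma::mat> mats;
    for (auto& kv : ent[s]) {
      int f = kv.first.first, t = kv.first.second;
      if (fwd[s][f] && bwd[s][f] && fwd[s + 1][t] && bwd[s + 1][t]) {
        from.push_back(f); to.push_back(t); mats.push_back(kv.second);
      }
    }
    // pass-through entries
    for (int c = 0; c < W; ++c) {
      if (fwd[s][c] && bwd[s][c] && fwd[s + 1][c] && bwd[s + 1][c]) {
        from.push_back(c); to.push_back(c);
        mats.push_back(chan_parity(c) ? arma::mat(par)
                                      : arma::eye(4, 4));
      }
    }
    int ne = from.size();
    IntegerVector fv(ne), tv(ne);
    arma::cube ops(4, 4, ne);
    for (int i = 0; i < ne; ++i) {
      fv[i] = from[i]; tv[i] = to[i];
      ops.slice(i) = mats[i];
    }
    sites[s] = List::create(_["from"] = fv, _["to"] = tv, _["ops"] = ops);
  }
  return List::create(_["k"] = k, _["W"] = W, _["sites"] = sites,
                      _["bonds"] = bonds);
}

namespace {

// helper: dense site tensor A passed as (Ml x 4 x Mr) cube
arma::cube as_cube3(NumericVector a) {
  IntegerVector d = a.attr("dim");
  arma::cube c(a.begin(), d[0], d[1], d[2], false);
  return c;
}

} // namespace

// Left environment update across one site.
// L: list over channels (NULL or Ml x Ml matrix, bra x ket),
// site: MPO entries, A: site tensor (Ml x 4 x Mr).
// [[Rcpp::export(name = ".cpp_env_left")]]
List cpp_env_left(List L, List site, NumericVector A, int W) {
  arma::cube Ac = as_cube3(A);
  int Ml = Ac.n_rows, Mr = Ac.n_slices;
  IntegerVector from = site["from"], to = site["to"];
  arma::cube ops = site["ops"];
  std::vector<arma::mat> out(W);
  std::vector<bool> has(W, false);
  // reshape A as matrices per physical index: A_s (Ml x Mr)
  std::vector<arma::mat> As(4);
  for (int s = 0; s < 4; ++s) {
    As[s].set_size(Ml, Mr);
    for (int i = 0; i < Ml; ++i)
      for (int j = 0; j < Mr; ++j) As[s](i, j) = Ac(i, s, j);
  }
  for (int e = 0; e < from.size(); ++e) {
    int f = from[e], t = to[e];
    if (f >= L.size() || Rf_isNull(L[f])) continue;
    NumericMatrix Lm = L[f];
    arma::mat Lf(Lm.begin(), Lm.nrow(), Lm.ncol(), false);
    arma::mat op = ops.slice(e);
    // L'[t]_{a',b'} = sum_{s',s} op(s',s) (A^{s'})^T L A^{s}
    arma::mat acc(Mr, Mr, arma::fill::zeros);
    for (int sp = 0; sp < 4; ++sp) {
      arma::mat tmp;
      bool have = false;
      for (int ss = 0; ss < 4; ++ss) {
        double v = op(sp, ss);
        if (v == 0.0) continue;
        if (!have) { tmp = v * As[ss]; have = true; }
        else tmp += v * As[ss];
      }
      if (!have) continue;
      acc += As[sp].t() * Lf * tmp;
    }
    if (!has[t]) { out[t] = acc; has[t] = true; }
    else out[t] += acc;
  }
  List res(W);
  for (int c = 0; c < W; ++c)
    if (has[c]) res[c] = wrap(out[c]);
  return res;
}

// Right environment update (mirror): R'[f]_{a,b} over left bond of site.
// [[Rcpp::export(name = ".cpp_env_right")]]
List cpp_env_right(List R, List site, NumericVector A, int W) {
  arma::cube Ac = as_cube3(A);
  int Ml = Ac.n_rows, Mr = Ac.n_slices;
  IntegerVector from = site["from"], to = site["to"];
  arma::cube ops = site["ops"];
  std::vector<arma::mat> out(W);
  std::vector<bool> has(W, false);
  std::vector<arma::mat> As(4);
  for (int s = 0; s < 4; ++s) {
    As[s].set_size(Ml, Mr);
    for (int i = 0; i < Ml; ++i)
      for (int j = 0; j < Mr; ++j) As[s](i, j) = Ac(i, s, j);
  }
  for (int e = 0; e < from.size(); ++e) {
    int f = from[e], t = to[e];
    if (t >= R.size() || Rf_isNull(R[t])) continue;
    NumericMatrix Rm = R[t];
    arma::mat Rt(Rm.begin(), Rm.nrow(), Rm.ncol(), false);
    arma::mat op = ops.slice(e);
    arma::mat acc(Ml, Ml, arma::fill::zeros);
    for (int sp = 0; sp < 4; ++sp) {
      arma::mat tmp;
      bool have = false;
      for (int ss = 0; ss < 4; ++ss) {
        double v = op(sp, ss);
        if (v == 0.0) continue;
        if (!have) { tmp = v * As[ss]; have = true; }
        else tmp += v * As[ss];
      }
      if (!have) continue;
      acc += As[sp] * Rt * tmp.t();
    }
    // acc_{a_bra?}: R[f]_{a_bra, a_ket} = sum A^{s'}_{abra,b'} R[t]_{b',b} A^{s}_{aket,b}
    if (!has[f]) { out[f] = acc; has[f] = true; }
    else out[f] += acc;
  }
  List res(W);
  for (int c = 0; c < W; ++c)
    if (has[c]) res[c] = wrap(out[c]);
  return res;
}

// Two-site effective Hamiltonian matvec.
// x: (Ml x 4 x 4 x Mr) flat; L/R: channel lists; s1/s2: MPO entries.
// [[Rcpp::export(name = ".cpp_heff_matvec")]]
NumericVector cpp_heff_matvec(List L, List R, List s1, List s2,
                              NumericVector x, int Ml, int Mr, int W) {
  IntegerVector f1 = s1["from"], t1 = s1["to"];
  arma::cube o1 = s1["ops"];
  IntegerVector f2 = s2["from"], t2 = s2["to"];
  arma::cube o2 = s2["ops"];
  // group W2 entries by middle channel
  std::vector<std::vector<int>> w2_by_mid(W);
  for (int e = 0; e < f2.size(); ++e) w2_by_mid[f2[e]].push_back(e);
  std::vector<std::vector<int>> w1_by_mid(W);
  for (int e = 0; e < f1.size(); ++e) {
    if (f1[e] < L.size() && !Rf_isNull(L[f1[e]])
        && !w2_by_mid[t1[e]].empty())
      w1_by_mid[t1[e]].push_back(e);
  }
  const double* X = x.begin();
  NumericVector y(x.size());
  double* Y = y.begin();
  // view x as Ml x (4*4*Mr) matrix (column-major: a fastest)
  arma::mat Xm(const_cast<double*>(X), Ml, 16 * Mr, false);
  arma::mat Ym(Y, Ml, 16 * Mr, false);
  arma::mat U(Ml, 16 * Mr);
  arma::mat V(Ml, 16 * Mr);
  // cache L[cl] * x products: the same left channel feeds several
  // entries (operator + parity pass-through), and the product dominates
  // the per-entry cost at small bond dimension
  std::vector<arma::mat> Tcache;
  std::vector<int> Tslot(W, -1);
  for (int cm = 0; cm < W; ++cm) {
    if (w1_by_mid[cm].empty() || w2_by_mid[cm].empty()) continue;
    bool anyR = false;
    for (int e : w2_by_mid[cm])
      if (t2[e] < R.size() && !Rf_isNull(R[t2[e]])) { anyR = true; break; }
    if (!anyR) continue;
    U.zeros();
    for (int e : w1_by_mid[cm]) {
      int cl = f1[e];
      if (Tslot[cl] < 0) {
        NumericMatrix Lm = L[cl];
        arma::mat Lf(Lm.begin(), Lm.nrow(), Lm.ncol(), false);
        Tcache.emplace_back(Lf * Xm);
        Tslot[cl] = Tcache.size() - 1;
      }
      const arma::mat& T = Tcache[Tslot[cl]];
      const arma::mat& op = o1.slice(e);
      // apply op1: U_{abra, s1', s2, b} += op(s1', s1) T_{abra, s1, s2, b}
      for (int sp = 0; sp < 4; ++sp)
        for (int ss = 0; ss < 4; ++ss) {
          double v = op(sp, ss);
          if (v == 0.0) continue;
          for (int rest = 0; rest < 4 * Mr; ++rest)
            U.col(sp + 4 * rest) += v * T.col(ss + 4 * rest);
        }
    }
    // apply op2 and right environments
    for (int e : w2_by_mid[cm]) {
      int cr = t2[e];
      if (cr >= R.size() || Rf_isNull(R[cr])) continue;
      const arma::mat& op = o2.slice(e);
      V.zeros();
      // layout x[a, s1, s2, b] column-major: column = s1 + 4*s2 + 16*b
      // V_{a, s1, s2', b} += op2(s2', s2) U_{a, s1, s2, b}
      for (int sp = 0; sp < 4; ++sp)
        for (int ss = 0; ss < 4; ++ss) {
          double v = op(sp, ss);
          if (v == 0.0) continue;
          for (int b = 0; b < Mr; ++b)
            for (int s1i = 0; s1i < 4; ++s1i)
              V.col(s1i + 4 * sp + 16 * b) +=
                v * U.col(s1i + 4 * ss + 16 * b);
        }
      NumericMatrix Rm = R[cr];
      arma::mat Rt(Rm.begin(), Rm.nrow(), Rm.ncol(), false); // (bra, ket)
      // Y_{abra, s1', s2', bbra} += V_{abra, s1', s2', bket} Rt_{bbra,bket}
      // treat V as (Ml*16) x Mr
      arma::mat Vm(V.memptr(), Ml * 16, Mr, false);
      arma::mat Ym2(Y, Ml * 16, Mr, false);
      Ym2 += Vm * Rt.t();
    }
  }
  return y;
}

// diagonal of the two-site effective Hamiltonian (for preconditioning)
// [[Rcpp::export(name = ".cpp_heff_diag")]]
NumericVector cpp_heff_diag(List L, List R, List s1, List s2,
                            int Ml, int Mr, int W) {
  IntegerVector f1 = s1["from"], t1 = s1["to"];
  arma::cube o1 = s1["ops"];
  IntegerVector f2 = s2["from"], t2 = s2["to"];
  arma::cube o2 = s2["ops"];
  std::vector<std::vector<int>> w2_by_mid(W);
  for (int e = 0; e < f2.size(); ++e) w2_by_mid[f2[e]].push_back(e);
  NumericVector out(Ml * 4 * 4 * Mr);
  double* O = out.begin();
  for (int e1 = 0; e1 < f1.size(); ++e1) {
    int cl = f1[e1], cm = t1[e1];
    if (cl >= L.size() || Rf_isNull(L[cl])) continue;
    if (w2_by_mid[cm].empty()) continue;
    arma::mat Lf = as<arma::mat>(L[cl]);
    arma::vec ld = Lf.diag();
    const arma::mat& op1 = o1.slice(e1);
    for (int e2 : w2_by_mid[cm]) {
      int cr = t2[e2];
      if (cr >= R.size() || Rf_isNull(R[cr])) continue;
      arma::mat Rt = as<arma::mat>(R[cr]);
      arma::vec rd = Rt.diag();
      const arma::mat& op2 = o2.slice(e2);
      for (int s2i = 0; s2i < 4; ++s2i) {
        double v2 = op2(s2i, s2i);
        if (v2 == 0.0) continue;
        for (int s1i = 0; s1i < 4; ++s1i) {
          double v1 = op1(s1i, s1i);
          if (v1 == 0.0) continue;
          for (int b = 0; b < Mr; ++b) {
            double f = v1 * v2 * rd(b);
            size_t base = Ml * (s1i + 4 * (s2i + 4 * (size_t)b));
            for (int a = 0; a < Ml; ++a)
              O[base + a] += f * ld(a);
          }
        }
      }
    }
  }
  return out;
}
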