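// Determinant-basis full CI: dense Hamiltonian build via Slater-Condon
// rules (S_z = 0 sector, bitstring determinants), plus 1-RDM assembly.
// This is the brute-force oracle: clarity over speed.
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

typedef uint32_t detstr;

int popcount(detstr x) { return __builtin_popcount(x); }

// parity of occupied orbitals strictly between positions p and q
int parity_between(detstr s, int p, int q) {
  if (p > q) std::swap(p, q);
  detstr mask = ((detstr(1) << q) - 1) & ~((detstr(1) << (p + 1)) - 1);
  return (popcount(s & mask) % 2) ? -1 : 1;
}

void gen_strings(int norb, int ne, std::vector<detstr>& out) {
  // lexicographic enumeration of ne-bit subsets of norb
  if (ne == 0) { out.push_back(0); return; }
  detstr s = (detstr(1) << ne) - 1;
  detstr limit = detstr(1) << norb;
  while (s < limit) {
    out.push_back(s);
    detstr c = s & -s;
    detstr r = s + c;
    s = (((r ^ s) >> 2) / c) | r;
  }
}

struct Ints {
  int n;
  const double* h;
  const double* eri; // chemist (pq|rs), full dense n^4, column-major
  double H1(int p, int q) const { return h[p + n * q]; }
  double V(int p, int q, int r, int s) const {
    return eri[p + n * (q + n * (r + (size_t)n * s))];
  }
};

void occ_list(detstr s, int norb, std::vector<int>& occ) {
  occ.clear();
  for (int i = 0; i < norb; ++i)
    if (s & (detstr(1) << i)) occ.push_back(i);
}

// <S|H|S'> for strings differing by a single excitation p->q in one spin
// channel; other-channel string o gives the Coulomb/exchange background.
double single_elem(const Ints& I, detstr same, detstr other,
                   int p, int q, int norb) {
  double v = I.H1(p, q);
  std::vector<int> occ;
  occ_list(same, norb, occ);
  for (int r : occ) {
    v += I.V(p, q, r, r) - I.V(p, r, r, q);
  }
  occ_list(other, norb, occ);
  for (int r : occ) v += I.V(p, q, r, r);
  return v;
}

} // namespace

// [[Rcpp::export(name = ".cpp_fci_strings")]]
IntegerVector cpp_fci_strings(int norb, int ne) {
  std::vector<detstr> s;
  gen_strings(norb, ne, s);
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (int)s[i];
  return out;
}

// [[Rcpp::export(name = ".cpp_fci_ham")]]
arma::mat cpp_fci_ham(int norb, arma::mat hmat, NumericVector eri,
                      IntegerVector strA, IntegerVector strB) {
  Ints I{norb, hmat.memptr(), eri.begin()};
  int nA = strA.size(), nB = strB.size();
  size_t dim = (size_t)nA * nB;
  arma::mat H(dim, dim, arma::fill::zeros);
  std::vector<int> occ, occ2;
  // index: det = ia + nA * ib  (column-major style pairing)
  for (int ib = 0; ib < nB; ++ib) {
    detstr sb = (detstr)strB[ib];
    for (int ia = 0; ia < nA; ++ia) {
      detstr sa = (detstr)strA[ia];
      size_t ii = ia + (size_t)nA * ib;
      // diagonal
      double e = 0.0;
      occ_list(sa, norb, occ);
      occ_list(sb, norb, occ2);
      for (int p : occ) e += I.H1(p, p);
      for (int p : occ2) e += I.H1(p, p);
      for (size_t x = 0; x < occ.size(); ++x)
        for (size_t y = 0; y < occ.size(); ++y) {
          e += 0.5 * (I.V(occ[x], occ[x], occ[y], occ[y])
                      - I.V(occ[x], occ[y], occ[y], occ[x]));
        }
      for (size_t x = 0; x < occ2.size(); ++x)
        for (size_t y = 0; y < occ2.size(); ++y) {
          e += 0.5 * (I.V(occ2[x], occ2[x], occ2[y], occ2[y])
                      - I.V(occ2[x], occ2[y], occ2[y], occ2[x]));
        }
      for (size_t x = 0; x < occ.size(); ++x)
        for (size_t y = 0; y < occ2.size(); ++y)
          e += I.V(occ[x], occ[x], occ2[y], occ2[y]);
      H(ii, ii) = e;
      // off-diagonal: loop over other determinants with <= 2 diffs
      for (int jb = ib; jb < nB; ++jb) {
        detstr tb = (detstr)strB[jb];
        int db = popcount(sb ^ tb) / 2;
        if (db > 2) continue;
        int ja0 = (jb == ib) ? ia + 1 : 0;
        for (int ja = ja0; ja < nA; ++ja) {
          detstr ta = (detstr)strA[ja];
          int da = popcount(sa ^ ta) / 2;
          if (da + db > 2 || (da + db) == 0) continue;
          size_t jj = ja + (size_t)nA * jb;
          double v = 0.0;
          if (da == 1 && db == 0) {
            detstr rem = sa & ~ta, add = ta & ~sa;
            int p = __builtin_ctz(rem), q = __builtin_ctz(add);
            v = parity_between(sa, p, q) * single_elem(I, sa & ta, sb, p, q, norb);
          } else if (da == 0 && db == 1) {
            detstr rem = sb & ~tb, add = tb & ~sb;
            int p = __builtin_ctz(rem), q = __builtin_ctz(add);
            v = parity_between(sb, p, q) * single_elem(I, sb & tb, sa, p, q, norb);
          } else if (da == 1 && db == 1) {
            detstr rema = sa & ~ta, adda = ta & ~sa;
            int p = __builtin_ctz(rema), q = __builtin_ctz(adda);
            detstr remb = sb & ~tb, addb = tb & ~sb;
            int r = __builtin_ctz(remb), s = __builtin_ctz(addb);
            int ph = parity_between(sa, p, q) * parity_between(sb, r, s);
            v = ph * I.V(p, q, r, s);
          } else if (da == 2 && db == 0) {
            detstr rem = sa & ~ta, add = ta & ~sa;
            int p = __builtin_ctz(rem);
            int q = __builtin_ctz(rem & (rem - 1));
            int r = __builtin_ctz(add);
            int s = __builtin_ctz(add & (add - 1));
            int sign = 1;
            auto ann = [&](detstr& st, int o) {
              detstr mask = (detstr(1) << o) - 1;
              if (popcount(st & mask) % 2) sign = -sign;
              st &= ~(detstr(1) << o);
            };
            auto cre = [&](detstr& st, int o) {
              detstr mask = (detstr(1) << o) - 1;
              if (popcount(st & mask) % 2) sign = -sign;
              st |= (detstr(1) << o);
            };
            detstr st = sa;
            ann(st, p); ann(st, q); cre(st, s); cre(st, r);
            // (a_q a_p ordering then a+_r a+_s) ~ convention folds into V
            v = sign * (I.V(p, r, q, s) - I.V(p, s, q, r));
          } else { // da == 0 && db == 2
            detstr rem = sb & ~tb, add = tb & ~sb;
            int p = __builtin_ctz(rem);
            int q = __builtin_ctz(rem & (rem - 1));
            int r = __builtin_ctz(add);
            int s = __builtin_ctz(add & (add - 1));
            int sign = 1;
            auto ann = [&](detstr& st, int o) {
              detstr mask = (detstr(1) << o) - 1;
              if (popcount(st & mask) % 2) sign = -sign;
              st &= ~(detstr(1) << o);
            };
            auto cre = [&](detstr& st, int o) {
              detstr mask = (detstr(1) << o) - 1;
              if (popcount(st & mask) % 2) sign = -sign;
              st |= (detstr(1) << o);
            };
            detstr st = sb;
            ann(st, p); ann(st, q); cre(st, s); cre(st, r);
            v = sign * (I.V(p, r, q, s) - I.V(p, s, q, r));
          }
          H(ii, jj) = v;
          H(jj, ii) = v;
        }
      }
    }
  }
  return H;
}

// spin-summed spatial 1-RDM from a CI vector
// [[Rcpp::export(name = ".cpp_fci_rdm1")]]
arma::mat cpp_fci_rdm1(int norb, arma::vec ci,
                       IntegerVector strA, IntegerVector strB) {
  int nA = strA.size(), nB = strB.size();
  arma::mat G(norb, norb, arma::fill::zeros);
  std::vector<int> occ;
  for (int ib = 0; ib < nB; ++ib) {
    detstr sb = (detstr)strB[ib];
    for (int ia = 0; ia < nA; ++ia) {
      detstr sa = (detstr)strA[ia];
      size_t ii = ia + (size_t)nA * ib;
      double ci_i = ci(ii);
      if (ci_i == 0) continue;
      occ_list(sa, norb, occ);
      for (int p : occ) G(p, p) += ci_i * ci_i;
      occ_list(sb, norb, occ);
      for (int p : occ) G(p, p) += ci_i * ci_i;
      // alpha singles
      for (int ja = 0; ja < nA; ++ja) {
        if (ja == ia) continue;
        detstr ta = (detstr)strA[ja];
        if (popcount(sa ^ ta) != 2) continue;
        detstr rem = sa & ~ta, add = ta & ~sa;
        int p = __builtin_ctz(rem), q = __builtin_ctz(add);
        size_t jj = ja + (size_t)nA * ib;
        G(q, p) += parity_between(sa, p, q) * ci_i * ci(jj);
      }
      // beta singles
      for (int jb = 0; jb < nB; ++jb) {
        if (jb == ib) continue;
        detstr tb = (detstr)strB[jb];
        if (popcount(sb ^ tb) != 2) continue;
        detstr rem = sb & ~tb, add = tb & ~sb;
        int p = __builtin_ctz(rem), q = __builtin_ctz(add);
        size_t jj = ia + (size_t)nA * jb;
        G(q, p) += parity_between(sb, p, q) * ci_i * ci(jj);
      }
    }
  }
  return 0.5 * (G + G.t());
}
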