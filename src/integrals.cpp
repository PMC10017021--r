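// Gaussian integral engine: McMurchie-Davidson scheme over contracted
// cartesian shells (l <= 2), transformed to real spherical harmonics.
// All lengths in bohr. AO ordering: p -> (x,y,z); d -> (xy, yz, z2, xz, x2-y2).
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double PI = 3.14159265358979323846;

struct Shell {
  int l;
  int atom;
  arma::vec3 R;
  std::vector<double> exps;
  std::vector<double> coefs; // include primitive normalization
  int nsph() const { return 2 * l + 1; }
  int ncart() const { return (l + 1) * (l + 2) / 2; }
};

// cartesian component exponents per l, fixed ordering
// l=0: (000); l=1: x,y,z; l=2: xx,xy,xz,yy,yz,zz
static const int CART2[6][3] = {{2,0,0},{1,1,0},{1,0,1},{0,2,0},{0,1,1},{0,0,2}};
static const int CART1[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
static const int CART0[1][3] = {{0,0,0}};

inline void cart_comp(int l, int k, int* out) {
  const int (*tab)[3] = (l == 0) ? CART0 : (l == 1 ? CART1 : CART2);
  out[0] = tab[k][0]; out[1] = tab[k][1]; out[2] = tab[k][2];
}

// spherical transform: rows = sph, cols = cart
arma::mat sph_transform(int l) {
  if (l == 0) return arma::mat(1, 1, arma::fill::ones);
  if (l == 1) return arma::eye(3, 3);
  arma::mat T(5, 6, arma::fill::zeros);
  const double s3 = std::sqrt(3.0);
  T(0, 1) = s3;                       // xy
  T(1, 4) = s3;                       // yz
  T(2, 0) = -0.5; T(2, 3) = -0.5; T(2, 5) = 1.0; // (2z2-x2-y2)/2
  T(3, 2) = s3;                       // xz
  T(4, 0) = 0.5 * s3; T(4, 3) = -0.5 * s3;       // (x2-y2)*sqrt3/2
  return T;
}

// Boys function F_m(T) for m = 0..mmax
void boys(int mmax, double T, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(PI / T);
    double eT = (T < 700.0) ? std::exp(-T) : 0.0;
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - eT) / (2.0 * T);
    return;
  }
  // series for F_mmax: t_0 = 1/(2m+1), t_i = t_{i-1} * 2T/(2m+2i+1),
  // then stable downward recursion
  double t = 1.0 / (2.0 * mmax + 1.0);
  double acc = t;
  for (int i = 1; i < 300; ++i) {
    t *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    acc += t;
    if (t < acc * 1e-17) break;
  }
  double eT = std::exp(-T);
  F[mmax] = acc * eT;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// Hermite expansion coefficients E_t^{ij} along one dimension.
// E[i][j][t], i<=imax, j<=jmax, t<=i+j
struct Etab {
  int imax, jmax;
  std::vector<double> v;
  double& at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

Etab build_E(int imax, int jmax, double a, double b, double AB) {
  Etab E;
  E.imax = imax; E.jmax = jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (imax + jmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  double PA = -b / p * AB; // P - A where AB = A - B
  double PB = a / p * AB;  // P - B
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      if (j == 0) {
        for (int t = 0; t <= i + j; ++t)
          E.at(i, j, t) = 1.0 / (2.0 * p) * E.get(i - 1, j, t - 1)
                        + PA * E.get(i - 1, j, t)
                        + (t + 1) * E.get(i - 1, j, t + 1);
      } else {
        for (int t = 0; t <= i + j; ++t)
          E.at(i, j, t) = 1.0 / (2.0 * p) * E.get(i, j - 1, t - 1)
                        + PB * E.get(i, j - 1, t)
                        + (t + 1) * E.get(i, j - 1, t + 1);
      }
    }
  }
  return E;
}

// Hermite Coulomb integrals R_{tuv} (n=0) via recursion
struct Rtab {
  int tmax;
  std::vector<double> v;
  double& at(int t, int u, int w) {
    return v[(t * (tmax + 1) + u) * (tmax + 1) + w];
  }
  double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (tmax + 1) + u) * (tmax + 1) + w];
  }
};

Rtab build_R(int tmax, double p, const arma::vec3& PC) {
  // R^n auxiliary: iterate n from high to low
  double T = p * arma::dot(PC, PC);
  std::vector<double> F(tmax + 1);
  boys(tmax, T, F.data());
  // R^n_{tuv} stored per n in maps; use dense (tmax+1)^3 per n
  int dim = (tmax + 1) * (tmax + 1) * (tmax + 1);
  std::vector<std::vector<double>> Rn(tmax + 1, std::vector<double>(dim, 0.0));
  auto idx = [tmax](int t, int u, int w) {
    return (t * (tmax + 1) + u) * (tmax + 1) + w;
  };
  for (int n = 0; n <= tmax; ++n) {
    double f = std::pow(-2.0 * p, n);
    Rn[n][idx(0, 0, 0)] = f * F[n];
  }
  // build up total order L = t+u+v from 1..tmax
  for (int L = 1; L <= tmax; ++L) {
    for (int n = 0; n <= tmax - L; ++n) {
      for (int t = 0; t <= L; ++t)
        for (int u = 0; u <= L - t; ++u) {
          int w = L - t - u;
          double val = 0.0;
          if (t > 0) {
            val = PC(0) * Rn[n + 1][idx(t - 1, u, w)];
            if (t > 1) val += (t - 1) * Rn[n + 1][idx(t - 2, u, w)];
          } else if (u > 0) {
            val = PC(1) * Rn[n + 1][idx(t, u - 1, w)];
            if (u > 1) val += (u - 1) * Rn[n + 1][idx(t, u - 2, w)];
          } else {
            val = PC(2) * Rn[n + 1][idx(t, u, w - 1)];
            if (w > 1) val += (w - 1) * Rn[n + 1][idx(t, u, w - 2)];
          }
          Rn[n][idx(t, u, w)] = val;
        }
    }
  }
  Rtab R;
  R.tmax = tmax;
  R.v = Rn[0];
  return R;
}

std::vector<Shell> parse_shells(const List& shells) {
  std::vector<Shell> out;
  for (int i = 0; i < shells.size(); ++i) {
    List s = shells[i];
    Shell sh;
    sh.l = as<int>(s["l"]);
    sh.atom = as<int>(s["atom"]);
    NumericVector R = s["center"];
    sh.R = {R[0], R[1], R[2]};
    NumericVector e = s["exp"], c = s["coef"];
    sh.exps.assign(e.begin(), e.end());
    sh.coefs.assign(c.begin(), c.end());
    out.push_back(sh);
  }
  return out;
}

// 1D overlap from E table: S_ij = E_0 * sqrt(pi/p)
// cartesian overlap/kinetic block between two shells (contracted)
void one_electron_block(const Shell& A, const Shell& B,
                        arma::mat& Sblk, arma::mat& Tblk) {
  int na = A.ncart(), nb = B.ncart();
  Sblk.zeros(na, nb);
  Tblk.zeros(na, nb);
  int la = A.l, lb = B.l;
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double a = A.exps[ia], b = B.exps[ib];
      double cc = A.coefs[ia] * B.coefs[ib];
      double p = a + b;
      double fac = std::pow(PI / p, 1.5);
      // need up to j+2 for kinetic
      Etab Ex = build_E(la, lb + 2, a, b, A.R(0) - B.R(0));
      Etab Ey = build_E(la, lb + 2, a, b, A.R(1) - B.R(1));
      Etab Ez = build_E(la, lb + 2, a, b, A.R(2) - B.R(2));
      for (int ka = 0; ka < na; ++ka) {
        int ea[3]; cart_comp(la, ka, ea);
        for (int kb = 0; kb < nb; ++kb) {
          int eb[3]; cart_comp(lb, kb, eb);
          double Sx = Ex.get(ea[0], eb[0], 0);
          double Sy = Ey.get(ea[1], eb[1], 0);
          double Sz = Ez.get(ea[2], eb[2], 0);
          Sblk(ka, kb) += cc * fac * Sx * Sy * Sz;
          // 1D kinetic: T_ij = -0.5*[ j(j-1) S_{i,j-2} - 2b(2j+1) S_{i,j}
          //                           + 4b^2 S_{i,j+2} ]
          auto t1d = [&](const Etab& E, int i, int j) {
            double s2m = (j >= 2) ? E.get(i, j - 2, 0) : 0.0;
            double s0 = E.get(i, j, 0);
            double s2p = E.get(i, j + 2, 0);
            return -0.5 * (j * (j - 1) * s2m - 2.0 * b * (2 * j + 1) * s0
                           + 4.0 * b * b * s2p);
          };
          double Tx = t1d(Ex, ea[0], eb[0]);
          double Ty = t1d(Ey, ea[1], eb[1]);
          double Tz = t1d(Ez, ea[2], eb[2]);
          Tblk(ka, kb) += cc * fac * (Tx * Sy * Sz + Sx * Ty * Sz + Sx * Sy * Tz);
        }
      }
    }
}

void nuclear_block(const Shell& A, const Shell& B,
                   const arma::mat& atomR, const arma::vec& Z,
                   arma::mat& Vblk) {
  int na = A.ncart(), nb = B.ncart();
  Vblk.zeros(na, nb);
  int la = A.l, lb = B.l;
  int ltot = la + lb;
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double a = A.exps[ia], b = B.exps[ib];
      double cc = A.coefs[ia] * B.coefs[ib];
      double p = a + b;
      arma::vec3 P = (a * A.R + b * B.R) / p;
      Etab Ex = build_E(la, lb, a, b, A.R(0) - B.R(0));
      Etab Ey = build_E(la, lb, a, b, A.R(1) - B.R(1));
      Etab Ez = build_E(la, lb, a, b, A.R(2) - B.R(2));
      for (arma::uword ic = 0; ic < Z.n_elem; ++ic) {
        arma::vec3 C = atomR.col(ic);
        Rtab R = build_R(ltot, p, P - C);
        double pref = -Z(ic) * 2.0 * PI / p * cc;
        for (int ka = 0; ka < na; ++ka) {
          int ea[3]; cart_comp(la, ka, ea);
          for (int kb = 0; kb < nb; ++kb) {
            int eb[3]; cart_comp(lb, kb, eb);
            double val = 0.0;
            for (int t = 0; t <= ea[0] + eb[0]; ++t)
              for (int u = 0; u <= ea[1] + eb[1]; ++u)
                for (int w = 0; w <= ea[2] + eb[2]; ++w)
                  val += Ex.get(ea[0], eb[0], t) * Ey.get(ea[1], eb[1], u)
                       * Ez.get(ea[2], eb[2], w) * R.get(t, u, w);
            Vblk(ka, kb) += pref * val;
          }
        }
      }
    }
}

} // namespace

// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List shells, arma::mat atom_coords, arma::vec Z) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int i = 0; i < nsh; ++i) off[i + 1] = off[i] + sh[i].nsph();
  int nao = off[nsh];
  arma::mat S(nao, nao, arma::fill::zeros);
  arma::mat T(nao, nao, arma::fill::zeros);
  arma::mat V(nao, nao, arma::fill::zeros);
  arma::mat atR = atom_coords.t(); // 3 x natom
  for (int i = 0; i < nsh; ++i) {
    arma::mat Ti = sph_transform(sh[i].l);
    for (int j = 0; j <= i; ++j) {
      arma::mat Tj = sph_transform(sh[j].l);
      arma::mat Sb, Tb, Vb;
      one_electron_block(sh[i], sh[j], Sb, Tb);
      nuclear_block(sh[i], sh[j], atR, Z, Vb);
      arma::mat Ss = Ti * Sb * Tj.t();
      arma::mat Ts = Ti * Tb * Tj.t();
      arma::mat Vs = Ti * Vb * Tj.t();
      S.submat(off[i], off[j], off[i + 1] - 1, off[j + 1] - 1) = Ss;
      T.submat(off[i], off[j], off[i + 1] - 1, off[j + 1] - 1) = Ts;
      V.submat(off[i], off[j], off[i + 1] - 1, off[j + 1] - 1) = Vs;
      if (i != j) {
        S.submat(off[j], off[i], off[j + 1] - 1, off[i + 1] - 1) = Ss.t();
        T.submat(off[j], off[i], off[j + 1] - 1, off[i + 1] - 1) = Ts.t();
        V.submat(off[j], off[i], off[j + 1] - 1, off[i + 1] - 1) = Vs.t();
      }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

namespace {

// contracted cartesian ERI block for shell quartet (A B | C D)
void eri_block(const Shell& A, const Shell& B, const Shell& C, const Shell& D,
               arma::vec& out) {
  int na = A.ncart(), nb = B.ncart(), nc = C.ncart(), nd = D.ncart();
  out.zeros(na * nb * nc * nd);
  int la = A.l, lb = B.l, lc = C.l, ld = D.l;
  int ltot = la + lb + lc + ld;
  for (size_t ia = 0; ia < A.exps.size(); ++ia)
    for (size_t ib = 0; ib < B.exps.size(); ++ib) {
      double a = A.exps[ia], b = B.exps[ib];
      double p = a + b;
      arma::vec3 P = (a * A.R + b * B.R) / p;
      double ccab = A.coefs[ia] * B.coefs[ib];
      double mu_ab = a * b / p;
      double ab2 = arma::dot(A.R - B.R, A.R - B.R);
      if (std::exp(-mu_ab * ab2) < 1e-16) continue;
      Etab Exab = build_E(la, lb, a, b, A.R(0) - B.R(0));
      Etab Eyab = build_E(la, lb, a, b, A.R(1) - B.R(1));
      Etab Ezab = build_E(la, lb, a, b, A.R(2) - B.R(2));
      for (size_t ic = 0; ic < C.exps.size(); ++ic)
        for (size_t id = 0; id < D.exps.size(); ++id) {
          double c = C.exps[ic], d = D.exps[id];
          double q = c + d;
          arma::vec3 Q = (c * C.R + d * D.R) / q;
          double cc = ccab * C.coefs[ic] * D.coefs[id];
          double mu_cd = c * d / q;
          double cd2 = arma::dot(C.R - D.R, C.R - D.R);
          if (std::exp(-mu_cd * cd2) < 1e-16) continue;
          Etab Excd = build_E(lc, ld, c, d, C.R(0) - D.R(0));
          Etab Eycd = build_E(lc, ld, c, d, C.R(1) - D.R(1));
          Etab Ezcd = build_E(lc, ld, c, d, C.R(2) - D.R(2));
          double alpha = p * q / (p + q);
          Rtab R = build_R(ltot, alpha, P - Q);
          double pref = 2.0 * std::pow(PI, 2.5)
                        / (p * q * std::sqrt(p + q)) * cc;
          int pos = 0;
          for (int ka = 0; ka < na; ++ka) {
            int ea[3]; cart_comp(la, ka, ea);
            for (int kb = 0; kb < nb; ++kb) {
              int eb[3]; cart_comp(lb, kb, eb);
              for (int kc = 0; kc < nc; ++kc) {
                int ec[3]; cart_comp(lc, kc, ec);
                for (int kd = 0; kd < nd; ++kd, ++pos) {
                  int ed[3]; cart_comp(ld, kd, ed);
                  double val = 0.0;
                  for (int t = 0; t <= ea[0] + eb[0]; ++t) {
                    double ext = Exab.get(ea[0], eb[0], t);
                    if (ext == 0.0) continue;
                    for (int u = 0; u <= ea[1] + eb[1]; ++u) {
                      double eyu = Eyab.get(ea[1], eb[1], u);
                      if (eyu == 0.0) continue;
                      for (int w = 0; w <= ea[2] + eb[2]; ++w) {
                        double ezw = Ezab.get(ea[2], eb[2], w);
                        if (ezw == 0.0) continue;
                        double inner = 0.0;
                        for (int tt = 0; tt <= ec[0] + ed[0]; ++tt) {
                          double e2 = Excd.get(ec[0], ed[0], tt);
                          if (e2 == 0.0) continue;
                          for (int uu = 0; uu <= ec[1] + ed[1]; ++uu) {
                            double e3 = Eycd.get(ec[1], ed[1], uu);
                            if (e3 == 0.0) continue;
                            for (int ww = 0; ww <= ec[2] + ed[2]; ++ww) {
                              double e4 = Ezcd.get(ec[2], ed[2], ww);
                              if (e4 == 0.0) continue;
                              double sgn = ((tt + uu + ww) % 2) ? -1.0 : 1.0;
                              inner += sgn * e2 * e3 * e4
                                       * R.get(t + tt, u + uu, w + ww);
                            }
                          }
                        }
                        val += ext * eyu * ezw * inner;
                      }
                    }
                  }
                  out(pos) += pref * val;
                }
              }
            }
          }
        }
    }
}

arma::mat eri_block_sph(const Shell& A, const Shell& B,
                        const Shell& C, const Shell& D) {
  arma::vec blk;
  eri_block(A, B, C, D, blk);
  int na = A.ncart(), nb = B.ncart(), nc = C.ncart(), nd = D.ncart();
  // transform: result dims (sphA*sphB) x (sphC*sphD)
  arma::mat Ta = sph_transform(A.l), Tb = sph_transform(B.l);
  arma::mat Tc = sph_transform(C.l), Td = sph_transform(D.l);
  // view as (na*nb) x (nc*nd): index pos = ((ka*nb+kb)*nc+kc)*nd+kd
  arma::mat M(nc * nd, na * nb);
  for (int ka = 0; ka < na; ++ka)
    for (int kb = 0; kb < nb; ++kb)
      for (int kc = 0; kc < nc; ++kc)
        for (int kd = 0; kd < nd; ++kd)
          M(kc * nd + kd, ka * nb + kb) =
            blk(((ka * nb + kb) * nc + kc) * nd + kd);
  // transform cd side: rows (cart c,d) -> (sph c,d)
  arma::mat Tcd = arma::kron(Tc, Td);
  arma::mat Tab = arma::kron(Ta, Tb);
  arma::mat out = Tcd * M * Tab.t(); // (sphc*sphd) x (spha*sphb)
  return out;
}

} // namespace

// Full ERI tensor in chemist notation (pq|rs), returned as a flat vector
// with column-major-compatible index p + q*n + r*n^2 + s*n^3 (0-based).
// [[Rcpp::export(name = ".cpp_eri")]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int i = 0; i < nsh; ++i) off[i + 1] = off[i] + sh[i].nsph();
  size_t nao = off[nsh];
  NumericVector out(nao * nao * nao * nao);
  double* O = out.begin();
  // Schwarz diagonal per shell pair
  int npair = nsh * (nsh + 1) / 2;
  std::vector<double> schwarz(npair, 0.0);
  auto pidx = [](int i, int j) { return i * (i + 1) / 2 + j; }; // i >= j
  for (int i = 0; i < nsh; ++i)
    for (int j = 0; j <= i; ++j) {
      arma::vec blk;
      eri_block(sh[i], sh[j], sh[i], sh[j], blk);
      schwarz[pidx(i, j)] = std::sqrt(std::abs(blk.max()));
    }
  auto put = [&](size_t p, size_t q, size_t r, size_t s, double v) {
    O[p + nao * (q + nao * (r + nao * s))] = v;
    O[q + nao * (p + nao * (r + nao * s))] = v;
    O[p + nao * (q + nao * (s + nao * r))] = v;
    O[q + nao * (p + nao * (s + nao * r))] = v;
    O[r + nao * (s + nao * (p + nao * q))] = v;
    O[s + nao * (r + nao * (p + nao * q))] = v;
    O[r + nao * (s + nao * (q + nao * p))] = v;
    O[s + nao * (r + nao * (q + nao * p))] = v;
  };
  for (int i = 0; i < nsh; ++i)
    for (int j = 0; j <= i; ++j) {
      double sij = schwarz[pidx(i, j)];
      for (int k = 0; k <= i; ++k) {
        int lmax = (k == i) ? j : k;
        for (int l = 0; l <= lmax; ++l) {
          if (sij * schwarz[pidx(k, l)] < 1e-14) continue;
          arma::mat blk = eri_block_sph(sh[i], sh[j], sh[k], sh[l]);
          int ni = sh[i].nsph(), nj = sh[j].nsph();
          int nk = sh[k].nsph(), nl = sh[l].nsph();
          for (int a = 0; a < ni; ++a)
            for (int b = 0; b < nj; ++b)
              for (int c = 0; c < nk; ++c)
                for (int d = 0; d < nl; ++d)
                  put(off[i] + a, off[j] + b, off[k] + c, off[l] + d,
                      blk(c * nl + d, a * nj + b));
        }
      }
    }
  return out;
}

// AO values (and gradients) on a set of grid points.
// Returns list: ao (npts x nao), dx, dy, dz.
// [[Rcpp::export(name = ".cpp_eval_ao")]]
List cpp_eval_ao(List shells, arma::mat pts, bool deriv) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size();
  std::vector<int> off(nsh + 1, 0);
  for (int i = 0; i < nsh; ++i) off[i + 1] = off[i] + sh[i].nsph();
  int nao = off[nsh];
  int npt = pts.n_rows;
  arma::mat AO(npt, nao, arma::fill::zeros);
  arma::mat DX, DY, DZ;
  if (deriv) {
    DX.zeros(npt, nao); DY.zeros(npt, nao); DZ.zeros(npt, nao);
  }
  for (int is = 0; is < nsh; ++is) {
    const Shell& s = sh[is];
    int nc = s.ncart();
    arma::mat Tsph = sph_transform(s.l);
    arma::vec cart(nc), dcx(nc), dcy(nc), dcz(nc);
    for (int ip = 0; ip < npt; ++ip) {
      double x = pts(ip, 0) - s.R(0);
      double y = pts(ip, 1) - s.R(1);
      double z = pts(ip, 2) - s.R(2);
      double r2 = x * x + y * y + z * z;
      double g = 0.0, dg = 0.0; // radial contracted value, d/dr2 factor
      for (size_t ipr = 0; ipr < s.exps.size(); ++ipr) {
        double e = std::exp(-s.exps[ipr] * r2) * s.coefs[ipr];
        g += e;
        dg += -2.0 * s.exps[ipr] * e;
      }
      cart.zeros(); dcx.zeros(); dcy.zeros(); dcz.zeros();
      for (int k = 0; k < nc; ++k) {
        int e[3]; cart_comp(s.l, k, e);
        double px = std::pow(x, e[0]), py = std::pow(y, e[1]),
               pz = std::pow(z, e[2]);
        double poly = px * py * pz;
        cart(k) = poly * g;
        if (deriv) {
          double dpx = (e[0] > 0) ? e[0] * std::pow(x, e[0] - 1) : 0.0;
          double dpy = (e[1] > 0) ? e[1] * std::pow(y, e[1] - 1) : 0.0;
          double dpz = (e[2] > 0) ? e[2] * std::pow(z, e[2] - 1) : 0.0;
          dcx(k) = dpx * py * pz * g + poly * dg * x;
          dcy(k) = px * dpy * pz * g + poly * dg * y;
          dcz(k) = px * py * dpz * g + poly * dg * z;
        }
      }
      arma::vec sph = Tsph * cart;
      for (int m = 0; m < s.nsph(); ++m) AO(ip, off[is] + m) = sph(m);
      if (deriv) {
        arma::vec sx = Tsph * dcx, sy = Tsph * dcy, sz = Tsph * dcz;
        for (int m = 0; m < s.nsph(); ++m) {
          DX(ip, off[is] + m) = sx(m);
          DY(ip, off[is] + m) = sy(m);
          DZ(ip, off[is] + m) = sz(m);
        }
      }
    }
  }
  if (deriv)
    return List::create(_["ao"] = AO, _["dx"] = DX, _["dy"] = DY,
                        _["dz"] = DZ);
  return List::create(_["ao"] = AO);
}
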