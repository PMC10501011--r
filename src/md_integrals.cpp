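// McMurchie-Davidson Gaussian integrals over contracted Cartesian shells
// (s and p are what the package uses; the recurrences are general in l).
// Produces the one-electron matrices S, T, V and the full two-electron
// integral matrix in chemists' notation, (mu nu | la si), stored as a
// K^2 x K^2 matrix with composite row index (mu-1)*K + nu (column-major
// friendly for the R side's kronecker-based MO transform).
//
// Everything is in atomic units (bohr, hartree).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- Boys function --------------------------------------------------------

// F_n(T) for n = 0..nmax by downward recursion; series for moderate T,
// asymptotic + upward for large T (stable there).
static void boys(double T, int nmax, std::vector<double>& F) {
  F.assign(nmax + 1, 0.0);
  if (T < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (T < 35.0) {
    // series for F_nmax: e^{-T} sum_k (2T)^k (2n-1)!! / (2n+2k+1)!!
    double expT = std::exp(-T);
    double num = 1.0;
    double den = 2.0 * nmax + 1.0;
    double sum = 1.0 / den;
    for (int k = 1; k < 200; ++k) {
      num *= 2.0 * T;
      den *= (2.0 * nmax + 2.0 * k + 1.0);
      double term = num / den;
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    F[nmax] = expT * sum;
    for (int n = nmax; n > 0; --n)
      F[n - 1] = (2.0 * T * F[n] + expT) / (2.0 * n - 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double expT = std::exp(-T);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - expT) / (2.0 * T);
  }
}

// ---- Hermite expansion coefficients ---------------------------------------

// E_t^{i,j} along one dimension for exponents a, b with A-B separation AB.
// Filled into E[i][j][t]; t ranges 0..i+j.
struct EArr {
  int imax, jmax;
  std::vector<double> v;
  EArr(int i, int j) : imax(i), jmax(j), v((i + 1) * (j + 1) * (i + j + 1), 0.0) {}
  double& at(int i, int j, int t) {
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (imax + jmax + 1) + t];
  }
};

static void hermite_E(int imax, int jmax, double a, double b, double AB,
                      EArr& E) {
  double p = a + b;
  double mu = a * b / p;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double PA = -b * AB / p;  // P - A with AB = A - B
  double PB = a * AB / p;   // P - B
  for (int i = 0; i <= imax; ++i) {
    for (int j = 0; j <= jmax; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val;
        if (i > 0) {
          val = (1.0 / (2.0 * p)) * E.get(i - 1, j, t - 1)
              + PA * E.get(i - 1, j, t)
              + (t + 1.0) * E.get(i - 1, j, t + 1);
        } else {
          val = (1.0 / (2.0 * p)) * E.get(i, j - 1, t - 1)
              + PB * E.get(i, j - 1, t)
              + (t + 1.0) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// ---- Hermite Coulomb auxiliary R_{tuv} ------------------------------------

struct RArr {
  int tmax;
  std::vector<double> v;
  RArr(int t) : tmax(t), v((t + 1) * (t + 1) * (t + 1), 0.0) {}
  double& at(int t, int u, int w) {
    return v[(t * (tmax + 1) + u) * (tmax + 1) + w];
  }
};

// R^0_{tuv}(p, PC) for all t+u+v <= tmax
static void hermite_R(int tmax, double p, double X, double Y, double Z,
                      RArr& R) {
  double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F;
  boys(T, tmax, F);
  // Rn[t][u][v] at auxiliary order n, built downward in n
  int d = tmax + 1;
  std::vector<double> cur(d * d * d, 0.0), nxt(d * d * d, 0.0);
  auto idx = [d](int t, int u, int v) { return (t * d + u) * d + v; };
  for (int n = tmax; n >= 0; --n) {
    // start from R^n_{000}
    std::fill(nxt.begin(), nxt.end(), 0.0);
    nxt[idx(0, 0, 0)] = std::pow(-2.0 * p, n) * F[n];
    // cur holds order n+1 values from the previous iteration
    for (int t = 0; t <= tmax - n; ++t)
      for (int u = 0; u <= tmax - n - t; ++u)
        for (int v = 0; v <= tmax - n - t - u; ++v) {
          if (t + u + v == 0) continue;
          double val;
          if (t > 0) {
            val = X * cur[idx(t - 1, u, v)]
                + (t > 1 ? (t - 1) * cur[idx(t - 2, u, v)] : 0.0);
          } else if (u > 0) {
            val = Y * cur[idx(t, u - 1, v)]
                + (u > 1 ? (u - 1) * cur[idx(t, u - 2, v)] : 0.0);
          } else {
            val = Z * cur[idx(t, u, v - 1)]
                + (v > 1 ? (v - 1) * cur[idx(t, u, v - 2)] : 0.0);
          }
          nxt[idx(t, u, v)] = val;
        }
    std::swap(cur, nxt);
  }
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= tmax - t; ++u)
      for (int v = 0; v <= tmax - t - u; ++v)
        R.at(t, u, v) = cur[idx(t, u, v)];
}

// ---- basis bookkeeping ----------------------------------------------------

struct Prim {
  double exp, coef;  // coef includes primitive normalization
};

struct CFunc {              // one contracted Cartesian function
  double cx, cy, cz;        // center, bohr
  int lx, ly, lz;
  std::vector<Prim> prims;  // coef includes overall contraction normalization
};

static double dfact(int n) {  // (2n-1)!! with n>=0 -> 1,1,3,15,...
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

// primitive Cartesian normalization
static double prim_norm(double a, int lx, int ly, int lz) {
  int l = lx + ly + lz;
  double num = std::pow(2.0 * a / M_PI, 0.75) * std::pow(4.0 * a, 0.5 * l);
  return num / std::sqrt(dfact(lx) * dfact(ly) * dfact(lz));
}

// primitive overlap between two Cartesian Gaussians
static double prim_overlap(const CFunc& A, int ia, const CFunc& B, int ib) {
  double a = A.prims[ia].exp, b = B.prims[ib].exp;
  double p = a + b;
  EArr Ex(A.lx, B.lx), Ey(A.ly, B.ly), Ez(A.lz, B.lz);
  hermite_E(A.lx, B.lx, a, b, A.cx - B.cx, Ex);
  hermite_E(A.ly, B.ly, a, b, A.cy - B.cy, Ey);
  hermite_E(A.lz, B.lz, a, b, A.cz - B.cz, Ez);
  return Ex.get(A.lx, B.lx, 0) * Ey.get(A.ly, B.ly, 0) *
         Ez.get(A.lz, B.lz, 0) * std::pow(M_PI / p, 1.5);
}

static double contr_overlap(const CFunc& A, const CFunc& B) {
  double s = 0.0;
  for (size_t i = 0; i < A.prims.size(); ++i)
    for (size_t j = 0; j < B.prims.size(); ++j)
      s += A.prims[i].coef * B.prims[j].coef * prim_overlap(A, i, B, j);
  return s;
}

// kinetic energy via raised/lowered overlaps on the ket
static double prim_kinetic(const CFunc& A, int ia, const CFunc& B, int ib) {
  double b = B.prims[ib].exp;
  CFunc B2 = B;
  double term = b * (2.0 * (B.lx + B.ly + B.lz) + 3.0) * prim_overlap(A, ia, B, ib);
  // -2 b^2 (l+2) overlaps
  int shift[3][3] = {{2, 0, 0}, {0, 2, 0}, {0, 0, 2}};
  int lb[3] = {B.lx, B.ly, B.lz};
  for (int d = 0; d < 3; ++d) {
    B2.lx = B.lx + shift[d][0];
    B2.ly = B.ly + shift[d][1];
    B2.lz = B.lz + shift[d][2];
    term -= 2.0 * b * b * prim_overlap(A, ia, B2, ib);
    if (lb[d] >= 2) {
      B2.lx = B.lx - shift[d][0];
      B2.ly = B.ly - shift[d][1];
      B2.lz = B.lz - shift[d][2];
      term -= 0.5 * lb[d] * (lb[d] - 1) * prim_overlap(A, ia, B2, ib);
    }
  }
  return term;
}

// nuclear attraction of one primitive pair to all nuclei
static double prim_nuclear(const CFunc& A, int ia, const CFunc& B, int ib,
                           const NumericMatrix& coords,
                           const IntegerVector& Z) {
  double a = A.prims[ia].exp, b = B.prims[ib].exp;
  double p = a + b;
  double Px = (a * A.cx + b * B.cx) / p;
  double Py = (a * A.cy + b * B.cy) / p;
  double Pz = (a * A.cz + b * B.cz) / p;
  int tmax = A.lx + A.ly + A.lz + B.lx + B.ly + B.lz;
  EArr Ex(A.lx, B.lx), Ey(A.ly, B.ly), Ez(A.lz, B.lz);
  hermite_E(A.lx, B.lx, a, b, A.cx - B.cx, Ex);
  hermite_E(A.ly, B.ly, a, b, A.cy - B.cy, Ey);
  hermite_E(A.lz, B.lz, a, b, A.cz - B.cz, Ez);
  double v = 0.0;
  RArr R(tmax);
  for (int c = 0; c < coords.nrow(); ++c) {
    if (Z[c] == 0) continue;
    hermite_R(tmax, p, Px - coords(c, 0), Py - coords(c, 1),
              Pz - coords(c, 2), R);
    double s = 0.0;
    for (int t = 0; t <= A.lx + B.lx; ++t)
      for (int u = 0; u <= A.ly + B.ly; ++u)
        for (int w = 0; w <= A.lz + B.lz; ++w)
          s += Ex.get(A.lx, B.lx, t) * Ey.get(A.ly, B.ly, u) *
               Ez.get(A.lz, B.lz, w) * R.at(t, u, w);
    v -= Z[c] * (2.0 * M_PI / p) * s;
  }
  return v;
}

// precomputed Hermite data for one primitive pair of a contracted pair:
// combined coefficient, total exponent, product center, and the nonzero
// Hermite expansion products e1(t,u,v)
struct PrimPair {
  double coef, p, Px, Py, Pz;
  int tmax[3];
  std::vector<double> E;  // E[(t*(u1+1)+u)*(v1+1)+v]
  double e(int t, int u, int v) const {
    return E[(t * (tmax[1] + 1) + u) * (tmax[2] + 1) + v];
  }
};

static std::vector<PrimPair> pair_data(const CFunc& A, const CFunc& B) {
  std::vector<PrimPair> out;
  int t1 = A.lx + B.lx, u1 = A.ly + B.ly, v1 = A.lz + B.lz;
  for (size_t i = 0; i < A.prims.size(); ++i)
    for (size_t j = 0; j < B.prims.size(); ++j) {
      double a = A.prims[i].exp, b = B.prims[j].exp;
      PrimPair pp;
      pp.coef = A.prims[i].coef * B.prims[j].coef;
      pp.p = a + b;
      pp.Px = (a * A.cx + b * B.cx) / pp.p;
      pp.Py = (a * A.cy + b * B.cy) / pp.p;
      pp.Pz = (a * A.cz + b * B.cz) / pp.p;
      pp.tmax[0] = t1; pp.tmax[1] = u1; pp.tmax[2] = v1;
      EArr Ex(A.lx, B.lx), Ey(A.ly, B.ly), Ez(A.lz, B.lz);
      hermite_E(A.lx, B.lx, a, b, A.cx - B.cx, Ex);
      hermite_E(A.ly, B.ly, a, b, A.cy - B.cy, Ey);
      hermite_E(A.lz, B.lz, a, b, A.cz - B.cz, Ez);
      pp.E.assign((t1 + 1) * (u1 + 1) * (v1 + 1), 0.0);
      for (int t = 0; t <= t1; ++t)
        for (int u = 0; u <= u1; ++u)
          for (int v = 0; v <= v1; ++v)
            pp.E[(t * (u1 + 1) + u) * (v1 + 1) + v] =
              Ex.get(A.lx, B.lx, t) * Ey.get(A.ly, B.ly, u) *
              Ez.get(A.lz, B.lz, v);
      out.push_back(std::move(pp));
    }
  return out;
}

// contracted ERI (ab|cd) from precomputed primitive-pair data
static double contr_eri_pp(const std::vector<PrimPair>& bra,
                           const std::vector<PrimPair>& ket) {
  double s = 0.0;
  for (const auto& b : bra)
    for (const auto& k : ket) {
      double theta = b.p * k.p / (b.p + k.p);
      int tmax = b.tmax[0] + b.tmax[1] + b.tmax[2] +
                 k.tmax[0] + k.tmax[1] + k.tmax[2];
      RArr R(tmax);
      hermite_R(tmax, theta, b.Px - k.Px, b.Py - k.Py, b.Pz - k.Pz, R);
      double acc = 0.0;
      for (int t = 0; t <= b.tmax[0]; ++t)
        for (int u = 0; u <= b.tmax[1]; ++u)
          for (int v = 0; v <= b.tmax[2]; ++v) {
            double e1 = b.e(t, u, v);
            if (e1 == 0.0) continue;
            for (int tt = 0; tt <= k.tmax[0]; ++tt)
              for (int uu = 0; uu <= k.tmax[1]; ++uu)
                for (int vv = 0; vv <= k.tmax[2]; ++vv) {
                  double e2 = k.e(tt, uu, vv);
                  if (e2 == 0.0) continue;
                  double sign = ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
                  acc += e1 * e2 * sign * R.at(t + tt, u + uu, v + vv);
                }
          }
      s += b.coef * k.coef * acc * 2.0 * std::pow(M_PI, 2.5) /
           (b.p * k.p * std::sqrt(b.p + k.p));
    }
  return s;
}

// ---- entry point ----------------------------------------------------------

// coords: n_atoms x 3 (bohr); Z: nuclear charges; shells: list of
// list(atom = 1-based index, l = 0/1/.., exps, coefs)
// [[Rcpp::export]]
List cpp_md_integrals(NumericMatrix coords, IntegerVector Z, List shells,
                      bool want_eri = true) {
  std::vector<CFunc> fns;
  for (int s = 0; s < shells.size(); ++s) {
    List sh = shells[s];
    int atom = as<int>(sh["atom"]) - 1;
    int l = as<int>(sh["l"]);
    NumericVector ex = sh["exps"], cf = sh["coefs"];
    // all Cartesian components of this shell
    for (int lx = l; lx >= 0; --lx)
      for (int ly = l - lx; ly >= 0; --ly) {
        int lz = l - lx - ly;
        CFunc f;
        f.cx = coords(atom, 0); f.cy = coords(atom, 1); f.cz = coords(atom, 2);
        f.lx = lx; f.ly = ly; f.lz = lz;
        for (int p = 0; p < ex.size(); ++p) {
          Prim pr;
          pr.exp = ex[p];
          pr.coef = cf[p] * prim_norm(ex[p], lx, ly, lz);
          f.prims.push_back(pr);
        }
        // normalize the contracted function
        double nrm = contr_overlap(f, f);
        for (auto& pr : f.prims) pr.coef /= std::sqrt(nrm);
        fns.push_back(f);
      }
  }
  int K = fns.size();
  NumericMatrix S(K, K), T(K, K), V(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = i; j < K; ++j) {
      double s = 0.0, t = 0.0, v = 0.0;
      for (size_t pi = 0; pi < fns[i].prims.size(); ++pi)
        for (size_t pj = 0; pj < fns[j].prims.size(); ++pj) {
          double cc = fns[i].prims[pi].coef * fns[j].prims[pj].coef;
          s += cc * prim_overlap(fns[i], pi, fns[j], pj);
          t += cc * prim_kinetic(fns[i], pi, fns[j], pj);
          v += cc * prim_nuclear(fns[i], pi, fns[j], pj, coords, Z);
        }
      S(i, j) = S(j, i) = s;
      T(i, j) = T(j, i) = t;
      V(i, j) = V(j, i) = v;
    }
  List out = List::create(Named("S") = S, Named("T") = T, Named("V") = V,
                          Named("K") = K);
  if (want_eri) {
    NumericMatrix ERI(K * K, K * K);
    // Hermite pair data once per unique function pair
    std::vector<std::vector<PrimPair>> pd(K * (K + 1) / 2);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j <= i; ++j)
        pd[i * (i + 1) / 2 + j] = pair_data(fns[i], fns[j]);
    // unique (ij), (kl) pairs with 8-fold symmetry
    for (int i = 0; i < K; ++i)
      for (int j = 0; j <= i; ++j) {
        int ij = i * (i + 1) / 2 + j;
        for (int k = 0; k < K; ++k)
          for (int l = 0; l <= k; ++l) {
            int kl = k * (k + 1) / 2 + l;
            if (kl > ij) continue;
            double e = contr_eri_pp(pd[ij], pd[kl]);
            // composite row index (mu)*K + nu (0-based) for (mu nu | la si)
            int perm[8][4] = {{i, j, k, l}, {j, i, k, l}, {i, j, l, k},
                              {j, i, l, k}, {k, l, i, j}, {l, k, i, j},
                              {k, l, j, i}, {l, k, j, i}};
            for (int p = 0; p < 8; ++p) {
              int mu = perm[p][0], nu = perm[p][1], la = perm[p][2],
                  si = perm[p][3];
              ERI(mu * K + nu, la * K + si) = e;
            }
          }
      }
    out["ERI"] = ERI;
  }
  return out;
}
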