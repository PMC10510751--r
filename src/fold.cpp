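// Partition-function and minimum-free-energy dynamic programming for the
// nearest-neighbor model over the six-letter alphabet. The energy model must
// stay in lock-step with the R reference evaluator (fold_energy); both are
// documented in R/fold.R.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF_E = 1e30;

struct Tables {
  const double *stackE;   // [x1 + 6*(x2 + 6*(y1 + 6*y2))], top x1x2 / bottom y1y2
  const double *tmm;      // [X + 6*(Y + 6*(a + 6*b))]
  const double *d5;       // [X + 6*(Y + 6*b)]
  const double *d3;
  const double *pen;      // [X + 6*Y]
  const int *allowed;     // [X + 6*Y]
  const double *int11;    // [x1,y1,x2,y2,a,b] column-major base 6
  const double *int21;    // [x1,y1,x2,y2,a1,a2,b]
  const double *int22;    // [x1,y1,x2,y2,a1,a2,b1,b2]
  const double *hp_init;  // hp_init[sz-1], pre-extended to sequence length
  const double *bulge_init;
  const double *intl_init;
  double mb_a, mb_b, mb_c;
  double RT;
  int max_loop, min_hairpin, hp_len;
};

static inline int i2(int a, int b) { return a + 6 * b; }
static inline int i3(int a, int b, int c) { return a + 6 * (b + 6 * c); }
static inline int i4(int a, int b, int c, int d) {
  return a + 6 * (b + 6 * (c + 6 * d));
}
static inline long i6(int a, int b, int c, int d, int e, int f) {
  return a + 6L * (b + 6L * (c + 6L * (d + 6L * (e + 6L * f))));
}
static inline long i7(int a, int b, int c, int d, int e, int f, int g) {
  return a + 6L * (b + 6L * (c + 6L * (d + 6L * (e + 6L * (f + 6L * g)))));
}
static inline long i8(int a, int b, int c, int d, int e, int f, int g, int h) {
  return a + 6L * (b + 6L * (c + 6L * (d + 6L * (e + 6L * (f + 6L * (g + 6L * h))))));
}

class Fold {
public:
  std::vector<int> s;
  int n;
  Tables T;

  Fold(const IntegerVector &seq, const Tables &tab) : T(tab) {
    n = seq.size();
    s.assign(seq.begin(), seq.end());
  }

  bool pairable(int i, int j) const {
    return j - i - 1 >= T.min_hairpin && T.allowed[i2(s[i], s[j])] != 0;
  }
  double pen(int i, int j) const { return T.pen[i2(s[i], s[j])]; }
  double tmm_in(int i, int j) const {
    return T.tmm[i4(s[i], s[j], s[i + 1], s[j - 1])];
  }
  double tmm_out(int k, int l) const {
    return T.tmm[i4(s[l], s[k], s[l + 1], s[k - 1])];
  }

  // exterior coupling term for a top-level pair (k,l)
  double ext_term(int k, int l) const {
    double e = pen(k, l);
    if (k > 0 && l < n - 1) e += tmm_out(k, l);
    else if (k > 0) e += T.d5[i3(s[k], s[l], s[k - 1])];
    else if (l < n - 1) e += T.d3[i3(s[l], s[k], s[l + 1])];
    return e;
  }

  double hairpinE(int i, int j) const {
    int sz = j - i - 1;
    return T.hp_init[sz - 1] + tmm_in(i, j) + pen(i, j);
  }

  // interior-loop energy for outer (i,j), inner (k,l); INF if unsupported
  double intE(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    if (n1 == 0 && n2 == 0)
      return T.stackE[i4(s[i], s[k], s[j], s[l])];
    double pens = pen(i, j) + pen(k, l);
    int sz = n1 + n2;
    if (sz > T.max_loop) return INF_E;
    if (n1 == 0 || n2 == 0)
      return T.bulge_init[sz - 1] + pens;
    if (n1 == 1 && n2 == 1)
      return T.int11[i6(s[i], s[j], s[k], s[l], s[i + 1], s[j - 1])] + pens;
    if (n1 == 2 && n2 == 1)
      return T.int21[i7(s[i], s[j], s[k], s[l], s[i + 1], s[i + 2], s[j - 1])] + pens;
    if (n1 == 1 && n2 == 2)
      return T.int21[i7(s[l], s[k], s[j], s[i], s[l + 1], s[l + 2], s[i + 1])] + pens;
    if (n1 == 2 && n2 == 2)
      return T.int22[i8(s[i], s[j], s[k], s[l], s[i + 1], s[i + 2],
                        s[j - 1], s[j - 2])] + pens;
    return T.intl_init[sz - 1] + tmm_in(i, j) + tmm_out(k, l) + pens;
  }

  // ---- partition function -------------------------------------------------
  std::vector<double> Qb, Qm, Qm1, powc;
  std::vector<double> Qe, Qhat;
  double Qtot;

  inline double &QB(int i, int j) { return Qb[(size_t)i * n + j]; }
  inline double &QM(int i, int j) { return Qm[(size_t)i * n + j]; }
  inline double &QM1(int i, int j) { return Qm1[(size_t)i * n + j]; }
  inline double qm(int i, int j) { return (i > j || i < 0 || j >= n) ? 0.0 : QM(i, j); }
  inline double qm1(int i, int j) { return (i > j) ? 0.0 : QM1(i, j); }

  double bf(double e) const { return e >= INF_E / 2 ? 0.0 : std::exp(-e / T.RT); }

  // multibranch coupling for a branch (k,l) seen from inside a closure
  double Bm_factor(int k, int l) const {
    if (k == 0 || l == n - 1) return 0.0;  // cannot be inside any closure
    return bf(T.mb_b + tmm_out(k, l) + pen(k, l));
  }

  void partition() {
    Qb.assign((size_t)n * n, 0.0);
    Qm.assign((size_t)n * n, 0.0);
    Qm1.assign((size_t)n * n, 0.0);
    powc.resize(n + 2);
    double c = bf(T.mb_c);
    powc[0] = 1.0;
    for (int t = 1; t <= n + 1; ++t) powc[t] = powc[t - 1] * c;

    for (int d = T.min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (pairable(i, j)) {
          double q = bf(hairpinE(i, j));
          int kmax = std::min(j - 1, i + T.max_loop + 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + T.min_hairpin + 1, j - 1 - (T.max_loop - n1));
            for (int l = lmin; l < j; ++l) {
              if (!pairable(k, l)) continue;
              double e = intE(i, j, k, l);
              if (e < INF_E / 2) q += bf(e) * QB(k, l);
            }
          }
          // multibranch closure: >= 2 branches inside
          double mbsum = 0.0;
          for (int k = i + 2; k < j - 1; ++k) {
            double left = qm(i + 1, k - 1);
            if (left > 0.0) mbsum += left * qm1(k, j - 1);
          }
          if (mbsum > 0.0)
            q += bf(T.mb_a + T.mb_b + tmm_in(i, j) + pen(i, j)) * mbsum;
          QB(i, j) = q;
        }
        // QM1(i,j): exactly one branch starting at i, trailing unpaired
        {
          double v = (j > i) ? QM1(i, j - 1) * c : 0.0;
          if (pairable(i, j)) v += QB(i, j) * Bm_factor(i, j);
          QM1(i, j) = v;
        }
        // QM(i,j): >= 1 branch
        {
          double v = (j > i) ? QM(i, j - 1) * c : 0.0;
          for (int k = i; k <= j; ++k) {
            if (!pairable(k, j)) continue;
            double w = QB(k, j) * Bm_factor(k, j);
            if (w == 0.0) continue;
            v += (powc[k - i] + qm(i, k - 1)) * w;
          }
          QM(i, j) = v;
        }
      }
    }

    Qe.assign(n + 1, 1.0);
    for (int t = 1; t <= n; ++t) {
      int j = t - 1;
      double v = Qe[t - 1];
      for (int k = 0; k <= j; ++k) {
        if (!pairable(k, j)) continue;
        v += Qe[k] * QB(k, j) * bf(ext_term(k, j));
      }
      Qe[t] = v;
    }
    Qtot = Qe[n];

    Qhat.assign(n + 2, 1.0);
    for (int t = n - 1; t >= 0; --t) {
      double v = Qhat[t + 1];
      for (int l = t; l < n; ++l) {
        if (!pairable(t, l)) continue;
        v += QB(t, l) * bf(ext_term(t, l)) * Qhat[l + 1];
      }
      Qhat[t] = v;
    }
  }

  NumericMatrix probabilities() {
    // outside values, by decreasing span
    std::vector<double> Pout((size_t)n * n, 0.0);
    // partner lists for the multibranch enclosure scan
    std::vector<std::vector<int>> partners(n);
    for (int i = 0; i < n; ++i)
      for (int j = i + T.min_hairpin + 1; j < n; ++j)
        if (pairable(i, j) && QB(i, j) > 0.0) partners[i].push_back(j);

    for (int d = n - 1; d >= T.min_hairpin + 1; --d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (!pairable(i, j) || QB(i, j) == 0.0) continue;
        double out = Qe[i] * bf(ext_term(i, j)) * Qhat[j + 1];
        // enclosed in an interior loop of (k,l)
        int kmin = std::max(0, i - T.max_loop - 1);
        for (int k = kmin; k < i; ++k) {
          int n1 = i - k - 1;
          int lmax = std::min(n - 1, j + 1 + (T.max_loop - n1));
          for (int l = j + 1; l <= lmax; ++l) {
            if (!pairable(k, l)) continue;
            double po = Pout[(size_t)k * n + l];
            if (po == 0.0) continue;
            double e = intE(k, l, i, j);
            if (e < INF_E / 2) out += po * bf(e);
          }
        }
        // branch of a multibranch loop closed by (k,l)
        double bmf = Bm_factor(i, j);
        if (bmf > 0.0) {
          double acc = 0.0;
          for (int k = 0; k < i; ++k) {
            for (int l : partners[k]) {
              if (l <= j) continue;
              double po = Pout[(size_t)k * n + l];
              if (po == 0.0) continue;
              double left = qm(k + 1, i - 1);
              double right = qm(j + 1, l - 1);
              double ways = left * powc[l - j - 1] + left * right +
                            powc[i - k - 1] * right;
              if (ways > 0.0)
                acc += po * bf(T.mb_a + T.mb_b + tmm_in(k, l) + pen(k, l)) * ways;
            }
          }
          out += bmf * acc;
        }
        Pout[(size_t)i * n + j] = out;
      }
    }

    NumericMatrix p(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (!pairable(i, j)) continue;
        double v = QB(i, j) * Pout[(size_t)i * n + j] / Qtot;
        p(i, j) = v;
        p(j, i) = v;
      }
    return p;
  }

  // ---- minimum free energy ------------------------------------------------
  std::vector<double> Vb, Vm, Vm1, Ve;
  inline double &VB(int i, int j) { return Vb[(size_t)i * n + j]; }
  inline double &VM(int i, int j) { return Vm[(size_t)i * n + j]; }
  inline double &VM1(int i, int j) { return Vm1[(size_t)i * n + j]; }
  inline double vm(int i, int j) { return (i > j || i < 0 || j >= n) ? INF_E : VM(i, j); }
  inline double vm1(int i, int j) { return (i > j) ? INF_E : VM1(i, j); }

  double VBm(int k, int l) {
    if (k == 0 || l == n - 1) return INF_E;
    double v = VB(k, l);
    if (v >= INF_E / 2) return INF_E;
    return v + T.mb_b + tmm_out(k, l) + pen(k, l);
  }
  double VBe(int k, int l) {
    double v = VB(k, l);
    if (v >= INF_E / 2) return INF_E;
    return v + ext_term(k, l);
  }

  void mfe() {
    Vb.assign((size_t)n * n, INF_E);
    Vm.assign((size_t)n * n, INF_E);
    Vm1.assign((size_t)n * n, INF_E);
    double mbc = T.mb_c;
    for (int d = T.min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        if (pairable(i, j)) {
          double v = hairpinE(i, j);
          int kmax = std::min(j - 1, i + T.max_loop + 1);
          for (int k = i + 1; k <= kmax; ++k) {
            int n1 = k - i - 1;
            int lmin = std::max(k + T.min_hairpin + 1, j - 1 - (T.max_loop - n1));
            for (int l = lmin; l < j; ++l) {
              if (!pairable(k, l) || VB(k, l) >= INF_E / 2) continue;
              double e = intE(i, j, k, l);
              if (e < INF_E / 2 && e + VB(k, l) < v) v = e + VB(k, l);
            }
          }
          double best2 = INF_E;
          for (int k = i + 2; k < j - 1; ++k) {
            double left = vm(i + 1, k - 1);
            double right = vm1(k, j - 1);
            if (left < INF_E / 2 && right < INF_E / 2 && left + right < best2)
              best2 = left + right;
          }
          if (best2 < INF_E / 2) {
            double e = T.mb_a + T.mb_b + tmm_in(i, j) + pen(i, j) + best2;
            if (e < v) v = e;
          }
          VB(i, j) = v;
        }
        {
          double v = (j > i && VM1(i, j - 1) < INF_E / 2) ? VM1(i, j - 1) + mbc : INF_E;
          if (pairable(i, j)) v = std::min(v, VBm(i, j));
          VM1(i, j) = v;
        }
        {
          double v = (j > i && VM(i, j - 1) < INF_E / 2) ? VM(i, j - 1) + mbc : INF_E;
          for (int k = i; k <= j; ++k) {
            if (!pairable(k, j)) continue;
            double w = VBm(k, j);
            if (w >= INF_E / 2) continue;
            double pre = std::min(mbc * (k - i), vm(i, k - 1));
            if (pre < INF_E / 2 && pre + w < v) v = pre + w;
          }
          VM(i, j) = v;
        }
      }
    }
    Ve.assign(n + 1, 0.0);
    for (int t = 1; t <= n; ++t) {
      int j = t - 1;
      double v = Ve[t - 1];
      for (int k = 0; k <= j; ++k) {
        if (!pairable(k, j)) continue;
        double w = VBe(k, j);
        if (w < INF_E / 2 && Ve[k] + w < v) v = Ve[k] + w;
      }
      Ve[t] = v;
    }
  }

  // deterministic traceback; ties resolved in DP enumeration order
  IntegerMatrix traceback() {
    const double eps = 1e-9;
    std::vector<std::pair<int, int>> pairs;
    std::vector<std::array<int, 3>> tasks;  // {type 0=B,1=M,2=EXT, i, j}
    tasks.push_back({2, 0, n});
    double mbc = T.mb_c;
    while (!tasks.empty()) {
      auto tk = tasks.back();
      tasks.pop_back();
      if (tk[0] == 2) {
        int t = tk[2];
        while (t > 0) {
          int j = t - 1;
          if (std::fabs(Ve[t] - Ve[t - 1]) <= eps) { t = t - 1; continue; }
          bool found = false;
          for (int k = 0; k <= j && !found; ++k) {
            if (!pairable(k, j)) continue;
            double w = VBe(k, j);
            if (w < INF_E / 2 && std::fabs(Ve[k] + w - Ve[t]) <= eps) {
              pairs.push_back({k, j});
              tasks.push_back({0, k, j});
              t = k;
              found = true;
            }
          }
          if (!found) stop("traceback failure (exterior)");
        }
      } else if (tk[0] == 0) {
        int i = tk[1], j = tk[2];
        double v = VB(i, j);
        if (std::fabs(hairpinE(i, j) - v) <= eps) continue;
        bool found = false;
        int kmax = std::min(j - 1, i + T.max_loop + 1);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int n1 = k - i - 1;
          int lmin = std::max(k + T.min_hairpin + 1, j - 1 - (T.max_loop - n1));
          for (int l = lmin; l < j && !found; ++l) {
            if (!pairable(k, l) || VB(k, l) >= INF_E / 2) continue;
            double e = intE(i, j, k, l);
            if (e < INF_E / 2 && std::fabs(e + VB(k, l) - v) <= eps) {
              pairs.push_back({k, l});
              tasks.push_back({0, k, l});
              found = true;
            }
          }
        }
        if (found) continue;
        double closure = T.mb_a + T.mb_b + tmm_in(i, j) + pen(i, j);
        for (int k = i + 2; k < j - 1 && !found; ++k) {
          double left = vm(i + 1, k - 1), right = vm1(k, j - 1);
          if (left >= INF_E / 2 || right >= INF_E / 2) continue;
          if (std::fabs(closure + left + right - v) <= eps) {
            // trace VM1(k, j-1): branch (k,l) + trailing unpaired
            int t2 = j - 1;
            while (t2 >= k) {
              double w = pairable(k, t2) ? VBm(k, t2) : INF_E;
              if (w < INF_E / 2 &&
                  std::fabs(w + mbc * (j - 1 - t2) - vm1(k, j - 1)) <= eps) {
                pairs.push_back({k, t2});
                tasks.push_back({0, k, t2});
                break;
              }
              --t2;
            }
            if (t2 < k) stop("traceback failure (multibranch VM1)");
            tasks.push_back({1, i + 1, k - 1});
            found = true;
          }
        }
        if (!found) stop("traceback failure (pair)");
      } else {
        int a = tk[1], b = tk[2];
        while (b >= a) {
          double v = VM(a, b);
          if (b > a && VM(a, b - 1) < INF_E / 2 &&
              std::fabs(VM(a, b - 1) + mbc - v) <= eps) { --b; continue; }
          bool found = false;
          for (int k = a; k <= b && !found; ++k) {
            if (!pairable(k, b)) continue;
            double w = VBm(k, b);
            if (w >= INF_E / 2) continue;
            if (std::fabs(mbc * (k - a) + w - v) <= eps) {
              pairs.push_back({k, b});
              tasks.push_back({0, k, b});
              b = a - 1;  // done with this region
              found = true;
            } else if (vm(a, k - 1) < INF_E / 2 &&
                       std::fabs(vm(a, k - 1) + w - v) <= eps) {
              pairs.push_back({k, b});
              tasks.push_back({0, k, b});
              b = k - 1;
              found = true;
            }
          }
          if (!found) stop("traceback failure (multibranch region)");
        }
      }
    }
    IntegerMatrix out(pairs.size(), 2);
    for (size_t r = 0; r < pairs.size(); ++r) {
      out(r, 0) = pairs[r].first + 1;
      out(r, 1) = pairs[r].second + 1;
    }
    return out;
  }
};

static Tables unpack(const List &tab) {
  Tables T;
  T.stackE = REAL(VECTOR_ELT(tab, tab.findName("stackE")));
  T.tmm = REAL(VECTOR_ELT(tab, tab.findName("tmm")));
  T.d5 = REAL(VECTOR_ELT(tab, tab.findName("d5")));
  T.d3 = REAL(VECTOR_ELT(tab, tab.findName("d3")));
  T.pen = REAL(VECTOR_ELT(tab, tab.findName("pen")));
  T.allowed = INTEGER(VECTOR_ELT(tab, tab.findName("allowed")));
  T.int11 = REAL(VECTOR_ELT(tab, tab.findName("int11")));
  T.int21 = REAL(VECTOR_ELT(tab, tab.findName("int21")));
  T.int22 = REAL(VECTOR_ELT(tab, tab.findName("int22")));
  SEXP hp = VECTOR_ELT(tab, tab.findName("hp_init"));
  T.hp_init = REAL(hp);
  T.hp_len = LENGTH(hp);
  T.bulge_init = REAL(VECTOR_ELT(tab, tab.findName("bulge_init")));
  T.intl_init = REAL(VECTOR_ELT(tab, tab.findName("intl_init")));
  NumericVector mb = tab["mb"];
  T.mb_a = mb[0]; T.mb_b = mb[1]; T.mb_c = mb[2];
  T.RT = as<double>(tab["RT"]);
  T.max_loop = as<int>(tab["max_loop"]);
  T.min_hairpin = as<int>(tab["min_hairpin"]);
  return T;
}

// [[Rcpp::export]]
List c_fold(IntegerVector seq, List tab, bool want_prob, bool want_mfe) {
  Tables T = unpack(tab);
  Fold F(seq, T);
  List out;
  F.partition();
  out["Q"] = F.Qtot;
  if (want_prob) out["p"] = F.probabilities();
  if (want_mfe) {
    F.mfe();
    out["mfe_energy"] = F.Ve[F.n];
    out["mfe_pairs"] = F.traceback();
  }
  return out;
}
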