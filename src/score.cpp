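#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Pair scoring kernel. Genotypes are pre-encoded per marker:
//   off(i, m): 0 = missing, else 1..K_m indexing the marker's triploid
//              genotype list;
//   sire(s, m), dam(d, m): 1..P_m indexing the marker's diploid genotype
//              list, whose last entry is the Missing class.
// lik[[m]] is a K x P x P array of log10 transmission probabilities,
// mm[[m]] the matching integer mismatch array. For each offspring x
// (sire, dam) pair the kernel sums both over the markers where the
// offspring call is non-missing. Pair index = (d * n_sire + s).

// [[Rcpp::export]]
List score_pairs_cpp(IntegerMatrix off, IntegerMatrix sire, IntegerMatrix dam,
                     List lik, List mm) {
  const int n_off = off.nrow(), n_s = sire.nrow(), n_d = dam.nrow();
  const int M = off.ncol();
  if (sire.ncol() != M || dam.ncol() != M || lik.size() != M ||
      mm.size() != M)
    stop("marker dimensions disagree");

  std::vector<const double*> likp(M);
  std::vector<const int*> mmp(M);
  std::vector<int> K(M), P(M);
  for (int m = 0; m < M; ++m) {
    NumericVector lv = lik[m];
    IntegerVector mv = mm[m];
    IntegerVector dims = lv.attr("dim");
    K[m] = dims[0];
    P[m] = dims[1];
    likp[m] = REAL(lv);
    mmp[m] = INTEGER(mv);
  }

  // per-marker offsets for sire and dam codes
  std::vector<int> soff((size_t)n_s * M), doff((size_t)n_d * M);
  for (int m = 0; m < M; ++m) {
    for (int s = 0; s < n_s; ++s) soff[(size_t)s * M + m] = (sire(s, m) - 1) * K[m];
    for (int d = 0; d < n_d; ++d)
      doff[(size_t)d * M + m] = (dam(d, m) - 1) * K[m] * P[m];
  }

  const long n_pairs = (long)n_s * n_d;
  NumericMatrix lik_sum(n_off, n_pairs);
  IntegerMatrix mm_sum(n_off, n_pairs);
  IntegerVector n_used(n_off);

  std::vector<int> use(M);
  std::vector<const double*> lbase(M);
  std::vector<const int*> mbase(M);
  std::vector<const double*> lrow(M);
  std::vector<const int*> mrow(M);

  for (int i = 0; i < n_off; ++i) {
    int nu = 0;
    for (int m = 0; m < M; ++m) {
      int o = off(i, m);
      if (o > 0) {
        use[nu] = m;
        lbase[nu] = likp[m] + (o - 1);
        mbase[nu] = mmp[m] + (o - 1);
        ++nu;
      }
    }
    n_used[i] = nu;
    for (int s = 0; s < n_s; ++s) {
      const int* so = &soff[(size_t)s * M];
      for (int u = 0; u < nu; ++u) {
        lrow[u] = lbase[u] + so[use[u]];
        mrow[u] = mbase[u] + so[use[u]];
      }
      for (int d = 0; d < n_d; ++d) {
        const int* dofs = &doff[(size_t)d * M];
        double ls = 0.0;
        int ms = 0;
        for (int u = 0; u < nu; ++u) {
          const int dd = dofs[use[u]];
          ls += lrow[u][dd];
          ms += mrow[u][dd];
        }
        const long pair = (long)d * n_s + s;
        lik_sum(i, pair) = ls;
        mm_sum(i, pair) = ms;
      }
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lik_sum"] = lik_sum, _["mm_sum"] = mm_sum,
                      _["n_used"] = n_used);
}

// BLAS reformulation of the same sums. The contraction
//   score(i, (s,d)) = sum_m T_m[og(i,m), sg(s,m), dg(d,m)]
// decomposes over parent-class pairs (a, b):
//   score = sum_{a,b} C_ab %*% t(E_ab)
// with C_ab(i, m) = T_m[og(i,m), a, b] (0 when the offspring call is
// missing or the marker has fewer classes) and E_ab((s,d), m) = 1 exactly
// when sg(s,m) == a and dg(d,m) == b. Each term is a dense n_off x M x
// n_pairs dgemm, which is an order of magnitude faster than gathering.
// lik values must be finite (probability-0 cells are floored upstream);
// mismatch sums are returned as doubles.

// [[Rcpp::export]]
List score_pairs_blas(IntegerMatrix off, IntegerMatrix sire, IntegerMatrix dam,
                      List lik, List mm, bool want_mm) {
  const int n_off = off.nrow(), n_s = sire.nrow(), n_d = dam.nrow();
  const int M = off.ncol();
  if (sire.ncol() != M || dam.ncol() != M || lik.size() != M ||
      mm.size() != M)
    stop("marker dimensions disagree");
  const R_xlen_t n_pairs = (R_xlen_t)n_s * n_d;
  if (n_pairs > INT_MAX) stop("too many candidate pairs");

  std::vector<const double*> likp(M);
  std::vector<const int*> mmp(M);
  std::vector<int> K(M), P(M);
  int Pmax = 0;
  for (int m = 0; m < M; ++m) {
    NumericVector lv = lik[m];
    IntegerVector mv = mm[m];
    IntegerVector dims = lv.attr("dim");
    K[m] = dims[0];
    P[m] = dims[1];
    if (P[m] > Pmax) Pmax = P[m];
    likp[m] = REAL(lv);
    mmp[m] = INTEGER(mv);
  }

  // class membership lists per marker
  std::vector<std::vector<std::vector<int> > > s_by(M), d_by(M);
  for (int m = 0; m < M; ++m) {
    s_by[m].assign(P[m], std::vector<int>());
    d_by[m].assign(P[m], std::vector<int>());
    for (int s = 0; s < n_s; ++s) s_by[m][sire(s, m) - 1].push_back(s);
    for (int d = 0; d < n_d; ++d) d_by[m][dam(d, m) - 1].push_back(d);
  }

  NumericMatrix lik_sum(n_off, (int)n_pairs);
  NumericMatrix mm_sum(want_mm ? n_off : 1, want_mm ? (int)n_pairs : 1);
  IntegerVector n_used(n_off);
  for (int i = 0; i < n_off; ++i) {
    int nu = 0;
    for (int m = 0; m < M; ++m) if (off(i, m) > 0) ++nu;
    n_used[i] = nu;
  }

  std::vector<double> E((size_t)n_pairs * M);
  std::vector<double> C((size_t)n_off * M);
  const double one = 1.0;
  const int im = n_off, ik = M;
  const int in = (int)n_pairs;

  for (int a = 1; a <= Pmax; ++a) {
    for (int b = 1; b <= Pmax; ++b) {
      std::fill(E.begin(), E.end(), 0.0);
      bool anyE = false;
      for (int m = 0; m < M; ++m) {
        if (a > P[m] || b > P[m]) continue;
        const std::vector<int>& ds = d_by[m][b - 1];
        const std::vector<int>& ss = s_by[m][a - 1];
        if (ds.empty() || ss.empty()) continue;
        anyE = true;
        double* Em = &E[(size_t)m * n_pairs];
        for (size_t di = 0; di < ds.size(); ++di) {
          double* row = Em + (size_t)ds[di] * n_s;
          for (size_t si = 0; si < ss.size(); ++si) row[ss[si]] = 1.0;
        }
      }
      if (!anyE) continue;
      // likelihood contribution
      for (int m = 0; m < M; ++m) {
        double* Cm = &C[(size_t)m * n_off];
        if (a > P[m] || b > P[m]) {
          std::fill(Cm, Cm + n_off, 0.0);
          continue;
        }
        const double* tab = likp[m] + (size_t)K[m] * ((a - 1) +
                                                      (size_t)P[m] * (b - 1));
        for (int i = 0; i < n_off; ++i) {
          const int o = off(i, m);
          Cm[i] = (o > 0) ? tab[o - 1] : 0.0;
        }
      }
      F77_CALL(dgemm)("N", "T", &im, &in, &ik, &one, C.data(), &im,
                      E.data(), &in, &one, REAL(lik_sum), &im FCONE FCONE);
      if (want_mm) {
        for (int m = 0; m < M; ++m) {
          double* Cm = &C[(size_t)m * n_off];
          if (a > P[m] || b > P[m]) {
            std::fill(Cm, Cm + n_off, 0.0);
            continue;
          }
          const int* tab = mmp[m] + (size_t)K[m] * ((a - 1) +
                                                    (size_t)P[m] * (b - 1));
          for (int i = 0; i < n_off; ++i) {
            const int o = off(i, m);
            Cm[i] = (o > 0) ? (double)tab[o - 1] : 0.0;
          }
        }
        F77_CALL(dgemm)("N", "T", &im, &in, &ik, &one, C.data(), &im,
                        E.data(), &in, &one, REAL(mm_sum), &im FCONE FCONE);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["lik_sum"] = lik_sum, _["mm_sum"] = mm_sum,
                      _["n_used"] = n_used);
}

// Row-wise best and runner-up (value and 1-based column index), plus the
// number of columns tied with the best value (exact equality). With
// minimize = true the "best" is the smallest value.

// [[Rcpp::export]]
List best2_rows_cpp(NumericMatrix x, bool minimize) {
  const int n = x.nrow();
  const long p = x.ncol();
  NumericVector best(n), second(n);
  IntegerVector best_j(n), second_j(n), n_tied(n);
  for (int i = 0; i < n; ++i) {
    double b1 = NA_REAL, b2 = NA_REAL;
    long j1 = -1, j2 = -1;
    int ties = 0;
    for (long j = 0; j < p; ++j) {
      double v = x(i, j);
      if (ISNAN(v)) continue;
      if (minimize) v = -v;
      if (j1 < 0 || v > b1) {
        b2 = b1; j2 = j1;
        b1 = v; j1 = j;
        ties = 1;
      } else if (v == b1) {
        ++ties;
        b2 = v; j2 = j;
      } else if (j2 < 0 || v > b2) {
        b2 = v; j2 = j;
      }
    }
    best[i] = (j1 < 0) ? NA_REAL : (minimize ? -b1 : b1);
    second[i] = (j2 < 0) ? NA_REAL : (minimize ? -b2 : b2);
    best_j[i] = (int)(j1 + 1);
    second_j[i] = (int)(j2 + 1);
    n_tied[i] = ties;
  }
  return List::create(_["best"] = best, _["best_idx"] = best_j,
                      _["second"] = second, _["second_idx"] = second_j,
                      _["n_tied"] = n_tied);
}

// Single-parent exclusion counts for the sex-agnostic comparator.
//   excl[[m]]: K x P 0/1 matrix, 1 when the parent genotype is excluded at
//              this offspring genotype whichever role (sire or dam) it takes,
//              the other parent being unknown (opposed-homozygote signal);
//   damspec[[m]]: K x P 0/1, 1 when the genotype is excluded as dam but
//              compatible as sire (dam-specific exclusion, used to orient
//              the retained pair);
//   par_missing: per-marker code of the Missing parent class (1-based).
// Returns exclusion counts, dam-specific counts and the number of markers
// where both the offspring and the parent are genotyped.

// [[Rcpp::export]]
List single_parent_counts_cpp(IntegerMatrix off, IntegerMatrix par,
                              List excl, List damspec,
                              IntegerVector par_missing) {
  const int n_off = off.nrow(), n_p = par.nrow(), M = off.ncol();
  if (par.ncol() != M || excl.size() != M || damspec.size() != M)
    stop("marker dimensions disagree");
  std::vector<const int*> ep(M), dp(M);
  std::vector<int> K(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector ev = excl[m], dv = damspec[m];
    IntegerVector dims = ev.attr("dim");
    K[m] = dims[0];
    ep[m] = INTEGER(ev);
    dp[m] = INTEGER(dv);
  }
  IntegerMatrix n_excl(n_off, n_p), n_damspec(n_off, n_p), n_comp(n_off, n_p);
  for (int i = 0; i < n_off; ++i) {
    for (int p = 0; p < n_p; ++p) {
      int ne = 0, nd = 0, nc = 0;
      for (int m = 0; m < M; ++m) {
        const int o = off(i, m);
        const int g = par(p, m);
        if (o == 0 || g == par_missing[m]) continue;
        ++nc;
        const int idx = (o - 1) + K[m] * (g - 1);
        ne += ep[m][idx];
        nd += dp[m][idx];
      }
      n_excl(i, p) = ne;
      n_damspec(i, p) = nd;
      n_comp(i, p) = nc;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["n_excl"] = n_excl, _["n_damspec"] = n_damspec,
                      _["n_compared"] = n_comp);
}
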