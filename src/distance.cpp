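// Maximum-likelihood pairwise amino-acid distances under a reversible
// empirical rate model. The rate matrix eigensystem is computed once in R;
// here each likelihood evaluation reconstructs P(t) = U diag(exp(lambda t)) W
// (20x20) and sums pattern-count-weighted log(pi_i P_ij(t)). The distance is
// the Brent minimiser of the negative log-likelihood on [lo, hi].

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr int NS = 20;

struct Model {
  const double *U, *W, *lambda, *logpi;
};

// Site patterns of one pair, collapsed to the distinct (i, j) cells with
// multiplicities; the likelihood only ever needs those P entries.
struct Patterns {
  std::vector<int> cell;      // i + NS * j
  std::vector<double> mult;   // site count per cell
  double const_logpi = 0.0;   // sum over sites of log pi_i
};

// negative log-likelihood of the pattern set at distance t; reconstructs
// only the needed entries of P(t) = U diag(exp(lambda t)) W
double negloglik(double t, const Model& m, const Patterns& pat) {
  double el[NS];
  for (int k = 0; k < NS; ++k) el[k] = std::exp(m.lambda[k] * t);
  double ll = pat.const_logpi;
  for (size_t c = 0; c < pat.cell.size(); ++c) {
    int i = pat.cell[c] % NS, j = pat.cell[c] / NS;
    double p = 0.0;
    for (int k = 0; k < NS; ++k) p += m.U[i + NS * k] * el[k] * m.W[k + NS * j];
    if (p < 1e-300) p = 1e-300;
    ll += pat.mult[c] * std::log(p);
  }
  return -ll;
}

// Brent's method for scalar minimisation (golden section + successive
// parabolic interpolation), as in standard numerical references.
double brent_min(double lo, double hi, const Model& m, const Patterns& pat,
                 double tol) {
  const double golden = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + golden * (b - a), w = x, v = x;
  double fx = negloglik(x, m, pat), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x >= xm) ? a - x : b - x;
      d = golden * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = negloglik(u, m, pat);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

inline void count_patterns(const int* a, const int* b, int len,
                           const Model& m, Patterns& pat,
                           double* scratch400,
                           double& n_sites, double& n_diff) {
  n_sites = 0.0;
  n_diff = 0.0;
  std::fill(scratch400, scratch400 + NS * NS, 0.0);
  for (int s = 0; s < len; ++s) {
    int x = a[s], y = b[s];
    if (x > 0 && y > 0) {
      scratch400[(x - 1) + NS * (y - 1)] += 1.0;
      n_sites += 1.0;
      if (x != y) n_diff += 1.0;
    }
  }
  pat.cell.clear();
  pat.mult.clear();
  pat.const_logpi = 0.0;
  for (int c = 0; c < NS * NS; ++c) {
    if (scratch400[c] > 0.0) {
      pat.cell.push_back(c);
      pat.mult.push_back(scratch400[c]);
      pat.const_logpi += scratch400[c] * m.logpi[c % NS];
    }
  }
}

double fit_one(const Model& m, const Patterns& pat, double n_diff,
               double lo, double hi, double tol) {
  if (n_diff == 0.0) return 0.0;  // identical comparable columns
  return brent_min(lo, hi, m, pat, tol);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_pair_distance")]]
List cpp_pair_distance(IntegerVector a, IntegerVector b,
                       NumericMatrix U, NumericMatrix W,
                       NumericVector lambda, NumericVector logpi,
                       double lo, double hi, double tol) {
  Model m{U.begin(), W.begin(), lambda.begin(), logpi.begin()};
  Patterns pat;
  std::vector<double> scratch(NS * NS);
  double n_sites, n_diff;
  count_patterns(a.begin(), b.begin(), a.size(), m, pat, scratch.data(),
                 n_sites, n_diff);
  if (n_sites == 0.0) {
    return List::create(_["t_hat"] = NA_REAL, _["n_sites"] = 0.0);
  }
  double t_hat = fit_one(m, pat, n_diff, lo, hi, tol);
  return List::create(_["t_hat"] = t_hat, _["n_sites"] = n_sites);
}

// All pairwise distances for an encoded alignment (rows x columns, 0 =
// missing). Returns per-pair t_hat and comparable-site counts; pairs with
// no comparable columns get NA.
// [[Rcpp::export(name = ".cpp_all_pair_distances")]]
List cpp_all_pair_distances(IntegerMatrix aln,
                            NumericMatrix U, NumericMatrix W,
                            NumericVector lambda, NumericVector logpi,
                            double lo, double hi, double tol) {
  Model m{U.begin(), W.begin(), lambda.begin(), logpi.begin()};
  int n = aln.nrow(), len = aln.ncol();
  int np = n * (n - 1) / 2;
  NumericVector t_hat(np), n_sites(np);
  IntegerVector row_i(np), row_j(np);
  // column-wise copy of each row for cache-friendly pattern counting
  std::vector<int> rows((size_t)n * len);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < len; ++s) rows[(size_t)i * len + s] = aln(i, s);
  Patterns pat;
  std::vector<double> scratch(NS * NS);
  int k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      double ns, nd;
      count_patterns(&rows[(size_t)i * len], &rows[(size_t)j * len], len,
                     m, pat, scratch.data(), ns, nd);
      row_i[k] = i + 1;
      row_j[k] = j + 1;
      n_sites[k] = ns;
      t_hat[k] = (ns == 0.0) ? NA_REAL
                             : fit_one(m, pat, nd, lo, hi, tol);
    }
  }
  return List::create(_["i"] = row_i, _["j"] = row_j,
                      _["t_hat"] = t_hat, _["n_sites"] = n_sites);
}
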