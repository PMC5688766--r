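// Exhaustive enumeration oracle for small reconstruction instances.
//
// Enumerates every assignment of the directed traversal-count
// variables in [0, bound], keeps those satisfying the balance
// equalities, and evaluates the discordance score directly in its
// non-linearized form (length-weighted |f - w| plus the
// support-weighted penalty for bridges with f = 0). Serves as an
// independent check of the MIP formulation and its linearization on
// graphs small enough to enumerate.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Problem {
  int n_vars;
  int bound;
  // equality rows: sparse coefficients per row
  std::vector<std::vector<int>> row_var;
  std::vector<std::vector<double>> row_coef;
  // per-connection objective data
  std::vector<int> var1, var2;   // -1 if absent
  std::vector<int> type;         // 0 interval, 1 reference, 2 bridge
  std::vector<double> w, lnorm;  // weight; l_e / L for intervals
  double alpha, mu;
};

class Enumerator {
public:
  explicit Enumerator(const Problem& p) : p_(p) {
    n_rows_ = (int)p.row_var.size();
    row_sum_.assign(n_rows_, 0.0);
    row_left_.assign(n_rows_, 0);
    row_posrem_.assign(n_rows_, 0.0);
    row_negrem_.assign(n_rows_, 0.0);
    vars_rows_.assign(p.n_vars, {});
    for (int r = 0; r < n_rows_; ++r) {
      for (size_t k = 0; k < p.row_var[r].size(); ++k) {
        int v = p.row_var[r][k];
        double c = p.row_coef[r][k];
        vars_rows_[v].push_back({r, c});
        row_left_[r]++;
        if (c > 0) row_posrem_[r] += c * p.bound;
        else row_negrem_[r] += c * p.bound;
      }
    }
    x_.assign(p.n_vars, 0);
    best_obj_ = R_PosInf;
  }

  void run() { dfs(0); }

  double best_obj() const { return best_obj_; }
  const std::vector<int>& best_x() const { return best_x_; }
  double n_feasible() const { return n_feasible_; }

private:
  struct RC { int row; double coef; };

  void dfs(int v) {
    if (v == p_.n_vars) {
      for (int r = 0; r < n_rows_; ++r)
        if (row_left_[r] == 0 && std::abs(row_sum_[r]) > 1e-9) return;
      n_feasible_ += 1.0;
      double obj = objective();
      if (obj < best_obj_ - 1e-12) {
        best_obj_ = obj;
        best_x_ = x_;
      }
      return;
    }
    for (int val = 0; val <= p_.bound; ++val) {
      x_[v] = val;
      bool ok = true;
      for (const RC& rc : vars_rows_[v]) {
        row_sum_[rc.row] += rc.coef * val;
        row_left_[rc.row]--;
        if (rc.coef > 0) row_posrem_[rc.row] -= rc.coef * p_.bound;
        else row_negrem_[rc.row] -= rc.coef * p_.bound;
      }
      for (const RC& rc : vars_rows_[v]) {
        int r = rc.row;
        if (row_left_[r] == 0) {
          if (std::abs(row_sum_[r]) > 1e-9) { ok = false; break; }
        } else {
          // equality can still be reached only if 0 lies in the
          // attainable range of the remaining variables
          if (row_sum_[r] + row_negrem_[r] > 1e-9 ||
              row_sum_[r] + row_posrem_[r] < -1e-9) { ok = false; break; }
        }
      }
      if (ok) dfs(v + 1);
      for (const RC& rc : vars_rows_[v]) {
        row_sum_[rc.row] -= rc.coef * val;
        row_left_[rc.row]++;
        if (rc.coef > 0) row_posrem_[rc.row] += rc.coef * p_.bound;
        else row_negrem_[rc.row] += rc.coef * p_.bound;
      }
    }
    x_[v] = 0;
  }

  double objective() const {
    double obj = 0.0;
    for (size_t i = 0; i < p_.var1.size(); ++i) {
      int f = (p_.var1[i] >= 0 ? x_[p_.var1[i]] : 0) +
              (p_.var2[i] >= 0 ? x_[p_.var2[i]] : 0);
      if (p_.type[i] == 0) {
        obj += p_.lnorm[i] * std::abs((double)f - p_.w[i]);
      } else if (p_.type[i] == 2 && p_.mu > 0) {
        obj += p_.alpha * (p_.w[i] / p_.mu) * (1.0 - std::min(1, f));
      }
    }
    return obj;
  }

  Problem p_;
  int n_rows_;
  std::vector<double> row_sum_, row_posrem_, row_negrem_;
  std::vector<int> row_left_;
  std::vector<std::vector<RC>> vars_rows_;
  std::vector<int> x_, best_x_;
  double best_obj_;
  double n_feasible_ = 0.0;
};

}  // namespace

// [[Rcpp::export(name = ".brute_force_cpp")]]
List brute_force_cpp(int n_vars, int bound, List row_var, List row_coef,
                     IntegerVector var1, IntegerVector var2,
                     IntegerVector type, NumericVector w,
                     NumericVector lnorm, double alpha, double mu) {
  Problem p;
  p.n_vars = n_vars;
  p.bound = bound;
  for (R_xlen_t r = 0; r < row_var.size(); ++r) {
    IntegerVector rv = row_var[r];
    NumericVector rc = row_coef[r];
    p.row_var.push_back(std::vector<int>(rv.begin(), rv.end()));
    p.row_coef.push_back(std::vector<double>(rc.begin(), rc.end()));
  }
  p.var1 = std::vector<int>(var1.begin(), var1.end());
  p.var2 = std::vector<int>(var2.begin(), var2.end());
  p.type = std::vector<int>(type.begin(), type.end());
  p.w = std::vector<double>(w.begin(), w.end());
  p.lnorm = std::vector<double>(lnorm.begin(), lnorm.end());
  p.alpha = alpha;
  p.mu = mu;
  Enumerator e(p);
  e.run();
  return List::create(_["objective"] = e.best_obj(),
                      _["x"] = IntegerVector(e.best_x().begin(),
                                             e.best_x().end()),
                      _["n_feasible"] = e.n_feasible());
}
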