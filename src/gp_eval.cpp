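#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Postfix genome encoding shared with R/gp_tree.R:
//   code[i] > 0 : binary operator (1 add, 2 sub, 3 mul, 4 protected div)
//   code[i] == 0: ephemeral constant, value in vals[i]
//   code[i] < 0 : predictor variable, 1-based column index -code[i]

// [[Rcpp::export]]
NumericVector eval_postfix_cpp(IntegerVector code, NumericVector vals,
                               NumericMatrix X) {
  const int n = X.nrow();
  const int m = code.size();
  std::vector< std::vector<double> > stack;
  stack.reserve(64);
  for (int i = 0; i < m; ++i) {
    int c = code[i];
    if (c < 0) {
      int col = -c - 1;
      if (col >= X.ncol())
        stop("unbound variable x%d: predictor matrix has %d column(s)",
             -c, X.ncol());
      std::vector<double> v(n);
      for (int r = 0; r < n; ++r) v[r] = X(r, col);
      stack.push_back(std::move(v));
    } else if (c == 0) {
      stack.push_back(std::vector<double>(n, vals[i]));
    } else {
      if (stack.size() < 2)
        stop("malformed expression: operator at node %d lacks operands", i + 1);
      std::vector<double> b = std::move(stack.back());
      stack.pop_back();
      std::vector<double>& a = stack.back();
      switch (c) {
      case 1: for (int r = 0; r < n; ++r) a[r] += b[r]; break;
      case 2: for (int r = 0; r < n; ++r) a[r] -= b[r]; break;
      case 3: for (int r = 0; r < n; ++r) a[r] *= b[r]; break;
      case 4:
        for (int r = 0; r < n; ++r)
          a[r] = (std::fabs(b[r]) > 1e-9) ? a[r] / b[r] : 1.0;
        break;
      default: stop("unknown operator code %d", c);
      }
    }
  }
  if (stack.size() != 1)
    stop("malformed expression: %d values left on stack", (int)stack.size());
  return wrap(stack.back());
}

// [[Rcpp::export]]
int postfix_depth_cpp(IntegerVector code) {
  std::vector<int> st;
  st.reserve(64);
  for (int i = 0; i < code.size(); ++i) {
    if (code[i] > 0) {
      if (st.size() < 2) stop("malformed expression");
      int b = st.back(); st.pop_back();
      int a = st.back(); st.pop_back();
      st.push_back(1 + (a > b ? a : b));
    } else {
      st.push_back(1);
    }
  }
  if (st.size() != 1) stop("malformed expression");
  return st.back();
}

// Start index (1-based) of the subtree whose root sits at 1-based
// position `end` of a postfix genome.
// [[Rcpp::export]]
int subtree_start_cpp(IntegerVector code, int end) {
  if (end < 1 || end > code.size()) stop("node index out of range");
  int need = 1;
  for (int j = end - 1; j >= 0; --j) {
    if (code[j] > 0) need += 1; else need -= 1;
    if (need == 0) return j + 1;
  }
  stop("malformed expression: no subtree ends at node %d", end);
}
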