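// Projected-gradient solver for the principal convex hull (archetypal
// analysis) factorization  min_{C,S} ||X - X C S||_F^2  with
//   S >= 0, colsum(S) = 1          (cells as convex mixtures of archetypes)
//   C >= 0, colsum(C) in [1-delta, 1+delta]
// X is feature-major (d x n). Alternating projected-gradient updates with a
// monotone backtracking line search, so the objective never increases.
// Feasible-set projections are exact Euclidean projections (sort-based
// simplex projection; for C, orthant projection with the column sum pulled
// back into [1-delta, 1+delta] when violated).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double sse(const mat& X, const mat& XC, const mat& S) {
  return accu(square(X - XC * S));
}

// Euclidean projection of col (length n, in place) onto
// {w >= 0, sum(w) = target}, by Michelot's iterative thresholding:
// the active set shrinks monotonically, each pass is O(n), and the fixed
// point gives the exact simplex projection.
static void proj_simplex_inplace(double* col, uword n, double target,
                                 std::vector<double>& buf) {
  buf.resize(n);
  std::copy(col, col + n, buf.begin());
  uword m = n;
  double tau = 0.0;
  for (;;) {
    double s = 0.0;
    for (uword i = 0; i < m; ++i) s += buf[i];
    tau = (s - target) / m;
    uword kept = 0;
    for (uword i = 0; i < m; ++i) {
      if (buf[i] > tau) buf[kept++] = buf[i];
    }
    if (kept == m || kept == 0) break;
    m = kept;
  }
  for (uword i = 0; i < n; ++i) {
    double w = col[i] - tau;
    col[i] = w > 0.0 ? w : 0.0;
  }
}

// columns onto the probability simplex, in place; columns are short
// (k archetypes) and there are many of them, so avoid per-column
// allocations
static void project_S(mat& S) {
  const uword k = S.n_rows;
  std::vector<double> buf(k);
  for (uword j = 0; j < S.n_cols; ++j) {
    double* col = S.colptr(j);
    std::copy(col, col + k, buf.begin());
    std::sort(buf.begin(), buf.end(), std::greater<double>());
    double css = 0.0, tau = 0.0;
    for (uword i = 0; i < k; ++i) {
      css += buf[i];
      double t = (css - 1.0) / (i + 1);
      if (buf[i] - t > 0) tau = t;
    }
    for (uword i = 0; i < k; ++i) {
      double w = col[i] - tau;
      col[i] = w > 0.0 ? w : 0.0;
    }
  }
}

// columns onto {c >= 0, 1-delta <= sum(c) <= 1+delta}
static void project_C(mat& C, double delta) {
  const uword n = C.n_rows;
  std::vector<double> buf;
  for (uword j = 0; j < C.n_cols; ++j) {
    double* col = C.colptr(j);
    double s_pos = 0.0;
    for (uword i = 0; i < n; ++i) {
      if (col[i] > 0.0) s_pos += col[i];
    }
    if (s_pos < 1.0 - delta) {
      proj_simplex_inplace(col, n, 1.0 - delta, buf);
    } else if (s_pos > 1.0 + delta) {
      proj_simplex_inplace(col, n, 1.0 + delta, buf);
    } else {
      for (uword i = 0; i < n; ++i) {
        if (col[i] < 0.0) col[i] = 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List pcha_solve_cpp(const arma::mat& X, arma::mat C, arma::mat S,
                          double delta, double tol, int max_iter) {
  project_C(C, delta);
  project_S(S);

  mat XC = X * C;
  double obj = sse(X, XC, S);
  double muS = 1.0, muC = 1.0;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  trace.push_back(obj);

  const double xx = accu(square(X));
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double obj_prev = obj;

    // --- S step (gradient and objective in Gram form: cost independent
    // of d beyond the one-off B = XC'X) ---
    mat G = XC.t() * XC;          // k x k
    mat B = XC.t() * X;           // k x n
    mat gS = 2.0 * (G * S - B);   // = 2 XC'(XC S - X)
    muS *= 2.0;  // allow the step size to recover between iterations
    for (int ls = 0; ls < 20; ++ls) {
      mat S_try = S - muS * gS;
      project_S(S_try);
      double o = xx - 2.0 * accu(S_try % B) + accu((G * S_try) % S_try);
      if (o <= obj) {
        S = S_try;
        obj = o;
        break;
      }
      muS *= 0.5;
    }

    // --- C step ---
    mat R = XC * S - X;                 // d x n residual
    mat gC = 2.0 * X.t() * R * S.t();   // n x k
    muC *= 2.0;
    for (int ls = 0; ls < 20; ++ls) {
      mat C_try = C - muC * gC;
      project_C(C_try, delta);
      mat XC_try = X * C_try;
      double o = sse(X, XC_try, S);
      if (o <= obj) {
        C = C_try;
        XC = XC_try;
        obj = o;
        break;
      }
      muC *= 0.5;
    }

    trace.push_back(obj);
    double denom = obj_prev > 0.0 ? obj_prev : 1.0;
    if ((obj_prev - obj) / denom < tol) {
      converged = true;
      break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("C") = C,
      Rcpp::Named("S") = S,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("n_iter") = (it > max_iter ? max_iter : it),
      Rcpp::Named("converged") = converged);
}

// Given fixed archetypes Z (d x k), find the simplex-constrained weights S
// (k x n) minimizing ||X - Z S||_F^2. Used to describe held-out cells.
// [[Rcpp::export]]
arma::mat project_cells_cpp(const arma::mat& X, const arma::mat& Z,
                            double tol, int max_iter) {
  mat S(Z.n_cols, X.n_cols, fill::value(1.0 / Z.n_cols));
  const mat G = Z.t() * Z;
  const mat B = Z.t() * X;
  const double xx = accu(square(X));
  double obj = xx - 2.0 * accu(S % B) + accu((G * S) % S);
  double mu = 1.0;
  for (int it = 0; it < max_iter; ++it) {
    double obj_prev = obj;
    mat g = 2.0 * (G * S - B);
    mu *= 2.0;
    for (int ls = 0; ls < 20; ++ls) {
      mat S_try = S - mu * g;
      project_S(S_try);
      double o = xx - 2.0 * accu(S_try % B) + accu((G * S_try) % S_try);
      if (o <= obj) {
        S = S_try;
        obj = o;
        break;
      }
      mu *= 0.5;
    }
    double denom = std::abs(obj_prev) > 0.0 ? std::abs(obj_prev) : 1.0;
    if ((obj_prev - obj) / denom < tol) break;
  }
  return S;
}
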