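#' @useDynLib paretoscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Greedy max-min seeding: pick k well-spread cells to initialize archetypes.
furthest_sum_init <- function(X, k, start) {
  n <- ncol(X)
  chosen <- integer(k)
  chosen[1] <- start
  mindist <- sqrt(colSums((X - X[, start])^2))
  if (k > 1) {
    for (j in 2:k) {
      chosen[j] <- which.max(mindist)
      d <- sqrt(colSums((X - X[, chosen[j]])^2))
      mindist <- pmin(mindist, d)
    }
  }
  chosen
}

#' Fit a k-vertex polytope by principal convex hull analysis
#'
#' Solves the archetypal-analysis factorization
#' \eqn{\min_{C,S} \|X - XCS\|_F^2} with \eqn{S \ge 0}, columns of S summing
#' to 1, \eqn{C \ge 0}, and columns of C summing to a value in
#' \eqn{[1-\delta, 1+\delta]}. The archetypes \eqn{Z = XC} are weighted
#' averages of cells, so with \eqn{\delta = 0} they lie on or inside the data
#' convex hull; \eqn{\delta > 0} lets them move slightly outside. The solver
#' is a projected-gradient procedure with a monotone line search, restarted
#' from several greedy max-min seedings and keeping the best objective.
#'
#' @param mat ExpressionMatrix or cells x features matrix.
#' @param k number of archetypes (vertices), `2 <= k <= n_cells`.
#' @param delta hull relaxation; 0 for explained-variance and significance
#'   work, 0.5 for archetype characterization.
#' @param seed integer seed controlling initialization.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum projected-gradient iterations per restart.
#' @param n_restarts number of random restarts (best objective kept).
#' @param C0,S0 optional warm-start matrices (n x k and k x n); when given,
#'   restarts are skipped.
#' @return A `PolytopeFit`: list with `archetypes` (k x d), `C` (n x k),
#'   `S` (k x n), `delta`, `ev` (explained variance, per-point definition),
#'   `ev_sse`, `objective`, `n_iter`, `converged`, `k`, `seed`, and the
#'   per-iteration objective `trace` of the winning restart.
#' @export
pcha_fit <- function(mat, k, delta = 0, seed = 1L, tol = 1e-6,
                     max_iter = 2000L, n_restarts = 5L, C0 = NULL, S0 = NULL) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  n <- nrow(V); d <- ncol(V)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop(sprintf("k (%d) exceeds number of cells (%d)", k, n))
  if (!all(is.finite(V))) stop("data must be finite")
  if (all(apply(V, 2, stats::sd) == 0)) {
    stop("all-constant data: polytope geometry is degenerate")
  }
  X <- t(V)  # feature-major, d x n

  run_once <- function(C_init, S_init) {
    pcha_solve_cpp(X, C_init, S_init, delta, tol, as.integer(max_iter))
  }

  if (!is.null(C0)) {
    stopifnot(nrow(C0) == n, ncol(C0) == k)
    if (is.null(S0)) S0 <- matrix(1 / k, k, n)
    best <- run_once(C0, S0)
  } else {
    best <- NULL
    starts <- withr::with_seed(seed, sample.int(n, n_restarts, replace = TRUE))
    for (r in seq_len(n_restarts)) {
      idx <- furthest_sum_init(X, k, starts[r])
      C_init <- matrix(0, n, k)
      C_init[cbind(idx, seq_len(k))] <- 1
      S_init <- matrix(1 / k, k, n)
      fit <- run_once(C_init, S_init)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }

  # invariant: the line-searched objective never increases
  stopifnot(all(diff(best$trace) <= 1e-10 * (abs(best$trace[1]) + 1)))

  C <- best$C; S <- best$S
  Z <- t(X %*% C)  # k x d, rows are archetype positions

  # canonical ordering: project archetypes on the data's first two PCs
  sv <- svd(scale(V, center = TRUE, scale = FALSE), nu = 0, nv = min(2, d))
  proj <- Z %*% sv$v
  ord <- order(round(proj[, 1], 10), if (ncol(proj) > 1) round(proj[, 2], 10) else seq_len(k))
  Z <- Z[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  rownames(Z) <- rownames(S) <- colnames(C) <- paste0("A", seq_len(k))
  colnames(Z) <- mat$feature_ids

  fit <- structure(
    list(archetypes = Z, C = C, S = S, delta = delta, k = k,
         objective = best$objective, n_iter = best$n_iter,
         converged = best$converged, seed = seed, trace = best$trace),
    class = "PolytopeFit")
  fit$ev_sse <- explained_variance(mat, fit, "sse_ratio")
  fit$ev <- explained_variance(mat, fit, "as_printed")
  fit
}

#' @export
print.PolytopeFit <- function(x, ...) {
  cat(sprintf("PolytopeFit: k = %d archetypes in %d dims (delta = %g)\n",
              x$k, ncol(x$archetypes), x$delta))
  cat(sprintf("  EV = %.4f (per-point), %.4f (SSE ratio); %s in %d iterations\n",
              x$ev, x$ev_sse,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Explained variance of a polytope fit
#'
#' Two definitions are supported. `"as_printed"` is the per-point statistic
#' \deqn{EV = \frac{1}{N}\sum_n \left(1 - \frac{\|p_n - s_n\|}{\|p_n\|}\right)}
#' where \eqn{s_n} is the polytope reconstruction \eqn{(XCS)_n} of cell
#' \eqn{p_n}; `"sse_ratio"` is the conventional
#' \eqn{1 - \|X - XCS\|_F^2 / \|X\|_F^2} used internally by the optimizer.
#' Cells lying exactly at the origin are excluded from the per-point mean
#' (their relative error is undefined) with a warning.
#'
#' @param mat the ExpressionMatrix the fit was produced from.
#' @param fit a `PolytopeFit`.
#' @param definition `"as_printed"` or `"sse_ratio"`.
#' @return A scalar `<= 1`.
#' @export
explained_variance <- function(mat, fit,
                               definition = c("as_printed", "sse_ratio")) {
  definition <- match.arg(definition)
  mat <- as_expression_matrix(mat)
  V <- mat$values                       # n x d
  recon <- t(fit$S) %*% fit$archetypes  # n x d, (XCS)' with Z = XC
  if (definition == "sse_ratio") {
    return(1 - sum((V - recon)^2) / sum(V^2))
  }
  pn <- sqrt(rowSums(V^2))
  err <- sqrt(rowSums((V - recon)^2))
  zero <- pn == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) at the origin excluded from per-point EV", sum(zero)))
  }
  mean(1 - err[!zero] / pn[!zero])
}

#' Describe cells as convex mixtures of fixed archetypes
#'
#' Solves the simplex-constrained least-squares problem for S with the
#' archetype positions held fixed; used for describing held-out or
#' bootstrap-external cells.
#'
#' @param mat ExpressionMatrix or matrix (cells x features).
#' @param archetypes k x d archetype matrix.
#' @param tol,max_iter solver controls.
#' @return A k x n_cells weight matrix with nonnegative columns summing to 1.
#' @export
project_on_archetypes <- function(mat, archetypes, tol = 1e-8, max_iter = 500L) {
  V <- as.matrix(as_expression_matrix(mat)$values)
  project_cells_cpp(t(V), t(archetypes), tol, as.integer(max_iter))
}
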