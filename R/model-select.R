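# Choosing the number of archetypes: explained-variance curve with elbow
# detection, and effective data dimensionality by PCA against shuffled data.

# index of the elbow: the point most distant from the chord through the
# first and last points of the (k, ev) curve; ties -> smallest k
elbow_k <- function(k_values, ev) {
  stopifnot(length(k_values) == length(ev), length(ev) >= 2)
  p1 <- c(k_values[1], ev[1])
  p2 <- c(k_values[length(k_values)], ev[length(ev)])
  v <- p2 - p1
  v <- v / sqrt(sum(v^2))
  dists <- vapply(seq_along(ev), function(i) {
    w <- c(k_values[i], ev[i]) - p1
    sqrt(max(0, sum(w^2) - sum(w * v)^2))   # perpendicular distance
  }, numeric(1))
  list(k_star = k_values[which.max(round(dists, 12))], distances = dists)
}

#' Explained variance versus number of archetypes
#'
#' Fits a k-vertex polytope (delta = 0) for every k in `2..k_max` and
#' records the explained variance. The chosen number of archetypes `k_star`
#' is the elbow of the curve: the k whose (k, EV) point is most distant from
#' the straight line through the first (k = 2) and last (k = k_max) points;
#' ties resolve to the smallest k.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k_max largest k fitted (default 11).
#' @param seed integer seed for the fits.
#' @param definition EV definition passed to [explained_variance()].
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `ev_curve`: `k_values`, `ev`, `k_star`,
#'   `elbow_distances`, `converged`, `fits`.
#' @export
ev_curve <- function(mat, k_max = 11L, seed = 1L,
                     definition = c("as_printed", "sse_ratio"), ...) {
  definition <- match.arg(definition)
  if (k_max < 3) stop("k_max must be at least 3")
  mat <- as_expression_matrix(mat)
  ks <- 2:k_max
  fits <- lapply(ks, function(k) {
    pcha_fit(mat, k = k, delta = 0, seed = seed, ...)
  })
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(conv)) {
    warning("fits not converged for k = ", paste(ks[!conv], collapse = ", "))
  }
  ev <- vapply(fits, function(f) explained_variance(mat, f, definition), numeric(1))
  if (any(diff(ev) < -0.02)) {
    warning("EV decreased with k beyond optimizer noise; consider more restarts")
  }
  el <- elbow_k(ks, ev)
  structure(list(k_values = ks, ev = ev, k_star = el$k_star,
                 elbow_distances = el$distances, converged = conv,
                 definition = definition, fits = fits),
            class = "ev_curve")
}

#' @export
print.ev_curve <- function(x, ...) {
  cat("Explained variance by number of archetypes:\n")
  print(data.frame(k = x$k_values, ev = round(x$ev, 4),
                   elbow_dist = round(x$elbow_distances, 4)), row.names = FALSE)
  cat(sprintf("k* (elbow) = %d\n", x$k_star))
  invisible(x)
}

#' Shuffle each feature independently across cells
#'
#' Randomly permutes the values of each column separately, preserving every
#' feature's marginal distribution exactly while destroying correlations
#' between features. This is the null model for all shuffle-based tests.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param seed integer seed.
#' @return An `ExpressionMatrix` of the same shape, ids and modality.
#' @export
shuffle_matrix <- function(mat, seed = 1L) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  Vs <- withr::with_seed(seed, {
    apply(V, 2, sample)
  })
  dimnames(Vs) <- dimnames(V)
  expression_matrix(Vs, mat$cell_ids, mat$feature_ids, mat$modality,
                    centered = mat$centered)
}

#' Effective data dimensionality by PCA against shuffled data
#'
#' Compares the variance explained by each principal component of the real
#' (centered) data with the same quantity for column-shuffled data. The
#' estimated dimensionality D is the number of leading components whose
#' real explained variance stays above the shuffled mean plus one standard
#' deviation; D is (index of the first component falling below that
#' threshold) - 1. With `rule = "band"` a component already inside
#' mean +/- 1 SD terminates the count.
#'
#' @param mat centered ExpressionMatrix.
#' @param n_shuffles number of shuffled replicates (default 100; must be
#'   >= 2 for the SD to exist).
#' @param seed integer seed.
#' @param rule `"above"` (default: crossing below mean + 1 SD) or `"band"`
#'   (entering mean +/- 1 SD).
#' @return List of class `dimensionality_result`: `D`, `real_ev`,
#'   `shuffled_mean`, `shuffled_sd`, `significant` (the components above
#'   threshold), `n_shuffles`, `seed`.
#' @export
pca_dimensionality <- function(mat, n_shuffles = 100L, seed = 1L,
                               rule = c("above", "band")) {
  rule <- match.arg(rule)
  if (n_shuffles < 2) stop("n_shuffles must be at least 2 (SD undefined)")
  mat <- as_expression_matrix(mat)
  V <- mat$values
  if (!mat$centered) {
    V <- scale(V, center = TRUE, scale = FALSE)
  }
  comp_ev <- function(M) {
    d2 <- svd(M, nu = 0, nv = 0)$d^2
    d2 / sum(d2)
  }
  real_ev <- comp_ev(V)
  ncomp <- length(real_ev)
  null_ev <- vapply(seq_len(n_shuffles), function(i) {
    Vs <- shuffle_matrix(mat, seed = (seed + i) %% .Machine$integer.max)$values
    comp_ev(scale(Vs, center = TRUE, scale = FALSE))
  }, numeric(ncomp))
  mu <- rowMeans(null_ev)
  sdv <- apply(null_ev, 1, stats::sd)
  thresh_hi <- mu + sdv
  below <- if (rule == "above") {
    real_ev < thresh_hi
  } else {
    real_ev < thresh_hi & real_ev > mu - sdv
  }
  D <- if (any(below)) which(below)[1] - 1L else ncomp
  structure(list(D = as.integer(D), real_ev = real_ev, shuffled_mean = mu,
                 shuffled_sd = sdv, significant = real_ev > thresh_hi,
                 n_shuffles = as.integer(n_shuffles), seed = seed,
                 rule = rule),
            class = "dimensionality_result")
}

#' @export
print.dimensionality_result <- function(x, ...) {
  cat(sprintf("Effective dimensionality D = %d (%d shuffles, rule = %s)\n",
              x$D, x$n_shuffles, x$rule))
  invisible(x)
}
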