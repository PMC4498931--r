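# Convex-hull geometry: d-dimensional hull volume (beneath-beyond
# incremental algorithm), the t-ratio polytope-likeness statistic, and the
# distribution-uniformity ratio rho.

# hyperplane through d points (rows of P), oriented away from `inside`;
# returns list(normal, offset) with normal . x <= offset for the inside
facet_plane <- function(P, inside) {
  d <- ncol(P)
  A <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
  normal <- c(svd(A, nu = 0, nv = d)$v[, d])   # null vector of the spanning set
  offset <- sum(normal * P[1, ])
  if (sum(normal * inside) > offset) {
    normal <- -normal
    offset <- -offset
  }
  list(normal = normal, offset = offset)
}

#' Convex hull of a point set
#'
#' Beneath-beyond incremental construction of the convex hull of `n` points
#' in `d` dimensions (the hull must be full-dimensional). Returns the
#' simplicial facet list, outward facet normals and offsets, the hull
#' vertices, and the d-dimensional volume (facet-pyramid triangulation
#' around an interior point).
#'
#' @param points n x d numeric matrix, `n >= d + 1`, affinely spanning d
#'   dimensions.
#' @param tol relative degeneracy tolerance.
#' @return List of class `convex_hull` with elements `facets` (matrix of
#'   point indices, one row per simplicial facet), `normals`, `offsets`,
#'   `vertices` (indices of hull vertices), `volume`, `dim`, and `points`.
#' @export
convex_hull <- function(points, tol = 1e-9) {
  P <- as.matrix(points)
  n <- nrow(P); d <- ncol(P)
  if (n < d + 1) stop(sprintf("need at least %d points in %d dimensions", d + 1, d))
  ctr <- colMeans(P)
  scale_len <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)), 1e-300)
  eps <- tol * scale_len

  Pc <- sweep(P, 2, ctr)
  rank <- sum(svd(Pc, nu = 0, nv = 0)$d > tol * max(svd(Pc, nu = 0, nv = 0)$d, 1e-300))
  if (rank < d) {
    stop(sprintf("degenerate input: points span only %d of %d dimensions; project to rank dimensions first", rank, d))
  }

  if (d == 1) {
    lo <- which.min(P[, 1]); hi <- which.max(P[, 1])
    return(structure(list(facets = matrix(c(lo, hi), 2, 1),
                          normals = matrix(c(-1, 1), 2, 1),
                          offsets = c(-P[lo, 1], P[hi, 1]),
                          vertices = c(lo, hi),
                          volume = P[hi, 1] - P[lo, 1],
                          dim = 1L, points = P),
                     class = "convex_hull"))
  }

  # initial simplex: greedily pick affinely independent points
  idx <- which.max(rowSums(sweep(P, 2, ctr)^2))
  chosen <- idx
  for (j in 2:(d + 1)) {
    B <- sweep(P[chosen, , drop = FALSE], 2, P[chosen[1], ])
    # residual of every point against span of current difference vectors
    if (length(chosen) == 1) {
      res <- sweep(P, 2, P[chosen[1], ])
    } else {
      Q <- qr.Q(qr(t(B[-1, , drop = FALSE])))
      D <- sweep(P, 2, P[chosen[1], ])
      res <- D - D %*% Q %*% t(Q)
    }
    cand <- which.max(rowSums(res^2))
    if (rowSums(res^2)[cand] <= eps^2) stop("degenerate input: could not build initial simplex")
    chosen <- c(chosen, cand)
  }
  interior <- colMeans(P[chosen, , drop = FALSE])

  facets <- t(utils::combn(chosen, d))
  normals <- matrix(0, nrow(facets), d)
  offsets <- numeric(nrow(facets))
  for (f in seq_len(nrow(facets))) {
    pl <- facet_plane(P[facets[f, ], , drop = FALSE], interior)
    normals[f, ] <- pl$normal
    offsets[f] <- pl$offset
  }

  # insert remaining points, far points first
  rest <- setdiff(seq_len(n), chosen)
  rest <- rest[order(-rowSums(sweep(P[rest, , drop = FALSE], 2, interior)^2))]
  for (p in rest) {
    height <- drop(normals %*% P[p, ]) - offsets
    visible <- which(height > eps)
    if (!length(visible)) next
    # horizon ridges: (d-1)-subsets of visible facets seen exactly once
    ridge_keys <- character(0)
    ridge_rows <- list()
    for (f in visible) {
      vs <- facets[f, ]
      for (drop_i in seq_len(d)) {
        r <- sort(vs[-drop_i])
        ridge_keys <- c(ridge_keys, paste(r, collapse = "_"))
        ridge_rows[[length(ridge_rows) + 1L]] <- r
      }
    }
    tab <- table(ridge_keys)
    horizon <- ridge_rows[ridge_keys %in% names(tab)[tab == 1L]]
    keep <- setdiff(seq_len(nrow(facets)), visible)
    facets <- facets[keep, , drop = FALSE]
    normals <- normals[keep, , drop = FALSE]
    offsets <- offsets[keep]
    for (r in horizon) {
      newf <- c(r, p)
      pl <- facet_plane(P[newf, , drop = FALSE], interior)
      facets <- rbind(facets, newf)
      normals <- rbind(normals, pl$normal)
      offsets <- c(offsets, pl$offset)
    }
  }
  rownames(facets) <- NULL

  # volume: triangulate into pyramids over the interior point
  vol <- 0
  for (f in seq_len(nrow(facets))) {
    M <- sweep(P[facets[f, ], , drop = FALSE], 2, interior)
    vol <- vol + abs(det(M)) / factorial(d)
  }
  structure(list(facets = facets, normals = normals, offsets = offsets,
                 vertices = sort(unique(as.vector(facets))),
                 volume = vol, dim = as.integer(d), points = P,
                 interior = interior, eps = eps),
            class = "convex_hull")
}

#' Volume of the convex hull of a point set
#'
#' @param points n x d matrix affinely spanning d dimensions.
#' @return The d-dimensional Lebesgue volume.
#' @export
hull_volume <- function(points) convex_hull(points)$volume

#' Test points for membership in a convex hull
#'
#' @param hull a [convex_hull()] result.
#' @param x query points (m x d matrix or length-d vector).
#' @param tol boundary tolerance (absolute, on the hull's scale).
#' @return Logical vector of length m.
#' @export
in_hull <- function(hull, x, tol = hull$eps) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (hull$dim == 1) {
    return(x[, 1] >= -hull$offsets[1] - tol & x[, 1] <= hull$offsets[2] + tol)
  }
  H <- x %*% t(hull$normals)
  apply(sweep(H, 2, hull$offsets) <= tol, 1, all)
}

#' Uniform samples inside a convex hull
#'
#' Bounding-box rejection sampling against the hull's facet planes.
#'
#' @param hull a [convex_hull()] result.
#' @param n number of samples.
#' @return n x d matrix of points inside the hull.
#' @keywords internal
sample_in_hull <- function(hull, n) {
  P <- hull$points
  lo <- apply(P, 2, min); hi <- apply(P, 2, max)
  d <- hull$dim
  out <- matrix(NA_real_, 0, d)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- matrix(stats::runif(m * d, rep(lo, each = m), rep(hi, each = m)), m, d)
    out <- rbind(out, cand[in_hull(hull, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Volume of a simplex given its vertices
#'
#' @param Z k x (k-1) matrix of vertex coordinates.
#' @return The (k-1)-dimensional volume `|det(Z[-1,] - Z[1,])| / (k-1)!`.
#' @export
simplex_volume <- function(Z) {
  k <- nrow(Z)
  stopifnot(ncol(Z) == k - 1)
  abs(det(sweep(Z[-1, , drop = FALSE], 2, Z[1, ]))) / factorial(k - 1)
}

# project (centered) cell matrix on its first ncomp principal components
pc_scores <- function(V, ncomp) {
  Vc <- scale(V, center = TRUE, scale = FALSE)
  sv <- svd(Vc, nu = 0, nv = min(ncomp, ncol(Vc)))
  Vc %*% sv$v
}

#' t-ratio: volume of the best-fit polytope relative to the data hull
#'
#' Projects the cells to the space of their first k-1 principal components,
#' fits a k-vertex polytope there with delta = 0 (vertices on the data hull),
#' and returns the ratio of the polytope volume to the convex-hull volume of
#' the projected data. The ratio lies in (0, 1]; values near 1 mean the data
#' fills a k-vertex polytope (large t-ratio = more polytope-like). For k = 2
#' the "volumes" are segment lengths on the first principal axis.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k number of vertices (k >= 3 for a full polytope; k = 2 handled as
#'   a length ratio).
#' @param seed seed for the polytope fit.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `t_ratio` with `hull_volume`, `polytope_volume`,
#'   `ratio` and `dim` (= k - 1).
#' @export
t_ratio <- function(mat, k, seed = 1L, ...) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  dim_use <- k - 1
  Y <- pc_scores(V, dim_use)
  if (ncol(Y) < dim_use) {
    stop(sprintf("data has rank %d < k - 1 = %d", ncol(Y), dim_use))
  }
  fit <- pcha_fit(Y, k = k, delta = 0, seed = seed, ...)
  Z <- fit$archetypes
  pv <- tryCatch(simplex_volume(Z), error = function(e) 0)
  if (k == 2) {
    hv <- diff(range(Y[, 1]))
    pv <- abs(Z[2, 1] - Z[1, 1])
  } else {
    hv <- hull_volume(Y)
  }
  if (pv <= 0 || !is.finite(pv)) {
    warning("degenerate polytope (collinear archetypes): t-ratio set to 0")
    pv <- 0
  }
  structure(list(hull_volume = hv, polytope_volume = pv,
                 ratio = pv / hv, dim = as.integer(dim_use), fit = fit),
            class = "t_ratio")
}

#' Uniformity ratio rho of a cell cloud
#'
#' Measures how uniformly cells fill their convex hull. Cells are projected
#' to their first 3 principal components (or the data rank if lower, with a
#' warning); the hull volume V_hull is split into per-point spheres of
#' volume `V = V_hull / N`, and the local density at each point is the
#' number of other points within the radius of that sphere, divided by V.
#' `rho_L` is the mean local density of the data; `rho_U` is the same
#' statistic for N points sampled uniformly inside the hull, averaged over
#' `n_repeats` draws; `rho = rho_L / rho_U`. Uniform data gives rho near 1,
#' clumped or clustered data gives rho well above 1. The self-comparison to
#' uniform samples inside the same hull controls for edge effects.
#'
#' @param mat ExpressionMatrix or matrix (cells x features).
#' @param n_repeats uniform reference draws (default 10).
#' @param seed integer seed.
#' @param n_components dimensionality of the projection (default 3).
#' @return List of class `uniformity_result` with `rho`, `rho_L`, `rho_U`,
#'   `rho_U_sd`, `rho_U_samples`, `n_repeats`, `seed`.
#' @export
uniformity_rho <- function(mat, n_repeats = 10L, seed = 1L, n_components = 3L) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  if (nrow(V) < 20) stop("need at least 20 cells")
  Y <- pc_scores(V, n_components)
  rank <- sum(svd(scale(V, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d >
                1e-9 * nrow(V))
  if (rank < n_components) {
    warning(sprintf("data rank %d < %d: projecting to rank dimensions", rank, n_components))
    Y <- Y[, seq_len(rank), drop = FALSE]
  }
  d <- ncol(Y)
  N <- nrow(Y)
  hull <- convex_hull(Y)
  Vball <- hull$volume / N
  r <- (Vball * gamma(d / 2 + 1) / pi^(d / 2))^(1 / d)

  mean_local_density <- function(pts) {
    cnt <- count_neighbors(pts, r)
    mean(cnt) / Vball
  }
  rho_L <- mean_local_density(Y)
  rho_U_samples <- withr::with_seed(seed, {
    vapply(seq_len(n_repeats), function(i) {
      mean_local_density(sample_in_hull(hull, N))
    }, numeric(1))
  })
  rho_U <- mean(rho_U_samples)
  structure(list(rho = rho_L / rho_U, rho_L = rho_L, rho_U = rho_U,
                 rho_U_sd = stats::sd(rho_U_samples),
                 rho_U_samples = rho_U_samples,
                 n_repeats = as.integer(n_repeats), seed = seed,
                 radius = r, dim = d),
            class = "uniformity_result")
}

# number of other points within radius r of each point (chunked pairwise
# distances; excludes the focal point itself)
count_neighbors <- function(pts, r) {
  n <- nrow(pts)
  cnt <- integer(n)
  chunk <- max(1L, floor(2e6 / n))
  sq <- rowSums(pts^2)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    block <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, "+") - 2 * block %*% t(pts)
    cnt[i:j] <- rowSums(d2 <= r^2) - 1L   # exclude self
    i <- j + 1L
  }
  cnt
}
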