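# Bootstrap stability of archetype positions, archetype matching across
# fits, per-cell description stability versus clustering/PCA comparators,
# and the archetype-splitting tree.

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Match two archetype sets by optimal assignment
#'
#' Finds the permutation of the candidate archetypes minimizing the total
#' Euclidean distance to the reference (linear sum assignment; Hungarian
#' method via `clue` when available, exact permutation search otherwise).
#'
#' @param reference,candidate k x d archetype matrices.
#' @return Integer permutation `perm` such that `candidate[perm, ]` aligns
#'   with `reference`.
#' @export
match_archetypes <- function(reference, candidate) {
  reference <- as.matrix(reference); candidate <- as.matrix(candidate)
  k <- nrow(reference)
  if (nrow(candidate) != k || ncol(candidate) != ncol(reference)) {
    stop("reference and candidate must have the same dimensions")
  }
  cost <- as.matrix(stats::dist(rbind(reference, candidate)))[
    seq_len(k), k + seq_len(k), drop = FALSE]
  if (requireNamespace("clue", quietly = TRUE)) {
    as.integer(clue::solve_LSAP(cost))
  } else {
    if (k > 9) stop("exact assignment fallback limited to k <= 9; install 'clue'")
    perms <- all_permutations(k)
    costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(k), p)]),
                    numeric(1))
    perms[[which.min(costs)]]
  }
}

#' Bootstrap stability of archetype positions
#'
#' Resamples cells with replacement `n_boot` times, refits the polytope,
#' and matches each replicate's archetypes to the full-data fit, yielding
#' one "cloud" of positions per archetype. Each archetype's error is the
#' standard deviation of its cloud along the cloud's top three principal
#' axes, divided by the distance of the cloud center from the origin (the
#' data are assumed centered, so the origin is the grand mean profile).
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k number of archetypes.
#' @param delta hull relaxation.
#' @param n_boot bootstrap replicates (>= 100 recommended for error
#'   reporting; 1000 for reports).
#' @param seed integer seed.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `bootstrap_ensemble`: `positions` (n_boot x k x d
#'   array of matched archetypes), `errors` (k x 3 SDs along principal
#'   noise axes, normalized), `mean_error`, `fit`, `n_boot`, `seed`.
#' @export
bootstrap_archetypes <- function(mat, k, delta = 0, n_boot = 100L, seed = 1L,
                                 ...) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  n <- nrow(V); d <- ncol(V)
  fit <- pcha_fit(mat, k = k, delta = delta, seed = seed, ...)
  pos <- array(NA_real_, c(n_boot, k, d))
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (attempt in 0:1) {
      s_b <- (seed + b + attempt * 7368787L) %% .Machine$integer.max
      idx <- withr::with_seed(s_b, sample.int(n, n, replace = TRUE))
      bmat <- V[idx, , drop = FALSE]
      rownames(bmat) <- NULL   # resampling duplicates cell ids
      bfit <- tryCatch(
        pcha_fit(bmat, k = k, delta = delta, seed = s_b, ...),
        error = function(e) NULL)
      if (!is.null(bfit)) {
        perm <- match_archetypes(fit$archetypes, bfit$archetypes)
        pos[b, , ] <- bfit$archetypes[perm, , drop = FALSE]
        ok <- TRUE
        break
      }
    }
    if (!ok) warning(sprintf("bootstrap replicate %d failed and was dropped", b))
  }
  keep <- !is.na(pos[, 1, 1])
  pos <- pos[keep, , , drop = FALSE]
  errors <- matrix(NA_real_, k, 3,
                   dimnames = list(paste0("A", seq_len(k)),
                                   paste0("axis_", 1:3)))
  for (a in seq_len(k)) {
    cloud <- pos[, a, ]
    ctr <- colMeans(cloud)
    dev <- sweep(cloud, 2, ctr)
    sv <- svd(dev, nu = 0, nv = 0)$d / sqrt(max(1, nrow(cloud) - 1))
    sds <- c(sv, 0, 0, 0)[1:3]
    errors[a, ] <- sds / sqrt(sum(ctr^2))
  }
  structure(list(positions = pos, errors = errors,
                 mean_error = mean(errors), fit = fit,
                 n_boot = as.integer(sum(keep)), seed = seed),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d replicates, k = %d\n", x$n_boot,
              nrow(x$errors)))
  print(round(x$errors, 4))
  cat(sprintf("mean error = %.4f\n", x$mean_error))
  invisible(x)
}

# centroids of a clustering, and the per-cell centroid approximation
centroid_description <- function(train, assign_train, query) {
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(train)), assign_train),
                                     function(i) colMeans(train[i, , drop = FALSE])))
  d2 <- outer(rowSums(query^2), rowSums(centroids^2), "+") -
    2 * query %*% t(centroids)
  centroids[max.col(-d2), , drop = FALSE]
}

#' Per-cell description stability under bootstrapping
#'
#' Each method describes every original cell by an approximation rebuilt
#' from a bootstrap replicate: the convex combination of the replicate's
#' (matched) archetypes; the projection on the replicate's k-1 principal
#' components; or the centroid of the cluster the cell is assigned to
#' (k-means, average-linkage hierarchical, 2x2 self-organizing map). The
#' per-cell normalized SD is the total standard deviation of that
#' approximation across replicates divided by the norm of its mean; the
#' summary per method is the fraction of cells whose normalized SD exceeds
#' 0.3.
#'
#' @param mat ExpressionMatrix or matrix (centered).
#' @param k number of archetypes / clusters (PCA uses k-1 components).
#' @param n_boot bootstrap replicates.
#' @param methods subset of `c("archetypes", "pca", "kmeans",
#'   "hierarchical", "som")`.
#' @param seed integer seed.
#' @param sd_threshold threshold on the normalized SD (default 0.3).
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `description_stability`: `normalized_sd` (cells x
#'   methods), `fraction_unstable` (per method), `n_boot`.
#' @export
description_stability <- function(mat, k, n_boot = 100L,
                                  methods = c("archetypes", "pca", "kmeans",
                                              "hierarchical", "som"),
                                  seed = 1L, sd_threshold = 0.3, ...) {
  allowed <- c("archetypes", "pca", "kmeans", "hierarchical", "som")
  bad <- setdiff(methods, allowed)
  if (length(bad)) stop("unknown method label(s): ", paste(bad, collapse = ", "))
  if ("som" %in% methods && !requireNamespace("class", quietly = TRUE)) {
    stop("method 'som' needs the 'class' package")
  }
  mat <- as_expression_matrix(mat)
  V <- mat$values
  n <- nrow(V); d <- ncol(V)
  fit <- pcha_fit(mat, k = k, delta = 0, seed = seed, ...)
  refV <- scale(V, center = TRUE, scale = FALSE)
  ref_pcs <- svd(refV, nu = 0, nv = max(1, k - 1))$v

  approx <- lapply(methods, function(m) array(NA_real_, c(n_boot, n, d)))
  names(approx) <- methods
  for (b in seq_len(n_boot)) {
    s_b <- (seed + b) %% .Machine$integer.max
    idx <- withr::with_seed(s_b, sample.int(n, n, replace = TRUE))
    B <- V[idx, , drop = FALSE]
    rownames(B) <- NULL   # resampling duplicates cell ids
    for (m in methods) {
      approx[[m]][b, , ] <- switch(
        m,
        archetypes = {
          bfit <- pcha_fit(B, k = k, delta = 0, seed = s_b, ...)
          perm <- match_archetypes(fit$archetypes, bfit$archetypes)
          Z <- bfit$archetypes[perm, , drop = FALSE]
          t(project_on_archetypes(V, Z)) %*% Z
        },
        pca = {
          Bc <- scale(B, center = TRUE, scale = FALSE)
          W <- svd(Bc, nu = 0, nv = max(1, k - 1))$v
          # align component signs to the reference axes
          sgn <- sign(diag(crossprod(W, ref_pcs)))
          sgn[sgn == 0] <- 1
          W <- sweep(W, 2, sgn, "*")
          ctr <- attr(Bc, "scaled:center")
          Q <- sweep(V, 2, ctr)
          sweep(Q %*% W %*% t(W), 2, ctr, "+")
        },
        kmeans = {
          km <- withr::with_seed(s_b, stats::kmeans(B, centers = k,
                                                    nstart = 5, iter.max = 50))
          centroid_description(B, km$cluster, V)
        },
        hierarchical = {
          hc <- stats::hclust(stats::dist(B), method = "average")
          centroid_description(B, stats::cutree(hc, k = k), V)
        },
        som = {
          sm <- withr::with_seed(s_b, class::batchSOM(
            B, grid = class::somgrid(2, 2, "rectangular"), radii = c(2, 1, 0)))
          d2 <- outer(rowSums(V^2), rowSums(sm$codes^2), "+") -
            2 * V %*% t(sm$codes)
          sm$codes[max.col(-d2), , drop = FALSE]
        })
    }
  }
  nsd <- vapply(methods, function(m) {
    A <- approx[[m]]
    vapply(seq_len(n), function(i) {
      Ai <- A[, i, , drop = TRUE]
      if (is.null(dim(Ai))) Ai <- matrix(Ai, nrow = n_boot)
      mu <- colMeans(Ai)
      total_sd <- sqrt(sum(apply(Ai, 2, stats::var)))
      total_sd / sqrt(sum(mu^2))
    }, numeric(1))
  }, numeric(n))
  frac <- colMeans(nsd > sd_threshold)
  structure(list(normalized_sd = nsd, fraction_unstable = frac,
                 n_boot = as.integer(n_boot), sd_threshold = sd_threshold,
                 fit = fit),
            class = "description_stability")
}

#' Archetype splitting tree across polytope orders
#'
#' Fits polytopes for `k = k_min..k_max` and assigns every level-k
#' archetype to its nearest archetype at level k-1 (Euclidean distance in
#' the full feature space), tracing how archetypes split as the polytope
#' order grows.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k_min,k_max smallest and largest polytope order (`k_min >= 2`).
#' @param delta hull relaxation.
#' @param seed integer seed.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `archetype_tree`: per level, `archetypes`,
#'   `parent` (index at the previous level; NA for the first level) and
#'   `parent_distance`.
#' @export
archetype_tree <- function(mat, k_min = 2L, k_max = 6L, delta = 0,
                           seed = 1L, ...) {
  if (k_min < 2) stop("k_min must be at least 2")
  stopifnot(k_max >= k_min)
  mat <- as_expression_matrix(mat)
  levels <- list()
  prev <- NULL
  for (k in k_min:k_max) {
    fit <- pcha_fit(mat, k = k, delta = delta, seed = seed, ...)
    Z <- fit$archetypes
    if (is.null(prev)) {
      parent <- rep(NA_integer_, k)
      pd <- rep(NA_real_, k)
    } else {
      d2 <- outer(rowSums(Z^2), rowSums(prev^2), "+") - 2 * Z %*% t(prev)
      parent <- max.col(-d2)
      pd <- sqrt(pmax(0, d2[cbind(seq_len(k), parent)]))
    }
    levels[[paste0("k", k)]] <- list(archetypes = Z, parent = parent,
                                     parent_distance = pd, fit = fit)
    prev <- Z
  }
  structure(list(levels = levels, k_min = as.integer(k_min),
                 k_max = as.integer(k_max)),
            class = "archetype_tree")
}
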