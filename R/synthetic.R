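# Synthetic datasets with the geometric structure the method assumes:
# cells as Dirichlet mixtures of k archetypes embedded in high dimension,
# isotropic additive noise, optional planted archetype-enriched features
# and gene sets, and a clumping knob (the Dirichlet concentration).

#' Vertices of a regular simplex
#'
#' k mutually equidistant points (unit edge) in k-1 dimensions, centered at
#' the origin, optionally padded with zeros to `ambient_dim` columns.
#'
#' @param k number of vertices.
#' @param ambient_dim embedding dimension (`>= k - 1`).
#' @return A k x ambient_dim matrix.
#' @export
regular_simplex <- function(k, ambient_dim = k - 1) {
  stopifnot(k >= 2, ambient_dim >= k - 1)
  D <- matrix(1, k, k) - diag(k)
  Z <- stats::cmdscale(D, k = k - 1)
  Z <- cbind(Z, matrix(0, k, ambient_dim - (k - 1)))
  dimnames(Z) <- list(NULL, paste0("dim_", seq_len(ambient_dim)))
  Z
}

#' Specification of a synthetic polytope dataset
#'
#' @param k number of archetypes.
#' @param ambient_dim number of geometry coordinates the polytope is
#'   embedded in (`k - 1 <= ambient_dim`); coordinates beyond k-1 carry only
#'   noise.
#' @param n_cells number of cells.
#' @param archetypes optional k x ambient_dim matrix; default is a regular
#'   simplex with unit edge length.
#' @param alpha Dirichlet concentration of the archetype weights: 1 samples
#'   uniformly over the polytope, values well below 1 clump cells near the
#'   vertices, large values concentrate them in the middle.
#' @param noise_sd SD of isotropic additive Gaussian noise on the geometry
#'   coordinates, in units of the (unit) edge length. Default 0: cells are
#'   sampled exactly inside the polytope.
#' @param n_noise_features number of additional pure-noise features appended
#'   to the geometry coordinates.
#' @param feature_noise_sd SD of the appended noise features and of the
#'   noise on planted enriched features.
#' @param enriched_plan optional data.frame with columns `feature` (name),
#'   `archetype` (index) and `effect` (peak height): each planted feature is
#'   a linearly decreasing function of the distance to its target archetype,
#'   `effect * (1 - d / max(d))`, plus `feature_noise_sd` noise.
#' @param gene_set_plan optional named list of character vectors (feature
#'   names) defining gene sets over planted/noise features.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(k = 4L, ambient_dim = 3L, n_cells = 400L,
                           archetypes = NULL, alpha = 1, noise_sd = 0,
                           n_noise_features = 0L, feature_noise_sd = 0.3,
                           enriched_plan = NULL, gene_set_plan = NULL,
                           seed = 1L) {
  stopifnot(k >= 2, ambient_dim >= k - 1, n_cells >= k, alpha > 0,
            noise_sd >= 0)
  if (is.null(archetypes)) archetypes <- regular_simplex(k, ambient_dim)
  archetypes <- as.matrix(archetypes)
  stopifnot(nrow(archetypes) == k, ncol(archetypes) == ambient_dim)
  if (qr(sweep(archetypes[-1, , drop = FALSE], 2, archetypes[1, ]))$rank < k - 1) {
    stop("archetypes are affinely dependent")
  }
  structure(list(k = as.integer(k), ambient_dim = as.integer(ambient_dim),
                 n_cells = as.integer(n_cells), archetypes = archetypes,
                 alpha = alpha, noise_sd = noise_sd,
                 n_noise_features = as.integer(n_noise_features),
                 feature_noise_sd = feature_noise_sd,
                 enriched_plan = enriched_plan,
                 gene_set_plan = gene_set_plan, seed = as.integer(seed)),
            class = "synthetic_spec")
}

rdirichlet <- function(n, alpha, k) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
  zero <- rowSums(g) == 0      # possible underflow at very small alpha
  if (any(zero)) {
    g[zero, ] <- t(vapply(which(zero), function(i) {
      v <- numeric(k); v[sample.int(k, 1)] <- 1; v
    }, numeric(k)))
  }
  g / rowSums(g)
}

#' Sample cells in and near a k-vertex polytope
#'
#' Cells are `W %*% Z + noise` with rows of W drawn from a symmetric
#' Dirichlet(alpha) over the archetypes and isotropic Gaussian noise on the
#' geometry coordinates. Planted enriched features decrease linearly with
#' distance to their target archetype; optional pure-noise features are
#' appended. All features are mean-centered.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `matrix` (centered `ExpressionMatrix`), `archetypes`
#'   (the true k x d geometry vertices), `weights` (n x k Dirichlet
#'   weights), `enriched_plan`, `gene_sets`.
#' @export
sample_polytope <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  k <- spec$k; n <- spec$n_cells; Z <- spec$archetypes
  out <- withr::with_seed(spec$seed, {
    W <- rdirichlet(n, spec$alpha, k)
    G <- W %*% Z
    X <- G + matrix(stats::rnorm(n * ncol(Z), 0, spec$noise_sd), n)
    colnames(X) <- paste0("dim_", seq_len(ncol(Z)))
    plan <- spec$enriched_plan
    if (!is.null(plan)) {
      planted <- vapply(seq_len(nrow(plan)), function(j) {
        a <- plan$archetype[j]
        d <- sqrt(rowSums(sweep(G, 2, Z[a, ])^2))
        plan$effect[j] * (1 - d / max(d)) +
          stats::rnorm(n, 0, spec$feature_noise_sd)
      }, numeric(n))
      colnames(planted) <- plan$feature
      X <- cbind(X, planted)
    }
    if (spec$n_noise_features > 0) {
      noise <- matrix(stats::rnorm(n * spec$n_noise_features, 0,
                                   spec$feature_noise_sd),
                      n, spec$n_noise_features)
      colnames(noise) <- paste0("noise_", seq_len(spec$n_noise_features))
      X <- cbind(X, noise)
    }
    list(X = X, W = W)
  })
  em <- center_features(expression_matrix(out$X, modality = "generic"))
  list(matrix = em, archetypes = Z, weights = out$W,
       enriched_plan = spec$enriched_plan, gene_sets = spec$gene_set_plan)
}

#' Sample vertex-clumped cells
#'
#' Convenience wrapper around [sample_polytope()] with the Dirichlet
#' concentration pushed far below 1, producing clouds concentrated at the
#' polytope vertices (the discrete-cell-type regime; uniformity ratio
#' rho well above 1).
#'
#' @param spec a [synthetic_spec()].
#' @param cluster_sd spread of each vertex cloud (overrides `noise_sd`).
#' @param alpha Dirichlet concentration (default 0.05).
#' @return As [sample_polytope()].
#' @export
sample_clustered <- function(spec, cluster_sd = 0.05, alpha = 0.05) {
  stopifnot(cluster_sd > 0)
  spec$alpha <- alpha
  spec$noise_sd <- cluster_sd
  sample_polytope(spec)
}

#' Canonical enrichment benchmark dataset
#'
#' A tetrahedron dataset with planted archetype-enriched features, used to
#' measure recovery of the leave-one-out enrichment test: `n_enriched`
#' features (cycled over the k archetypes) plus pure-noise features filling
#' up to `n_features` total columns (including the k-1 geometry
#' coordinates embedded in `ambient_dim` dims).
#'
#' @param n_cells number of cells.
#' @param n_features total feature count.
#' @param k archetypes.
#' @param ambient_dim geometry coordinates.
#' @param n_enriched number of planted enriched features.
#' @param effect peak effect size of planted features (edge-length units).
#' @param feature_noise_sd noise SD of planted and decoy features.
#' @param seed integer seed.
#' @return As [sample_polytope()].
#' @export
sample_enrichment_dataset <- function(n_cells = 400L, n_features = 60L,
                                      k = 4L, ambient_dim = 8L,
                                      n_enriched = 40L, effect = 1,
                                      feature_noise_sd = 0.3, seed = 1L) {
  stopifnot(n_features > ambient_dim + n_enriched)
  plan <- data.frame(
    feature = paste0("planted_", seq_len(n_enriched)),
    archetype = rep_len(seq_len(k), n_enriched),
    effect = effect)
  spec <- synthetic_spec(
    k = k, ambient_dim = ambient_dim, n_cells = n_cells,
    noise_sd = 0.02, n_noise_features = n_features - ambient_dim - n_enriched,
    feature_noise_sd = feature_noise_sd, enriched_plan = plan, seed = seed)
  sample_polytope(spec)
}
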