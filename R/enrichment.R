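# Archetype characterization: leave-one-out 1D binned enrichment per
# feature, 2D kernel-smoothed enrichment maps, and gene-set enrichment
# with BH-FDR and bootstrap robustness.

#' Equal-mass bins by distance
#'
#' Sorts cells by distance (stable: ties break by cell index) and splits
#' them into `n_bins` contiguous groups whose sizes differ by at most one;
#' when the cell count is not divisible, the larger bins come first. Bin 1
#' holds the closest cells.
#'
#' @param distances numeric vector of distances.
#' @param n_bins number of bins (`>= 2`, `<= length(distances)`).
#' @return Integer vector of bin assignments (1 = closest).
#' @export
equal_mass_bins <- function(distances, n_bins) {
  n <- length(distances)
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (n_bins > n) stop("n_bins exceeds number of cells")
  ord <- order(distances, seq_len(n))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

# one-sided (greater) rank-sum p for bin-1 expression vs the rest;
# alternative comparisons exposed for sensitivity checks
bin_rank_test <- function(expr, bins, sided = c("greater", "two.sided"),
                          comparison = c("pooled", "per_bin")) {
  sided <- match.arg(sided)
  comparison <- match.arg(comparison)
  x <- expr[bins == 1]
  if (stats::sd(expr) == 0) return(1)
  if (comparison == "pooled") {
    y <- expr[bins != 1]
    stats::wilcox.test(x, y, alternative = sided, exact = FALSE,
                       correct = TRUE)$p.value
  } else {
    ps <- vapply(setdiff(sort(unique(bins)), 1L), function(b) {
      stats::wilcox.test(x, expr[bins == b], alternative = sided,
                         exact = FALSE, correct = TRUE)$p.value
    }, numeric(1))
    max(ps)   # must beat every other bin
  }
}

#' Leave-one-out 1D enrichment of features at archetypes
#'
#' For each feature, the archetypes are recomputed on the data without that
#' feature (warm-started from the full fit to suppress restart noise), the
#' cells are divided into equal-mass bins by Euclidean distance from each
#' archetype in the reduced feature space, and the feature is called
#' enriched at an archetype when its mean expression is maximal in the
#' closest bin and the one-sided Wilcoxon rank-sum test (closest bin versus
#' all remaining cells) beats `p_threshold`. Removing one feature moves the
#' archetypes very little; the relative displacement is recorded per
#' feature.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k number of archetypes.
#' @param delta hull relaxation for the characterization fit (default 0.5).
#' @param n_bins number of equal-mass bins (default 10).
#' @param p_threshold significance threshold (default 0.001).
#' @param seed integer seed for the full fit.
#' @param sided,comparison rank-sum variants (see Details in the vignette).
#' @param fit optional precomputed full-data `PolytopeFit` to warm-start
#'   from.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `enrichment_table`: `table` (one row per feature x
#'   archetype with bin means, maximality flag, p-value and significance),
#'   `displacement` (per-feature relative archetype displacement), `fit`,
#'   `n_bins`, `threshold`.
#' @export
enrich_1d <- function(mat, k, delta = 0.5, n_bins = 10L, p_threshold = 0.001,
                      seed = 1L, sided = "greater", comparison = "pooled",
                      fit = NULL, ...) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  n <- nrow(V); d <- ncol(V)
  if (is.null(fit)) fit <- pcha_fit(mat, k = k, delta = delta, seed = seed, ...)
  scale_len <- mean(stats::dist(fit$archetypes))
  rows <- vector("list", d * k)
  displacement <- numeric(d)
  for (g in seq_len(d)) {
    Vg <- V[, -g, drop = FALSE]
    loo <- pcha_fit(Vg, k = k, delta = delta, seed = seed,
                    C0 = fit$C, S0 = fit$S, ...)
    perm <- match_archetypes(fit$archetypes[, -g, drop = FALSE], loo$archetypes)
    Zg <- loo$archetypes[perm, , drop = FALSE]
    displacement[g] <- mean(sqrt(rowSums(
      (Zg - fit$archetypes[, -g, drop = FALSE])^2))) / scale_len
    for (a in seq_len(k)) {
      dist_a <- sqrt(rowSums(sweep(Vg, 2, Zg[a, ])^2))
      bins <- equal_mass_bins(dist_a, n_bins)
      bm <- vapply(seq_len(n_bins), function(b) mean(V[bins == b, g]),
                   numeric(1))
      maximal <- which.max(bm) == 1L
      p <- bin_rank_test(V[, g], bins, sided, comparison)
      rows[[(g - 1) * k + a]] <- data.frame(
        feature = mat$feature_ids[g], archetype = a,
        t(stats::setNames(bm, paste0("bin_", seq_len(n_bins)))),
        first_bin_maximal = maximal, p_value = p,
        significant = maximal && p < p_threshold)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 displacement = stats::setNames(displacement, mat$feature_ids),
                 fit = fit, n_bins = as.integer(n_bins),
                 threshold = p_threshold),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  sig <- x$table[x$table$significant, c("feature", "archetype", "p_value")]
  cat(sprintf("Enrichment: %d significant (feature, archetype) pairs at p < %g, %d bins\n",
              nrow(sig), x$threshold, x$n_bins))
  if (nrow(sig)) print(utils::head(sig, 20), row.names = FALSE)
  invisible(x)
}

#' Mean relative archetype displacement upon leave-one-out
#'
#' Averages, over removed features and archetypes, the archetype shift
#' caused by removing one feature, in units of the mean pairwise archetype
#' distance of the full fit.
#'
#' @param table an [enrich_1d()] result.
#' @return A scalar (e.g. 0.0002 means 0.02%).
#' @export
loo_displacement_summary <- function(table) {
  stopifnot(inherits(table, "enrichment_table"))
  mean(table$displacement)
}

#' 2D kernel-smoothed enrichment map of one feature
#'
#' Removes the feature, recomputes PCA and the archetypes without it,
#' projects cells to the first two principal components, and smooths the
#' feature's expression over that plane with an anisotropic Gaussian kernel
#' whose per-axis bandwidths follow Silverman's rule of thumb,
#' `h_j = (4 sigma_j^5 / (3N))^{1/5}`. The smoothed map is multiplied by a
#' Hill function of the kernel density, `D^hn / (hk^hn + D^hn)` (defaults
#' hk = 8, hn = 2), suppressing spurious values where points are sparse.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param feature feature id (or column index) to map.
#' @param k number of archetypes.
#' @param delta hull relaxation for the archetype recomputation.
#' @param grid_size points per axis of the evaluation grid (default 200).
#' @param hill_k,hill_n Hill-function coefficients.
#' @param seed integer seed.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `density2d`: `grid_x`, `grid_y`, `M` (matrix of
#'   smoothed values), `bandwidths`, `argmax` (x, y of the maximum),
#'   `archetypes_2d` (archetypes projected on the same plane),
#'   `argmax_archetype_dist` (distance from the argmax to each archetype).
#' @export
enrich_2d <- function(mat, feature, k, delta = 0.5, grid_size = 200L,
                      hill_k = 8, hill_n = 2, seed = 1L, ...) {
  mat <- as_expression_matrix(mat)
  g <- if (is.character(feature)) match(feature, mat$feature_ids) else feature
  if (is.na(g)) stop("feature not found: ", feature)
  V <- mat$values
  N <- nrow(V)
  if (N < 3) stop("need at least 3 cells for a bandwidth")
  m_vals <- V[, g]
  Vg <- scale(V[, -g, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(Vg, nu = 0, nv = 2)
  XY <- Vg %*% sv$v
  fitg <- pcha_fit(Vg, k = k, delta = delta, seed = seed, ...)
  arch2d <- fitg$archetypes %*% sv$v

  h <- vapply(1:2, function(j) {
    s <- stats::sd(XY[, j])
    (4 * s^5 / (3 * N))^(1 / 5)
  }, numeric(1))

  pad <- h
  gx <- seq(min(XY[, 1]) - pad[1], max(XY[, 1]) + pad[1], length.out = grid_size)
  gy <- seq(min(XY[, 2]) - pad[2], max(XY[, 2]) + pad[2], length.out = grid_size)
  grid <- as.matrix(expand.grid(x = gx, y = gy))

  M <- numeric(nrow(grid))
  Dens <- numeric(nrow(grid))
  chunk <- max(1L, floor(4e6 / N))
  i <- 1L
  while (i <= nrow(grid)) {
    j <- min(i + chunk - 1L, nrow(grid))
    G <- grid[i:j, , drop = FALSE]
    K <- exp(-0.5 * (outer(G[, 1], XY[, 1], "-")^2 / h[1]^2 +
                       outer(G[, 2], XY[, 2], "-")^2 / h[2]^2))
    Dsum <- rowSums(K)
    M[i:j] <- (K %*% m_vals) / pmax(Dsum, .Machine$double.xmin)
    Dens[i:j] <- Dsum
    i <- j + 1L
  }
  M <- M * Dens^hill_n / (hill_k^hill_n + Dens^hill_n)
  Mmat <- matrix(M, grid_size, grid_size)   # rows follow gx, cols gy
  am <- grid[which.max(M), ]
  structure(list(grid_x = gx, grid_y = gy, M = Mmat,
                 bandwidths = h, hill_k = hill_k, hill_n = hill_n,
                 argmax = am, archetypes_2d = arch2d,
                 argmax_archetype_dist =
                   sqrt(rowSums(sweep(arch2d, 2, am)^2))),
            class = "density2d")
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then gene symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- lapply(lines, function(x) x[-(1:2)])
    names(sets) <- vapply(lines, `[[`, character(1), 1)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# per-archetype first-bin-maximal + rank-sum p for a matrix of per-cell
# scores, given archetype positions; returns data.frame rows
score_enrichment <- function(scores, V, Z, n_bins, sided, comparison) {
  k <- nrow(Z)
  out <- list()
  for (a in seq_len(k)) {
    dist_a <- sqrt(rowSums(sweep(V, 2, Z[a, ])^2))
    bins <- equal_mass_bins(dist_a, n_bins)
    for (s in colnames(scores)) {
      bm <- vapply(seq_len(n_bins), function(b) mean(scores[bins == b, s]),
                   numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        set = s, archetype = a,
        first_bin_maximal = which.max(bm) == 1L,
        p_value = bin_rank_test(scores[, s], bins, sided, comparison))
    }
  }
  do.call(rbind, out)
}

#' Gene-set enrichment at archetypes with bootstrap robustness
#'
#' Scores each gene set per cell as the mean centered expression of its
#' measured genes, tests first-bin maximality and the one-sided rank-sum
#' statistic per archetype, and controls the FDR across all (set,
#' archetype) pairs with Benjamini-Hochberg at `fdr_q`. A set is reported
#' only if it is significant at the same archetype in at least
#' `robustness_frac` of `n_boot` bootstrap refits (cells resampled with
#' replacement, archetypes recomputed and matched back).
#'
#' @param mat ExpressionMatrix or matrix (centered expression).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param k number of archetypes.
#' @param delta hull relaxation (default 0.5).
#' @param n_bins equal-mass bins (default 10).
#' @param fdr_q BH false-discovery-rate threshold (default 0.1).
#' @param n_boot bootstrap replicates (default 100).
#' @param robustness_frac required fraction of bootstraps (default 0.8).
#' @param seed integer seed.
#' @param ... further arguments to [pcha_fit()].
#' @return List of class `gene_set_enrichment`: `table` (set x archetype
#'   with p, BH-adjusted p, significance and bootstrap support),
#'   `reported` (rows passing both filters), `fit`.
#' @export
enrich_gene_sets <- function(mat, gene_sets, k, delta = 0.5, n_bins = 10L,
                             fdr_q = 0.1, n_boot = 100L,
                             robustness_frac = 0.8, seed = 1L, ...) {
  mat <- as_expression_matrix(mat)
  V <- mat$values
  measured <- lapply(gene_sets, intersect, y = mat$feature_ids)
  empty <- lengths(measured) == 0
  if (any(empty)) {
    warning("sets with no measured genes excluded: ",
            paste(names(measured)[empty], collapse = ", "))
    measured <- measured[!empty]
  }
  if (anyDuplicated(names(measured))) stop("duplicate set names")
  if (!length(measured)) stop("no gene set intersects the measured features")
  Vc <- scale(V, center = TRUE, scale = FALSE)
  scores <- vapply(measured, function(genes) {
    rowMeans(Vc[, genes, drop = FALSE])
  }, numeric(nrow(V)))

  fit <- pcha_fit(mat, k = k, delta = delta, seed = seed, ...)
  full <- score_enrichment(scores, V, fit$archetypes, n_bins,
                           "greater", "pooled")
  full$p_adjusted <- stats::p.adjust(full$p_value, "BH")
  full$significant <- full$first_bin_maximal & full$p_adjusted < fdr_q

  support <- matrix(0, nrow(full), 1)
  boot_hits <- numeric(nrow(full))
  n <- nrow(V)
  for (b in seq_len(n_boot)) {
    idx <- withr::with_seed((seed + b) %% .Machine$integer.max,
                            sample.int(n, n, replace = TRUE))
    bmat <- V[idx, , drop = FALSE]
    rownames(bmat) <- NULL   # resampling duplicates cell ids
    bfit <- tryCatch(
      pcha_fit(bmat, k = k, delta = delta,
               seed = (seed + b) %% .Machine$integer.max, ...),
      error = function(e) NULL)
    if (is.null(bfit)) next
    perm <- match_archetypes(fit$archetypes, bfit$archetypes)
    Zb <- bfit$archetypes[perm, , drop = FALSE]
    bt <- score_enrichment(scores, V, Zb, n_bins, "greater", "pooled")
    bt$p_adjusted <- stats::p.adjust(bt$p_value, "BH")
    hit <- bt$first_bin_maximal & bt$p_adjusted < fdr_q
    boot_hits <- boot_hits + as.numeric(hit)
  }
  full$bootstrap_support <- boot_hits / n_boot
  full$reported <- full$significant & full$bootstrap_support >= robustness_frac
  structure(list(table = full, reported = full[full$reported, ],
                 fit = fit, n_boot = as.integer(n_boot),
                 fdr_q = fdr_q, robustness_frac = robustness_frac),
            class = "gene_set_enrichment")
}

#' @export
print.gene_set_enrichment <- function(x, ...) {
  cat(sprintf("Gene-set enrichment: %d reported (FDR < %g in >= %g%% of %d bootstraps)\n",
              nrow(x$reported), x$fdr_q, 100 * x$robustness_frac, x$n_boot))
  if (nrow(x$reported)) {
    print(x$reported[, c("set", "archetype", "p_adjusted", "bootstrap_support")],
          row.names = FALSE)
  }
  invisible(x)
}
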