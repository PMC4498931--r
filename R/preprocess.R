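#' Preprocessing configuration
#'
#' Collects the modality-specific normalization thresholds in one place.
#'
#' @param ct_ceiling detection ceiling for qPCR Ct values; undetected entries
#'   (Ct above the ceiling, or missing) are set to this value before the
#'   (ceiling - Ct) flip. Default 30 cycles.
#' @param cell_drop_fraction fraction of lowest-total cells removed by
#'   [filter_low_expression()]. Default 0.10.
#' @param feature_drop_fraction fraction of lowest-total features removed.
#'   Default 0.10.
#' @param arcsinh_cofactor cofactor of the hyperbolic-arcsine transform for
#'   mass cytometry ion counts. Default 5.
#' @param downsample_target target molecule count N per cell for RNA-Seq
#'   downsampling. Default 400.
#' @param n_top_variable_genes number of highest-SD genes retained for sparse
#'   RNA-Seq matrices. Default 500.
#' @param rng_seed integer seed for stochastic steps.
#' @return A list of class `PreprocessConfig`.
#' @export
preprocess_config <- function(ct_ceiling = 30, cell_drop_fraction = 0.10,
                              feature_drop_fraction = 0.10,
                              arcsinh_cofactor = 5, downsample_target = 400L,
                              n_top_variable_genes = 500L, rng_seed = 1L) {
  stopifnot(ct_ceiling > 0,
            cell_drop_fraction >= 0, cell_drop_fraction < 0.5,
            feature_drop_fraction >= 0, feature_drop_fraction < 0.5,
            arcsinh_cofactor > 0,
            downsample_target >= 1, n_top_variable_genes >= 1)
  structure(list(ct_ceiling = ct_ceiling,
                 cell_drop_fraction = cell_drop_fraction,
                 feature_drop_fraction = feature_drop_fraction,
                 arcsinh_cofactor = arcsinh_cofactor,
                 downsample_target = as.integer(downsample_target),
                 n_top_variable_genes = as.integer(n_top_variable_genes),
                 rng_seed = as.integer(rng_seed)),
            class = "PreprocessConfig")
}

#' Normalize a single-cell qPCR Ct matrix
#'
#' Ct (cycle threshold) readouts are logarithmic in transcript abundance,
#' with larger Ct meaning lower expression and undetected transcripts encoded
#' as Ct far above the detection ceiling (e.g. 40 or 999) or missing. Every
#' entry above `ct_ceiling` (and every missing entry) is set to the ceiling,
#' the matrix is flipped to `ct_ceiling - Ct` so that zero marks the
#' detection limit, and each feature is mean-centered.
#'
#' @param raw_ct numeric matrix of Ct values, cells x features.
#' @param config a [preprocess_config()].
#' @return A centered `ExpressionMatrix` with `modality = "qpcr"`; the
#'   pre-centering `(ceiling - Ct)` values are kept in the `precenter` field
#'   so that expression totals remain available for filtering.
#' @export
normalize_qpcr <- function(raw_ct, config = preprocess_config()) {
  m <- as.matrix(raw_ct)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric Ct value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stop(sprintf("negative Ct value at row %d, column %d", bad[1, 1], bad[1, 2]))
  }
  ceil <- config$ct_ceiling
  m[is.na(m) | m > ceil] <- ceil      # undetected -> detection limit
  flipped <- ceil - m
  em <- expression_matrix(flipped,
                          cell_ids = rownames(raw_ct),
                          feature_ids = colnames(raw_ct),
                          modality = "qpcr", centered = FALSE)
  center_features(em)
}

#' Normalize a mass cytometry (CyTOF) ion-count matrix
#'
#' Channels measuring the same protein are united by their per-cell mean,
#' then every value x is replaced by `asinh(x / cofactor)`.
#'
#' @param raw_counts nonnegative numeric matrix, cells x channels.
#' @param duplicate_feature_groups optional named character vector mapping
#'   channel name -> group name; channels sharing a group are averaged and
#'   the merged feature takes the group name.
#' @param config a [preprocess_config()] (supplies the cofactor).
#' @param center if `TRUE`, per-feature means are removed afterwards.
#' @return An `ExpressionMatrix` with `modality = "cytof"`.
#' @export
normalize_cytof <- function(raw_counts, duplicate_feature_groups = NULL,
                            config = preprocess_config(), center = FALSE) {
  m <- as.matrix(raw_counts)
  if (any(m < 0)) stop("ion counts must be nonnegative")
  if (is.null(colnames(m))) colnames(m) <- paste0("f_", seq_len(ncol(m)))
  if (!is.null(duplicate_feature_groups)) {
    missing <- setdiff(names(duplicate_feature_groups), colnames(m))
    if (length(missing)) {
      stop("duplicate group names a missing feature: ",
           paste(missing, collapse = ", "))
    }
    groups <- split(names(duplicate_feature_groups),
                    unlist(duplicate_feature_groups))
    merged <- matrix(NA_real_, nrow(m), length(groups),
                     dimnames = list(rownames(m), names(groups)))
    for (g in names(groups)) {
      merged[, g] <- rowMeans(m[, groups[[g]], drop = FALSE])
    }
    keep <- setdiff(colnames(m), names(duplicate_feature_groups))
    m <- cbind(m[, keep, drop = FALSE], merged)
  }
  tr <- asinh(m / config$arcsinh_cofactor)
  em <- expression_matrix(tr, cell_ids = rownames(raw_counts),
                          modality = "cytof", centered = FALSE)
  if (center) center_features(em) else em
}

#' Downsample an RNA-Seq count matrix to a fixed depth
#'
#' Cells with fewer than `N` total molecules are dropped; each remaining
#' cell is replaced by a without-replacement sample of exactly `N` molecules
#' (a multivariate hypergeometric draw), equalizing sampling depth. Counts
#' are then transformed as `log2(x + 1)` and each gene is mean-centered.
#'
#' @param raw_counts integer matrix of molecule counts, cells x genes.
#' @param N target molecule count per cell.
#' @param rng_seed integer seed; each cell uses a substream derived from the
#'   seed and its own index, so results do not depend on cell order.
#' @return A centered `ExpressionMatrix` with `modality = "rnaseq"`. Dropped
#'   cell ids are recorded in the `"dropped_cells"` attribute.
#' @export
downsample_counts <- function(raw_counts, N = 400L, rng_seed = 1L) {
  m <- as.matrix(raw_counts)
  if (N <= 0) stop("N must be positive")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell_", seq_len(nrow(m)))
  totals <- rowSums(m)
  keep <- which(totals >= N)
  dropped <- rownames(m)[totals < N]
  if (!length(keep)) stop("no cell reaches the target depth N")
  out <- matrix(0, length(keep), ncol(m),
                dimnames = list(rownames(m)[keep], colnames(m)))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    row <- m[i, ]
    if (totals[i] == N) {            # full draw: counts unchanged
      out[ii, ] <- row
      next
    }
    out[ii, ] <- withr::with_seed((rng_seed + i) %% .Machine$integer.max, {
      draws <- sample.int(totals[i], N)          # molecule labels
      gene <- findInterval(draws - 0.5, c(0, cumsum(row)))
      tabulate(gene, nbins = ncol(m))
    })
  }
  em <- expression_matrix(log2(out + 1), modality = "rnaseq", centered = FALSE)
  em <- center_features(em)
  attr(em, "dropped_cells") <- dropped
  em
}

#' Keep the most variable features
#'
#' Retains the `n` features with highest per-feature standard deviation,
#' breaking ties by input order; kept features stay in input order.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param n number of features to keep.
#' @return An `ExpressionMatrix` with `n` columns.
#' @export
select_top_variable <- function(mat, n) {
  mat <- as_expression_matrix(mat)
  p <- ncol(mat$values)
  if (n > p) stop(sprintf("n (%d) exceeds number of features (%d)", n, p))
  sds <- apply(mat$values, 2, stats::sd)
  keep <- sort(order(-sds, seq_len(p))[seq_len(n)])
  mat[, keep]
}

#' Remove lowest-expressing cells and features
#'
#' Drops the `floor(cell_frac * n_cells)` cells with lowest total expression,
#' then (with totals recomputed on the remaining cells) the
#' `floor(feature_frac * n_features)` features with lowest total expression.
#' Totals are measured on the pre-centering scale when available, since
#' centering destroys them. Ties break by input order. If the input was
#' centered, the result is re-centered on the retained cells.
#'
#' @param mat ExpressionMatrix.
#' @param cell_frac,feature_frac fractions in `[0, 1)` to remove.
#' @param count_rule `"floor"` (default) or `"round"` for converting
#'   fractions to counts.
#' @return A filtered `ExpressionMatrix`; removed ids are in attributes
#'   `"dropped_cells"` and `"dropped_features"`.
#' @export
filter_low_expression <- function(mat, cell_frac = 0.10, feature_frac = 0.10,
                                  count_rule = c("floor", "round")) {
  count_rule <- match.arg(count_rule)
  mat <- as_expression_matrix(mat)
  if (cell_frac >= 1 || feature_frac >= 1) stop("fractions must be < 1")
  if (cell_frac < 0 || feature_frac < 0) stop("fractions must be >= 0")
  totals_of <- function(v) list(cell = rowSums(v), feature = colSums(v))
  base <- if (!is.null(mat$precenter)) mat$precenter else {
    if (mat$centered) {
      warning("input is centered and carries no pre-centering values; totals computed on centered scale")
    }
    mat$values
  }
  n_cells <- nrow(base)
  n_feat <- ncol(base)
  cnt <- switch(count_rule, floor = floor, round = round)
  n_drop_cells <- as.integer(cnt(cell_frac * n_cells))
  n_drop_feat <- as.integer(cnt(feature_frac * n_feat))

  keep_cells <- seq_len(n_cells)
  if (n_drop_cells > 0) {
    ct <- rowSums(base)
    drop <- order(ct, seq_len(n_cells))[seq_len(n_drop_cells)]
    keep_cells <- setdiff(keep_cells, drop)
  }
  keep_feat <- seq_len(n_feat)
  if (n_drop_feat > 0) {
    ft <- colSums(base[keep_cells, , drop = FALSE])   # recomputed after cell removal
    drop <- order(ft, seq_len(n_feat))[seq_len(n_drop_feat)]
    keep_feat <- setdiff(keep_feat, drop)
  }
  out <- mat[keep_cells, keep_feat]
  if (mat$centered) out <- center_features(out)
  attr(out, "dropped_cells") <- setdiff(mat$cell_ids, out$cell_ids)
  attr(out, "dropped_features") <- setdiff(mat$feature_ids, out$feature_ids)
  out
}
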