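# Shuffle-null significance tests: does a k-vertex polytope describe the
# data better than expected for data with the same per-feature marginals
# but no correlation structure?

new_significance_result <- function(kind, observed, null_samples, m, k, seed) {
  p <- mean(null_samples >= observed)
  structure(list(statistic_kind = kind, observed = observed,
                 null_samples = null_samples, p_value = p,
                 p_label = if (p == 0) sprintf("< %g", 1 / m) else sprintf("%g", p),
                 m = as.integer(m), k = as.integer(k), seed = seed),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("%s shuffle test, k = %d: observed = %.4f, p %s (m = %d)\n",
              x$statistic_kind, x$k, x$observed,
              if (x$p_value == 0) x$p_label else paste("=", x$p_label), x$m))
  invisible(x)
}

#' Explained-variance shuffle test for a k-vertex polytope
#'
#' Fits the best k-polytope (delta = 0) to the real data and to `m`
#' independently column-shuffled copies; the p-value is the fraction of
#' shuffled datasets whose explained variance is larger than or equal to
#' that of the real data. A p-value of zero is reported as `< 1/m`.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k number of archetypes.
#' @param m number of shuffles (default 1000 for reports; >= 10).
#' @param seed integer seed; shuffle i uses a substream derived from
#'   `seed + i`.
#' @param definition EV definition (see [explained_variance()]).
#' @param ... further arguments to [pcha_fit()] (`n_restarts`, `tol`, ...).
#' @return A `significance_result`.
#' @export
significance_ev <- function(mat, k, m = 1000L, seed = 1L,
                            definition = c("as_printed", "sse_ratio"), ...) {
  definition <- match.arg(definition)
  if (m < 10) stop("m must be at least 10")
  mat <- as_expression_matrix(mat)
  fit <- pcha_fit(mat, k = k, delta = 0, seed = seed, ...)
  observed <- explained_variance(mat, fit, definition)
  nulls <- numeric(m)
  kept <- logical(m)
  for (i in seq_len(m)) {
    sh <- shuffle_matrix(mat, seed = (seed + i) %% .Machine$integer.max)
    f <- pcha_fit(sh, k = k, delta = 0, seed = seed, ...)
    if (!f$converged) {  # one retry with a different restart stream
      f2 <- pcha_fit(sh, k = k, delta = 0, seed = seed + 104729L, ...)
      if (f2$converged || f2$objective < f$objective) f <- f2
    }
    if (f$converged) {
      nulls[i] <- explained_variance(sh, f, definition)
      kept[i] <- TRUE
    }
  }
  if (!all(kept)) {
    warning(sprintf("%d non-converged null fits dropped", sum(!kept)))
  }
  new_significance_result("ev", observed, nulls[kept], sum(kept), k, seed)
}

#' t-ratio shuffle test for a k-vertex polytope
#'
#' Compares the observed t-ratio (see [t_ratio()]) with t-ratios of `m`
#' column-shuffled datasets, each re-projected onto its own first k-1
#' principal components so the null reflects the full pipeline. The p-value
#' is the fraction of shuffled sets whose t-ratio is equal to or larger
#' than that of the data (a large t-ratio means more polytope-like).
#'
#' @inheritParams significance_ev
#' @param ... further arguments to [pcha_fit()] via [t_ratio()].
#' @return A `significance_result`.
#' @export
significance_tratio <- function(mat, k, m = 1000L, seed = 1L, ...) {
  if (k < 3) stop("t-ratio test requires k >= 3")
  if (m < 10) stop("m must be at least 10")
  mat <- as_expression_matrix(mat)
  observed <- t_ratio(mat, k = k, seed = seed, ...)$ratio
  nulls <- numeric(m)
  kept <- logical(m)
  for (i in seq_len(m)) {
    s_i <- (seed + i) %% .Machine$integer.max
    tr <- tryCatch({
      t_ratio(shuffle_matrix(mat, seed = s_i), k = k, seed = seed, ...)
    }, error = function(e) NULL)
    if (is.null(tr)) {  # degenerate null hull: resample once
      tr <- tryCatch({
        t_ratio(shuffle_matrix(mat, seed = (s_i + 15485863L) %% .Machine$integer.max),
                k = k, seed = seed, ...)
      }, error = function(e) NULL)
    }
    if (!is.null(tr)) {
      nulls[i] <- tr$ratio
      kept[i] <- TRUE
    }
  }
  if (!all(kept)) {
    warning(sprintf("%d degenerate null shuffles dropped", sum(!kept)))
  }
  new_significance_result("t_ratio", observed, nulls[kept], sum(kept), k, seed)
}

#' Significance scan over a range of polytope orders
#'
#' Runs the chosen shuffle test for every k in `k_range`, reporting raw
#' (uncorrected) p-values per k.
#'
#' @param mat ExpressionMatrix or matrix.
#' @param k_range integer vector of polytope orders (e.g. `3:5`).
#' @param m shuffles per test.
#' @param seed integer seed.
#' @param method `"tratio"` (default, the stringent test) or `"ev"`.
#' @param ... further arguments to the chosen test.
#' @return A list of `significance_result`, one per k, named `k<order>`.
#' @export
polytope_scan <- function(mat, k_range = 3:5, m = 1000L, seed = 1L,
                          method = c("tratio", "ev"), ...) {
  method <- match.arg(method)
  fn <- if (method == "tratio") significance_tratio else significance_ev
  res <- lapply(k_range, function(k) fn(mat, k = k, m = m, seed = seed, ...))
  names(res) <- paste0("k", k_range)
  res
}
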