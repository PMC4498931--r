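# Shared fixtures, built in code at test time.

# n points sampled uniformly in the triangle with the given 2-D vertices
triangle_cloud <- function(n, vertices = rbind(c(0, 0), c(1, 0), c(0.5, 1)),
                           seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(stats::rgamma(n * 3, 1), n, 3)
    (w / rowSums(w)) %*% vertices
  })
}

# maximum vertex-matching error between a fit and true archetypes
vertex_error <- function(fitted, truth) {
  perm <- match_archetypes(truth, fitted)
  max(sqrt(rowSums((fitted[perm, , drop = FALSE] - truth)^2)))
}

# exact rank-sum p-value by enumeration of all group assignments:
# P(W >= observed) for the one-sided (greater) test, ties handled by
# midranks as in the normal approximation
exact_ranksum_p <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(length(x) + length(y), n1)
  stats <- apply(combos, 2, function(i) sum(ranks[i]))
  mean(stats >= obs)
}

# shoelace polygon area of the 2-D convex hull (grDevices ordering)
shoelace_hull_area <- function(P) {
  v <- P[grDevices::chull(P), , drop = FALSE]
  j <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# brute-force optimal assignment over all permutations
brute_force_match <- function(reference, candidate) {
  k <- nrow(reference)
  perms <- if (k == 1) list(1L) else {
    do.call(rbind, lapply(combinat_perms(seq_len(k)), rbind))
  }
  cost <- function(p) {
    sum(sqrt(rowSums((candidate[p, , drop = FALSE] - reference)^2)))
  }
  costs <- apply(perms, 1, cost)
  perms[which.min(costs), ]
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
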