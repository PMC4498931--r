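test_that("archetype matching equals brute force over permutations", {
  expect_equal(match_archetypes(diag(3), diag(3)), 1:3)
  for (k in 3:5) {
    ref <- withr::with_seed(50 + k, matrix(rnorm(k * 4), k, 4))
    cand <- withr::with_seed(60 + k, ref[sample(k), ] +
                               matrix(rnorm(k * 4, 0, 0.1), k, 4))
    expect_equal(match_archetypes(ref, cand),
                 as.integer(brute_force_match(ref, cand)))
  }
  # a pure permutation is recovered exactly
  ref <- withr::with_seed(70, matrix(rnorm(20), 5, 4))
  p <- c(3, 5, 1, 2, 4)
  expect_equal(match_archetypes(ref, ref[p, ]), order(p))
  expect_error(match_archetypes(diag(3), diag(4)), "same dimensions")
})

test_that("bootstrap errors are near zero for noise-free vertex data", {
  Z <- regular_simplex(4, 4) + 1   # offset so cloud centers are off-origin
  V <- Z[rep(1:4, each = 30), ] +
    withr::with_seed(71, matrix(rnorm(480, 0, 1e-3), 120, 4))
  be <- bootstrap_archetypes(V, k = 4, n_boot = 30, seed = 1, n_restarts = 1)
  expect_lt(be$mean_error, 0.02)
  expect_equal(dim(be$positions), c(30, 4, 4))
})

test_that("bootstrap error shrinks with sample size", {
  # vertex-clumped data with known noise: each archetype is pinned by its
  # own cluster of ~n/3 cells, so the bootstrap error follows the CLT
  errs <- vapply(c(100, 400, 1600), function(n) {
    dat <- sample_polytope(synthetic_spec(k = 3, ambient_dim = 2,
                                          n_cells = n, noise_sd = 0.1,
                                          alpha = 0.1,
                                          archetypes = regular_simplex(3) + 0.8,
                                          seed = 72))
    bootstrap_archetypes(dat$matrix$values, k = 3, n_boot = 50,
                         seed = 1, n_restarts = 2)$mean_error
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # the delta = 0 vertex estimate leans on the extreme cells of each
  # cluster, so the decay is slower than the idealized 1/sqrt(n); a 16-fold
  # n increase still shrinks the error substantially
  expect_gt(errs[1] / errs[3], 1.5)
})

test_that("archetype description is more stable than clustering on continua", {
  dat <- sample_polytope(synthetic_spec(k = 3, ambient_dim = 2,
                                        n_cells = 150, noise_sd = 0.05,
                                        seed = 73))
  ds <- description_stability(dat$matrix, k = 3, n_boot = 12, seed = 1,
                              methods = c("archetypes", "kmeans", "pca"),
                              n_restarts = 1, max_iter = 500)
  expect_named(ds$fraction_unstable, c("archetypes", "kmeans", "pca"))
  # uniformly filled polytopes have arbitrary cluster boundaries: k-means
  # descriptions jump between bootstraps more than archetype descriptions
  expect_lte(ds$fraction_unstable[["archetypes"]],
             ds$fraction_unstable[["kmeans"]])
  expect_error(description_stability(dat$matrix, k = 3, methods = "voronoi"),
               "unknown method")
})

test_that("well-separated blobs are stable under every description", {
  # blobs kept away from the origin: the normalized SD divides by the norm
  # of the mean description, which must not vanish
  blobs <- rbind(
    withr::with_seed(74, matrix(rnorm(160, 1, 0.05), 80, 2)),
    withr::with_seed(75, matrix(rnorm(160, 3, 0.05), 80, 2)))
  ds <- description_stability(blobs, k = 2, n_boot = 10, seed = 2,
                              methods = c("archetypes", "kmeans"),
                              n_restarts = 1, max_iter = 400)
  expect_lt(ds$fraction_unstable[["kmeans"]], 0.05)
  expect_lt(ds$fraction_unstable[["archetypes"]], 0.05)
})

test_that("archetype tree splits one parent when blobs demand a new vertex", {
  centers <- rbind(c(0, 0), c(4, 0), c(4.4, 1.2))
  pts <- do.call(rbind, lapply(1:3, function(i) {
    withr::with_seed(76 + i, sweep(matrix(rnorm(120, 0, 0.1), 60, 2), 2,
                                   centers[i, ], "+"))
  }))
  tree <- archetype_tree(pts, k_min = 2, k_max = 3, seed = 1, n_restarts = 3)
  lv3 <- tree$levels$k3
  expect_equal(sort(unique(lv3$parent)) %in% 1:2, c(TRUE, TRUE))
  expect_equal(anyDuplicated(lv3$parent) > 0, TRUE)   # one parent splits
  expect_true(all(is.finite(lv3$parent_distance)))
  expect_true(all(is.na(tree$levels$k2$parent)))
})
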