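test_that("data consisting of exactly the simplex vertices represents itself", {
  V <- rbind(diag(3), c(1, 1, 1))   # tetrahedron corners, none at the origin
  fit <- pcha_fit(V, k = 4, delta = 0, seed = 1)
  expect_equal(fit$ev, 1, tolerance = 1e-4)
  expect_equal(fit$ev_sse, 1, tolerance = 1e-6)
  expect_equal(vertex_error(fit$archetypes, V), 0, tolerance = 1e-3)
})

test_that("uniform triangle samples recover the vertices", {
  X <- triangle_cloud(300, seed = 1)
  truth <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  fit <- pcha_fit(X, k = 3, delta = 0, seed = 2)
  # delta = 0 vertices cannot leave the data hull, so recovery is limited by
  # how close samples come to the corners (~1/sqrt(n) here)
  expect_lt(vertex_error(fit$archetypes, truth), 0.12)
  expect_gt(fit$ev_sse, 0.99)
})

test_that("objective is non-increasing and constraints hold", {
  X <- triangle_cloud(120, seed = 3)
  for (delta in c(0, 0.5)) {
    fit <- pcha_fit(X, k = 3, delta = delta, seed = 1)
    expect_true(all(diff(fit$trace) <= 1e-10))
    expect_true(all(fit$S >= 0))
    expect_equal(colSums(fit$S), rep(1, ncol(X) * 0 + 120), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(fit$C >= 0))
    cs <- colSums(fit$C)
    expect_true(all(cs >= 1 - delta - 1e-8 & cs <= 1 + delta + 1e-8))
    # archetypes are exactly X'C
    expect_equal(fit$archetypes, t(t(X) %*% fit$C), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("fits are invariant to cell and feature permutations", {
  X <- triangle_cloud(80, seed = 4)
  X <- cbind(X, X[, 1] - X[, 2])            # 3 features
  colnames(X) <- c("a", "b", "c")
  fit <- pcha_fit(X, k = 3, delta = 0, seed = 5)
  perm_cells <- withr::with_seed(6, sample(nrow(X)))
  perm_feat <- c(3, 1, 2)
  fit_p <- pcha_fit(X[perm_cells, perm_feat], k = 3, delta = 0, seed = 5)
  expect_equal(fit_p$archetypes[, order(perm_feat)], fit$archetypes,
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  X <- triangle_cloud(10, seed = 7)
  expect_error(pcha_fit(X, k = 11), "exceeds number of cells")
  expect_error(pcha_fit(X, k = 1), "at least 2")
  expect_error(pcha_fit(matrix(2, 10, 3), k = 2), "all-constant")
  X[1, 1] <- Inf
  expect_error(pcha_fit(X, k = 2), "finite")
})

test_that("explained variance matches hand computation", {
  # single cell p = (3,4), reconstruction s = (0,0): EV = 1 - 5/5 = 0
  fake <- list(S = matrix(c(1, 0), 2, 1), archetypes = matrix(0, 2, 2))
  expect_equal(explained_variance(matrix(c(3, 4), 1, 2), fake, "as_printed"), 0)

  # two cells, fixed reconstruction, both definitions computed by hand:
  # p1=(1,0) s1=(1,0); p2=(0,2) s2=(0,1)
  # as_printed: mean(1 - 0/1, 1 - 1/2) = 0.75
  # sse_ratio: 1 - (0 + 1)/(1 + 4) = 0.8
  V <- rbind(c(1, 0), c(0, 2))
  fake2 <- list(S = diag(2), archetypes = rbind(c(1, 0), c(0, 1)))
  expect_equal(explained_variance(V, fake2, "as_printed"), 0.75)
  expect_equal(explained_variance(V, fake2, "sse_ratio"), 0.8)

  # perfect reconstruction gives EV = 1 under both definitions
  fake3 <- list(S = diag(2), archetypes = V)
  expect_equal(explained_variance(V, fake3, "as_printed"), 1)
  expect_equal(explained_variance(V, fake3, "sse_ratio"), 1)

  # a cell at the exact origin is excluded with a warning
  V0 <- rbind(c(0, 0), c(1, 1))
  fake4 <- list(S = diag(2), archetypes = V0)
  expect_warning(ev <- explained_variance(V0, fake4, "as_printed"), "origin")
  expect_equal(ev, 1)
})

test_that("noise-free recovery improves as noise shrinks", {
  errs <- vapply(c(0.1, 0.01, 0), function(ns) {
    dat <- sample_polytope(synthetic_spec(k = 3, ambient_dim = 2,
                                          n_cells = 400, noise_sd = ns,
                                          alpha = 0.2, seed = 11))
    fit <- pcha_fit(dat$matrix, k = 3, delta = 0, seed = 1)
    vertex_error(fit$archetypes, dat$archetypes)
  }, numeric(1))
  expect_true(all(diff(errs) < 0.05))   # error shrinks (up to small jitter)
  expect_lt(errs[3], 0.06)
})

test_that("cells project onto fixed archetypes as simplex weights", {
  truth <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  X <- triangle_cloud(50, seed = 8)
  S <- project_on_archetypes(X, truth)
  expect_true(all(S >= -1e-12))
  expect_equal(colSums(S), rep(1, 50), tolerance = 1e-8, ignore_attr = TRUE)
  # noise-free interior points are reconstructed exactly
  expect_lt(max(abs(t(S) %*% truth - X)), 1e-3)
})
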