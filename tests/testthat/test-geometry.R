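test_that("hull volume is exact on known shapes", {
  expect_equal(hull_volume(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(hull_volume(rbind(c(0, 0, 0), diag(3))), 1 / 6)
  # interior points do not change the hull
  withr::with_seed(1, inner <- matrix(runif(30, 0.05, 0.2), 10, 3))
  expect_equal(hull_volume(rbind(c(0, 0, 0), diag(3), inner)), 1 / 6)
  # 4-D simplex: 1/4!
  expect_equal(hull_volume(rbind(rep(0, 4), diag(4))), 1 / 24)
})

test_that("2-D hull areas equal the shoelace formula", {
  for (s in 1:5) {
    P <- withr::with_seed(s, matrix(rnorm(100), 50, 2))
    expect_equal(hull_volume(P), shoelace_hull_area(P), tolerance = 1e-9)
  }
})

test_that("hull volume respects permutation, rotation and scaling", {
  P <- withr::with_seed(2, matrix(rnorm(90), 30, 3))
  v <- hull_volume(P)
  expect_equal(hull_volume(P[withr::with_seed(3, sample(30)), ]), v,
               tolerance = 1e-9)
  Q <- qr.Q(qr(withr::with_seed(4, matrix(rnorm(9), 3, 3))))
  expect_equal(hull_volume(P %*% Q), v, tolerance = 1e-8)
  expect_equal(hull_volume(2.5 * P), 2.5^3 * v, tolerance = 1e-8)
})

test_that("degenerate point sets are rejected with the detected rank", {
  P <- withr::with_seed(5, matrix(rnorm(40), 20, 2))
  flat <- cbind(P, P[, 1] + P[, 2])   # rank 2 in 3 dims
  expect_error(convex_hull(flat), "span only 2 of 3")
  expect_error(convex_hull(matrix(1:3, 3, 1) %x% t(rep(1, 2))), "span only 1")
})

test_that("membership tests and hull sampling agree", {
  h <- convex_hull(rbind(c(0, 0, 0), diag(3)))
  expect_true(in_hull(h, c(0.2, 0.2, 0.2)))
  expect_false(in_hull(h, c(0.5, 0.5, 0.5)))
  pts <- withr::with_seed(6, sample_in_hull(h, 300))
  expect_true(all(in_hull(h, pts)))
  expect_true(all(rowSums(pts) <= 1 + 1e-9) && all(pts >= -1e-9))
})

test_that("t-ratio approaches 1 for data that fills a triangle", {
  X <- triangle_cloud(500, seed = 7)
  X <- cbind(X, 0.5 * X[, 1] + 0.25 * X[, 2])   # embed in 3 features
  tr <- t_ratio(X, k = 3, seed = 1)
  expect_gt(tr$ratio, 0.85)
  expect_lte(tr$ratio, 1 + 1e-9)
})

test_that("t-ratio of a uniform disk matches the inscribed-triangle limit", {
  # largest triangle inscribed in a circle is equilateral:
  # area ratio 3*sqrt(3)/(4*pi) ~ 0.4135
  n <- 2000
  P <- withr::with_seed(8, {
    r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })
  tr <- t_ratio(P, k = 3, seed = 1)
  expect_equal(tr$ratio, 3 * sqrt(3) / (4 * pi), tolerance = 0.12)
})

test_that("uniformity rho is near 1 for uniform data, large for clusters", {
  dat <- sample_polytope(synthetic_spec(k = 4, ambient_dim = 3,
                                        n_cells = 600, seed = 9))
  u <- uniformity_rho(dat$matrix, seed = 2)
  expect_lt(abs(u$rho - 1), 3 * u$rho_U_sd / u$rho_U + 0.05)

  blobs <- rbind(
    withr::with_seed(10, matrix(rnorm(300 * 3, 0, 0.03), 300, 3)),
    withr::with_seed(11, matrix(rnorm(300 * 3, 0.8, 0.03), 300, 3)))
  u2 <- uniformity_rho(blobs, seed = 3)
  expect_gt(u2$rho, 3)
})

test_that("neighbor counts match a direct pairwise-distance oracle", {
  pts <- withr::with_seed(12, matrix(rnorm(75), 25, 3))
  r <- 0.8
  oracle <- rowSums(as.matrix(dist(pts)) <= r) - 1L
  expect_equal(paretoscope:::count_neighbors(pts, r), oracle,
               ignore_attr = TRUE)
})

test_that("simplex volume uses the determinant formula", {
  expect_equal(simplex_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplex_volume(rbind(rep(0, 3), diag(3))), 1 / 6)
  Z <- regular_simplex(4)   # unit edge tetrahedron: V = 1/(6*sqrt(2))
  expect_equal(simplex_volume(Z), 1 / (6 * sqrt(2)), tolerance = 1e-9)
})
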