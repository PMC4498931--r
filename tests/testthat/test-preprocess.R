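test_that("qPCR normalization ceils, flips and centers", {
  # hand-computed 2x2 example: ceiling/flip then centering
  raw <- matrix(c(10, 30, 20, 40), 2, 2)
  em <- normalize_qpcr(raw)
  expect_equal(unname(em$precenter), matrix(c(20, 0, 10, 0), 2, 2))
  expect_equal(unname(em$values), matrix(c(10, -10, 5, -5), 2, 2))
  expect_true(em$centered)
  expect_identical(em$modality, "qpcr")

  # undetected values (Ct > ceiling, or missing) land at the detection limit
  raw2 <- matrix(c(40, 999, NA, 30), 2, 2)
  em2 <- normalize_qpcr(raw2)
  expect_equal(unname(em2$precenter), matrix(0, 2, 2))

  expect_error(normalize_qpcr(matrix(c(-1, 10, 20, 30), 2, 2)),
               "negative Ct value at row 1, column 1")
})

test_that("re-centering already centered qPCR data is a no-op", {
  withr::with_seed(1, raw <- matrix(runif(40, 5, 35), 8, 5))
  em <- normalize_qpcr(raw)
  again <- center_features(em)
  expect_equal(again$values, em$values, tolerance = 1e-12)
})

test_that("CyTOF normalization applies arcsinh and unites duplicate channels", {
  m <- matrix(c(0, 5, 2, 4), 1, 4,
              dimnames = list("c1", c("CD19", "CD20", "CD3a", "CD3b")))
  em <- normalize_cytof(m, duplicate_feature_groups = c(CD3a = "CD3", CD3b = "CD3"))
  expect_equal(em$values[1, "CD19"], 0)                       # arcsinh(0)
  expect_equal(em$values[1, "CD20"], log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(em$values[1, "CD3"], asinh(3 / 5), tolerance = 1e-12)  # mean of 2 and 4
  expect_error(normalize_cytof(m, duplicate_feature_groups = c(CD99 = "CD3")),
               "missing feature")
  expect_error(normalize_cytof(matrix(-1, 1, 1)), "nonnegative")
})

test_that("downsampling equalizes depth and drops shallow cells", {
  counts <- rbind(c(200, 200),   # total 400: kept, unchanged
                  c(150, 249),   # total 399 < N: dropped
                  c(300, 300))   # total 600: sampled down
  rownames(counts) <- c("full", "shallow", "deep")
  em <- downsample_counts(counts, N = 400, rng_seed = 7)
  expect_equal(em$cell_ids, c("full", "deep"))
  expect_equal(attr(em, "dropped_cells"), "shallow")
  # totals on the count scale are exactly N
  counts_back <- 2^em$precenter - 1
  expect_equal(unname(rowSums(counts_back)), c(400, 400))
  expect_equal(unname(counts_back["full", ]), c(200, 200))
  expect_error(downsample_counts(counts, N = 0), "positive")
  expect_error(downsample_counts(matrix(1.5, 2, 2), N = 1), "integers")
})

test_that("downsampled counts follow the hypergeometric mean", {
  counts <- matrix(c(300, 300), 1, 2)
  draws <- vapply(1:400, function(s) {
    em <- downsample_counts(counts, N = 400, rng_seed = s)
    (2^em$precenter - 1)[1, 1]
  }, numeric(1))
  # mean N * m1 / m = 200; SE of the mean over 400 replicates
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 200), 3 * se + 1e-9)
})

test_that("downsampling is reproducible and cell-order independent", {
  withr::with_seed(3, counts <- matrix(rpois(60, 40), 6, 10))
  rownames(counts) <- paste0("c", 1:6)
  a <- downsample_counts(counts, N = 300, rng_seed = 11)
  b <- downsample_counts(counts, N = 300, rng_seed = 11)
  expect_equal(a$values, b$values)
})

test_that("top-variable selection keeps the highest-SD features in order", {
  m <- cbind(f1 = c(0, 2, 0, 2), f2 = c(0, 4, 0, 4), f3 = c(0, 1, 0, 1))
  out <- select_top_variable(m, 2)
  expect_equal(out$feature_ids, c("f1", "f2"))   # input order retained
  expect_equal(dim(out), c(4, 2))
  expect_equal(select_top_variable(m, 3)$values, expression_matrix(m)$values)
  expect_error(select_top_variable(m, 4), "exceeds")
})

test_that("low-expression filtering drops exact counts, cells before features", {
  withr::with_seed(4, m <- matrix(rexp(100, 1 / 10), 10, 10))
  m[3, ] <- 0   # all-zero cell
  m[, 7] <- 0   # all-zero feature
  em <- expression_matrix(m)
  out <- filter_low_expression(em, 0.10, 0.10)
  expect_equal(dim(out), c(9, 9))
  expect_equal(attr(out, "dropped_cells"), "cell_3")
  expect_equal(attr(out, "dropped_features"), "f_7")
  # zero fractions are the identity
  same <- filter_low_expression(em, 0, 0)
  expect_equal(same$values, em$values)
  expect_error(filter_low_expression(em, 1, 0), "< 1")
})

test_that("filtering centered qPCR data uses the pre-centering totals", {
  withr::with_seed(5, raw <- matrix(runif(200, 2, 35), 20, 10))
  raw[9, ] <- 29.9   # nearly undetected cell: lowest (30 - Ct) total
  em <- normalize_qpcr(raw)
  out <- filter_low_expression(em, 0.10, 0.10)
  expect_equal(dim(out), c(18, 9))
  expect_true("cell_9" %in% attr(out, "dropped_cells"))
  expect_true(out$centered)
  expect_equal(colMeans(out$values), rep(0, 9), tolerance = 1e-12,
               ignore_attr = TRUE)
})
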