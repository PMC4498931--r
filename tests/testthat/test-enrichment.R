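test_that("equal-mass bins split by distance with larger bins first", {
  expect_equal(table(equal_mass_bins(runif(10), 5)),
               table(rep(1:5, each = 2)))
  b <- equal_mass_bins(11:1, 5)   # distances decreasing: cell 11 is closest
  sizes <- as.integer(table(b))
  expect_equal(sizes, c(3L, 2L, 2L, 2L, 2L))
  expect_equal(b[11], 1L)         # smallest distance in first bin
  expect_error(equal_mass_bins(1:3, 5), "exceeds")
  expect_error(equal_mass_bins(1:3, 1), "at least 2")
})

test_that("rank-sum p equals exact enumeration for n <= 12", {
  cases <- list(
    withr::with_seed(41, list(x = rnorm(4), y = rnorm(8))),
    withr::with_seed(42, list(x = rnorm(6) + 1, y = rnorm(6))),
    withr::with_seed(43, list(x = runif(3), y = runif(9))))
  for (cs in cases) {
    enum_p <- exact_ranksum_p(cs$x, cs$y)
    exact_p <- wilcox.test(cs$x, cs$y, alternative = "greater",
                           exact = TRUE)$p.value
    expect_equal(exact_p, enum_p, tolerance = 1e-12)
    # the package's normal-approximation p agrees closely
    bins <- c(rep(1L, length(cs$x)), rep(2L, length(cs$y)))
    approx_p <- paretoscope:::bin_rank_test(c(cs$x, cs$y), bins)
    expect_equal(approx_p, enum_p, tolerance = 0.05)
  }
})

test_that("leave-one-out enrichment flags a planted gradient, not constants", {
  dat <- sample_polytope(synthetic_spec(
    k = 3, ambient_dim = 4, n_cells = 200, noise_sd = 0.02,
    enriched_plan = data.frame(feature = "grad", archetype = 2, effect = 1),
    feature_noise_sd = 0.05, seed = 44))
  X <- dat$matrix$values
  X <- cbind(X, flat = 0)   # constant feature
  en <- enrich_1d(X, k = 3, delta = 0.5, seed = 1, n_restarts = 2)
  tab <- en$table
  expect_true(all(!tab$significant[tab$feature == "flat"]))
  expect_equal(tab$p_value[tab$feature == "flat"], rep(1, 3))
  # the planted feature is enriched at exactly one archetype, the one
  # matching the generator's target
  sig <- tab[tab$feature == "grad" & tab$significant, ]
  expect_equal(nrow(sig), 1)
  perm <- match_archetypes(dat$archetypes, en$fit$archetypes[, 1:4])
  expect_equal(sig$archetype, perm[2])
  # significance rows obey the invariant significant => maximal & p < thr
  expect_true(all(!tab$significant | (tab$first_bin_maximal &
                                        tab$p_value < en$threshold)))
})

test_that("enrichment is invariant to adding a constant to a feature", {
  dat <- sample_enrichment_dataset(n_cells = 150, n_features = 20,
                                   ambient_dim = 5, n_enriched = 8, seed = 45)
  X <- dat$matrix$values
  en1 <- enrich_1d(X, k = 4, delta = 0.5, seed = 1, n_restarts = 2)
  X2 <- X; X2[, "planted_1"] <- X2[, "planted_1"] + 5
  en2 <- enrich_1d(X2, k = 4, delta = 0.5, seed = 1, n_restarts = 2)
  r1 <- en1$table[en1$table$feature == "planted_1", "significant"]
  r2 <- en2$table[en2$table$feature == "planted_1", "significant"]
  expect_equal(r1, r2)
})

test_that("archetype displacement on feature removal is tiny", {
  dat <- sample_enrichment_dataset(n_cells = 200, n_features = 30,
                                   ambient_dim = 5, n_enriched = 20, seed = 46)
  en <- enrich_1d(dat$matrix, k = 4, delta = 0.5, seed = 1, n_restarts = 2)
  disp <- loo_displacement_summary(en)
  expect_gte(disp, 0)
  expect_lt(disp, 0.05)   # well under the typical archetype separation
})

test_that("2D enrichment map matches a hand-evaluated kernel formula", {
  # three cells in 2 geometry features + the mapped feature
  G <- rbind(c(0, 0), c(1, 0), c(0, 1))
  colnames(G) <- c("g1", "g2")
  mvals <- c(1, 2, 3)
  X <- cbind(G, m = mvals)
  den <- enrich_2d(X, feature = "m", k = 3, delta = 0, grid_size = 5,
                   hill_k = 8, hill_n = 2, seed = 1, n_restarts = 2)
  # independent evaluation at one grid point
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sv <- svd(Gc, nu = 0, nv = 2)
  XY <- Gc %*% sv$v
  h <- vapply(1:2, function(j) (4 * sd(XY[, j])^5 / (3 * 3))^(1 / 5), numeric(1))
  gp <- c(den$grid_x[2], den$grid_y[4])
  K <- exp(-0.5 * ((gp[1] - XY[, 1])^2 / h[1]^2 + (gp[2] - XY[, 2])^2 / h[2]^2))
  D <- sum(K)
  expect_equal(den$bandwidths, h, tolerance = 1e-12)
  expect_equal(den$M[2, 4], sum(K * mvals) / D * D^2 / (8^2 + D^2),
               tolerance = 1e-10)
  # zero marker values give an identically zero map
  G0 <- G + withr::with_seed(47, matrix(rnorm(6, 0, .01), 3))
  colnames(G0) <- c("g1", "g2")
  X0 <- cbind(G0, m = 0)
  den0 <- enrich_2d(X0, feature = "m", k = 3, delta = 0, grid_size = 4,
                    seed = 1, n_restarts = 1)
  expect_true(all(den0$M == 0))
  expect_error(enrich_2d(X[1:2, ], feature = "m", k = 2), "at least 3")
})

test_that("2D map peaks near the archetype of a planted marker", {
  dat <- sample_polytope(synthetic_spec(
    k = 3, ambient_dim = 3, n_cells = 300, noise_sd = 0.02,
    enriched_plan = data.frame(feature = "mk", archetype = 1, effect = 1),
    feature_noise_sd = 0.1, seed = 48))
  den <- enrich_2d(dat$matrix, feature = "mk", k = 3, grid_size = 60,
                   seed = 1, n_restarts = 2)
  # the map's argmax is closest to one archetype; check it is the planted
  # one by matching fitted archetypes (without the marker) to the truth
  Vg <- dat$matrix$values[, setdiff(colnames(dat$matrix$values), "mk")]
  fitg <- pcha_fit(Vg, k = 3, delta = 0.5, seed = 1, n_restarts = 2)
  perm <- match_archetypes(dat$archetypes, fitg$archetypes)
  expect_equal(unname(which.min(den$argmax_archetype_dist)), perm[1])
})

test_that("GMT files round-trip and reject duplicate set names", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
  writeLines(c("s\td\tg1", "s\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate set names")
})

test_that("gene-set enrichment reports a planted set at its archetype", {
  dat <- sample_enrichment_dataset(n_cells = 250, n_features = 30,
                                   ambient_dim = 5, n_enriched = 12,
                                   seed = 49)
  plan <- dat$enriched_plan
  sets <- list(
    planted_set = plan$feature[plan$archetype == 2],
    decoy_set = grep("^noise_", colnames(dat$matrix$values), value = TRUE),
    constant_set = "nope")
  expect_warning(
    gse <- enrich_gene_sets(dat$matrix, sets, k = 4, n_boot = 15, seed = 1,
                            n_restarts = 2),
    "no measured genes")
  perm <- match_archetypes(dat$archetypes, gse$fit$archetypes[, 1:5])
  hit <- gse$reported[gse$reported$set == "planted_set", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$archetype, perm[2])
  expect_gte(hit$bootstrap_support, 0.8)
  expect_false("decoy_set" %in% gse$reported$set)
})
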