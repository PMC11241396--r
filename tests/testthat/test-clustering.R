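# k-means fitting and SD-index based selection of k.

two_clumps <- function(seed = 1) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
          matrix(rnorm(60, 8, 0.3), ncol = 2))
  })
}

test_that("k-means on two separated clumps matches the nearest-center oracle", {
  x <- two_clumps()
  km <- fit_kmeans(x, 2, seed = 4)
  nearest <- apply(x, 1, function(row) {
    which.min(colSums((t(km$centroids) - row)^2)) - 1L
  })
  expect_equal(km$assignments, unname(nearest))
  expect_equal(oracle_ari(km$assignments, rep(0:1, each = 30)), 1)
})

test_that("k = 1 gives the global mean and total sum of squares", {
  x <- two_clumps(2)
  km <- fit_kmeans(x, 1, seed = 1)
  expect_equal(unname(km$centroids[1, ]), unname(colMeans(x)))
  expect_equal(km$inertia, sum(sweep(x, 2, colMeans(x))^2))
})

test_that("k = n drives inertia to zero; k > n errors", {
  x <- matrix(rnorm(20), 10, 2)
  km <- fit_kmeans(x, 10, seed = 1)
  expect_equal(km$inertia, 0, tolerance = 1e-12)
  expect_error(fit_kmeans(x, 11, seed = 1), class = "mp_invalid_argument")
})

test_that("clusters are never empty and centroids equal member means", {
  # heavy duplication provokes empty-cluster repair
  x <- rbind(matrix(0, 18, 2), matrix(5, 3, 2), matrix(c(9, -4), 3, 2, byrow = TRUE))
  x <- x + withr::with_seed(5, matrix(rnorm(nrow(x) * 2, sd = 1e-3), ncol = 2))
  km <- fit_kmeans(x, 6, seed = 2)
  sizes <- tabulate(km$assignments + 1L, nbins = 6)
  expect_true(all(sizes >= 1))
  for (j in 0:5) {
    members <- x[km$assignments == j, , drop = FALSE]
    expect_equal(unname(km$centroids[j + 1, ]), unname(colMeans(members)),
                 tolerance = 1e-6)
  }
})

test_that("fits are deterministic given the seed and improve with restarts", {
  mx <- make_feature_mixture(5, 6, 30, 8, seed = 3)
  a <- fit_kmeans(mx$features, 5, seed = 7)
  b <- fit_kmeans(mx$features, 5, seed = 7)
  expect_identical(a, b)
  inertias <- vapply(1:6, function(k) fit_kmeans(mx$features, k, seed = 7)$inertia,
                     numeric(1))
  expect_true(all(diff(inertias) <= 1e-8))
})

test_that("assignments agree with an independent k-means on separated data", {
  mx <- make_feature_mixture(4, 6, 30, 10, seed = 6)
  ours <- fit_kmeans(mx$features, 4, seed = 2)
  ref <- withr::with_seed(2, stats::kmeans(mx$features$values, 4, nstart = 10))
  expect_equal(oracle_ari(ours$assignments[1:100], ref$cluster[1:100]), 1)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("SD index matches direct evaluation on six printed points", {
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10), c(10, 11), c(11, 10))
  km <- fit_kmeans(pts, 2, seed = 1)
  got <- sd_index(pts, km, alpha = 1)
  want <- oracle_sd_index(pts, km$assignments, km$centroids, alpha = 1)
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 0)
})

test_that("perfectly tight clusters have zero scattering", {
  pts <- rbind(matrix(c(0, 0), 5, 2, byrow = TRUE),
               matrix(c(6, 6), 5, 2, byrow = TRUE),
               matrix(c(0, 9), 5, 2, byrow = TRUE))
  km <- fit_kmeans(pts, 3, seed = 1)
  # with Scat = 0, the index reduces to Dis and is independent of alpha
  expect_equal(sd_index(pts, km, alpha = 1), sd_index(pts, km, alpha = 100))
})

test_that("SD index is minimized at the generative component count", {
  mx <- make_feature_mixture(3, 4, 30, 10, seed = 4)
  vals <- vapply(2:4, function(k) {
    sd_index(mx$features, fit_kmeans(mx$features, k, seed = 1), alpha = 1)
  }, numeric(1))
  expect_lt(vals[2], vals[1])   # SD(3) < SD(2)
  expect_lt(vals[2], vals[3])   # SD(3) < SD(4)
})

test_that("SD index rejects k < 2 and coincident centroids", {
  x <- two_clumps(3)
  km1 <- fit_kmeans(x, 1, seed = 1)
  expect_error(sd_index(x, km1), class = "mp_invalid_argument")
  km2 <- fit_kmeans(x, 2, seed = 1)
  km2$centroids[2, ] <- km2$centroids[1, ]
  expect_error(sd_index(x, km2), class = "mp_degenerate_clustering")
})

test_that("SD index is invariant to feature permutation and translation", {
  mx <- make_feature_mixture(3, 5, 20, 9, seed = 10)
  x <- mx$features$values
  km <- fit_kmeans(x, 3, seed = 1)
  base <- sd_index(x, km, alpha = 2)

  perm <- c(4, 1, 5, 2, 3)
  km_p <- km
  km_p$centroids <- km$centroids[, perm]
  expect_equal(sd_index(x[, perm], km_p, alpha = 2), base, tolerance = 1e-10)

  shift <- matrix(rep(c(5, -3, 2, 0, 7), each = nrow(x)), nrow(x), 5)
  km_t <- km
  km_t$centroids <- km$centroids + matrix(c(5, -3, 2, 0, 7), 3, 5, byrow = TRUE)
  expect_equal(sd_index(x + shift, km_t, alpha = 2), base, tolerance = 1e-10)
})

test_that("select_k recovers the true component count on separated mixtures", {
  mx4 <- make_feature_mixture(4, 8, 40, 12, seed = 1)
  scan4 <- select_k(mx4$features, 2, 10, seed = 1)
  expect_equal(scan4$chosen_k, 4)
  expect_equal(scan4$k_values, 2:10)
  expect_equal(scan4$chosen_k,
               scan4$k_values[which.min(scan4$sd_index)])

  mx8 <- make_feature_mixture(8, 8, 30, 8, seed = 8)
  expect_equal(select_k(mx8$features, 2, 12, seed = 1)$chosen_k, 8)
})

test_that("select_k validates its scan range", {
  mx <- make_feature_mixture(3, 4, 10, 10, seed = 2)
  expect_error(select_k(mx$features, 5, 5, seed = 1),
               class = "mp_invalid_argument")
  expect_error(select_k(mx$features, 2, 30, seed = 1),
               class = "mp_invalid_argument")
})

test_that("scan curves and assignments serialize", {
  mx <- make_feature_mixture(3, 4, 15, 10, seed = 3)
  scan <- select_k(mx$features, 2, 6, seed = 1, n_restarts = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_kscan(scan, f)
  rt <- jsonlite::fromJSON(f)
  expect_equal(rt$chosen_k, scan$chosen_k)
  expect_equal(rt$sd_index, scan$sd_index, tolerance = 1e-12)

  g <- withr::local_tempfile(fileext = ".csv")
  write_assignments(scan$model, mx$features$ids, g)
  asg <- read.csv(g, colClasses = c("character", "integer"))
  expect_equal(asg$cluster, scan$model$assignments)
})
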