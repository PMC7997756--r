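test_that("rank-1 data yields a single component with full contribution", {
  set.seed(11)
  t1 <- rnorm(100)
  x <- cbind(t1, 2 * t1)                  # variance only along one axis
  fit <- fit_ipca(x)
  expect_equal(fit$contribution[1], 1, tolerance = 1e-12)
  expect_equal(fit$n_selected, 1L)
})

test_that("component selection matches the brute-force eigen spectrum", {
  set.seed(12)
  n <- 10000
  x <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1))   # eigenvalues ~9 and ~1
  fit <- fit_ipca(x, threshold = 0.85)
  # independent oracle: eigendecomposition of the sample covariance
  xc <- sweep(x, 2, colMeans(x))
  oracle <- eigen(crossprod(xc) / n, symmetric = TRUE)
  expect_equal(fit$values, sort(pmax(oracle$values, 0), decreasing = TRUE),
               tolerance = 1e-10)
  expect_equal(fit$contribution, c(0.9, 0.1), tolerance = 0.05)
  expect_equal(fit$n_selected, 1L)
  expect_equal(sum(fit$contribution), 1, tolerance = 1e-9)
  # cross-check against prcomp (n-1 scaling converted to 1/n)
  pr <- prcomp(x)
  expect_equal(fit$values, pr$sdev^2 * (n - 1) / n, tolerance = 1e-8)
})

test_that("projection centres, decorrelates and reconstructs the data", {
  set.seed(13)
  x <- matrix(rnorm(600), 100, 6) %*% matrix(rnorm(36), 6, 6)
  fit <- fit_ipca(x)
  z_mean <- transform_ipca(fit, matrix(fit$mean, 1), n = 6)
  expect_equal(as.numeric(z_mean), rep(0, 6), tolerance = 1e-10)
  z <- transform_ipca(fit, x, n = 6)
  cz <- crossprod(sweep(z, 2, colMeans(z))) / nrow(z)
  expect_lt(max(abs(cz[upper.tri(cz)])), 1e-6)
  xr <- ipca_reconstruct(fit, z)
  expect_lt(norm(xr - x, "F") / norm(x, "F"), 1e-8)
  expect_error(transform_ipca(fit, x[, 1:3]), "mismatch")
})

test_that("raising the threshold never selects fewer components", {
  set.seed(14)
  x <- matrix(rnorm(2000), 200, 10) %*% diag(c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1))
  ns <- vapply(c(0.5, 0.7, 0.85, 0.95, 0.99),
               function(th) fit_ipca(x, th)$n_selected, integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("degenerate clustering puts every point at its own centre", {
  pts <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  km <- kmeans_lloyd(pts, k = 3, seed = 1)
  expect_equal(km$objective[length(km$objective)], 0)
  expect_error(kmeans_lloyd(pts, k = 4), "between 1")
})

test_that("well-separated clouds are recovered to their true means", {
  set.seed(15)
  sigma <- 0.1
  a <- matrix(rnorm(200, 0, sigma), 100, 2)
  b <- matrix(rnorm(200, 10, sigma), 100, 2)
  km <- kmeans_lloyd(rbind(a, b), k = 2, seed = 5)
  centres <- km$centers[order(km$centers[, 1]), ]
  expect_lt(max(abs(centres[1, ] - colMeans(a))), 0.1)
  expect_lt(max(abs(centres[2, ] - colMeans(b))), 0.1)
  # 10-sigma separation: centres within 3*sigma/sqrt(n) of the truth
  expect_lt(max(abs(centres[1, ] - 0)), 10 * 3 * sigma / sqrt(100))
  expect_lt(max(abs(centres[2, ] - 10)), 10 * 3 * sigma / sqrt(100))
})

test_that("the objective trace is non-increasing and centres are means", {
  set.seed(16)
  pts <- matrix(rnorm(400), 200, 2)
  km <- kmeans_lloyd(pts, k = 5, seed = 3)
  expect_true(all(diff(km$objective) <= 1e-9))
  for (j in seq_len(5)) {
    members <- km$cluster == j
    if (any(members))
      expect_equal(km$centers[j, ], colMeans(pts[members, , drop = FALSE]))
  }
  expect_lte(km$objective[length(km$objective)], km$objective[1])
})

test_that("lloyd iterations agree with the reference implementation", {
  set.seed(17)
  pts <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
               matrix(rnorm(100, 8, 0.5), 50, 2))
  km <- kmeans_lloyd(pts, k = 2, max_iter = 100, seed = 7)
  set.seed(7)
  init <- pts[sample.int(nrow(pts), 2), ]
  ref <- stats::kmeans(pts, centers = init, algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(km$objective[length(km$objective)], ref$tot.withinss,
               tolerance = 1e-8)
})

test_that("image segmentation separates tones and ranks labels by intensity", {
  two <- matrix(c(rep(10L, 32), rep(200L, 32)), 8, 8)
  seg <- segment_image(two, k = 2, seed = 1)
  expect_true(all(seg$labels[two == 10] == 1))
  expect_true(all(seg$labels[two == 200] == 2))
  expect_equal(seg$centers, c(10, 200))

  ph <- generate_phantom(phantom_config(), seed = 3, force_tumour = TRUE)
  seg3 <- segment_image(ph$image, k = 3, seed = 1)
  expect_gte(mean(seg3$labels[ph$mask] == 3), 0.95)

  const <- segment_image(matrix(50L, 8, 8), k = 1, seed = 1)
  expect_true(all(const$labels == 1))
})
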