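test_that("Gaussian fuzzification matches its closed form", {
  g <- fuzzify(matrix(c(0.5, 0.7, 0.2), 1), centers = 0.5, widths = 0.2)
  expect_equal(g[[1]][1, 1], 1)
  expect_equal(g[[1]][1, 2], exp(-0.5), tolerance = 1e-12)  # |x-Mx| = sigma
  x <- matrix(runif(100), 10)
  for (grid in fuzzify(x, centers = c(0.2, 0.8), widths = 0.1)) {
    expect_true(all(grid >= 0 & grid <= 1))
  }
  expect_error(fuzzify(x, 0.5, 0), "positive")
})

test_that("fuzzy convolution implements both compositions", {
  x <- matrix(c(1, 3, 2, 4), 2, 2)          # [[1,2],[3,4]] row-wise
  expect_true(all(fuzzy_convolve(x, matrix(0, 1, 1), "sum") == 0))
  expect_equal(fuzzy_convolve(x, matrix(2, 1, 1), "sum"), 2 * x)
  memb <- matrix(c(0.2, 0.6, 0.8, 0.9), 2, 2)  # [[0.2,0.8],[0.6,0.9]]
  expect_equal(fuzzy_convolve(memb, matrix(0.5, 1, 1), "minmax"),
               matrix(c(0.2, 0.5, 0.5, 0.5), 2, 2))
  expect_error(fuzzy_convolve(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
  # sum mode agrees with a direct double loop on a random case
  set.seed(20)
  xr <- matrix(runif(36), 6, 6); k <- matrix(runif(9), 3, 3)
  out <- fuzzy_convolve(xr, k, "sum")
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(out[i, j], sum(k * xr[i:(i + 2), j:(j + 2)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("activation and pooling obey ReLU and window contracts", {
  neg <- matrix(-runif(16), 4, 4)
  expect_equal(activate_pool(neg, c(2, 2)), rep(0, 4))
  grid <- matrix(c(1, 3, 5, 2), 2, 2)       # [[1,5],[3,2]]
  expect_equal(activate_pool(grid, c(1, 1)), 5)
  expect_length(activate_pool(matrix(runif(36), 6), c(2, 3)), 6)
})

test_that("defuzzification is a convex combination of its centres", {
  expect_equal(defuzzify(3, 0.7), 0.7)                 # singleton
  expect_equal(defuzzify(c(1, 1), c(0, 10)), 5)
  expect_equal(defuzzify(c(0, 0), c(2, 6)), 4)         # zero-sum fallback
  expect_error(defuzzify(c(-1, 1), c(0, 1)), "non-negative")
  set.seed(21)
  for (rep in 1:20) {
    x <- runif(4); my <- rnorm(4)
    y <- defuzzify(x, my)
    expect_gte(y, min(my)); expect_lte(y, max(my))
  }
})

test_that("the forward pass is a deterministic score in (0,1)", {
  m <- fcnn_model(seed = 2)
  img <- rand_img(16, 16, seed = 1)
  z <- fcnn_forward(m, img)
  expect_gt(z, 0); expect_lt(z, 1)
  expect_equal(z, 0.5)                      # wf initialized at zero
  m$wf <- matrix(rnorm(length(m$wf)), nrow(m$wf))
  expect_identical(fcnn_forward(m, img), fcnn_forward(m, img))
})

test_that("cross-entropy matches hand values and stays non-negative", {
  expect_lte(cross_entropy(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(cross_entropy(0.5, 1), -log(0.5), tolerance = 1e-12)
  set.seed(22)
  expect_true(all(replicate(20, cross_entropy(runif(5), rbinom(5, 1, 0.5))) >= 0))
  expect_error(cross_entropy(c(0.5, 0.5), 1), "lengths differ")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  m <- fcnn_model(n_mf = 2, n_kernels = 2, kernel_size = 3,
                  pool_grid = c(2, 2), seed = 3)
  m$mx <- c(0.3, 0.7); m$sigma_x <- c(0.2, 0.2)
  m$my <- matrix(runif(4), 2, 2)
  m$wf <- matrix(rnorm(8, 0, 0.5), 2, 4); m$bf <- 0.1
  m$mz <- rnorm(2, 0, 0.2)
  m$calibrated <- TRUE
  img <- rand_img(8, 8, seed = 5)
  g <- fcnn_gradients(m, img, 1)
  fd_grad <- function(get_len, bump) {
    vapply(seq_len(get_len), function(i) {
      up <- cross_entropy(fcnn_forward(bump(m, i, 1e-6), img), 1)
      dn <- cross_entropy(fcnn_forward(bump(m, i, -1e-6), img), 1)
      (up - dn) / 2e-6
    }, numeric(1))
  }
  rel_err <- function(a, b) max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
  checks <- list(
    wf = list(g$wf, fd_grad(8, function(m, i, h) { m$wf[i] <- m$wf[i] + h; m })),
    my = list(g$my, fd_grad(4, function(m, i, h) { m$my[i] <- m$my[i] + h; m })),
    mz = list(g$mz, fd_grad(2, function(m, i, h) { m$mz[i] <- m$mz[i] + h; m })),
    mx = list(g$mx, fd_grad(2, function(m, i, h) { m$mx[i] <- m$mx[i] + h; m })),
    bf = list(g$bf, fd_grad(1, function(m, i, h) { m$bf <- m$bf + h; m })))
  for (nm in names(checks)) {
    expect_lt(rel_err(as.numeric(checks[[nm]][[1]]),
                      as.numeric(checks[[nm]][[2]])), 1e-4)
  }
})

test_that("zero learning rates leave every parameter untouched", {
  ds <- generate_dataset(8, 0.5, phantom_config(width = 16, height = 16,
                                                tumour_radius = c(2, 4)),
                         seed = 30)
  m <- fcnn_model(n_kernels = 2, seed = 4)
  m2 <- fcnn_train(m, ds$images, ds$labels, epochs = 3,
                   rates = list(fc = 0, my = 0, mz = 0, mx = 0),
                   calibrate = FALSE)
  attr(m2, "loss") <- NULL
  expect_identical(unclass(m2), unclass(m))
})

test_that("training reduces the loss on separable phantoms", {
  ds <- generate_dataset(40, 0.5, phantom_config(width = 24, height = 24,
                                                 tumour_radius = c(3, 5)),
                         seed = 31)
  m <- fcnn_model(n_kernels = 4, seed = 5)
  m <- fcnn_train(m, ds$images, ds$labels, epochs = 20)
  loss <- attr(m, "loss")
  expect_lt(loss[20], loss[1])
  expect_error(fcnn_train(m, ds$images, rep(1, 40), epochs = 1),
               "both classes")
})

test_that("label permutation leaves held-out accuracy at chance", {
  ds <- generate_dataset(60, 0.5, phantom_config(width = 24, height = 24,
                                                 tumour_radius = c(3, 5)),
                         seed = 32)
  set.seed(32)
  idx <- sample(60); tr <- idx[1:45]; te <- idx[46:60]
  accs <- vapply(1:3, function(s) {
    set.seed(300 + s)
    perm <- sample(60)                     # permute all labels jointly
    plab <- ds$labels[perm]
    m <- fcnn_model(n_kernels = 4, seed = 6)
    m <- fcnn_train(m, ds$images[tr], plab[tr], epochs = 25)
    mean(fcnn_predict(m, ds$images[te])$class == plab[te])
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("classification metrics match their defining ratios", {
  perfect <- classification_metrics(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_true(all(perfect == 1))
  m <- classification_metrics(list(tp = 40, fn = 10, tn = 30, fp = 20))
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.6)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["precision"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(m["f_measure"]), 2 * (2 / 3) * 0.8 / ((2 / 3) + 0.8),
               tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))
  undef <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(undef["precision"]))
  expect_equal(unname(undef["accuracy"]), 1)
  counts <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(counts), c(tp = 1, fp = 1, tn = 1, fn = 1))
})
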