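#' Principal component analysis with explained-variance selection
#'
#' Centres the columns, forms the `1/n`-scaled sample covariance,
#' eigendecomposes it, sorts the eigenvalues in descending order and
#' selects the smallest number of components whose cumulative
#' contribution rate strictly exceeds `threshold` (default 85%).
#' Eigenvector signs are fixed so the largest-magnitude entry of each
#' column is positive, making fits reproducible.
#'
#' @param x numeric matrix, `n` samples by `m` dimensions (`n >= 2`).
#' @param threshold cumulative contribution threshold in (0, 1).
#' @return An object of class `ipca` with fields `mean`, `values`
#'   (eigenvalues, descending), `vectors` (orthonormal columns),
#'   `contribution`, `cumulative`, `n_selected`, `threshold`.
#' @examples
#' x <- cbind(rnorm(200, sd = 3), rnorm(200, sd = 1))
#' fit <- fit_ipca(x)
#' fit$contribution
#' @export
fit_ipca <- function(x, threshold = 0.85) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 samples are required")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  co <- crossprod(xc) / nrow(x)
  eig <- eigen(co, symmetric = TRUE)
  vals <- pmax(eig$values, 0)          # clamp negative round-off
  vecs <- eig$vectors
  for (k in seq_len(ncol(vecs))) {
    s <- sign(vecs[which.max(abs(vecs[, k])), k])
    if (s < 0) vecs[, k] <- -vecs[, k]
  }
  total <- sum(vals)
  if (total <= 0) stop("data has zero variance; nothing to decompose")
  contrib <- vals / total
  cumul <- cumsum(contrib)
  n_sel <- which(cumul > threshold)[1]
  structure(list(mean = mu, values = vals, vectors = vecs,
                 contribution = contrib, cumulative = cumul,
                 n_selected = n_sel, threshold = threshold),
            class = "ipca")
}

#' Project data onto selected principal components
#'
#' `z = E^T (x - mean)` restricted to the first `n` components.
#'
#' @param model a fitted [fit_ipca()].
#' @param x numeric matrix with the training dimensionality.
#' @param n number of components (default: the model's selected count).
#' @return `n_samples x n` score matrix.
#' @export
transform_ipca <- function(model, x, n = model$n_selected) {
  stopifnot(inherits(model, "ipca"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("dimensionality mismatch: expected ", length(model$mean),
         " columns, got ", ncol(x))
  sweep(x, 2, model$mean) %*% model$vectors[, seq_len(n), drop = FALSE]
}

#' Reconstruct data from principal-component scores
#'
#' With all components retained the reconstruction is exact up to
#' round-off (orthonormal basis).
#'
#' @param model a fitted [fit_ipca()].
#' @param z score matrix from [transform_ipca()].
#' @return matrix in the original coordinates.
#' @export
ipca_reconstruct <- function(model, z) {
  stopifnot(inherits(model, "ipca"))
  z <- as.matrix(z)
  n <- ncol(z)
  sweep(z %*% t(model$vectors[, seq_len(n), drop = FALSE]), 2,
        model$mean, "+")
}

#' K-means clustering by Lloyd iterations
#'
#' Seeded initial centres are drawn from the data points. Each iteration
#' assigns every point to its nearest centre (Euclidean, ties broken by
#' the lowest centre index) and recomputes each centre as the arithmetic
#' mean of its members. A centre left empty is re-seeded at the point
#' farthest from its nearest centre. The within-cluster sum of squared
#' distances is recorded after every assignment step and is
#' non-increasing.
#'
#' @param points numeric matrix (`n x d`) or vector.
#' @param k number of clusters (`k <= n`).
#' @param max_iter maximum Lloyd iterations.
#' @param seed RNG seed for the initial centre draw.
#' @return An object of class `kmeans_model` with `centers`, `cluster`,
#'   `objective` (trace, one value per iteration), `iterations`,
#'   `converged`.
#' @export
kmeans_lloyd <- function(points, k, max_iter = 100L, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must be between 1 and the number of points")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  set.seed(seed)
  centers <- points[sample.int(n, k), , drop = FALSE]
  assign_old <- integer(n)
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j)
      rowSums(sweep(points, 2, centers[j, ], "-")^2))
    d2 <- matrix(d2, n, k)
    assign_new <- max.col(-d2, ties.method = "first")
    objective <- c(objective, sum(d2[cbind(seq_len(n), assign_new)]))
    for (j in seq_len(k)) {
      members <- assign_new == j
      if (any(members)) {
        centers[j, ] <- colMeans(points[members, , drop = FALSE])
      } else {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        centers[j, ] <- points[far, ]
      }
    }
    if (it > 1L && all(assign_new == assign_old)) { converged <- TRUE; break }
    assign_old <- assign_new
  }
  structure(list(centers = centers, cluster = assign_new,
                 objective = objective, iterations = length(objective),
                 converged = converged, k = k, seed = seed),
            class = "kmeans_model")
}

#' Segment an image by K-means on pixel intensities
#'
#' Clusters the pixel intensities into `k` groups and relabels the
#' clusters by ascending centre intensity, so label `k` always marks the
#' brightest tissue class (e.g. a tumour) regardless of the random
#' initialization.
#'
#' @param img integer matrix in 0..255.
#' @param k number of intensity classes.
#' @param max_iter,seed passed to [kmeans_lloyd()].
#' @return list of class `segmentation` with `labels` (integer matrix,
#'   values 1..k ascending in intensity), `centers` (sorted intensities)
#'   and the underlying `model`.
#' @export
segment_image <- function(img, k, max_iter = 100L, seed = 1L) {
  img <- check_gray(img)
  km <- kmeans_lloyd(matrix(as.numeric(img), ncol = 1), k, max_iter, seed)
  ord <- order(km$centers[, 1])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- matrix(relabel[km$cluster], nrow(img), ncol(img))
  structure(list(labels = labels, centers = km$centers[ord, 1],
                 model = km),
            class = "segmentation")
}
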