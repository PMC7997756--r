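#' Gaussian fuzzification of a value grid
#'
#' Maps each crisp value to its degree of membership in each fuzzy set:
#' `exp(-(x - Mx)^2 / (2 sigma^2))` per centre. Memberships lie in
#' (0, 1].
#'
#' @param x numeric matrix (or vector) of crisp values.
#' @param centers membership-function centres `Mx`.
#' @param widths positive widths `sigma`, one per centre (recycled).
#' @return list of membership grids, one per centre.
#' @export
fuzzify <- function(x, centers, widths) {
  widths <- rep_len(widths, length(centers))
  if (any(widths <= 0)) stop("membership widths must be positive")
  lapply(seq_along(centers), function(f)
    exp(-(x - centers[f])^2 / (2 * widths[f]^2)))
}

#' Fuzzy convolution of a membership grid
#'
#' Valid (no padding) convolution of a membership grid with a fuzzified
#' kernel. `mode = "sum"` is the ordinary sum of products; `mode =
#' "minmax"` is the fuzzy-relational min-max composition, replacing
#' multiply/add with min/max.
#'
#' @param xhat membership grid (matrix).
#' @param kernel fuzzified kernel `Wt_mu` (matrix no larger than `xhat`).
#' @param mode `"sum"` or `"minmax"`.
#' @return feature grid of size `(nrow(xhat)-nrow(kernel)+1) x
#'   (ncol(xhat)-ncol(kernel)+1)`.
#' @export
fuzzy_convolve <- function(xhat, kernel, mode = c("sum", "minmax")) {
  mode <- match.arg(mode)
  kr <- nrow(kernel); kc <- ncol(kernel)
  nr <- nrow(xhat) - kr + 1L; nc <- ncol(xhat) - kc + 1L
  if (nr < 1L || nc < 1L) stop("kernel larger than the input grid")
  out <- matrix(if (mode == "sum") 0 else -Inf, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      win <- xhat[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
      out <- if (mode == "sum") out + kernel[a, b] * win
             else pmax(out, pmin(kernel[a, b], win))
    }
  }
  out
}

#' ReLU activation followed by max pooling
#'
#' Applies `f(x) = max(x, 0)` elementwise, then takes the maximum over
#' each window of a `pool_grid[1] x pool_grid[2]` partition of the grid
#' (contiguous, near-equal windows).
#'
#' @param x feature grid.
#' @param pool_grid windows along rows and columns; `c(1, 1)` pools the
#'   whole grid to a single value.
#' @return numeric vector of window maxima, length `prod(pool_grid)`,
#'   windows listed row-major.
#' @export
activate_pool <- function(x, pool_grid = c(1L, 1L)) {
  g <- pool_windows(dim(x), pool_grid)
  y <- pmax(x, 0)
  vapply(g, function(w) max(y[w$rows, w$cols]), numeric(1))
}

# Partition dims into a gr x gc grid of contiguous windows (row-major).
pool_windows <- function(dims, pool_grid) {
  gr <- as.integer(pool_grid[1]); gc <- as.integer(pool_grid[2])
  if (gr > dims[1] || gc > dims[2])
    stop("pool grid ", gr, "x", gc, " does not fit a ",
         dims[1], "x", dims[2], " grid")
  rb <- ceiling(seq_len(dims[1]) * gr / dims[1])
  cb <- ceiling(seq_len(dims[2]) * gc / dims[2])
  out <- vector("list", gr * gc)
  w <- 0L
  for (a in seq_len(gr)) {
    for (b in seq_len(gc)) {
      w <- w + 1L
      out[[w]] <- list(rows = which(rb == a), cols = which(cb == b))
    }
  }
  out
}

#' Centre-of-gravity defuzzification
#'
#' Collapses non-negative membership strengths back to a crisp value:
#' `y = sum(My * x) / sum(x)`, a convex combination of the centres. When
#' every strength is zero the mean of the centres is returned.
#'
#' @param x non-negative strengths.
#' @param centers defuzzification centres `My`, same length as `x`.
#' @return crisp value within `[min(My), max(My)]`.
#' @export
defuzzify <- function(x, centers) {
  if (any(x < 0)) stop("defuzzification inputs must be non-negative")
  if (length(x) != length(centers)) stop("`x` and `centers` lengths differ")
  s <- sum(x)
  if (s == 0) mean(centers) else sum(centers * x) / s
}

#' Construct a fuzzy convolutional network
#'
#' Architecture: Gaussian fuzzification of the input into `n_mf`
#' membership grids; `n_kernels` fuzzified convolution kernels (each
#' kernel's weights pass through a Gaussian membership with centre `Mz`
#' before use) applied to every membership grid; ReLU and max pooling on
#' a fixed window grid; centre-of-gravity defuzzification pairing the
#' membership branches per kernel/window; a fully connected sigmoid
#' output unit for the binary normal/abnormal decision.
#'
#' Fuzzification centres default to "dark"/"bright" placeholders and are
#' calibrated from training data by [fcnn_train()].
#'
#' @param n_mf number of membership functions on the input (default 2).
#' @param n_kernels number of convolution kernels.
#' @param kernel_size kernel side length.
#' @param pool_grid pooling windows, `c(rows, cols)`.
#' @param conv_mode `"sum"` (ordinary convolution of the printed model)
#'   or `"minmax"` (fuzzy relational composition).
#' @param sigma_z width of the kernel-weight membership.
#' @param seed RNG seed for kernel initialization.
#' @return An object of class `fcnn` holding `mx`, `sigma_x`, `wt`
#'   (kernel list), `mz`, `my`, `wf`, `bf` and the layout fields.
#' @export
fcnn_model <- function(n_mf = 2L, n_kernels = 4L, kernel_size = 3L,
                       pool_grid = c(2L, 2L),
                       conv_mode = c("sum", "minmax"),
                       sigma_z = 1, seed = 1L) {
  conv_mode <- match.arg(conv_mode)
  n_mf <- as.integer(n_mf); n_kernels <- as.integer(n_kernels)
  set.seed(seed)
  wt <- lapply(seq_len(n_kernels), function(c)
    matrix(stats::rnorm(kernel_size^2, 0, 0.5), kernel_size, kernel_size))
  n_windows <- prod(pool_grid)
  structure(list(
    n_mf = n_mf, n_kernels = n_kernels, kernel_size = as.integer(kernel_size),
    pool_grid = as.integer(pool_grid), conv_mode = conv_mode,
    mx = seq(0.2, 0.8, length.out = n_mf),
    sigma_x = rep(0.3, n_mf),
    wt = wt, mz = numeric(n_kernels), sigma_z = sigma_z,
    my = matrix(rep(seq(0, 1, length.out = n_mf), n_kernels), n_mf, n_kernels),
    wf = matrix(0, n_kernels, n_windows), bf = 0,
    calibrated = FALSE, seed = as.integer(seed)),
    class = "fcnn")
}

fuzzified_kernels <- function(model) {
  lapply(seq_len(model$n_kernels), function(c)
    exp(-(model$wt[[c]] - model$mz[c])^2 / (2 * model$sigma_z^2)))
}

# Forward pass with cached intermediates for the backward pass.
fcnn_forward_cache <- function(model, img) {
  x <- as.matrix(img) / 255
  xhat <- fuzzify(x, model$mx, model$sigma_x)
  wtmu <- fuzzified_kernels(model)
  nw <- prod(model$pool_grid)
  f_n <- model$n_mf; c_n <- model$n_kernels
  conv <- vector("list", f_n * c_n)
  p <- array(0, c(f_n, c_n, nw))
  argmax <- array(0L, c(f_n, c_n, nw, 2L))
  windows <- NULL
  for (f in seq_len(f_n)) {
    for (c in seq_len(c_n)) {
      cv <- fuzzy_convolve(xhat[[f]], wtmu[[c]], model$conv_mode)
      if (is.null(windows)) windows <- pool_windows(dim(cv), model$pool_grid)
      cvr <- pmax(cv, 0)
      conv[[(f - 1L) * c_n + c]] <- cv
      for (w in seq_len(nw)) {
        sub <- cvr[windows[[w]]$rows, windows[[w]]$cols, drop = FALSE]
        mi <- arrayInd(which.max(sub), dim(sub))
        p[f, c, w] <- sub[mi]
        argmax[f, c, w, ] <- c(windows[[w]]$rows[mi[1]],
                               windows[[w]]$cols[mi[2]])
      }
    }
  }
  y <- matrix(0, c_n, nw)
  s_tot <- matrix(0, c_n, nw)
  for (c in seq_len(c_n)) {
    for (w in seq_len(nw)) {
      s <- sum(p[, c, w])
      s_tot[c, w] <- s
      y[c, w] <- if (s == 0) mean(model$my[, c])
                 else sum(model$my[, c] * p[, c, w]) / s
    }
  }
  score_in <- sum(model$wf * y) + model$bf
  zhat <- 1 / (1 + exp(-score_in))
  list(x = x, xhat = xhat, wtmu = wtmu, conv = conv, p = p,
       argmax = argmax, s_tot = s_tot, y = y, zhat = zhat)
}

#' Forward pass of the fuzzy convolutional network
#'
#' @param model an [fcnn_model()].
#' @param img integer matrix in 0..255 (scaled internally to `[0, 1]`).
#' @return class score strictly in (0, 1).
#' @export
fcnn_forward <- function(model, img) {
  stopifnot(inherits(model, "fcnn"))
  fcnn_forward_cache(model, img)$zhat
}

#' Binary cross-entropy loss
#'
#' `CE = -(1/N) sum(z ln zhat + (1-z) ln(1-zhat))` with scores clipped to
#' `[1e-12, 1 - 1e-12]` (natural log).
#'
#' @param zhat predicted scores in (0, 1).
#' @param z binary labels (0/1).
#' @return non-negative loss.
#' @export
cross_entropy <- function(zhat, z) {
  if (length(zhat) != length(z)) stop("score and label lengths differ")
  eps <- 1e-12
  zhat <- pmin(pmax(zhat, eps), 1 - eps)
  -mean(z * log(zhat) + (1 - z) * log(1 - zhat))
}

#' Analytic gradients of the cross-entropy for one sample
#'
#' Chain-rule gradients of the per-sample cross-entropy with respect to
#' each trainable group: output weights `wf`/`bf`, defuzzification
#' centres `my`, kernel-membership centres `mz` and fuzzification centres
#' `mx`. In `minmax` convolution mode only `wf`, `bf` and `my` receive
#' gradients (min/max kernels are held fixed). Mainly exposed so the
#' gradients can be verified against finite differences.
#'
#' @param model an [fcnn_model()].
#' @param img integer matrix in 0..255.
#' @param label 0 or 1.
#' @return list with `wf`, `bf`, `my`, `mz`, `mx` and the sample loss.
#' @export
fcnn_gradients <- function(model, img, label) {
  stopifnot(inherits(model, "fcnn"))
  cache <- fcnn_forward_cache(model, img)
  f_n <- model$n_mf; c_n <- model$n_kernels
  nw <- prod(model$pool_grid)
  ks <- model$kernel_size
  g_s <- cache$zhat - label            # dCE/d(score input)
  g_wf <- g_s * cache$y
  g_bf <- g_s
  dL_dy <- g_s * model$wf
  g_my <- matrix(0, f_n, c_n)
  dL_dp <- array(0, c(f_n, c_n, nw))
  for (c in seq_len(c_n)) {
    for (w in seq_len(nw)) {
      s <- cache$s_tot[c, w]
      if (s == 0) {
        g_my[, c] <- g_my[, c] + dL_dy[c, w] / f_n
      } else {
        g_my[, c] <- g_my[, c] + dL_dy[c, w] * cache$p[, c, w] / s
        dL_dp[, c, w] <- dL_dy[c, w] * (model$my[, c] - cache$y[c, w]) / s
      }
    }
  }
  g_mz <- numeric(c_n)
  g_mx <- numeric(f_n)
  if (model$conv_mode == "sum") {
    for (c in seq_len(c_n)) {
      g_wtmu <- matrix(0, ks, ks)
      for (f in seq_len(f_n)) {
        for (w in seq_len(nw)) {
          gp <- dL_dp[f, c, w]
          if (gp == 0 || cache$p[f, c, w] <= 0) next
          io <- cache$argmax[f, c, w, 1]; jo <- cache$argmax[f, c, w, 2]
          patch <- cache$xhat[[f]][io:(io + ks - 1L), jo:(jo + ks - 1L)]
          g_wtmu <- g_wtmu + gp * patch
          # membership grid gradient routed straight to the centre mx[f]
          xpatch <- cache$x[io:(io + ks - 1L), jo:(jo + ks - 1L)]
          g_mx[f] <- g_mx[f] + gp * sum(
            cache$wtmu[[c]] * patch * (xpatch - model$mx[f]) /
              model$sigma_x[f]^2)
        }
      }
      g_mz[c] <- sum(g_wtmu * cache$wtmu[[c]] *
                       (model$wt[[c]] - model$mz[c]) / model$sigma_z^2)
    }
  }
  list(wf = g_wf, bf = g_bf, my = g_my, mz = g_mz, mx = g_mx,
       loss = cross_entropy(cache$zhat, label))
}

#' Train the fuzzy convolutional network
#'
#' Full-batch gradient descent with per-group learning rates on the
#' binary cross-entropy. Unless centres were calibrated already, the
#' fuzzification centres `Mx` are initialized at the 1st and 99th
#' intensity percentiles of the training pixels ("dark"/"bright"
#' linguistic labels) with widths set to half the centre distance, and
#' the defuzzification centres `My` are spread over `[0, 1]`.
#'
#' @param model an [fcnn_model()].
#' @param images list of integer matrices in 0..255.
#' @param labels binary vector (both classes must be present).
#' @param epochs training epochs.
#' @param rates named list of learning rates: `fc` (output weights), `my`,
#'   `mz`, `mx`.
#' @param calibrate recalibrate `Mx` from the data before training.
#' @return the trained model, with a `loss` attribute giving the
#'   per-epoch cross-entropy trace.
#' @export
fcnn_train <- function(model, images, labels, epochs = 50L,
                       rates = list(fc = 0.5, my = 0.05, mz = 0.02,
                                    mx = 0.02),
                       calibrate = TRUE) {
  stopifnot(inherits(model, "fcnn"))
  labels <- as.numeric(labels)
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  if (length(unique(labels)) < 2L)
    stop("training requires both classes to be present")
  if (calibrate && !model$calibrated) {
    px <- unlist(lapply(images, function(im) as.numeric(im) / 255))
    qs <- stats::quantile(px, probs = seq(0.01, 0.99,
                                          length.out = model$n_mf),
                          names = FALSE)
    qs <- qs + seq_along(qs) * 1e-6    # guard against coincident centres
    model$mx <- qs
    model$sigma_x <- rep(max(diff(range(qs)) / 2, 0.05), model$n_mf)
    model$calibrated <- TRUE
  }
  n <- length(images)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    acc <- NULL
    loss <- 0
    for (i in seq_len(n)) {
      g <- fcnn_gradients(model, images[[i]], labels[i])
      loss <- loss + g$loss
      if (is.null(acc)) acc <- g
      else {
        acc$wf <- acc$wf + g$wf; acc$bf <- acc$bf + g$bf
        acc$my <- acc$my + g$my; acc$mz <- acc$mz + g$mz
        acc$mx <- acc$mx + g$mx
      }
    }
    trace[ep] <- loss / n
    model$wf <- model$wf - rates$fc * acc$wf / n
    model$bf <- model$bf - rates$fc * acc$bf / n
    model$my <- model$my - rates$my * acc$my / n
    if (model$conv_mode == "sum") {
      model$mz <- model$mz - rates$mz * acc$mz / n
      model$mx <- model$mx - rates$mx * acc$mx / n
    }
  }
  attr(model, "loss") <- trace
  model
}

#' Predict class scores for a list of images
#'
#' @param model a trained [fcnn_model()].
#' @param images list of integer matrices.
#' @param threshold decision threshold on the sigmoid score.
#' @return list with `score` and binary `class` vectors.
#' @export
fcnn_predict <- function(model, images, threshold = 0.5) {
  score <- vapply(images, function(im) fcnn_forward(model, im), numeric(1))
  list(score = score, class = as.integer(score >= threshold))
}

#' Confusion counts for binary predictions
#'
#' @param predicted,truth binary vectors.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  list(tp = sum(predicted == 1 & truth == 1),
       fp = sum(predicted == 1 & truth == 0),
       tn = sum(predicted == 0 & truth == 0),
       fn = sum(predicted == 0 & truth == 1))
}

#' Classification metrics from confusion counts
#'
#' Specificity `TN/(TN+FP)`, sensitivity (= recall) `TP/(TP+FN)`,
#' accuracy `(TN+TP)/total`, precision `TP/(TP+FP)` and the F-measure
#' `2 * precision * recall / (precision + recall)`. A metric whose
#' denominator is zero is returned as `NA` rather than raising an error.
#'
#' @param counts a [confusion_counts()] list (or arguments `tp`, `fp`,
#'   `tn`, `fn`).
#' @return named numeric vector with `specificity`, `sensitivity`,
#'   `accuracy`, `precision`, `recall`, `f_measure`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  spec <- safe(tn, tn + fp)
  sens <- safe(tp, tp + fn)
  prec <- safe(tp, tp + fp)
  f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  c(specificity = spec, sensitivity = sens, accuracy = (tn + tp) / total,
    precision = prec, recall = sens, f_measure = f)
}
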