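#' Phantom generator configuration
#'
#' Geometry and intensity settings for the synthetic MRI-like brain
#' phantoms: an elliptical "brain" on a dark background with Gaussian
#' pixel noise and, optionally, a bright disk "tumour". Intensities are
#' 8-bit gray levels.
#'
#' @param width,height image size in pixels.
#' @param background background gray level.
#' @param brain_intensity gray level of the brain ellipse.
#' @param contrast tumour brightness above the brain level (tumour level
#'   = `brain_intensity + contrast`).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param tumour_prob probability that a phantom carries a tumour.
#' @param tumour_radius inclusive radius range in pixels.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(width = 64L, height = 64L, background = 15,
                           brain_intensity = 90, contrast = 110,
                           noise_sd = 8, tumour_prob = 0.5,
                           tumour_radius = c(4, 8)) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 8L || height < 8L) stop("phantoms must be at least 8x8")
  if (any(c(background, brain_intensity) < 0) ||
      brain_intensity + contrast > 255)
    stop("intensities must stay within 0..255")
  if (max(tumour_radius) >= min(width, height) / 2)
    stop("tumour radius too large for the image")
  structure(list(width = width, height = height, background = background,
                 brain_intensity = brain_intensity, contrast = contrast,
                 noise_sd = noise_sd, tumour_prob = tumour_prob,
                 tumour_radius = as.numeric(tumour_radius)),
            class = "phantom_config")
}

#' Generate one brain phantom
#'
#' Draws an ellipse ("brain") with slightly jittered axes, optional
#' bright tumour disk inside it, adds Gaussian noise and clips to 0..255.
#' Fully deterministic under `seed`.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @param force_tumour `NA` to draw presence with `tumour_prob`,
#'   otherwise `TRUE`/`FALSE` to force the class.
#' @return list with `image` (integer matrix), `label` (1 iff a tumour is
#'   present) and `mask` (logical matrix of tumour pixels).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L,
                             force_tumour = NA) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  w <- config$width; h <- config$height
  cx <- w / 2 + stats::runif(1, -1, 1)
  cy <- h / 2 + stats::runif(1, -1, 1)
  ax <- w * stats::runif(1, 0.33, 0.40)
  ay <- h * stats::runif(1, 0.28, 0.36)
  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  brain <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1
  img <- matrix(config$background, h, w)
  img[brain] <- config$brain_intensity
  has_tumour <- if (is.na(force_tumour))
    stats::runif(1) < config$tumour_prob else isTRUE(force_tumour)
  mask <- matrix(FALSE, h, w)
  if (has_tumour) {
    r <- stats::runif(1, config$tumour_radius[1], config$tumour_radius[2])
    tx <- cx + stats::runif(1, -0.5, 0.5) * (ax - r)
    ty <- cy + stats::runif(1, -0.5, 0.5) * (ay - r)
    mask <- (xg - tx)^2 + (yg - ty)^2 <= r^2
    img[mask] <- config$brain_intensity + config$contrast
  }
  img <- img + stats::rnorm(h * w, 0, config$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  list(image = img, label = as.integer(has_tumour), mask = mask)
}

#' Generate a stratified phantom dataset
#'
#' Exactly `round(n * tumour_fraction)` positives; each phantom is built
#' from its own sub-seed so the whole dataset is reproducible and the
#' class sequence is shuffled deterministically.
#'
#' @param n number of phantoms (>= 2).
#' @param tumour_fraction fraction of tumour-positive phantoms.
#' @param config a [phantom_config()].
#' @param seed master seed.
#' @return list with `images` (list), `labels` (integer vector), `masks`
#'   (list of logical matrices).
#' @export
generate_dataset <- function(n, tumour_fraction = 0.5,
                             config = phantom_config(), seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2")
  n_pos <- round(n * tumour_fraction)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, n)
  classes <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
  out <- lapply(seq_len(n), function(i)
    generate_phantom(config, subseeds[i], force_tumour = classes[i]))
  list(images = lapply(out, `[[`, "image"),
       labels = vapply(out, `[[`, integer(1), "label"),
       masks = lapply(out, `[[`, "mask"))
}

#' Canonical cipher test images
#'
#' Four standard images for entropy/correlation/differential studies: a
#' constant image, a horizontal gradient ramp, a checkerboard and a
#' uniform-random image.
#'
#' @param size side length (>= 2) or `c(rows, cols)`.
#' @param seed RNG seed for the random image.
#' @return named list of integer matrices.
#' @export
generate_cipher_testset <- function(size = 256L, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  p <- as.integer(size[1]); q <- as.integer(size[2])
  if (p < 2L || q < 2L) stop("`size` must be at least 2x2")
  constant <- matrix(128L, p, q)
  gradient <- matrix(rep(round(seq(0, 255, length.out = q)), each = p), p, q)
  checker <- matrix(ifelse((outer(seq_len(p), seq_len(q), "+")) %% 2 == 0,
                           0L, 255L), p, q)
  set.seed(seed)
  random <- matrix(sample(0:255, p * q, replace = TRUE), p, q)
  out <- list(constant = constant, gradient = gradient,
              checkerboard = checker, random = random)
  lapply(out, function(m) { storage.mode(m) <- "integer"; m })
}
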