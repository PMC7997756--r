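#' Shannon entropy of an 8-bit image
#'
#' `F = -sum p(v) log2 p(v)` over the 256-bin pixel histogram; empty bins
#' contribute zero. 8 bits is the ideal for the ciphertext of an 8-bit
#' cipher: a value near 8 means the gray levels are indistinguishable
#' from uniform.
#'
#' @param img integer matrix with values in 0..255.
#' @return entropy in bits per pixel, in `[0, 8]`.
#' @export
img_entropy <- function(img) {
  img <- check_gray(img)
  p <- tabulate(as.vector(img) + 1L, 256L) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Correlation of adjacent pixel pairs
#'
#' Samples `n_pairs` random positions that have a valid neighbour in the
#' requested direction (horizontal = offset (0,+1), vertical = (+1,0),
#' diagonal = (+1,+1)) and returns the Pearson correlation of the pixel
#' and its neighbour. Plain images score near 1; a good ciphertext scores
#' near 0 in every direction. If either marginal is constant the
#' correlation is undefined; 0 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param img integer matrix.
#' @param direction one of `"horizontal"`, `"vertical"`, `"diagonal"`.
#' @param n_pairs number of sampled pairs (default 2000).
#' @param seed RNG seed for the sampling.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
adjacent_correlation <- function(img,
                                 direction = c("horizontal", "vertical",
                                               "diagonal"),
                                 n_pairs = 2000L, seed = 1L) {
  direction <- match.arg(direction)
  img <- check_gray(img)
  off <- switch(direction, horizontal = c(0L, 1L), vertical = c(1L, 0L),
                diagonal = c(1L, 1L))
  nr <- nrow(img) - off[1]; nc <- ncol(img) - off[2]
  if (nr < 1L || nc < 1L || nr * nc < n_pairs)
    stop("image too small to supply ", n_pairs, " ", direction, " pairs")
  set.seed(seed)
  idx <- sample.int(nr * nc, n_pairs)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  x <- img[cbind(i, j)]
  y <- img[cbind(i + off[1], j + off[2])]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y)
}

#' Number of pixels change rate (NPCR)
#'
#' Percentage of positions at which two equally sized images differ:
#' `100 * #\{E1(i,j) != E2(i,j)\} / (m*n)`. For a strong cipher two
#' ciphertexts of one-pixel-different plaintexts behave as independent
#' uniform images, giving an expectation of `100 * (1 - 2^-8) = 99.61`.
#'
#' @param e1,e2 integer matrices of identical shape.
#' @return percentage in `[0, 100]`.
#' @export
npcr <- function(e1, e2) {
  if (!all(dim(e1) == dim(e2))) stop("images must have identical shapes")
  100 * mean(e1 != e2)
}

#' Unified average changing intensity (UACI)
#'
#' Mean absolute intensity difference as a percentage of the maximum gray
#' level: `100 * mean(|E1 - E2| / 255)`. For independent uniform 8-bit
#' images the expectation is 33.46.
#'
#' @inheritParams npcr
#' @return percentage in `[0, 100]`.
#' @export
uaci <- function(e1, e2) {
  if (!all(dim(e1) == dim(e2))) stop("images must have identical shapes")
  100 * mean(abs(as.numeric(e1) - as.numeric(e2)) / 255)
}

#' Full cryptanalysis report for a plain/cipher image pair
#'
#' Encrypts `plain`, then encrypts a copy with one randomly chosen pixel
#' replaced by a new uniform value, and assembles entropy, directional
#' adjacent-pixel correlations (plain and cipher), NPCR and UACI of the
#' ciphertext pair.
#'
#' @param plain integer matrix in 0..255.
#' @param key a [chaos_key()].
#' @param config a [cipher_config()].
#' @param n_pairs sampled pairs per correlation direction.
#' @param seed RNG seed (pixel perturbation and correlation sampling).
#' @return list of class `security_report`.
#' @export
security_report <- function(plain, key, config = cipher_config(),
                            n_pairs = 2000L, seed = 1L) {
  plain <- check_gray(plain)
  set.seed(seed)
  pos <- sample.int(length(plain), 1L)
  old <- plain[pos]
  plain2 <- plain
  plain2[pos] <- sample(setdiff(0:255, old), 1L)
  e1 <- encrypt_image(plain, key, config)$cipher
  e2 <- encrypt_image(plain2, key, config)$cipher
  dirs <- c("horizontal", "vertical", "diagonal")
  corr <- function(im) vapply(dirs, function(d)
    as.numeric(adjacent_correlation(im, d, n_pairs, seed)), numeric(1))
  structure(list(entropy_plain = img_entropy(plain),
                 entropy_cipher = img_entropy(e1),
                 correlation_plain = corr(plain),
                 correlation_cipher = corr(e1),
                 npcr = npcr(e1, e2), uaci = uaci(e1, e2),
                 n_pairs = n_pairs, seed = seed),
            class = "security_report")
}

#' @export
print.security_report <- function(x, ...) {
  cat("<security_report>\n")
  cat(sprintf("  entropy   plain %.4f  cipher %.4f bits\n",
              x$entropy_plain, x$entropy_cipher))
  cat(sprintf("  corr plain   H %+ .4f  V %+ .4f  D %+ .4f\n",
              x$correlation_plain[1], x$correlation_plain[2],
              x$correlation_plain[3]))
  cat(sprintf("  corr cipher  H %+ .4f  V %+ .4f  D %+ .4f\n",
              x$correlation_cipher[1], x$correlation_cipher[2],
              x$correlation_cipher[3]))
  cat(sprintf("  NPCR %.4f %%   UACI %.4f %%  (%d pairs, seed %d)\n",
              x$npcr, x$uaci, x$n_pairs, x$seed))
  invisible(x)
}

#' Differential-attack benchmark over seeded trials
#'
#' For each trial: draw a uniform-random plaintext, flip one uniformly
#' chosen pixel to a new uniform value, encrypt both copies with one
#' random key, and record NPCR and UACI of the ciphertext pair. Keys and
#' images are derived from per-trial sub-seeds of `seed`, so the whole
#' study is reproducible.
#'
#' @param n_trials number of seeded trials (default 50).
#' @param size image size `c(rows, cols)` or a single side length.
#' @param seed master seed.
#' @param config a [cipher_config()].
#' @return list with per-trial `npcr`/`uaci` vectors and their means.
#' @export
differential_analysis <- function(n_trials = 50L, size = 256L, seed = 1L,
                                  config = cipher_config()) {
  if (length(size) == 1L) size <- c(size, size)
  p <- as.integer(size[1]); q <- as.integer(size[2])
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, n_trials)
  np <- numeric(n_trials); ua <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(subseeds[t])
    img1 <- matrix(sample(0:255, p * q, replace = TRUE), p, q)
    pos <- sample.int(p * q, 1L)
    img2 <- img1
    img2[pos] <- sample(setdiff(0:255, img1[pos]), 1L)
    key <- chaos_key(x0 = stats::runif(3, 0.05, 0.95))
    e1 <- encrypt_image(img1, key, config)$cipher
    e2 <- encrypt_image(img2, key, config)$cipher
    np[t] <- npcr(e1, e2)
    ua[t] <- uaci(e1, e2)
  }
  list(npcr = np, uaci = ua,
       mean_npcr = mean(np), mean_uaci = mean(ua),
       n_trials = n_trials, size = c(p, q), seed = seed)
}
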