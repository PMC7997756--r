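#' Cipher configuration
#'
#' @param use_compression logical; when `TRUE` the image is normalized,
#'   cut into blocks and compressed by the block autoencoder before
#'   confusion/diffusion, and decryption is lossy. The default (`FALSE`)
#'   keeps the cipher lossless on raw 8-bit pixels, which is what a
#'   downstream diagnostic stage requires.
#' @param block_size side of the square sub-image blocks fed to the
#'   compressor.
#' @param hidden_nodes autoencoder hidden-layer width; the compression
#'   rate is `block_size^2 / hidden_nodes`.
#' @param epochs,rate,momentum compressor training settings.
#' @param target normalization target interval `[Ymin, Ymax]`.
#' @param chain diffusion chaining rule passed to [diffuse()];
#'   `"arx"` (default) propagates carries so one plaintext change
#'   reaches essentially every ciphertext byte, `"xor"` is the plain XOR
#'   chain.
#' @param rounds number of forward+reverse diffusion rounds. One round
#'   leaves a small-probability event in which the chain value at the
#'   modified position coincides and the whole prefix stays unchanged;
#'   the second round removes it.
#' @param seed seed for compressor weight initialization.
#' @return list of class `cipher_config`.
#' @export
cipher_config <- function(use_compression = FALSE, block_size = 8L,
                          hidden_nodes = 16L, epochs = 500L, rate = 0.2,
                          momentum = 0.9, target = c(0, 1),
                          chain = c("arx", "xor"), rounds = 2L,
                          seed = 1L) {
  chain <- match.arg(chain)
  rounds <- as.integer(rounds)
  if (rounds < 1L) stop("`rounds` must be >= 1")
  block_size <- as.integer(block_size)
  hidden_nodes <- as.integer(hidden_nodes)
  if (block_size < 1L) stop("`block_size` must be >= 1")
  if (hidden_nodes < 1L) stop("`hidden_nodes` must be >= 1")
  if (length(target) != 2L || target[2] <= target[1])
    stop("`target` must be an increasing interval")
  structure(list(use_compression = isTRUE(use_compression),
                 block_size = block_size, hidden_nodes = hidden_nodes,
                 epochs = as.integer(epochs), rate = rate,
                 momentum = momentum, target = as.numeric(target),
                 chain = chain, rounds = rounds, seed = as.integer(seed)),
            class = "cipher_config")
}

#' Min-max normalization of an image
#'
#' Linearly maps the observed pixel range `[Xmin, Xmax]` onto the target
#' `[Ymin, Ymax]` (default `[0, 1]`), accelerating compressor training. A
#' constant image maps everywhere to `Ymin`.
#'
#' @param img numeric matrix.
#' @param target `c(Ymin, Ymax)`.
#' @return list with `values` (normalized matrix), `xmin`, `xmax`.
#' @export
normalize_image <- function(img, target = c(0, 1)) {
  xmin <- min(img); xmax <- max(img)
  ymin <- target[1]; ymax <- target[2]
  vals <- if (xmax > xmin) {
    (ymax - ymin) * (img - xmin) / (xmax - xmin) + ymin
  } else {
    matrix(ymin, nrow(img), ncol(img))
  }
  list(values = vals, xmin = xmin, xmax = xmax)
}

denormalize_image <- function(vals, xmin, xmax, target = c(0, 1)) {
  ymin <- target[1]; ymax <- target[2]
  if (xmax > xmin) {
    (vals - ymin) / (ymax - ymin) * (xmax - xmin) + xmin
  } else {
    matrix(xmin, nrow(vals), ncol(vals))
  }
}

#' Cut an image into square blocks (and back)
#'
#' `blockify` reflect-pads the image up to the next multiple of `m` in
#' each dimension and cuts it into `H = ceil(P/m) * ceil(Q/m)` blocks of
#' `m x m`, returned flattened one block per row (row-major within the
#' block, blocks listed row-major across the grid). `deblockify` inverts
#' the operation exactly, stripping the recorded padding.
#'
#' @param img numeric matrix.
#' @param m block side (>= 1).
#' @param bs a block set produced by `blockify`.
#' @return `blockify`: list of class `block_set` with `blocks`
#'   (`H x m^2` matrix), `m`, `shape`, `pad`. `deblockify`: the original
#'   matrix.
#' @export
blockify <- function(img, m) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1")
  p <- nrow(img); q <- ncol(img)
  pr <- (m - p %% m) %% m
  pc <- (m - q %% m) %% m
  padded <- img
  if (pr > 0L) {
    refl <- img[p:(p - pr + 1L), , drop = FALSE]  # reflect-pad rows
    padded <- rbind(padded, refl)
  }
  if (pc > 0L) {
    refl <- padded[, q:(q - pc + 1L), drop = FALSE]
    padded <- cbind(padded, refl)
  }
  gr <- nrow(padded) %/% m; gc <- ncol(padded) %/% m
  blocks <- matrix(0, gr * gc, m * m)
  h <- 0L
  for (bi in seq_len(gr)) {
    for (bj in seq_len(gc)) {
      h <- h + 1L
      blk <- padded[((bi - 1L) * m + 1L):(bi * m),
                    ((bj - 1L) * m + 1L):(bj * m), drop = FALSE]
      blocks[h, ] <- as.vector(t(blk))
    }
  }
  structure(list(blocks = blocks, m = m, shape = c(p, q), pad = c(pr, pc)),
            class = "block_set")
}

#' @rdname blockify
#' @export
deblockify <- function(bs) {
  stopifnot(inherits(bs, "block_set"))
  m <- bs$m
  p <- bs$shape[1]; q <- bs$shape[2]
  gr <- (p + bs$pad[1]) %/% m; gc <- (q + bs$pad[2]) %/% m
  out <- matrix(0, gr * m, gc * m)
  h <- 0L
  for (bi in seq_len(gr)) {
    for (bj in seq_len(gc)) {
      h <- h + 1L
      out[((bi - 1L) * m + 1L):(bi * m), ((bj - 1L) * m + 1L):(bj * m)] <-
        matrix(bs$blocks[h, ], m, m, byrow = TRUE)
    }
  }
  out[seq_len(p), seq_len(q), drop = FALSE]
}

#' Neural transfer functions
#'
#' `logsig(x) = 1/(1 + e^-x)` and `tansig(x) = 2/(1 + e^-2x) - 1`, the
#' hidden/output transfer functions of the block autoencoder.
#'
#' @param x numeric.
#' @param kind `"logsig"` or `"tansig"`.
#' @return numeric of the same shape.
#' @export
transfer_fun <- function(x, kind = c("logsig", "tansig")) {
  kind <- match.arg(kind)
  switch(kind,
         logsig = 1 / (1 + exp(-x)),
         tansig = 2 / (1 + exp(-2 * x)) - 1)
}

#' Fit the block autoencoder compressor
#'
#' Trains a single-hidden-layer feed-forward autoencoder (tansig hidden,
#' logsig output) on the image's own normalized blocks by full-batch
#' gradient descent with momentum on mean squared error. The hidden layer
#' is the compressed code; the compression rate is
#' `t = input_nodes / hidden_nodes`.
#'
#' @param bs a [blockify()] result whose blocks are scaled to `[0, 1]`.
#' @param hidden number of hidden nodes (>= 1).
#' @param epochs,rate,momentum training hyperparameters.
#' @param seed RNG seed for weight initialization (reproducible fits).
#' @return list of class `bp_compressor` with encoder/decoder weights,
#'   `rate_t` (compression rate) and the training loss trace.
#' @export
fit_compressor <- function(bs, hidden, epochs = 500L, rate = 0.2,
                           momentum = 0.9, seed = 1L) {
  stopifnot(inherits(bs, "block_set"))
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("`hidden` must be >= 1")
  x <- bs$blocks
  ui <- ncol(x)
  set.seed(seed)
  w1 <- matrix(stats::runif(ui * hidden, -0.5, 0.5), ui, hidden) / sqrt(ui)
  b1 <- numeric(hidden)
  w2 <- matrix(stats::runif(hidden * ui, -0.5, 0.5), hidden, ui) / sqrt(hidden)
  b2 <- numeric(ui)
  v1 <- w1 * 0; vb1 <- b1; v2 <- w2 * 0; vb2 <- b2
  n <- nrow(x)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    h <- tanh(sweep(x %*% w1, 2, b1, "+"))
    o <- transfer_fun(sweep(h %*% w2, 2, b2, "+"), "logsig")
    err <- o - x
    trace[ep] <- mean(err^2)
    do <- 2 * err * o * (1 - o) / (n * ui)
    dh <- (do %*% t(w2)) * (1 - h^2)
    g2 <- t(h) %*% do;  gb2 <- colSums(do)
    g1 <- t(x) %*% dh;  gb1 <- colSums(dh)
    v1 <- momentum * v1 - rate * g1;   w1 <- w1 + v1
    vb1 <- momentum * vb1 - rate * gb1; b1 <- b1 + vb1
    v2 <- momentum * v2 - rate * g2;   w2 <- w2 + v2
    vb2 <- momentum * vb2 - rate * gb2; b2 <- b2 + vb2
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 input_nodes = ui, hidden_nodes = hidden,
                 rate_t = ui / hidden, loss = trace),
            class = "bp_compressor")
}

#' Compress / reconstruct blocks through the autoencoder
#'
#' `compress_blocks` maps each block to its hidden code (tansig values in
#' (-1, 1)) quantized to 8-bit, giving an `H x hidden` code image.
#' `reconstruct_blocks` de-quantizes and applies the decoder. The round
#' trip is lossy by design.
#'
#' @param bs a [blockify()] result with blocks in `[0, 1]`.
#' @param comp a fitted [fit_compressor()].
#' @param code integer code-image matrix from `compress_blocks`.
#' @param layout block layout recorded by `compress_blocks` (carried as an
#'   attribute of the code image).
#' @return `compress_blocks`: integer matrix in 0..255;
#'   `reconstruct_blocks`: a `block_set` with reconstructed blocks in
#'   `[0, 1]`.
#' @export
compress_blocks <- function(bs, comp) {
  stopifnot(inherits(bs, "block_set"), inherits(comp, "bp_compressor"))
  if (ncol(bs$blocks) != comp$input_nodes)
    stop("block size does not match the fitted compressor")
  h <- tanh(sweep(bs$blocks %*% comp$w1, 2, comp$b1, "+"))
  code <- round((h + 1) / 2 * 255)
  storage.mode(code) <- "integer"
  attr(code, "layout") <- list(m = bs$m, shape = bs$shape, pad = bs$pad)
  code
}

#' @rdname compress_blocks
#' @export
reconstruct_blocks <- function(code, comp, layout = attr(code, "layout")) {
  stopifnot(inherits(comp, "bp_compressor"))
  if (ncol(code) != comp$hidden_nodes)
    stop("code width does not match the fitted compressor")
  h <- code / 255 * 2 - 1
  o <- transfer_fun(sweep(h %*% comp$w2, 2, comp$b2, "+"), "logsig")
  structure(list(blocks = o, m = layout$m, shape = layout$shape,
                 pad = layout$pad),
            class = "block_set")
}

#' Chained diffusion of a byte sequence
#'
#' Two chaining rules are available. `op = "xor"` is the plain XOR chain:
#' forward `E[i] = E[i-1] XOR R[i] XOR Q[i]` scanning left to right with
#' `E[0-boundary] = iv`, reverse `E[i] = E[i+1] XOR R[i] XOR Q[i]`
#' scanning right to left. The XOR chain is affine over GF(2): however
#' many passes are composed, a single changed input byte can never alter
#' more than about half the output bytes, because differences telescope
#' along the chain and cancel pairwise. `op = "arx"` therefore chains
#' through a carry-propagating ARX step,
#' `E[i] = Q[i] XOR rotl8((R[i] + E[i-1]) mod 256, 3)`; the addition
#' propagates carries and the rotation keeps the top bit from forming an
#' absorbing linear difference state, which together break that linearity; it is the rule the image cipher uses, and under it one
#' changed byte alters essentially every byte after a forward+reverse
#' double pass.
#'
#' @param q integer vector of plaintext bytes (0..255).
#' @param r keystream bytes, at least as long as `q`.
#' @param iv boundary byte.
#' @param direction `"forward"` or `"reverse"`.
#' @param op chaining rule, `"xor"` or `"arx"`.
#' @return integer vector of diffused bytes.
#' @export
diffuse <- function(q, r, iv = 0L, direction = c("forward", "reverse"),
                    op = c("xor", "arx")) {
  direction <- match.arg(direction)
  op <- match.arg(op)
  if (length(r) < length(q)) stop("keystream shorter than the sequence")
  xor_diffuse_cpp(as.integer(q), as.integer(r[seq_along(q)]),
                  as.integer(iv), direction == "forward", op == "arx")
}

#' Invert the chained diffusion
#'
#' For `op = "xor"`: forward-inverse `P[i] = C[i-1] XOR C[i] XOR S[i]`
#' (boundary `iv`), reverse-inverse symmetric. For `op = "arx"`:
#' `P[i] = C[i] XOR rotl8((S[i] + C[i-1]) mod 256, 3)`. With `S` equal to the
#' diffusion keystream this is the exact inverse of [diffuse()] under the
#' same `op`.
#'
#' @param e diffused bytes.
#' @param s keystream bytes.
#' @inheritParams diffuse
#' @return integer vector of recovered bytes.
#' @export
undiffuse <- function(e, s, iv = 0L, direction = c("forward", "reverse"),
                      op = c("xor", "arx")) {
  direction <- match.arg(direction)
  op <- match.arg(op)
  if (length(s) < length(e)) stop("keystream shorter than the sequence")
  xor_undiffuse_cpp(as.integer(e), as.integer(s[seq_along(e)]),
                    as.integer(iv), direction == "forward", op == "arx")
}

#' Encrypt an 8-bit grayscale image
#'
#' Pipeline: (optionally) normalize, cut into blocks and compress through
#' the block autoencoder; scramble with the extended zigzag confusion
#' (start corner chosen by the chaotic keystream); flatten row-major;
#' forward XOR diffusion with keystream `R1`; reverse XOR diffusion with
#' `R2`; reshape. In the default lossless mode the cipher operates
#' directly on the raw pixels and `decrypt_image(encrypt_image(x)) == x`
#' bit-exactly.
#'
#' @param img integer matrix with values in 0..255.
#' @param key a [chaos_key()].
#' @param config a [cipher_config()].
#' @return list of class `encrypted_image` with `cipher` (integer matrix)
#'   and `meta` (corner, shape, compression sidecar data).
#' @examples
#' key <- chaos_key(x0 = c(0.31, 0.62, 0.47))
#' img <- matrix(sample(0:255, 64 * 64, TRUE), 64)
#' enc <- encrypt_image(img, key)
#' identical(decrypt_image(enc, key), img)
#' @export
encrypt_image <- function(img, key, config = cipher_config()) {
  stopifnot(inherits(key, "chaos_key"), inherits(config, "cipher_config"))
  img <- check_gray(img)
  comp_meta <- NULL
  if (config$use_compression) {
    nm <- normalize_image(img, config$target)
    bs <- blockify(nm$values, config$block_size)
    comp <- fit_compressor(bs, config$hidden_nodes, config$epochs,
                           config$rate, config$momentum, config$seed)
    work <- compress_blocks(bs, comp)
    layout <- attr(work, "layout")
    comp_meta <- list(decoder = list(w2 = comp$w2, b2 = comp$b2,
                                     hidden_nodes = comp$hidden_nodes,
                                     input_nodes = comp$input_nodes),
                      layout = layout, xmin = nm$xmin, xmax = nm$xmax,
                      target = config$target, rate_t = comp$rate_t)
    attr(work, "layout") <- NULL
  } else {
    work <- img
  }
  p <- nrow(work); q <- ncol(work)
  ks <- keystream(key, p * q * config$rounds)
  corner <- select_corner(ks)
  plan <- zigzag_plan(p, q, corner)
  e <- as.vector(t(scramble(work, plan)))
  for (rd in seq_len(config$rounds)) {
    sl <- ((rd - 1L) * p * q + 1L):(rd * p * q)   # fresh bytes per round
    e <- diffuse(e, ks$R1[sl], ks$iv_forward, "forward", config$chain)
    e <- diffuse(e, ks$R2[sl], ks$iv_reverse, "reverse", config$chain)
  }
  cipher <- matrix(e, p, q, byrow = TRUE)
  structure(list(cipher = cipher,
                 meta = list(version = "1", corner = corner,
                             shape = dim(img), chain = config$chain,
                             rounds = config$rounds,
                             use_compression = config$use_compression,
                             compression = comp_meta)),
            class = "encrypted_image")
}

#' Decrypt an encrypted image
#'
#' Exact inverse stage order: reverse-inverse diffusion with `R2`, then
#' forward-inverse with `R1`, then the inverse zigzag, then (if the image
#' was compressed) decoding and de-normalization. The corner and both
#' diffusion boundary bytes are regenerated from the key, so a wrong key
#' silently yields noise; there is no integrity tag.
#'
#' @param enc an `encrypted_image` (or a bare cipher matrix together with
#'   `meta`).
#' @param key the [chaos_key()] used for encryption.
#' @param meta metadata list, defaulting to `enc$meta`.
#' @return integer matrix; bit-exact original in lossless mode, lossy
#'   reconstruction when compression was used.
#' @export
decrypt_image <- function(enc, key, meta = NULL) {
  stopifnot(inherits(key, "chaos_key"))
  if (inherits(enc, "encrypted_image")) {
    cipher <- enc$cipher
    if (is.null(meta)) meta <- enc$meta
  } else {
    cipher <- enc
    if (is.null(meta)) stop("`meta` is required when `enc` is a bare matrix")
  }
  p <- nrow(cipher); q <- ncol(cipher)
  chain <- if (is.null(meta$chain)) "arx" else meta$chain
  rounds <- if (is.null(meta$rounds)) 2L else as.integer(meta$rounds)
  ks <- keystream(key, p * q * rounds)
  corner <- select_corner(ks)
  plan <- zigzag_plan(p, q, corner)
  v <- as.vector(t(cipher))
  for (rd in rev(seq_len(rounds))) {
    sl <- ((rd - 1L) * p * q + 1L):(rd * p * q)
    v <- undiffuse(v, ks$R2[sl], ks$iv_reverse, "reverse", chain)
    v <- undiffuse(v, ks$R1[sl], ks$iv_forward, "forward", chain)
  }
  work <- unscramble(matrix(v, p, q, byrow = TRUE), plan)
  if (isTRUE(meta$use_compression)) {
    cm <- meta$compression
    comp <- structure(list(w2 = cm$decoder$w2, b2 = cm$decoder$b2,
                           hidden_nodes = cm$decoder$hidden_nodes,
                           input_nodes = cm$decoder$input_nodes),
                      class = "bp_compressor")
    bs <- reconstruct_blocks(work, comp, cm$layout)
    vals <- deblockify(bs)
    out <- denormalize_image(vals, cm$xmin, cm$xmax, cm$target)
    out <- round(pmin(pmax(out, 0), 255))
    storage.mode(out) <- "integer"
    out
  } else {
    storage.mode(work) <- "integer"
    work
  }
}

#' Peak signal-to-noise ratio between two images
#'
#' @param a,b numeric matrices of identical shape.
#' @param peak maximum representable value (255 for 8-bit images).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(a, b, peak = 255) {
  if (!all(dim(a) == dim(b))) stop("images must have identical shapes")
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

check_gray <- function(img) {
  if (!is.matrix(img)) stop("image must be a matrix")
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != round(img)))
    stop("image pixels must be integers in 0..255")
  storage.mode(img) <- "integer"
  img
}
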