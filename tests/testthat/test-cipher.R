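test_that("normalization maps the observed range onto the target", {
  img <- matrix(0:255, 16, 16)
  nm <- normalize_image(img)
  expect_equal(min(nm$values), 0)
  expect_equal(max(nm$values), 1)
  expect_equal(nm$values[img == 128][1], 128 / 255, tolerance = 1e-12)
  const <- normalize_image(matrix(7, 4, 4), target = c(0.2, 1))
  expect_true(all(const$values == 0.2))
})

test_that("blockify pads, counts and round-trips exactly", {
  img <- rand_img(4, 4)
  bs <- blockify(img, 2)
  expect_equal(nrow(bs$blocks), 4L)           # (4/2) * (4/2)
  expect_equal(deblockify(bs), img)

  odd <- rand_img(5, 5, seed = 2)
  bs5 <- blockify(odd, 2)
  expect_equal(nrow(bs5$blocks), 9L)          # padded to 6x6
  expect_equal(bs5$pad, c(1L, 1L))
  expect_equal(deblockify(bs5), odd)

  one <- matrix(9, 1, 1)
  bs1 <- blockify(one, 1)
  expect_equal(nrow(bs1$blocks), 1L)
  expect_equal(deblockify(bs1), one)
})

test_that("transfer functions match their closed forms", {
  expect_equal(transfer_fun(0, "logsig"), 0.5)
  expect_equal(transfer_fun(0, "tansig"), 0)
  expect_equal(transfer_fun(log(3), "logsig"), 0.75, tolerance = 1e-12)
  expect_equal(transfer_fun(1, "tansig"), tanh(1), tolerance = 1e-12)
})

test_that("the block autoencoder trains and reports its compression rate", {
  blocks <- matrix(0.5, 50, 64)
  bs <- structure(list(blocks = blocks, m = 8L, shape = c(40L, 80L),
                       pad = c(0L, 0L)), class = "block_set")
  comp <- fit_compressor(bs, 16, epochs = 100)
  expect_equal(comp$rate_t, 4)
  expect_lt(comp$loss[length(comp$loss)], comp$loss[1])
  comp1 <- fit_compressor(bs, 64, epochs = 1)
  expect_equal(comp1$rate_t, 1)
  expect_error(fit_compressor(bs, 0), ">= 1")
})

test_that("code images have the contracted shape and 8-bit range", {
  img <- rand_img(16, 16, seed = 3)
  nm <- normalize_image(img)
  bs <- blockify(nm$values, 8)
  comp <- fit_compressor(bs, 16, epochs = 50)
  code <- compress_blocks(bs, comp)
  expect_equal(dim(code), c(4L, 16L))          # H x hidden
  expect_true(all(code >= 0 & code <= 255))
  rec <- reconstruct_blocks(code, comp)
  expect_equal(dim(rec$blocks), dim(bs$blocks))
})

test_that("smooth images survive compression at useful fidelity", {
  smooth <- generate_cipher_testset(64, 1)$gradient
  cfg <- cipher_config(use_compression = TRUE, block_size = 8,
                       hidden_nodes = 16, epochs = 500)
  key <- test_key()
  dec <- decrypt_image(encrypt_image(smooth, key, cfg), key)
  expect_gte(psnr(smooth, dec), 25)
})

test_that("the XOR chain reproduces hand-computed diffusion", {
  expect_equal(diffuse(c(0, 0, 0), c(0, 0, 0), 0, "forward", "xor"),
               c(0L, 0L, 0L))
  expect_equal(diffuse(c(1, 2, 3), c(5, 5, 5), 0, "forward", "xor"),
               c(4L, 3L, 5L))
  expect_equal(undiffuse(c(4, 3, 5), c(5, 5, 5), 0, "forward", "xor"),
               c(1L, 2L, 3L))
  expect_error(diffuse(c(1, 2, 3), c(5, 5), 0), "shorter")
})

test_that("undiffuse inverts diffuse for both chains and directions", {
  set.seed(4)
  for (op in c("xor", "arx")) {
    for (dir in c("forward", "reverse")) {
      for (rep in 1:10) {
        q <- sample(0:255, 100, replace = TRUE)
        r <- sample(0:255, 100, replace = TRUE)
        iv <- sample(0:255, 1)
        e <- diffuse(q, r, iv, dir, op)
        expect_identical(undiffuse(e, r, iv, dir, op), as.integer(q))
      }
    }
  }
})

test_that("the arx double round has full avalanche; the xor chain stays affine", {
  set.seed(5)
  n <- 4096
  rs <- replicate(4, sample(0:255, n, replace = TRUE), simplify = FALSE)
  two_rounds <- function(x, op) {
    x <- diffuse(x, rs[[1]], 7, "forward", op)
    x <- diffuse(x, rs[[2]], 9, "reverse", op)
    x <- diffuse(x, rs[[3]], 7, "forward", op)
    diffuse(x, rs[[4]], 9, "reverse", op)
  }
  q <- sample(0:255, n, replace = TRUE)
  q2 <- q
  q2[1500] <- bitwXor(q[1500], 128L)   # worst case: top-bit-only change
  expect_gte(mean(two_rounds(q, "arx") != two_rounds(q2, "arx")), 0.99)
  # the affine chain maps a one-byte change to a fixed pattern whose
  # byte-level XOR differences take at most two values (0 and the delta)
  dxor <- bitwXor(two_rounds(q, "xor"), two_rounds(q2, "xor"))
  expect_lte(length(unique(dxor)), 2L)
  expect_true(all(dxor %in% c(0L, 128L)))
})

test_that("encryption round-trips exactly in lossless mode", {
  key <- test_key()
  sizes <- list(c(1, 1), c(1, 7), c(5, 1), c(8, 8), c(13, 9), c(17, 32),
                c(31, 31), c(2, 63))
  for (i in seq_along(sizes)) {
    img <- rand_img(sizes[[i]][1], sizes[[i]][2], seed = i)
    enc <- encrypt_image(img, key)
    expect_equal(dim(enc$cipher), dim(img))
    expect_identical(decrypt_image(enc, key), img)
  }
})

test_that("ciphertext statistics are flat for structured plaintexts", {
  key <- test_key()
  ts <- generate_cipher_testset(256, 1)
  crit <- 1.2 * qchisq(0.99, 255)
  for (name in c("constant", "gradient", "random")) {
    e <- encrypt_image(ts[[name]], key)$cipher
    expect_gte(img_entropy(e), 7.99)
    expect_lt(hist_chisq(e), crit)
  }
})

test_that("a wrong key yields noise, not the plaintext", {
  key <- test_key()
  wrong <- test_key(x0 = c(0.31 + 1e-10, 0.62, 0.47))
  img <- rand_img(64, 64, seed = 6)
  enc <- encrypt_image(img, key)
  garbage <- decrypt_image(enc, wrong)
  expect_gte(npcr(garbage, img), 99)
})

test_that("key sensitivity shows in the ciphertext difference", {
  img <- rand_img(64, 64, seed = 7)
  e1 <- encrypt_image(img, test_key())$cipher
  e2 <- encrypt_image(img, test_key(x0 = c(0.31, 0.62, 0.47 + 1e-10)))$cipher
  expect_gte(npcr(e1, e2), 99)
  expect_equal(uaci(e1, e2), 33.46, tolerance = 1)
})

test_that("compressed-mode decryption is lossy but close", {
  img <- generate_phantom(phantom_config(noise_sd = 2), seed = 4,
                          force_tumour = TRUE)$image
  key <- test_key()
  cfg <- cipher_config(use_compression = TRUE, block_size = 8,
                       hidden_nodes = 16, epochs = 300)
  dec <- decrypt_image(encrypt_image(img, key, cfg), key)
  expect_equal(dim(dec), dim(img))
  expect_gte(psnr(img, dec), 15)
  expect_false(identical(dec, img))
})

test_that("images with out-of-range pixels are rejected", {
  key <- test_key()
  expect_error(encrypt_image(matrix(-1, 2, 2), key), "0..255")
  expect_error(encrypt_image(matrix(0.5, 2, 2), key), "integers")
})
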