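#' Read / write 8-bit grayscale images
#'
#' PNG files are handled through the png package (multi-channel files are
#' collapsed to their first channel); `.pgm` files use the binary P5
#' format with maxval 255.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @param img integer matrix with values in 0..255.
#' @return `read_gray_image`: integer matrix; `write_gray_image`: `path`
#'   invisibly.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    img <- round(a * 255)
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else {
    stop("unsupported image format: .", ext)
  }
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path) {
  img <- check_gray(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  if (token() != "P5") stop("only binary (P5) PGM is supported")
  q <- as.integer(token()); p <- as.integer(token())
  maxval <- as.integer(token())
  if (maxval > 255L) stop("16-bit PGM is not supported")
  raw <- readBin(con, "integer", p * q, size = 1L, signed = FALSE)
  matrix(raw, p, q, byrow = TRUE)
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.integer(as.vector(t(img))), con, size = 1L)
  invisible(path)
}

#' Write / read an encrypted image with its metadata sidecar
#'
#' The ciphertext is stored as an ordinary 8-bit image; everything needed
#' to decrypt it (except the key) travels in a JSON sidecar: corner,
#' shape, and, when compression was used, the decoder weights encoded as
#' base64 little-endian doubles. The decoder weights are cleartext; the
#' secrecy of the scheme rests entirely on the chaotic key.
#'
#' @param enc an `encrypted_image` from [encrypt_image()].
#' @param image_path destination for the cipher image (`.png`/`.pgm`).
#' @param meta_path destination for the JSON sidecar (default: image path
#'   with `.json` appended).
#' @return `write_encrypted`: `image_path` invisibly; `read_encrypted`:
#'   an `encrypted_image`.
#' @export
write_encrypted <- function(enc, image_path,
                            meta_path = paste0(image_path, ".json")) {
  stopifnot(inherits(enc, "encrypted_image"))
  write_gray_image(enc$cipher, image_path)
  meta <- enc$meta
  if (is.null(meta$compression)) {
    meta[["compression"]] <- NULL     # drop rather than serialize as {}
  } else {
    dec <- meta$compression$decoder
    meta$compression$decoder <- list(
      w2 = encode_doubles(dec$w2), w2_dim = dim(dec$w2),
      b2 = encode_doubles(dec$b2),
      hidden_nodes = dec$hidden_nodes, input_nodes = dec$input_nodes)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' @rdname write_encrypted
#' @export
read_encrypted <- function(image_path,
                           meta_path = paste0(image_path, ".json")) {
  cipher <- read_gray_image(image_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (length(meta$compression)) {
    dec <- meta$compression$decoder
    w2 <- matrix(decode_doubles(dec$w2), dec$w2_dim[1], dec$w2_dim[2])
    meta$compression$decoder <- list(
      w2 = w2, b2 = decode_doubles(dec$b2),
      hidden_nodes = dec$hidden_nodes, input_nodes = dec$input_nodes)
    meta$compression$layout$shape <- as.integer(meta$compression$layout$shape)
    meta$compression$layout$pad <- as.integer(meta$compression$layout$pad)
  }
  structure(list(cipher = cipher, meta = meta), class = "encrypted_image")
}

encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

decode_doubles <- function(s) {
  readBin(jsonlite::base64_dec(s), "numeric",
          n = length(jsonlite::base64_dec(s)) %/% 8L,
          size = 8L, endian = "little")
}
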