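#' Chaotic cipher key
#'
#' Constructs the secret key of the image cipher: the initial state and
#' control parameters of a three-component chaotic system, the transient
#' length (iterates discarded before any value is used) and the quantizer
#' scale used to turn raw chaotic values into bytes.
#'
#' The default (and currently only) system, `"logistic3"`, is three
#' independent logistic maps \eqn{x \leftarrow r x (1 - x)} with control
#' parameters in the fully chaotic regime. The `system` field is a
#' pluggable interface so other chaotic systems (e.g. fractional-order
#' ones) can be added without changing the cipher.
#'
#' @param x0 numeric(3), initial state; each component strictly inside
#'   (0, 1) and away from the map's fixed points.
#' @param r numeric(3), logistic control parameters, each in (3.57, 4].
#' @param transient non-negative integer; number of leading iterates
#'   discarded before any keystream value is drawn. Large transients make
#'   the keystream sensitive to all key digits.
#' @param scale positive quantizer scale; byte = floor(u * scale) mod 256.
#' @param system chaotic system identifier.
#' @return An object of class `chaos_key`.
#' @examples
#' key <- chaos_key(x0 = c(0.2, 0.5, 0.7))
#' ks <- keystream(key, 16)
#' range(ks$R1)
#' @export
chaos_key <- function(x0 = c(0.2461, 0.3582, 0.7913),
                      r = c(3.99, 3.98, 3.97),
                      transient = 1000L,
                      scale = 1e10,
                      system = "logistic3") {
  system <- match.arg(system, "logistic3")
  x0 <- as.numeric(x0)
  r <- as.numeric(r)
  if (length(x0) != 3L || length(r) != 3L)
    stop("`x0` and `r` must each have length 3")
  if (any(!is.finite(x0)) || any(x0 <= 0) || any(x0 >= 1))
    stop("initial state components must lie strictly inside (0, 1)")
  fixed <- 1 - 1 / r
  if (any(abs(x0 - fixed) < 1e-12))
    stop("initial state coincides with a fixed point of the map")
  if (any(!is.finite(r)) || any(r <= 3.57) || any(r > 4))
    stop("control parameters must lie in (3.57, 4] (chaotic regime)")
  transient <- as.integer(transient)
  if (is.na(transient) || transient < 0L)
    stop("`transient` must be a non-negative integer")
  if (!is.finite(scale) || scale <= 0 || scale > 1e10)
    stop("`scale` must be positive and at most 1e10")
  structure(list(system = system, x0 = x0, r = r,
                 transient = transient, scale = scale),
            class = "chaos_key")
}

#' @export
print.chaos_key <- function(x, ...) {
  cat("<chaos_key>", x$system,
      "| transient:", x$transient,
      "| scale:", format(x$scale, scientific = TRUE), "\n")
  invisible(x)
}

#' Write / read a cipher key as JSON
#'
#' The JSON file *is* the secret key:
#' `{"system": "logistic3", "x0": [...], "r": [...], "m": 1000,
#'   "scale": 1e10}`.
#'
#' @param key a [chaos_key()].
#' @param path file path.
#' @return `write_chaos_key` returns `path` invisibly; `read_chaos_key`
#'   returns a `chaos_key`.
#' @export
write_chaos_key <- function(key, path) {
  stopifnot(inherits(key, "chaos_key"))
  obj <- list(system = key$system, x0 = key$x0, r = key$r,
              m = key$transient, scale = key$scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chaos_key
#' @export
read_chaos_key <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chaos_key(x0 = obj$x0, r = obj$r, transient = obj$m,
            scale = obj$scale, system = obj$system)
}

#' Iterate the chaotic system
#'
#' Runs the key's chaotic system for `transient + n` steps and returns the
#' `n` post-transient iterates of the three components. Deterministic: the
#' same key always yields bit-identical series.
#'
#' @param key a [chaos_key()].
#' @param n number of post-transient iterates to return.
#' @return A list with `series` (an `n x 3` numeric matrix, one column per
#'   map) and `last_transient` (the final discarded triple, `NA` when the
#'   transient is zero).
#' @export
chaos_iterate <- function(key, n) {
  stopifnot(inherits(key, "chaos_key"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
  chaos_iterate_cpp(key$x0, key$r, n, key$transient)
}

#' Derive keystream bytes from chaotic series
#'
#' Each raw value `u` is quantized to a byte `floor(u * scale) mod 256`;
#' the two pseudorandom byte series are then formed by mixing the three
#' component streams: `R1 = b1 XOR b2`, `R2 = b2 XOR b3`. XOR of two
#' quantized streams keeps the bytes close to uniform and ties every
#' output byte to more than one component of the chaotic state.
#'
#' @param series numeric matrix with three columns of raw chaotic values.
#' @param length number of bytes to derive from the leading rows.
#' @param scale quantizer scale (default `1e10`).
#' @return list with integer vectors `R1` and `R2`, values in 0..255.
#' @export
derive_keystreams <- function(series, length, scale = 1e10) {
  series <- as.matrix(series)
  length <- as.integer(length)
  if (is.na(length) || length < 0L) stop("`length` must be non-negative")
  if (ncol(series) != 3L) stop("`series` must have three columns")
  if (nrow(series) < length)
    stop("series too short: ", nrow(series), " rows for length ", length)
  if (length == 0L) return(list(R1 = integer(0), R2 = integer(0)))
  b1 <- quantize_bytes_cpp(series[seq_len(length), 1], scale)
  b2 <- quantize_bytes_cpp(series[seq_len(length), 2], scale)
  b3 <- quantize_bytes_cpp(series[seq_len(length), 3], scale)
  list(R1 = bitwXor(b1, b2), R2 = bitwXor(b2, b3))
}

#' Full keystream for an image of n pixels
#'
#' Draws `n + 1` post-transient iterates: the first value of the first
#' component is reserved for corner selection (so the corner choice and
#' the diffusion bytes are independent draws), the remaining `n` rows feed
#' [derive_keystreams()]. The initial values of the two diffusion chains
#' are bytes quantized from the last *discarded* transient values of the
#' first and third components (0 when the transient is zero), so the
#' whole keystream is regenerable from the key alone.
#'
#' @inheritParams chaos_iterate
#' @return An object of class `keystream`: list with `R1`, `R2`,
#'   `corner_value`, `iv_forward`, `iv_reverse`.
#' @export
keystream <- function(key, n) {
  n <- as.integer(n)
  it <- chaos_iterate(key, n + 1L)
  ks <- derive_keystreams(it$series[-1L, , drop = FALSE], n, key$scale)
  lt <- it$last_transient
  ivs <- if (anyNA(lt)) c(0L, 0L) else quantize_bytes_cpp(lt[c(1L, 3L)], key$scale)
  structure(list(R1 = ks$R1, R2 = ks$R2,
                 corner_value = it$series[1L, 1L],
                 iv_forward = ivs[1L], iv_reverse = ivs[2L]),
            class = "keystream")
}

#' Select the zigzag start corner from the keystream
#'
#' The scrambling scan may begin from any of the four corners; the corner
#' is chosen by the chaotic draw reserved for it:
#' `corner = floor(v * 1e4) mod 4` with 0 = top-left, 1 = top-right,
#' 2 = bottom-left, 3 = bottom-right.
#'
#' @param x a [keystream()] or a bare numeric corner value.
#' @return integer in 0..3.
#' @export
select_corner <- function(x) {
  v <- if (inherits(x, "keystream")) x$corner_value else as.numeric(x)
  if (!is.finite(v)) stop("corner value must be finite")
  as.integer(floor(v * 1e4)) %% 4L
}

#' Corner labels used by the zigzag scan
#' @keywords internal
corner_names <- c("TL", "TR", "BL", "BR")
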