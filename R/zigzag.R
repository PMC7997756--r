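#' Extended zigzag scan plan
#'
#' Builds the scan order of the extended zigzag confusion for an arbitrary
#' (possibly non-square) matrix, starting from any of the four corners.
#' The top-left traversal scans anti-diagonals `d = i + j` in increasing
#' `d`, alternating direction (the classic JPEG zigzag); the other corners
#' are the horizontal/vertical reflections of that traversal.
#'
#' @param rows,cols matrix dimensions (>= 1).
#' @param corner integer 0..3 or one of `"TL","TR","BL","BR"`.
#' @return An object of class `zigzag_plan`: list with `rows`, `cols`,
#'   `corner`, and `order`, a permutation of `1:(rows*cols)` in row-major
#'   linear indices giving the scan sequence.
#' @examples
#' p <- zigzag_plan(3, 3, "TL")
#' matrix(1:9, 3, byrow = TRUE)[cbind((p$order - 1) %/% 3 + 1,
#'                                    (p$order - 1) %% 3 + 1)]
#' @export
zigzag_plan <- function(rows, cols, corner = 0L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("`rows` and `cols` must be >= 1")
  if (is.character(corner)) corner <- match(corner, corner_names) - 1L
  corner <- as.integer(corner)
  if (is.na(corner) || corner < 0L || corner > 3L)
    stop("`corner` must be in 0..3 or one of TL, TR, BL, BR")
  i <- rep(seq_len(rows), each = cols) - 1L   # 0-based row, row-major listing
  j <- rep(seq_len(cols), times = rows) - 1L
  d <- i + j
  # odd anti-diagonals are scanned with increasing row (down-left), even
  # ones with decreasing row (up-right)
  key2 <- ifelse(d %% 2L == 1L, i, -i)
  ord <- order(d, key2)
  ti <- i[ord]; tj <- j[ord]
  if (corner == 1L || corner == 3L) tj <- cols - 1L - tj  # reflect columns
  if (corner == 2L || corner == 3L) ti <- rows - 1L - ti  # reflect rows
  structure(list(rows = rows, cols = cols, corner = corner,
                 order = ti * cols + tj + 1L),
            class = "zigzag_plan")
}

#' Scramble / unscramble pixels along a zigzag plan
#'
#' `scramble` reads the image in the plan's scan order and rewrites the
#' sequence into the grid row-major; `unscramble` inverts it exactly. Both
#' are pure permutations: the multiset of pixel values is unchanged.
#'
#' @param img numeric/integer matrix.
#' @param plan a [zigzag_plan()] matching `dim(img)`.
#' @return matrix of the same shape.
#' @export
scramble <- function(img, plan) {
  check_plan(img, plan)
  v <- as.vector(t(img))            # row-major flatten
  matrix(v[plan$order], plan$rows, plan$cols, byrow = TRUE)
}

#' @rdname scramble
#' @export
unscramble <- function(img, plan) {
  check_plan(img, plan)
  v <- numeric(length(plan$order))
  v[plan$order] <- as.vector(t(img))
  matrix(v, plan$rows, plan$cols, byrow = TRUE)
}

check_plan <- function(img, plan) {
  if (!inherits(plan, "zigzag_plan")) stop("`plan` must be a zigzag_plan")
  if (nrow(img) != plan$rows || ncol(img) != plan$cols)
    stop("plan shape (", plan$rows, "x", plan$cols,
         ") does not match image (", nrow(img), "x", ncol(img), ")")
  invisible(TRUE)
}
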