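# Feature extraction: block-mean pooling followed by centre-symmetric
# local binary pattern coding of the pooled matrix ("BACS-LBP").

#' Block specification
#'
#' A block specification gives the pixel size of the rectangular blocks the
#' image is partitioned into before per-block averaging: `a` rows by `b`
#' columns. The field convention writes it "a x b", e.g. `3x8`.
#'
#' @param a Block height in pixels (positive integer).
#' @param b Block width in pixels (positive integer).
#' @return An object of class `block_spec`: a named integer vector with
#'   elements `a` and `b`.
#' @examples
#' block_spec(3, 8)
#' parse_block_spec("5x5")
#' @export
block_spec <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) ||
      a < 1 || b < 1 || a != floor(a) || b != floor(b)) {
    stop("invalid block spec: 'a' and 'b' must be positive integers",
         call. = FALSE)
  }
  structure(c(a = as.integer(a), b = as.integer(b)), class = "block_spec")
}

#' @rdname block_spec
#' @param x A string of the form `"AxB"` (rows x cols), e.g. `"3x8"`.
#' @export
parse_block_spec <- function(x) {
  if (inherits(x, "block_spec")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(block_spec(x[[1L]], x[[2L]]))
  m <- regmatches(x, regexec("^([0-9]+)[xX]([0-9]+)$", as.character(x)))[[1L]]
  if (length(m) != 3L) {
    stop("cannot parse block spec '", x, "': expected \"AxB\", e.g. \"3x8\"",
         call. = FALSE)
  }
  block_spec(as.integer(m[2L]), as.integer(m[3L]))
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("block spec %dx%d (rows x cols)\n", x[["a"]], x[["b"]]))
  invisible(x)
}

# Validate a grayscale image matrix: numeric, finite, intensities in [0,255].
check_gray_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1L || ncol(img) < 1L) {
    stop("invalid ", what, ": expected a non-empty numeric matrix",
         call. = FALSE)
  }
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255)) {
    stop("invalid ", what, ": intensities must be finite and in [0, 255]",
         call. = FALSE)
  }
  invisible(img)
}

#' Zero-pad an image to block-size multiples
#'
#' Appends rows and columns of intensity 0 at the bottom and right so that
#' the image dimensions become the smallest multiples of the block height
#' and width. Original pixels are preserved at the top-left. Padding with 0
#' (rather than replication) means boundary blocks average in the padding;
#' see [block_mean_matrix()].
#'
#' @param img Numeric matrix of intensities in `[0, 255]`, rows = image
#'   height.
#' @param spec A [block_spec()] (or anything [parse_block_spec()] accepts).
#' @return The padded matrix.
#' @examples
#' pad_to_multiple(matrix(7, 1, 1), block_spec(3, 3))
#' @export
pad_to_multiple <- function(img, spec) {
  spec <- parse_block_spec(spec)
  check_gray_image(img)
  a <- spec[["a"]]; b <- spec[["b"]]
  ap <- ceiling(nrow(img) / a) * a
  bp <- ceiling(ncol(img) / b) * b
  if (ap == nrow(img) && bp == ncol(img)) return(img)
  out <- matrix(0, ap, bp)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

#' Block-mean matrix of an image
#'
#' Partitions the (zero-padded) image into `a x b` blocks and returns the
#' `p x q` matrix of per-block arithmetic means, `p = ceiling(A/a)`,
#' `q = ceiling(B/b)`. Padding zeros are included in the means of boundary
#' blocks, which biases those means downward; this is the canonical
#' behaviour of the coder, documented rather than corrected.
#'
#' @inheritParams pad_to_multiple
#' @return A `p x q` numeric matrix of block means.
#' @examples
#' block_mean_matrix(matrix(c(0, 0, 4, 4, 8, 8, 12, 12), 2, 4), block_spec(2, 2))
#' @export
block_mean_matrix <- function(img, spec) {
  spec <- parse_block_spec(spec)
  check_gray_image(img)
  padded <- pad_to_multiple(img, spec)
  a <- spec[["a"]]; b <- spec[["b"]]
  p <- nrow(padded) %/% a
  q <- ncol(padded) %/% b
  # two rowsum passes: sum over row-groups, then over column-groups
  rs <- rowsum(padded, rep.int(seq_len(p), rep.int(a, p)), reorder = FALSE)
  cs <- t(rowsum(t(rs), rep.int(seq_len(q), rep.int(b, q)), reorder = FALSE))
  cs / (a * b)
}

#' Partition a matrix into 3x3 tiles
#'
#' Splits a `p x q` matrix into non-overlapping 3x3 tiles in row-major
#' order, zero-padding the bottom/right boundary where `p` or `q` is not a
#' multiple of 3. The tile count is `ceiling(p/3) * ceiling(q/3)`.
#'
#' @param M Numeric matrix (e.g. a block-mean matrix).
#' @return A list of 3x3 matrices in row-major tile order.
#' @export
tile_partition <- function(M) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) < 1L || ncol(M) < 1L) {
    stop("invalid matrix: expected a non-empty numeric matrix", call. = FALSE)
  }
  Mp <- pad_to_multiple(M, block_spec(3, 3))
  P <- nrow(Mp) %/% 3L
  Q <- ncol(Mp) %/% 3L
  tiles <- vector("list", P * Q)
  k <- 0L
  for (i in seq_len(P)) {
    for (j in seq_len(Q)) {
      k <- k + 1L
      tiles[[k]] <- Mp[(3L * i - 2L):(3L * i), (3L * j - 2L):(3L * j)]
    }
  }
  tiles
}

#' Border neighbours of a 3x3 tile
#'
#' Reads the eight border entries of a 3x3 tile in the package's fixed
#' convention: clockwise from the top-left corner, i.e. `n1..n8 =`
#' `m[1,1], m[1,2], m[1,3], m[2,3], m[3,3], m[3,2], m[3,1], m[2,1]`. The
#' centre `m[2,2]` is never read. Under this ordering the centrosymmetric
#' pairs are `(n_j, n_{j+4})` for `j = 1..4`.
#'
#' @param tile A 3x3 numeric matrix.
#' @return Numeric vector `n1..n8`.
#' @export
neighbor_ring <- function(tile) {
  if (!is.matrix(tile) || !identical(dim(tile), c(3L, 3L))) {
    stop("invalid tile: expected a 3x3 matrix", call. = FALSE)
  }
  c(tile[1L, 1L], tile[1L, 2L], tile[1L, 3L], tile[2L, 3L],
    tile[3L, 3L], tile[3L, 2L], tile[3L, 1L], tile[2L, 1L])
}

#' Centre-symmetric code of a neighbour ring
#'
#' Emits 4 bits: bit `j` is 1 iff `n_j >= n_{j+4}` for `j = 1..4`. Ties
#' encode 1 (the comparison is `>=`), so a constant tile codes `1111`.
#'
#' @param ring Numeric vector of length 8 (see [neighbor_ring()]).
#' @return Integer vector of 4 bits (0/1).
#' @export
cs_lbp_tile <- function(ring) {
  if (length(ring) != 8L || !is.numeric(ring)) {
    stop("invalid neighbour ring: expected 8 numeric values", call. = FALSE)
  }
  as.integer(ring[1:4] >= ring[5:8])
}

#' Encode a grayscale image into a binary vein codeword
#'
#' The full coding pipeline: zero-pad the image to block multiples, pool to
#' the block-mean matrix, partition that matrix into 3x3 tiles (zero-padded
#' at the boundary), code each tile's centrosymmetric neighbour pairs into 4
#' bits, and concatenate the tiles' bits in row-major tile order. The code
#' length is `L = 4 * ceiling(p/3) * ceiling(q/3)` with `p = ceiling(A/a)`,
#' `q = ceiling(B/b)` -- it depends only on the image size and block spec,
#' never on pixel content. Because each bit is an order comparison, the code
#' is invariant under positive affine intensity maps that do not clip.
#'
#' @inheritParams pad_to_multiple
#' @return An object of class `vein_code`: list with elements `bits`
#'   (integer 0/1 vector of length `L`), `L`, `spec`, and `convention`.
#' @examples
#' code <- encode_image(matrix(128, 9, 9), block_spec(3, 3))
#' code$bits  # constant image: single all-ties tile -> 1 1 1 1
#' @export
encode_image <- function(img, spec) {
  spec <- parse_block_spec(spec)
  check_gray_image(img)
  M <- block_mean_matrix(img, spec)
  Mp <- pad_to_multiple(M, block_spec(3, 3))
  P <- nrow(Mp) %/% 3L
  Q <- ncol(Mp) %/% 3L
  ri <- function(k) Mp[seq.int(k, by = 3L, length.out = P), , drop = FALSE]
  row1 <- ri(1L); row2 <- ri(2L); row3 <- ri(3L)
  ci <- function(X, k) X[, seq.int(k, by = 3L, length.out = Q), drop = FALSE]
  # P x Q matrices of the eight border neighbours of every tile
  n1 <- ci(row1, 1L); n2 <- ci(row1, 2L); n3 <- ci(row1, 3L)
  n4 <- ci(row2, 3L); n5 <- ci(row3, 3L); n6 <- ci(row3, 2L)
  n7 <- ci(row3, 1L); n8 <- ci(row2, 1L)
  # 4 x m bit matrix, tiles in row-major order down the columns
  bits4 <- rbind(as.integer(t(n1 >= n5)), as.integer(t(n2 >= n6)),
                 as.integer(t(n3 >= n7)), as.integer(t(n4 >= n8)))
  vein_code(as.vector(bits4), spec)
}

#' Construct a vein code object
#'
#' @param bits Integer/logical vector of bits (0/1), length a positive
#'   multiple of 4.
#' @param spec The [block_spec()] the code was produced under (optional,
#'   recorded for serialisation headers).
#' @param convention Neighbour-ordering tag; codes are comparable only
#'   within one convention.
#' @return An object of class `vein_code`.
#' @export
vein_code <- function(bits, spec = NULL, convention = "cw-tl-v1") {
  bits <- as.integer(bits)
  if (length(bits) < 4L || length(bits) %% 4L != 0L ||
      anyNA(bits) || any(bits < 0L | bits > 1L)) {
    stop("invalid vein code: bits must be 0/1 with length a positive multiple of 4",
         call. = FALSE)
  }
  structure(list(bits = bits, L = length(bits),
                 spec = if (!is.null(spec)) parse_block_spec(spec),
                 convention = convention),
            class = "vein_code")
}

#' @export
print.vein_code <- function(x, ...) {
  spec <- if (is.null(x$spec)) "unspecified" else
    sprintf("%dx%d", x$spec[["a"]], x$spec[["b"]])
  cat(sprintf("vein code: %d bits (block spec %s, neighbours %s)\n",
              x$L, spec, x$convention))
  head_bits <- paste(x$bits[seq_len(min(32L, x$L))], collapse = "")
  cat(sprintf("  bits: %s%s\n", head_bits, if (x$L > 32L) "..." else ""))
  invisible(x)
}

#' @export
length.vein_code <- function(x) x$L

#' Codeword length implied by an image size and block spec
#'
#' @param A,B Image height and width in pixels.
#' @param spec A [block_spec()].
#' @return Integer code length `L = 4 * ceiling(p/3) * ceiling(q/3)`.
#' @export
code_length <- function(A, B, spec) {
  spec <- parse_block_spec(spec)
  p <- ceiling(A / spec[["a"]])
  q <- ceiling(B / spec[["b"]])
  as.integer(4L * ceiling(p / 3) * ceiling(q / 3))
}
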