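# Plain-text codeword serialisation ("veincode" format) and image I/O.
#
# A veincode file is:
#   #veincode v1 spec=<AxB|unspecified> neighbors=<tag>
#   <image-id> TAB <L> TAB <hex payload, MSB-first, zero-padded to a byte>
# Codes are comparable only within one neighbour-ordering convention, so
# the convention tag travels in the header.

bits_to_hex <- function(bits) {
  pad <- (-length(bits)) %% 8L
  m <- matrix(c(bits, rep.int(0L, pad)), nrow = 8L)
  bytes <- packBits(as.logical(m[8L:1L, ]), type = "raw")  # MSB-first per byte
  toupper(paste(as.character(bytes), collapse = ""))
}

hex_to_bits <- function(hex, L) {
  n <- nchar(hex)
  if (n %% 2L != 0L || n * 4L < L || n * 4L >= L + 8L) {
    stop("corrupt code record: payload '", substr(hex, 1, 16),
         "...' does not match L = ", L, call. = FALSE)
  }
  bytes <- as.raw(strtoi(substring(hex, seq(1L, n, 2L), seq(2L, n, 2L)),
                         base = 16L))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)
  bits <- as.vector(m[8L:1L, ])  # undo MSB-first packing
  if (any(bits[-seq_len(L)] != 0L)) {
    stop("corrupt code record: nonzero padding bits", call. = FALSE)
  }
  bits[seq_len(L)]
}

#' Serialise a vein code to one text record
#'
#' @param code A [vein_code()].
#' @param id Image identifier; must not contain tabs or newlines.
#' @return A single string `"<id>\t<L>\t<hex>"` with MSB-first bit packing,
#'   zero-padded to a whole byte.
#' @examples
#' serialize_code(vein_code(c(1, 1, 1, 1)), "a")  # "a\t4\tF0"
#' @export
serialize_code <- function(code, id) {
  stopifnot(inherits(code, "vein_code"))
  id <- as.character(id)
  if (length(id) != 1L || grepl("[\t\n\r]", id) || !nzchar(id)) {
    stop("invalid id: must be non-empty without tab/newline", call. = FALSE)
  }
  paste(id, code$L, bits_to_hex(code$bits), sep = "\t")
}

#' @rdname serialize_code
#' @param line A record line produced by `serialize_code()`.
#' @param spec,convention Metadata (normally from the file header) attached
#'   to the parsed code.
#' @return `parse_code()`: list with `id` and `code` (round-trips exactly).
#' @export
parse_code <- function(line, spec = NULL, convention = "cw-tl-v1") {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop("corrupt code record: expected 3 tab-separated fields", call. = FALSE)
  }
  L <- as.integer(parts[2L])
  list(id = parts[1L],
       code = vein_code(hex_to_bits(parts[3L], L), spec, convention))
}

veincode_header <- function(spec, convention) {
  sprintf("#veincode v1 spec=%s neighbors=%s",
          if (is.null(spec)) "unspecified"
          else sprintf("%dx%d", spec[["a"]], spec[["b"]]),
          convention)
}

#' Read and write veincode files
#'
#' A veincode file holds one serialised code per line under a header that
#' records the format version, block spec and neighbour-ordering
#' convention.
#'
#' @param codes Named list of [vein_code()] objects (names are image ids).
#' @param path File path.
#' @return `read_veincodes()`: a named list of `vein_code` objects with
#'   attributes `spec` and `convention` from the header.
#' @export
write_veincodes <- function(codes, path) {
  stopifnot(is.list(codes), length(codes) >= 1L, !is.null(names(codes)))
  spec <- codes[[1L]]$spec
  convention <- codes[[1L]]$convention
  lines <- c(veincode_header(spec, convention),
             vapply(names(codes), function(id)
               serialize_code(codes[[id]], id), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_veincodes
#' @export
read_veincodes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#veincode v1")) {
    stop("not a veincode v1 file: '", path, "'", call. = FALSE)
  }
  spec_m <- regmatches(lines[1L], regexec("spec=([0-9xX]+|unspecified)", lines[1L]))[[1L]]
  conv_m <- regmatches(lines[1L], regexec("neighbors=(\\S+)", lines[1L]))[[1L]]
  spec <- if (length(spec_m) == 2L && spec_m[2L] != "unspecified")
    parse_block_spec(spec_m[2L])
  convention <- if (length(conv_m) == 2L) conv_m[2L] else "cw-tl-v1"
  recs <- lapply(lines[-1L][nzchar(lines[-1L])], parse_code,
                 spec = spec, convention = convention)
  codes <- lapply(recs, `[[`, "code")
  names(codes) <- vapply(recs, `[[`, "", "id")
  attr(codes, "spec") <- spec
  attr(codes, "convention") <- convention
  codes
}

#' Read a grayscale image file
#'
#' Reads PNG (or TIFF, if the tiff package is available) into an intensity
#' matrix on the `[0, 255]` scale. Colour images are converted to grayscale
#' by the standard Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B); alpha
#' channels are ignored. Higher bit depths are rescaled to `[0, 255]`.
#'
#' @param path Image file path (`.png`, `.tif`/`.tiff`).
#' @return Numeric matrix, rows = image height, intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format '.", ext, "': use PNG or TIFF",
         call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    arr <- if (nch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else arr[, , 1L]
  }
  clip255(arr * 255)
}

#' @rdname read_gray_image
#' @param img Intensity matrix in `[0, 255]`.
#' @export
write_gray_image <- function(img, path) {
  check_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
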