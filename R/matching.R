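# Multi-template minimum-Hamming-distance matching.

as_bits <- function(x) {
  if (inherits(x, "vein_code")) x$bits else as.integer(x)
}

#' Hamming distance between two vein codes
#'
#' Number of differing bit positions (XOR then popcount). Both codes must
#' have the same length.
#'
#' @param x,y `vein_code` objects or raw 0/1 bit vectors of equal length.
#' @return Non-negative integer in `[0, L]`.
#' @examples
#' hamming_distance(c(1, 0, 1, 0), c(0, 1, 1, 0))  # 2
#' @export
hamming_distance <- function(x, y) {
  bx <- as_bits(x); by <- as_bits(y)
  if (length(bx) != length(by)) {
    stop("incompatible codes: lengths differ (", length(bx), " vs ",
         length(by), ")", call. = FALSE)
  }
  sum(bx != by)
}

#' Enroll a template set
#'
#' An enrollment stores the `N` binary codewords of a subject's registered
#' images. All codes must share one length `L`.
#'
#' @param codes List of `vein_code` objects (or bit vectors) of equal length.
#' @param subject Subject identifier.
#' @return Object of class `template_set`: list with `subject`, `codes`
#'   (an `L x N` 0/1 integer matrix, one template per column), `N`, `L`.
#' @export
template_set <- function(codes, subject = "subject") {
  if (!is.list(codes) || length(codes) < 1L) {
    stop("invalid enrollment: need at least one template code", call. = FALSE)
  }
  mats <- lapply(codes, as_bits)
  L <- length(mats[[1L]])
  if (any(vapply(mats, length, 1L) != L)) {
    stop("incompatible codes: templates have differing lengths", call. = FALSE)
  }
  structure(list(subject = as.character(subject),
                 codes = matrix(unlist(mats), nrow = L),
                 N = length(mats), L = L),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template set '%s': %d templates of %d bits\n",
              x$subject, x$N, x$L))
  invisible(x)
}

#' Matching score of a probe against a template set
#'
#' The score is the minimum Hamming distance between the probe code and any
#' enrolled template, divided by the codeword length: a value in `[0, 1]`,
#' 0 iff the probe equals some template exactly. Adding templates can never
#' increase the score (minimum over a superset).
#'
#' @param probe A `vein_code` or bit vector.
#' @param templates A [template_set()].
#' @return Numeric matching score in `[0, 1]`.
#' @examples
#' ts <- template_set(list(c(0, 0, 0, 0), c(1, 1, 1, 1)))
#' match_score(c(1, 1, 1, 0), ts)  # min(3, 1) / 4 = 0.25
#' @export
match_score <- function(probe, templates) {
  if (!inherits(templates, "template_set")) {
    stop("invalid enrollment: 'templates' must be a template_set",
         call. = FALSE)
  }
  bp <- as_bits(probe)
  if (length(bp) != templates$L) {
    stop("incompatible codes: probe length ", length(bp),
         " does not match template length ", templates$L, call. = FALSE)
  }
  # hamming(x, t) = sum(x) + sum(t) - 2 * <x, t> for 0/1 vectors
  dots <- as.vector(crossprod(templates$codes, bp))
  dists <- sum(bp) + colSums(templates$codes) - 2 * dots
  min(dists) / templates$L
}

#' Accept/reject decision at a threshold
#'
#' Accepts iff the matching score is `<=` the decision threshold `dt`
#' (the boundary accepts).
#'
#' @inheritParams match_score
#' @param dt Decision threshold in `[0, 1]`.
#' @return Logical: `TRUE` = accept.
#' @export
verify_probe <- function(probe, templates, dt) {
  if (length(dt) != 1L || !is.finite(dt) || dt < 0 || dt > 1) {
    stop("invalid threshold: dt must be a single value in [0, 1]",
         call. = FALSE)
  }
  match_score(probe, templates) <= dt
}

# All probe-vs-template-set scores at once: codes and probes as L x n
# matrices, template membership given by a factor over template columns.
# Returns an n_subjects x n_probes score matrix. Shared by run_protocol.
score_matrix <- function(template_codes, template_subject, probe_codes) {
  L <- nrow(template_codes)
  ip <- crossprod(template_codes, probe_codes)          # nT x nP
  d <- matrix(colSums(template_codes), nrow(ip), ncol(ip)) +
    matrix(colSums(probe_codes), nrow(ip), ncol(ip), byrow = TRUE) - 2 * ip
  grp <- as.factor(template_subject)
  mins <- do.call(rbind, lapply(split(seq_len(nrow(d)), grp), function(idx) {
    if (length(idx) == 1L) d[idx, ] else apply(d[idx, , drop = FALSE], 2L, min)
  }))
  rownames(mins) <- levels(grp)
  mins / L
}
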