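# Verification protocol: templates-first split, genuine (1:1) and impostor
# (1:N) trials, FAR/FRR curves, equal error rate, decision-threshold rates.

# Normalise a dataset argument to a named list of lists of image matrices.
as_subject_list <- function(dataset) {
  if (inherits(dataset, "vein_dataset")) dataset <- dataset$images
  if (!is.list(dataset) || length(dataset) < 2L) {
    stop("protocol error: dataset must hold at least two subjects",
         call. = FALSE)
  }
  if (is.null(names(dataset)) || any(names(dataset) == "")) {
    names(dataset) <- sprintf("subject%03d", seq_along(dataset))
  }
  dataset
}

#' Run the verification protocol on a dataset
#'
#' For each subject the first `N` samples (in the dataset's stored order)
#' are enrolled as templates and the remaining samples become probes. Every
#' probe is scored once against its own subject's template set (a genuine,
#' 1:1 trial) and once against every other subject's template set (impostor,
#' 1:N trials), each score being the minimum normalised Hamming distance to
#' that subject's `N` templates. With `S` subjects of `k` samples this
#' yields `S * (k - N)` genuine and `S * (k - N) * (S - 1)` impostor trials.
#' FAR/FRR are swept on a threshold grid and the equal error rate is
#' interpolated from their crossing.
#'
#' @param dataset A `vein_dataset` (see [generate_dataset()]) or a named
#'   list, one element per subject, each an ordered list of grayscale image
#'   matrices.
#' @param N Number of templates enrolled per subject.
#' @param spec [block_spec()] used for encoding.
#' @param thresholds Threshold grid in `[0, 1]` for the FAR/FRR sweep.
#' @param dts Decision thresholds at which recognition rates are tabulated.
#' @return Object of class `vein_eval`; see Details. Contains `genuine` and
#'   `impostor` score vectors, `far`/`frr` on `thresholds`, `eer`, trial
#'   `counts`, and a `rates` table (one row per `dts` value).
#' @export
run_protocol <- function(dataset, N = 6, spec = block_spec(3, 8),
                         thresholds = seq(0, 1, length.out = 1001),
                         dts = c(0.18, 0.19, 0.20, 0.21)) {
  spec <- parse_block_spec(spec)
  dataset <- as_subject_list(dataset)
  N <- as.integer(N)
  if (N < 1L) stop("protocol error: N must be >= 1", call. = FALSE)
  ns <- vapply(dataset, length, 1L)
  short <- names(dataset)[ns <= N]
  if (length(short)) {
    stop("protocol error: subject(s) ", paste(short, collapse = ", "),
         " have <= N = ", N, " samples", call. = FALSE)
  }
  subjects <- names(dataset)
  codes <- lapply(dataset, function(samples) {
    vapply(samples, function(im) encode_image(im, spec)$bits,
           integer(code_length(nrow(samples[[1L]]), ncol(samples[[1L]]), spec)))
  })
  L <- nrow(codes[[1L]])
  if (any(vapply(codes, nrow, 1L) != L)) {
    stop("protocol error: subjects have differing image dimensions",
         call. = FALSE)
  }
  tmpl <- lapply(codes, function(cm) cm[, seq_len(N), drop = FALSE])
  prob <- lapply(codes, function(cm) cm[, -seq_len(N), drop = FALSE])
  template_codes <- do.call(cbind, tmpl)
  template_subject <- rep(subjects, each = N)
  probe_codes <- do.call(cbind, prob)
  probe_subject <- rep(subjects, times = ns - N)
  S <- score_matrix(template_codes, template_subject, probe_codes)
  own <- cbind(match(probe_subject, rownames(S)), seq_len(ncol(S)))
  genuine <- S[own]
  impostor <- as.vector(S[-(own[, 1L] + (own[, 2L] - 1L) * nrow(S))])
  curves <- far_frr(genuine, impostor, thresholds)
  rates <- do.call(rbind, lapply(dts, function(dt)
    as.data.frame(recognition_rates_scores(genuine, impostor, dt))))
  structure(list(genuine = genuine, impostor = impostor,
                 probe_subject = probe_subject,
                 thresholds = thresholds, far = curves$far, frr = curves$frr,
                 eer = eer(curves$far, curves$frr, thresholds),
                 counts = c(n_genuine = length(genuine),
                            n_impostor = length(impostor)),
                 rates = rates, N = N, spec = spec,
                 n_subjects = length(subjects), L = L),
            class = "vein_eval")
}

#' FAR and FRR over a threshold grid
#'
#' `FAR(t)` is the fraction of impostor scores accepted at threshold `t`
#' (score `<= t`, consistent with [verify_probe()]); `FRR(t)` the fraction
#' of genuine scores rejected (score `> t`). FAR is non-decreasing and FRR
#' non-increasing in `t`.
#'
#' @param genuine,impostor Numeric score vectors (both non-empty).
#' @param thresholds Numeric grid in `[0, 1]`.
#' @return List with `far` and `frr` vectors aligned to `thresholds`.
#' @export
far_frr <- function(genuine, impostor,
                    thresholds = seq(0, 1, length.out = 1001)) {
  if (length(genuine) < 1L || length(impostor) < 1L) {
    stop("evaluation error: need at least one genuine and one impostor score",
         call. = FALSE)
  }
  list(far = stats::ecdf(impostor)(thresholds),
       frr = 1 - stats::ecdf(genuine)(thresholds))
}

#' Equal error rate from sampled FAR/FRR curves
#'
#' Linearly interpolates the crossing of the (non-decreasing) FAR and
#' (non-increasing) FRR curves on their common threshold grid. If the two
#' are exactly equal over an interval of the grid, the value at the
#' interval's midpoint is returned.
#'
#' @param far,frr Curves sampled on `thresholds` (see [far_frr()]).
#' @param thresholds The common grid.
#' @return The equal error rate, in `[0, 1]`.
#' @export
eer <- function(far, frr, thresholds) {
  stopifnot(length(far) == length(frr), length(far) == length(thresholds))
  d <- far - frr  # non-decreasing
  if (d[1L] >= 0) {
    zero <- which(d == 0)
    if (length(zero) && zero[1L] == 1L) {
      run <- zero[seq_len(match(FALSE, diff(zero) == 1L, nomatch = length(zero) + 1L) - 1L)]
      return(far[run[ceiling(length(run) / 2)]])
    }
    return((far[1L] + frr[1L]) / 2)
  }
  i <- match(TRUE, d >= 0)
  if (is.na(i)) return((far[length(far)] + frr[length(frr)]) / 2)
  if (d[i] == 0) {
    zero <- which(d == 0)
    run <- zero[zero >= i]
    run <- run[seq_len(match(FALSE, diff(run) == 1L, nomatch = length(run) + 1L) - 1L)]
    return(far[run[ceiling(length(run) / 2)]])
  }
  alpha <- -d[i - 1L] / (d[i] - d[i - 1L])
  far[i - 1L] + alpha * (far[i] - far[i - 1L])
}

recognition_rates_scores <- function(genuine, impostor, dt) {
  if (length(dt) != 1L || !is.finite(dt) || dt < 0 || dt > 1) {
    stop("invalid threshold: dt must be in [0, 1]", call. = FALSE)
  }
  fr <- sum(genuine > dt)     # genuine rejected
  fa <- sum(impostor <= dt)   # impostors accepted
  list(dt = dt,
       n_genuine = length(genuine), false_rejects = as.integer(fr),
       intra_rate = 100 * (1 - fr / length(genuine)),
       n_impostor = length(impostor), false_accepts = as.integer(fa),
       inter_rate = 100 * (1 - fa / length(impostor)))
}

#' Recognition rates at a decision threshold
#'
#' Tabulates, at threshold `dt`, the intra-instance (1:1) recognition rate
#' (percentage of genuine trials accepted), the inter-instance (1:N) rate
#' (percentage of impostor trials rejected), and the integer false counts.
#'
#' @param report A `vein_eval` object from [run_protocol()].
#' @param dt Decision threshold in `[0, 1]`.
#' @return List: `dt`, `n_genuine`, `false_rejects`, `intra_rate` (percent),
#'   `n_impostor`, `false_accepts`, `inter_rate` (percent).
#' @export
recognition_rates <- function(report, dt) {
  stopifnot(inherits(report, "vein_eval"))
  recognition_rates_scores(report$genuine, report$impostor, dt)
}

#' @export
print.vein_eval <- function(x, ...) {
  cat(sprintf(
    "vein verification report: %d subjects, N = %d templates, block spec %dx%d, L = %d bits\n",
    x$n_subjects, x$N, x$spec[["a"]], x$spec[["b"]], x$L))
  cat(sprintf("  genuine trials:  %d\n  impostor trials: %d\n",
              x$counts[["n_genuine"]], x$counts[["n_impostor"]]))
  cat(sprintf("  EER: %.2f%%\n", 100 * x$eer))
  invisible(x)
}

#' @export
summary.vein_eval <- function(object, ...) {
  print(object)
  cat("\nrecognition rates by decision threshold:\n")
  print(object$rates, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.vein_eval <- function(x, ...) {
  graphics::plot(x$thresholds, x$far, type = "l", col = "firebrick",
                 xlab = "decision threshold", ylab = "error rate",
                 main = sprintf("FAR/FRR sweep (EER = %.2f%%)", 100 * x$eer),
                 ...)
  graphics::lines(x$thresholds, x$frr, col = "steelblue")
  graphics::abline(h = x$eer, lty = 3, col = "grey40")
  graphics::legend("right", legend = c("FAR", "FRR"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
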