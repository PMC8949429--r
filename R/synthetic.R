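# Seeded synthetic finger-vein dataset generator: class-specific vein
# patterns (dark curvilinear ridges on a brighter, low-contrast background
# with a smooth illumination gradient) plus per-sample pose jitter and
# sensor noise. Geometry is spline-based, not physiological; it exists to
# exercise a texture coder, not to look like real NIR tissue.

#' Synthetic dataset configuration
#'
#' Bundles every knob of the generator. The defaults define the package's
#' reference benchmark: 50 fingers with 12 samples each at 128 x 192 px,
#' seven veins per finger, mild pose jitter (3 px, 2 degrees) and moderate
#' Gaussian sensor noise. All fingers share one canonical vein layout;
#' identities differ by bounded deviations from it (`class_spread`), which
#' is what makes impostor trials realistically hard rather than random.
#'
#' @param n_subjects Number of classes (fingers).
#' @param samples_per_subject Samples per class.
#' @param size Image size `c(A, B)` = rows x cols, at least 9 x 9.
#' @param n_veins Veins per class pattern (0 gives pure background).
#' @param class_spread Identity strength: veins sit at canonical anatomical
#'   row positions shared by every finger, and each subject's control
#'   points deviate from them by at most `class_spread * A` pixels. Smaller
#'   values make fingers more alike (harder impostor trials); 0 makes all
#'   identities share one vein layout.
#' @param vein_width Range (px) the per-vein ridge width is drawn from.
#' @param vein_contrast Range of the per-vein darkening depth (intensity
#'   units).
#' @param background Mean background intensity (0-255).
#' @param gradient Peak-to-centre amplitude of the smooth illumination
#'   gradient.
#' @param blur_sigma Gaussian blur (px) applied to the finished pattern.
#' @param max_translation Per-sample translation jitter bound (px, each
#'   axis).
#' @param max_rotation Per-sample rotation jitter bound (degrees).
#' @param noise_sigma Additive Gaussian sensor-noise standard deviation
#'   (intensity units); ignored when `snr_db` is set.
#' @param snr_db Target signal-to-noise ratio in dB (`10*log10` of whole-
#'   image signal power over noise power); the strings `"30dB"`/`"40dB"`
#'   are accepted as presets.
#' @param pepper_density Fraction of pixels set to 0 (pepper noise).
#' @param seed Base seed; the full dataset is a pure function of the
#'   configuration, so identical configs give bit-identical datasets.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 50, samples_per_subject = 12,
                         size = c(128, 192), n_veins = 7, class_spread = 0.04,
                         vein_width = c(5, 9), vein_contrast = c(60, 110),
                         background = 190, gradient = 25, blur_sigma = 1.2,
                         max_translation = 3, max_rotation = 2,
                         noise_sigma = 5, snr_db = NULL,
                         pepper_density = 0, seed = 42) {
  if (is.character(snr_db)) {
    snr_db <- as.numeric(sub("[dD][bB]$", "", snr_db))
  }
  cfg <- list(n_subjects = as.integer(n_subjects),
              samples_per_subject = as.integer(samples_per_subject),
              size = as.integer(size), n_veins = as.integer(n_veins),
              class_spread = as.numeric(class_spread),
              vein_width = as.numeric(vein_width),
              vein_contrast = as.numeric(vein_contrast),
              background = as.numeric(background),
              gradient = as.numeric(gradient),
              blur_sigma = as.numeric(blur_sigma),
              max_translation = as.numeric(max_translation),
              max_rotation = as.numeric(max_rotation),
              noise_sigma = as.numeric(noise_sigma),
              snr_db = if (!is.null(snr_db)) as.numeric(snr_db),
              pepper_density = as.numeric(pepper_density),
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L || cfg$samples_per_subject < 1L || cfg$n_veins < 0L)
    stop("config error: counts must be positive", call. = FALSE)
  if (length(cfg$size) != 2L || any(cfg$size < 9L))
    stop("config error: image size must be at least 9 x 9", call. = FALSE)
  if (cfg$class_spread < 0)
    stop("config error: class_spread must be non-negative", call. = FALSE)
  if (cfg$max_translation < 0 || cfg$max_rotation < 0 ||
      cfg$noise_sigma < 0 || cfg$pepper_density < 0 || cfg$pepper_density > 1)
    stop("config error: jitter and noise must be non-negative", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "synthetic vein dataset config: %d subjects x %d samples, %d x %d px, seed %d\n",
    x$n_subjects, x$samples_per_subject, x$size[1L], x$size[2L], x$seed))
  noise <- if (!is.null(x$snr_db)) sprintf("SNR %g dB", x$snr_db)
           else sprintf("sigma %g", x$noise_sigma)
  cat(sprintf("  %d veins, jitter +-%g px / +-%g deg, Gaussian noise %s, pepper %g\n",
              x$n_veins, x$max_translation, x$max_rotation, noise,
              x$pepper_density))
  invisible(x)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  code
}

# Mix a base seed with stream indices; stays below 2^31 - 1.
derive_seed <- function(seed, a, b = 0) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(a) * 16807 +
                as.numeric(b) * 69621 + 12345) %% 2147483647)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Generate the identity pattern of one synthetic finger
#'
#' Draws a class-specific "clean" vein image: a bright background with a
#' smooth illumination gradient, overlaid with `n_veins` dark ridges. Each
#' ridge is a spline through random control points running along the image
#' width (veins follow the finger axis), with a Gaussian cross-section of
#' random width and depth; the finished pattern is lightly blurred. The
#' result is deterministic given `cfg$seed` and `subject`.
#'
#' @param cfg A [synth_config()].
#' @param subject Integer subject index (the class identity).
#' @return Image matrix in `[0, 255]` with attribute `vein_mask`, a logical
#'   matrix marking ridge centrelines.
#' @export
make_class_pattern <- function(cfg, subject) {
  stopifnot(inherits(cfg, "synth_config"))
  A <- cfg$size[1L]; B <- cfg$size[2L]
  with_seed(derive_seed(cfg$seed, subject), {
    R <- matrix(seq(0, 1, length.out = A), A, B)
    C <- matrix(seq(0, 1, length.out = B), A, B, byrow = TRUE)
    gdir <- stats::runif(2, -1, 1)
    ph <- stats::runif(2, 0, 2 * pi)
    field <- cfg$background +
      cfg$gradient * (gdir[1L] * (R - 0.5) + gdir[2L] * (C - 0.5)) +
      0.4 * cfg$gradient * sin(2 * pi * 0.7 * R + ph[1L]) *
        cos(2 * pi * 0.5 * C + ph[2L])
    mask <- matrix(FALSE, A, B)
    if (cfg$n_veins > 0L) {
      rows <- matrix(seq_len(A), A, B)
      dark <- matrix(0, A, B)
      # canonical anatomy shared by all fingers; identity lives in the
      # per-subject control-point deviations around it
      base <- seq(0.15, 0.85, length.out = cfg$n_veins) * A
      for (k in seq_len(cfg$n_veins)) {
        ncp <- 5L
        xs <- seq(1, B, length.out = ncp)
        ys <- base[k] + stats::runif(ncp, -cfg$class_spread,
                                     cfg$class_spread) * A
        ys <- pmin(pmax(ys, 2), A - 1)
        center <- stats::spline(xs, ys, xout = seq_len(B))$y
        center <- pmin(pmax(center, 1), A)
        w <- stats::runif(1, cfg$vein_width[1L], cfg$vein_width[2L])
        depth <- stats::runif(1, cfg$vein_contrast[1L], cfg$vein_contrast[2L])
        cmat <- matrix(center, A, B, byrow = TRUE)
        dark <- dark + depth * exp(-(rows - cmat)^2 / (2 * (w / 2.355)^2))
        mask[cbind(round(center), seq_len(B))] <- TRUE
      }
      field <- field - dark
    }
    img <- clip255(field)
    if (cfg$blur_sigma > 0) {
      img <- clip255(255 * EBImage::imageData(
        EBImage::gblur(EBImage::as.Image(img / 255), sigma = cfg$blur_sigma)))
    }
    attr(img, "vein_mask") <- mask
    img
  })
}

#' Render one acquisition of a pattern
#'
#' Applies the per-sample perturbations of a capture: a rigid pose jitter
#' (translation up to `max_translation` px per axis and rotation up to
#' `max_rotation` degrees about the image centre, drawn uniformly; exposed
#' borders are filled with the configured background level, not black, to
#' avoid artificial high-contrast edges), then additive Gaussian sensor
#' noise (fixed sigma, or sigma derived from the whole-image `snr_db`) and
#' optional pepper noise, with final clipping to `[0, 255]`.
#'
#' @param pattern Image matrix from [make_class_pattern()].
#' @param cfg A [synth_config()].
#' @param seed Seed for this sample's perturbation draws.
#' @return Perturbed image matrix with attribute `perturbation` (named
#'   vector `dx`, `dy`, `angle`, `sigma`, `pepper`).
#' @export
render_sample <- function(pattern, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  check_gray_image(pattern, "pattern")
  with_seed(seed, {
    dx <- stats::runif(1, -cfg$max_translation, cfg$max_translation)
    dy <- stats::runif(1, -cfg$max_translation, cfg$max_translation)
    ang <- stats::runif(1, -cfg$max_rotation, cfg$max_rotation)
    img <- pattern
    attributes(img) <- list(dim = dim(pattern))
    if (dx != 0 || dy != 0 || ang != 0) {
      th <- ang * pi / 180
      Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
      ctr <- (dim(img) + 1) / 2
      off <- ctr - as.vector(ctr %*% Rm) + c(dx, dy)
      img <- EBImage::imageData(EBImage::affine(
        EBImage::as.Image(img / 255), rbind(Rm, off),
        filter = "bilinear", bg.col = cfg$background / 255,
        antialias = FALSE)) * 255
    }
    sigma <- if (!is.null(cfg$snr_db)) {
      sqrt(mean(img^2) / 10^(cfg$snr_db / 10))
    } else cfg$noise_sigma
    if (sigma > 0) img <- img + stats::rnorm(length(img), 0, sigma)
    if (cfg$pepper_density > 0) {
      n_pep <- round(cfg$pepper_density * length(img))
      if (n_pep > 0) img[sample.int(length(img), n_pep)] <- 0
    }
    img <- clip255(img)
    attr(img, "perturbation") <- c(dx = dx, dy = dy, angle = ang,
                                   sigma = sigma, pepper = cfg$pepper_density)
    img
  })
}

#' Generate a full synthetic dataset
#'
#' Produces `n_subjects * samples_per_subject` images (one pattern per
#' subject, each sample an independently perturbed rendering) together with
#' a manifest recording the perturbation parameters of every sample. When
#' `dir` is given, images are additionally written as 8-bit grayscale PNGs
#' in one directory per class, with the manifest as `manifest.csv`. Two
#' runs with the same configuration are bit-identical.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory.
#' @return Object of class `vein_dataset`: list with `images` (named list
#'   per subject of sample matrices), `manifest` (data frame), `cfg`, and
#'   `dir` (or `NA`).
#' @export
generate_dataset <- function(cfg = synth_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  subjects <- sprintf("subject%03d", seq_len(cfg$n_subjects))
  images <- vector("list", cfg$n_subjects)
  names(images) <- subjects
  rows <- vector("list", cfg$n_subjects * cfg$samples_per_subject)
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    pattern <- make_class_pattern(cfg, s)
    samples <- vector("list", cfg$samples_per_subject)
    for (i in seq_len(cfg$samples_per_subject)) {
      samples[[i]] <- render_sample(pattern, cfg, derive_seed(cfg$seed, s, i))
      k <- k + 1L
      pert <- attr(samples[[i]], "perturbation")
      rows[[k]] <- data.frame(subject_id = subjects[s], sample_idx = i,
                              path = file.path(subjects[s],
                                               sprintf("sample%02d.png", i)),
                              dx = pert[["dx"]], dy = pert[["dy"]],
                              angle = pert[["angle"]],
                              sigma = pert[["sigma"]],
                              pepper = pert[["pepper"]])
    }
    images[[s]] <- samples
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop("cannot create output directory '", dir, "'", call. = FALSE)
    }
    for (s in subjects) {
      dir.create(file.path(dir, s), showWarnings = FALSE)
    }
    for (j in seq_len(nrow(manifest))) {
      img <- images[[manifest$subject_id[j]]][[manifest$sample_idx[j]]]
      write_gray_image(round(img), file.path(dir, manifest$path[j]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(images = images, manifest = manifest, cfg = cfg,
                 dir = if (is.null(dir)) NA_character_ else dir),
            class = "vein_dataset")
}

#' @export
print.vein_dataset <- function(x, ...) {
  cat(sprintf("synthetic vein dataset: %d subjects x %d samples, %d x %d px\n",
              x$cfg$n_subjects, x$cfg$samples_per_subject,
              x$cfg$size[1L], x$cfg$size[2L]))
  if (!is.na(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}

#' Load a dataset previously written by [generate_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and per-class PNGs.
#' @return A `vein_dataset` (without the generating `cfg`).
#' @export
read_dataset_dir <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) {
    stop("no manifest.csv found in '", dir, "'", call. = FALSE)
  }
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  subjects <- unique(manifest$subject_id)
  images <- lapply(subjects, function(s) {
    rows <- manifest[manifest$subject_id == s, ]
    rows <- rows[order(rows$sample_idx), ]
    lapply(rows$path, function(p) read_gray_image(file.path(dir, p)))
  })
  names(images) <- subjects
  structure(list(images = images, manifest = manifest, cfg = NULL, dir = dir),
            class = "vein_dataset")
}

#' Measured signal-to-noise ratio between a clean and noisy image
#'
#' `10 * log10(mean(clean^2) / mean((noisy - clean)^2))`, the whole-image
#' power definition the generator's `snr_db` targets.
#'
#' @param clean,noisy Image matrices of identical size.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  stopifnot(identical(dim(clean), dim(noisy)))
  10 * log10(mean(clean^2) / mean((noisy - clean)^2))
}
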