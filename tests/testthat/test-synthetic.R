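# Small configurations keep these fast; the full reference benchmark is
# exercised in test-acceptance.R.
small_cfg <- function(...) {
  synth_config(n_subjects = 3, samples_per_subject = 4, size = c(48, 64),
               seed = 123, ...)
}

test_that("patterns are deterministic, background-dominated, vein-dark", {
  cfg <- small_cfg()
  p1 <- make_class_pattern(cfg, 1)
  p2 <- make_class_pattern(cfg, 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_class_pattern(cfg, 2)))

  flat <- make_class_pattern(small_cfg(n_veins = 0), 1)
  expect_lt(abs(mean(flat) - 190), 15)  # pure background near its level

  mask <- attr(p1, "vein_mask")
  expect_true(any(mask))
  expect_lt(mean(p1[mask]), mean(p1))   # ridge centrelines darker than image

  expect_error(synth_config(size = c(5, 5)), "config error")
  expect_error(synth_config(noise_sigma = -1), "config error")
})

test_that("rendering with zero jitter and zero noise is the identity", {
  cfg <- small_cfg(max_translation = 0, max_rotation = 0, noise_sigma = 0)
  p <- make_class_pattern(cfg, 1)
  s <- render_sample(p, cfg, seed = 5)
  expect_equal(matrix(s, nrow(p)), matrix(p, nrow(p)))
})

test_that("SNR presets land within 1 dB of the requested ratio", {
  for (preset in c("30dB", "40dB")) {
    cfg <- synth_config(n_subjects = 3, samples_per_subject = 4, seed = 123,
                        max_translation = 0, max_rotation = 0,
                        snr_db = preset, size = c(96, 128))
    target <- cfg$snr_db
    p <- make_class_pattern(cfg, 1)
    s <- render_sample(p, cfg, seed = 9)
    expect_lt(abs(measure_snr(matrix(p, nrow(p)), matrix(s, nrow(p))) - target), 1)
  }
})

test_that("pepper noise blacks out the configured pixel fraction", {
  cfg <- small_cfg(max_translation = 0, max_rotation = 0, noise_sigma = 0,
                   pepper_density = 0.05)
  p <- make_class_pattern(cfg, 1)
  s <- render_sample(p, cfg, seed = 2)
  expect_equal(sum(s == 0), round(0.05 * length(p)), tolerance = 0.1)
})

test_that("datasets have the configured shape and reproduce bit-for-bit", {
  cfg <- synth_config(n_subjects = 2, samples_per_subject = 12,
                      size = c(48, 64), seed = 7)
  d1 <- generate_dataset(cfg)
  expect_length(d1$images, 2L)
  expect_length(d1$images[[1]], 12L)
  expect_equal(nrow(d1$manifest), 24L)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$manifest, d2$manifest)
})

test_that("written datasets round-trip through PNG and the manifest", {
  cfg <- small_cfg()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  ds <- generate_dataset(cfg, dir = dir1)
  generate_dataset(cfg, dir = dir2)
  files <- list.files(dir1, recursive = TRUE)
  expect_length(files, 3 * 4 + 1)  # images + manifest
  sums1 <- tools::md5sum(file.path(dir1, sort(files)))
  sums2 <- tools::md5sum(file.path(dir2, sort(files)))
  expect_identical(unname(sums1), unname(sums2))

  back <- read_dataset_dir(dir1)
  expect_identical(names(back$images), names(ds$images))
  # PNG stores rounded 8-bit intensities
  expect_equal(back$images[[1]][[1]],
               round(matrix(ds$images[[1]][[1]], cfg$size[1])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("classes separate: inter-class code distance exceeds intra-class", {
  cfg <- synth_config(n_subjects = 4, samples_per_subject = 4,
                      size = c(64, 96), seed = 99)
  ds <- generate_dataset(cfg)
  codes <- lapply(ds$images, function(ss)
    lapply(ss, function(im) encode_image(matrix(im, nrow(im)), block_spec(3, 8))))
  intra <- c(); inter <- c()
  for (s1 in 1:4) for (s2 in s1:4) {
    for (i in 1:4) for (j in 1:4) {
      if (s1 == s2 && i >= j) next
      d <- hamming_distance(codes[[s1]][[i]], codes[[s2]][[j]])
      if (s1 == s2) intra <- c(intra, d) else inter <- c(inter, d)
    }
  }
  expect_gt(mean(inter), mean(intra))
})
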