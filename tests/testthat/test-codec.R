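test_that("code records pack bits MSB-first and round-trip", {
  expect_identical(serialize_code(vein_code(c(1, 1, 1, 1)), "a"),
                   "a\t4\tF0")
  set.seed(41)
  for (i in 1:50) {
    bits <- random_bits(4 * sample(1:50, 1))
    line <- serialize_code(vein_code(bits), sprintf("img%02d", i))
    back <- parse_code(line)
    expect_identical(back$code$bits, as.integer(bits))
    expect_identical(back$id, sprintf("img%02d", i))
  }
  expect_error(vein_code(integer(0)), "invalid vein code")
  expect_error(serialize_code(vein_code(c(1, 0, 1, 0)), "bad\tid"),
               "invalid id")
  expect_error(parse_code("x\t4\tFF"), "padding")
})

test_that("veincode files carry spec and convention in the header", {
  set.seed(42)
  spec <- block_spec(3, 8)
  codes <- lapply(1:5, function(i)
    encode_image(random_image(20, 30), spec))
  names(codes) <- sprintf("s%d", 1:5)
  path <- withr::local_tempfile(fileext = ".codes")
  write_veincodes(codes, path)
  expect_match(readLines(path, n = 1), "^#veincode v1 spec=3x8 neighbors=cw-tl-v1$")
  back <- read_veincodes(path)
  expect_identical(names(back), names(codes))
  for (i in 1:5) expect_identical(back[[i]]$bits, codes[[i]]$bits)
  expect_identical(attr(back, "spec"), spec)
})

test_that("grayscale image I/O round-trips 8-bit PNG content", {
  img <- matrix(sample(0:255, 40 * 30, TRUE), 40, 30)
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_image(img, path)
  expect_equal(read_gray_image(path), img, tolerance = 1e-10)
  expect_error(read_gray_image("x.gif"), "unsupported image format")
})

test_that("cli encode/match produce records and score CSVs end-to-end", {
  tmp <- withr::local_tempdir()
  set.seed(50)
  base <- random_image(48, 64)
  # two near-copies of one finger and one unrelated image
  for (f in c("t1", "t2", "probe_same")) {
    noisy <- pmin(pmax(base + matrix(sample(-10:10, length(base), TRUE),
                                     48), 0), 255)
    write_gray_image(noisy, file.path(tmp, paste0(f, ".png")))
  }
  write_gray_image(random_image(48, 64), file.path(tmp, "probe_other.png"))

  out <- utils::capture.output(
    status <- cli_dispatch(c("encode", "--block-spec", "3x8",
                             file.path(tmp, "t1.png"))))
  expect_identical(status, 0L)
  expect_match(out[1], "^#veincode v1")
  expect_match(out[2], "^t1\t")

  expect_identical(cli_dispatch(c("enroll", "--block-spec", "3x8",
                                  "--subject", "A",
                                  "--out", file.path(tmp, "A.codes"),
                                  file.path(tmp, "t1.png"),
                                  file.path(tmp, "t2.png"))), 0L)
  expect_identical(cli_dispatch(c("encode", "--block-spec", "3x8",
                                  "--out", file.path(tmp, "probes.codes"),
                                  file.path(tmp, "probe_same.png"),
                                  file.path(tmp, "probe_other.png"))), 0L)
  expect_identical(cli_dispatch(c("match",
                                  "--templates", file.path(tmp, "A.codes"),
                                  "--probe", file.path(tmp, "probes.codes"),
                                  "--dt", "0.19",
                                  "--out", file.path(tmp, "scores.csv"))), 0L)
  scores <- utils::read.csv(file.path(tmp, "scores.csv"))
  expect_identical(nrow(scores), 2L)
  expect_lt(scores$score[scores$probe_id == "probe_same"],
            scores$score[scores$probe_id == "probe_other"])
  expect_identical(scores$decision[scores$probe_id == "probe_same"], "accept")

  expect_identical(cli_dispatch(c("bogus")), 2L)
})

test_that("cli synth + evaluate run the full pipeline reproducibly", {
  tmp <- withr::local_tempdir()
  args <- c("synth", "--subjects", "3", "--samples", "8",
            "--size", "48x64", "--seed", "11",
            "--out", file.path(tmp, "ds"), "--log-level", "warn")
  expect_identical(cli_dispatch(args), 0L)
  expect_true(file.exists(file.path(tmp, "ds", "manifest.csv")))

  rep1 <- file.path(tmp, "r1.json"); rep2 <- file.path(tmp, "r2.json")
  eval_args <- function(out) c("evaluate", "--dir", file.path(tmp, "ds"),
                               "--templates", "6", "--block-spec", "3x8",
                               "--out", out, "--roc", file.path(tmp, "roc.csv"),
                               "--log-level", "warn")
  expect_identical(cli_dispatch(eval_args(rep1)), 0L)
  expect_identical(cli_dispatch(eval_args(rep2)), 0L)
  j1 <- jsonlite::read_json(rep1); j2 <- jsonlite::read_json(rep2)
  j1$meta <- NULL; j2$meta <- NULL  # timestamps live in a separate field
  expect_identical(j1, j2)
  expect_identical(j1$counts$n_genuine, 3L * 2L)
  expect_identical(j1$counts$n_impostor, 3L * 2L * 2L)
  expect_true(is.numeric(j1$eer))
  roc <- utils::read.csv(file.path(tmp, "roc.csv"))
  expect_identical(names(roc), c("threshold", "far", "frr"))

  # a YAML config file can supply any flag
  cfgfile <- file.path(tmp, "cfg.yaml")
  yaml::write_yaml(list(dir = file.path(tmp, "ds"), templates = 6,
                        `block-spec` = "3x8", `log-level` = "warn"), cfgfile)
  rep3 <- file.path(tmp, "r3.json")
  expect_identical(cli_dispatch(c("evaluate", "--config", cfgfile,
                                  "--out", rep3)), 0L)
  j3 <- jsonlite::read_json(rep3); j3$meta <- NULL; j3$roc_csv <- NULL
  j1b <- j1; j1b$roc_csv <- NULL
  expect_identical(j3, j1b)
})
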