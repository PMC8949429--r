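# Naive triple-loop reference encoder: explicit padding, explicit per-block
# means, explicit per-tile centrosymmetric comparisons. Deliberately written
# with scalar loops, independent of the package's vectorised path.
oracle_encode <- function(img, a, b) {
  A <- nrow(img); B <- ncol(img)
  Ap <- ceiling(A / a) * a; Bp <- ceiling(B / b) * b
  pad <- matrix(0, Ap, Bp)
  pad[seq_len(A), seq_len(B)] <- img
  p <- Ap / a; q <- Bp / b
  M <- matrix(0, p, q)
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      acc <- 0
      for (r in ((i - 1) * a + 1):(i * a)) {
        for (cc in ((j - 1) * b + 1):(j * b)) acc <- acc + pad[r, cc]
      }
      M[i, j] <- acc / (a * b)
    }
  }
  P <- ceiling(p / 3); Q <- ceiling(q / 3)
  Mp <- matrix(0, 3 * P, 3 * Q)
  Mp[seq_len(p), seq_len(q)] <- M
  bits <- integer(0)
  for (ti in seq_len(P)) {
    for (tj in seq_len(Q)) {
      tl <- Mp[(3 * ti - 2):(3 * ti), (3 * tj - 2):(3 * tj)]
      n <- c(tl[1, 1], tl[1, 2], tl[1, 3], tl[2, 3],
             tl[3, 3], tl[3, 2], tl[3, 1], tl[2, 1])
      for (j in 1:4) bits <- c(bits, as.integer(n[j] >= n[j + 4]))
    }
  }
  bits
}

random_image <- function(A, B) matrix(sample(0:255, A * B, replace = TRUE), A, B)

random_bits <- function(L) sample(0:1, L, replace = TRUE)

# Tiny in-memory dataset of identical constant-plus-id images: enough
# structure for protocol bookkeeping tests without a generator run.
dummy_dataset <- function(n_subjects, samples, A = 9, B = 9) {
  images <- lapply(seq_len(n_subjects), function(s)
    lapply(seq_len(samples), function(i) random_image(A, B)))
  names(images) <- sprintf("f%03d", seq_len(n_subjects))
  images
}
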