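# Orthonormal multi-level 2-D Haar transform.
#
# The analysis/synthesis pair is exactly orthonormal, which makes the l1
# proximal step of the CS solver exact (soft-thresholding of coefficients).
# Grids must be divisible by 2^levels along both axes.

haar_check <- function(n, levels) {
  stop_if_not(all(n %% 2^levels == 0),
              "grid of %d x %d not divisible by 2^%d; reduce wavelet levels",
              n[1], n[2], levels)
}

haar_step_fwd <- function(b) {
  m1 <- nrow(b); m2 <- ncol(b)
  odd1 <- seq(1, m1, 2); evn1 <- odd1 + 1
  a <- (b[odd1, , drop = FALSE] + b[evn1, , drop = FALSE]) / sqrt(2)
  d <- (b[odd1, , drop = FALSE] - b[evn1, , drop = FALSE]) / sqrt(2)
  b <- rbind(a, d)
  odd2 <- seq(1, m2, 2); evn2 <- odd2 + 1
  a <- (b[, odd2, drop = FALSE] + b[, evn2, drop = FALSE]) / sqrt(2)
  d <- (b[, odd2, drop = FALSE] - b[, evn2, drop = FALSE]) / sqrt(2)
  cbind(a, d)
}

haar_step_inv <- function(b) {
  m1 <- nrow(b); m2 <- ncol(b)
  h2 <- m2 / 2
  a <- b[, seq_len(h2), drop = FALSE]; d <- b[, h2 + seq_len(h2), drop = FALSE]
  out <- matrix(b[1] * 0, m1, m2)
  out[, seq(1, m2, 2)] <- (a + d) / sqrt(2)
  out[, seq(2, m2, 2)] <- (a - d) / sqrt(2)
  b <- out
  h1 <- m1 / 2
  a <- b[seq_len(h1), , drop = FALSE]; d <- b[h1 + seq_len(h1), , drop = FALSE]
  out <- matrix(b[1] * 0, m1, m2)
  out[seq(1, m1, 2), ] <- (a + d) / sqrt(2)
  out[seq(2, m1, 2), ] <- (a - d) / sqrt(2)
  out
}

haar2_forward <- function(x, levels = 3) {
  n <- dim(x); haar_check(n, levels)
  for (l in seq_len(levels)) {
    m <- n %/% 2^(l - 1)
    x[seq_len(m[1]), seq_len(m[2])] <-
      haar_step_fwd(x[seq_len(m[1]), seq_len(m[2]), drop = FALSE])
  }
  x
}

haar2_inverse <- function(x, levels = 3) {
  n <- dim(x); haar_check(n, levels)
  for (l in rev(seq_len(levels))) {
    m <- n %/% 2^(l - 1)
    x[seq_len(m[1]), seq_len(m[2])] <-
      haar_step_inv(x[seq_len(m[1]), seq_len(m[2]), drop = FALSE])
  }
  x
}

# complex soft-thresholding
soft_threshold <- function(z, t) {
  m <- Mod(z)
  sc <- pmax(m - t, 0) / pmax(m, .Machine$double.eps)
  z * sc
}
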