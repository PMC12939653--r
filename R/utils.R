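#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards, so all generators are pure in (args, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# circular shifts used by the centered-FFT helpers
circshift2 <- function(x, s) {
  n <- dim(x)
  i <- ((seq_len(n[1]) - 1 - s[1]) %% n[1]) + 1
  j <- ((seq_len(n[2]) - 1 - s[2]) %% n[2]) + 1
  x[i, j, drop = FALSE]
}

fftshift2 <- function(x) circshift2(x, floor(dim(x) / 2))
ifftshift2 <- function(x) circshift2(x, -floor(dim(x) / 2))

#' Centered unitary 2-D Fourier transform
#'
#' Forward/inverse discrete Fourier transforms with the DC component at the
#' grid center (index `floor(n/2)+1` along each axis) and unitary scaling, the
#' convention used for all k-space arrays in this package.
#'
#' @param x numeric or complex matrix.
#' @return complex matrix of the same dimension.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(as.matrix(x)))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(as.matrix(x)), inverse = TRUE)) / sqrt(length(x))
}

# index of the conjugate-symmetric partner of centered index i (1-based):
# frequency -f modulo n, so the extreme (Nyquist) index of an even grid is
# its own partner
conj_index <- function(i, n) {
  ctr <- floor(n / 2) + 1
  ((2 * ctr - i - 1) %% n) + 1
}

# trapezoidal rule
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

vnorm <- function(v) sqrt(sum(v^2))
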