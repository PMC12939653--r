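#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in dB; `Inf` when the images are equal.
#' Complex inputs are compared on magnitude.
#'
#' @param ref,test images (matrices or [image_volume()]).
#' @param data_range dynamic range (default: reference max - min).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = NULL) {
  ref <- Mod(as_values(ref)); test <- Mod(as_values(test))
  stop_if_not(all(dim(ref) == dim(test)), "shape mismatch")
  if (is.null(data_range)) data_range <- diff(range(ref))
  stop_if_not(data_range > 0, "data_range must be > 0")
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window; symmetric in its arguments.
#' Complex inputs are compared on magnitude.
#'
#' @param ref,test images (matrices or [image_volume()]).
#' @param window odd Gaussian window size.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param k1,k2 stabilization constants.
#' @param data_range dynamic range (default: reference max - min).
#' @return scalar SSIM in [-1, 1].
#' @export
ssim <- function(ref, test, window = 7, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 data_range = NULL) {
  x <- Mod(as_values(ref)); y <- Mod(as_values(test))
  stop_if_not(all(dim(x) == dim(y)), "shape mismatch")
  # joint range keeps the measure symmetric in its arguments
  if (is.null(data_range)) data_range <- diff(range(c(x, y)))
  if (data_range <= 0) data_range <- 1
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  half <- floor(window / 2)
  g <- outer(stats::dnorm(-half:half, sd = sigma),
             stats::dnorm(-half:half, sd = sigma))
  g <- g / sum(g)
  f <- function(z) EBImage::filter2(z, g, boundary = "replicate")
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2; syy <- f(y * y) - my^2; sxy <- f(x * y) - mx * my
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Normalized mean squared error
#'
#' `||test - ref||^2 / ||ref||^2` (magnitudes for complex inputs).
#'
#' @param ref,test images (matrices or [image_volume()]).
#' @return non-negative scalar.
#' @export
nmse <- function(ref, test) {
  ref <- Mod(as_values(ref)); test <- Mod(as_values(test))
  stop_if_not(all(dim(ref) == dim(test)), "shape mismatch")
  denom <- sum(ref^2)
  stop_if_not(denom > 0, "reference must not be identically zero")
  sum((test - ref)^2) / denom
}

as_values <- function(x) {
  if (inherits(x, "image_volume")) x$values else as.matrix(x)
}

#' Image-fidelity report for a set of reconstructions
#'
#' @param ref reference image.
#' @param recons named list of reconstructed images.
#' @param extra optional data.frame of per-method columns to append.
#' @return data.frame with one row per method (psnr_db, ssim, nmse).
#' @export
fidelity_report <- function(ref, recons, extra = NULL) {
  rows <- lapply(names(recons), function(nm) {
    data.frame(method = nm,
               psnr_db = psnr(ref, recons[[nm]]),
               ssim = ssim(ref, recons[[nm]]),
               nmse = nmse(ref, recons[[nm]]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(extra)) out <- cbind(out, extra)
  rownames(out) <- NULL
  out
}
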