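#' Multi-scale Hessian vesselness filter
#'
#' Frangi-type tubularity response for bright curvilinear structures: at each
#' scale the image is Gaussian-smoothed, the scale-normalized Hessian
#' eigenvalues are computed, and the 2-D vesselness combines the blobness
#' ratio and second-order structure strength. The per-voxel maximum over
#' scales is normalized to [0, 1].
#'
#' @param img an [image_volume()] (magnitude is used for complex input).
#' @param scales_mm Gaussian scales (standard deviations) in mm.
#' @param beta blobness sensitivity.
#' @param return_scales if TRUE, also return the per-voxel argmax scale.
#' @return an [image_volume()] with values in [0, 1] (attribute
#'   `scale_mm` holds the argmax-scale map when requested).
#' @export
vesselness <- function(img, scales_mm = c(0.5, 1, 1.5, 2), beta = 0.5,
                       return_scales = FALSE) {
  stop_if_not(length(scales_mm) >= 1, "need at least one scale")
  x <- Mod(img$values)
  vox <- img$voxel_size_mm
  best <- matrix(0, nrow(x), ncol(x))
  bsc <- matrix(scales_mm[1], nrow(x), ncol(x))
  for (s_mm in scales_mm) {
    s <- max(s_mm / vox, 0.6)
    xs <- EBImage::gblur(x, sigma = s)
    # scale-normalized second derivatives (central differences)
    dxx <- s^2 * (rbind(xs[-1, ], xs[nrow(xs), ]) +
                    rbind(xs[1, ], xs[-nrow(xs), ]) - 2 * xs)
    dyy <- s^2 * (cbind(xs[, -1], xs[, ncol(xs)]) +
                    cbind(xs[, 1], xs[, -ncol(xs)]) - 2 * xs)
    dx <- (rbind(xs[-1, ], xs[nrow(xs), ]) - rbind(xs[1, ], xs[-nrow(xs), ])) / 2
    dxy <- (cbind(dx[, -1], dx[, ncol(dx)]) - cbind(dx[, 1], dx[, -ncol(dx)])) / 2
    dxy <- s^2 * dxy
    # eigenvalues of [[dxx, dxy], [dxy, dyy]]
    tr <- (dxx + dyy) / 2
    rt <- sqrt(pmax(((dxx - dyy) / 2)^2 + dxy^2, 0))
    l1 <- tr + rt; l2 <- tr - rt
    # order |l1| <= |l2|
    swap <- abs(l1) > abs(l2)
    tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
    S2 <- l1^2 + l2^2
    c2 <- max(S2) / 4
    if (c2 <= 0) next
    rb2 <- (l1 / pmin(l2, -.Machine$double.eps))^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * c2)))
    v[l2 >= 0] <- 0       # bright tubes have strongly negative l2
    upd <- v > best
    best[upd] <- v[upd]
    bsc[upd] <- s_mm
  }
  # suppress spurious ridge responses at the image border (finite-difference
  # stencils see the replicated edge as a structure)
  bw <- 3
  if (nrow(best) > 2 * bw && ncol(best) > 2 * bw) {
    best[c(seq_len(bw), nrow(best) - seq_len(bw) + 1), ] <- 0
    best[, c(seq_len(bw), ncol(best) - seq_len(bw) + 1)] <- 0
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  out <- image_volume(best, vox, img$origin_mm)
  if (return_scales) attr(out, "scale_mm") <- bsc
  out
}
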