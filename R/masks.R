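#' Sampling mask for Cartesian k-space
#'
#' Binary indicator of acquired k-space locations on the centered grid, with
#' a fully sampled low-frequency center band (a contiguous block of
#' phase-encode lines, i.e. matrix rows, around DC). The acceleration is the
#' fraction of locations NOT sampled and is always recomputed from the
#' indicator.
#'
#' @param mask logical matrix of sampled locations.
#' @param center_fraction fraction of phase-encode lines forming the fully
#'   sampled center band.
#' @param seed seed used to build the mask (metadata).
#' @return an object of class `sampling_mask` with fields `mask`,
#'   `center_fraction`, `center_rows`, `acceleration`, `seed`.
#' @export
sampling_mask <- function(mask, center_fraction = 0, seed = NA_integer_) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  rows <- center_band_rows(nrow(mask), center_fraction)
  if (length(rows)) {
    stop_if_not(all(mask[rows, ]), "center band must be fully sampled")
  }
  structure(list(mask = mask, center_fraction = center_fraction,
                 center_rows = rows,
                 acceleration = 1 - mean(mask), seed = seed),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d x %d, acceleration %.3f, center band %d lines\n",
              nrow(x$mask), ncol(x$mask), x$acceleration, length(x$center_rows)))
  invisible(x)
}

#' Rows of the centered low-frequency band
#'
#' Indices of the contiguous phase-encode lines (matrix rows) forming the
#' fully sampled center band around the DC row.
#'
#' @param n number of phase-encode lines.
#' @param center_fraction band fraction of `n`.
#' @return integer vector of row indices (empty when the fraction rounds to
#'   zero lines).
#' @export
center_band_rows <- function(n, center_fraction) {
  nb <- round(center_fraction * n)
  if (nb <= 0) return(integer())
  ctr <- floor(n / 2) + 1
  lo <- ctr - floor((nb - 1) / 2)
  seq(lo, lo + nb - 1)
}

#' Fully sampled mask
#'
#' @param shape grid shape (rows, cols).
#' @param center_fraction center-band fraction recorded on the mask.
#' @return a [sampling_mask()] sampling every location.
#' @export
full_mask <- function(shape, center_fraction = 0) {
  sampling_mask(matrix(TRUE, shape[1], shape[2]), center_fraction)
}

#' Poisson-disc sampling mask
#'
#' Random k-space sampling with a minimum pairwise distance (blue-noise)
#' constraint outside a fully sampled center band. Dart throwing runs to
#' saturation, then the accepted set is randomly thinned to the target
#' density, so the distance constraint holds exactly and the achieved
#' acceleration is within 2% absolute of the target (or an error names the
#' maximum achievable density).
#'
#' @param shape grid shape (rows, cols).
#' @param target_acceleration fraction of locations NOT sampled, in [0, 1).
#' @param min_radius minimum pairwise distance between sampled locations
#'   outside the center band, in grid units (pixels).
#' @param center_fraction fully sampled center-band fraction.
#' @param seed integer seed.
#' @param pf_fraction optional partial-Fourier restriction in [0.5, 1]:
#'   random samples are only placed on the first `ceiling(pf_fraction * n)`
#'   phase-encode lines (plus the center band), so the remaining lines can
#'   be completed by conjugate symmetry.
#' @return a [sampling_mask()].
#' @export
poisson_disc_mask <- function(shape, target_acceleration = 0.7,
                              min_radius = 1.2, center_fraction = 0.08,
                              seed = 1, pf_fraction = 1) {
  stop_if_not(target_acceleration >= 0 && target_acceleration < 1,
              "target_acceleration must lie in [0, 1)")
  stop_if_not(min_radius >= 0, "min_radius must be >= 0")
  n1 <- shape[1]; n2 <- shape[2]
  rows <- center_band_rows(n1, center_fraction)
  mask <- matrix(FALSE, n1, n2)
  mask[rows, ] <- TRUE
  if (target_acceleration == 0) {
    mask[] <- TRUE
    return(sampling_mask(mask, center_fraction, seed))
  }
  n_target <- round((1 - target_acceleration) * n1 * n2)
  n_center <- length(rows) * n2
  n_outside <- max(0L, n_target - n_center)

  # neighbourhood offsets violating the distance constraint
  r <- min_radius
  w <- floor(r)
  offs <- expand.grid(di = -w:w, dj = -w:w)
  offs <- offs[offs$di^2 + offs$dj^2 < r^2 & !(offs$di == 0 & offs$dj == 0), ]

  stop_if_not(pf_fraction >= 0.5 && pf_fraction <= 1,
              "pf_fraction must lie in [0.5, 1]")
  pf_rows <- seq_len(ceiling(pf_fraction * n1))
  with_seed(seed, {
    out_idx <- which(!(row(mask) %in% rows) & (row(mask) %in% pf_rows))
    cand <- sample(out_idx)
    acc <- matrix(FALSE, n1, n2)
    if (nrow(offs) == 0) {
      acc[cand] <- TRUE
    } else {
      ci <- ((cand - 1) %% n1) + 1
      cj <- ((cand - 1) %/% n1) + 1
      for (q in seq_along(cand)) {
        i <- ci[q]; j <- cj[q]
        ok <- TRUE
        for (o in seq_len(nrow(offs))) {
          ii <- i + offs$di[o]; jj <- j + offs$dj[o]
          if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && acc[ii, jj]) {
            ok <- FALSE; break
          }
        }
        if (ok) acc[i, j] <- TRUE
      }
    }
    n_sat <- sum(acc)
    if (n_sat < n_outside - 0.02 * n1 * n2) {
      stop(sprintf(paste0("min_radius %.2f is infeasible for target acceleration %.2f: ",
                          "maximum achievable sampled density is %.3f"),
                   min_radius, target_acceleration,
                   (n_sat + n_center) / (n1 * n2)), call. = FALSE)
    }
    if (n_sat > n_outside) {
      keep <- sample(which(acc), n_outside)
      acc[] <- FALSE
      acc[keep] <- TRUE
    }
    mask[acc] <- TRUE
    sampling_mask(mask, center_fraction, seed)
  })
}

#' Partial Fourier sampling mask
#'
#' Contiguous block covering `pf_fraction` of the phase-encode lines from the
#' low-index k-space edge through the symmetric center band; the center band
#' is always fully sampled.
#'
#' @param shape grid shape (rows, cols).
#' @param pf_fraction fraction of phase-encode lines acquired, in [0.5, 1].
#' @param center_fraction fully sampled center-band fraction.
#' @return a [sampling_mask()].
#' @export
partial_fourier_mask <- function(shape, pf_fraction = 0.625,
                                 center_fraction = 0.08) {
  stop_if_not(pf_fraction >= 0.5 && pf_fraction <= 1,
              "pf_fraction must lie in [0.5, 1]")
  n1 <- shape[1]
  mask <- matrix(FALSE, n1, shape[2])
  mask[seq_len(ceiling(pf_fraction * n1)), ] <- TRUE
  mask[center_band_rows(n1, center_fraction), ] <- TRUE
  sampling_mask(mask, center_fraction)
}
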