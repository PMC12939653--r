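#' Reconstruction configuration
#'
#' Settings for the compressed-sensing solver and its optional structured
#' priors. The solver minimizes `0.5 * ||F_M x - y||^2 + lambda * ||Psi x||_1`
#' by monotone accelerated proximal gradient (MFISTA); with the unitary
#' Fourier operator the gradient Lipschitz constant is 1, so `step_size`
#' must not exceed 1.
#'
#' @param lambda_reg regularization weight (>= 0).
#' @param transform sparsifying transform: "haar" (orthonormal wavelet),
#'   "identity", or "fd" (anisotropic finite differences).
#' @param levels wavelet decomposition levels.
#' @param max_iterations iteration budget.
#' @param step_size gradient step (must be <= 1).
#' @param tol relative objective-change stopping tolerance.
#' @param hankel list: `enabled`, `window`, `rank`, `every` (apply the
#'   Hankel low-rank projection along image rows/columns every `every`
#'   iterations).
#' @param pf list: `enabled`, `phase_band_fraction` (partial-Fourier
#'   completion used once, as initialization).
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(lambda_reg = 1e-3, transform = c("haar", "identity", "fd"),
                         levels = 3, max_iterations = 60, step_size = 1,
                         tol = 1e-6,
                         hankel = list(enabled = FALSE, window = 16, rank = 8,
                                       every = 10),
                         pf = list(enabled = FALSE, phase_band_fraction = 0.08)) {
  transform <- match.arg(transform)
  stop_if_not(lambda_reg >= 0, "lambda_reg must be >= 0")
  stop_if_not(tol > 0, "tol must be > 0")
  stop_if_not(max_iterations >= 1, "max_iterations must be >= 1")
  hk <- utils::modifyList(list(enabled = FALSE, window = 16, rank = 8,
                               every = 10), hankel)
  stop_if_not(hk$rank >= 1, "hankel rank must be >= 1")
  pfl <- utils::modifyList(list(enabled = FALSE, phase_band_fraction = 0.08), pf)
  if (step_size > 1 + 1e-12) {
    stop(sprintf("step_size %.3g violates the convergence bound; use step_size <= 1",
                 step_size), call. = FALSE)
  }
  structure(list(lambda_reg = lambda_reg, transform = transform,
                 levels = levels, max_iterations = max_iterations,
                 step_size = step_size, tol = tol, hankel = hk, pf = pfl),
            class = "recon_config")
}

# sparsity penalty value and proximal operator for the configured transform
psi_penalty <- function(x, cfg) {
  switch(cfg$transform,
         haar = sum(Mod(haar2_forward(x, cfg$levels))),
         identity = sum(Mod(x)),
         fd = sum(Mod(x[-1, ] - x[-nrow(x), ])) + sum(Mod(x[, -1] - x[, -ncol(x)])))
}

psi_prox <- function(x, t, cfg) {
  switch(cfg$transform,
         haar = haar2_inverse(soft_threshold(haar2_forward(x, cfg$levels), t),
                              cfg$levels),
         identity = soft_threshold(x, t),
         fd = fd_prox(x, t))
}

# anisotropic TV prox by a few dual (Chambolle-type) iterations
fd_prox <- function(x, t, iters = 12) {
  if (t <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  p1 <- matrix(0i, n1 - 1, n2); p2 <- matrix(0i, n1, n2 - 1)
  tau <- 0.25
  for (it in seq_len(iters)) {
    div <- matrix(0i, n1, n2)
    div[-n1, ] <- div[-n1, ] - p1; div[-1, ] <- div[-1, ] + p1
    div[, -n2] <- div[, -n2] - p2; div[, -1] <- div[, -1] + p2
    u <- x - div
    g1 <- u[-1, ] - u[-n1, ]; g2 <- u[, -1] - u[, -n2]
    p1 <- p1 + tau / t * g1; p2 <- p2 + tau / t * g2
    p1 <- p1 / pmax(1, Mod(p1)); p2 <- p2 / pmax(1, Mod(p2))
  }
  div <- matrix(0i, n1, n2)
  div[-n1, ] <- div[-n1, ] - p1; div[-1, ] <- div[-1, ] + p1
  div[, -n2] <- div[, -n2] - p2; div[, -1] <- div[, -1] + p2
  x - t * div
}

# data-fidelity objective with optional per-sample weights (full-grid matrix)
fidelity_obj <- function(x, y, w2) {
  r <- fft2c(x) - y$values
  0.5 * sum(w2 * Mod(r)^2)
}

# core MFISTA loop shared by cs_reconstruct and weighted_reconstruct;
# hook(x, iter) is applied after the proximal step (structured priors)
mfista <- function(y, cfg, weights = NULL, hook = NULL, x0 = NULL) {
  m <- y$mask$mask
  w2 <- if (is.null(weights)) m * 1 else (weights^2) * m
  x <- if (is.null(x0)) ifft2c(y$values * (w2 > 0)) else x0
  obj <- function(z) fidelity_obj(z, y, w2) + cfg$lambda_reg * psi_penalty(z, cfg)
  fx <- obj(x)
  z <- x; tmom <- 1
  objs <- numeric(cfg$max_iterations)
  for (it in seq_len(cfg$max_iterations)) {
    grad <- ifft2c(w2 * (fft2c(z) - y$values))
    xc <- psi_prox(z - cfg$step_size * grad, cfg$lambda_reg * cfg$step_size, cfg)
    fc <- obj(xc)
    if (fc <= fx) {           # monotone step (MFISTA)
      xn <- xc; fn <- fc
    } else {
      xn <- x; fn <- fx
    }
    if (!is.null(hook)) {     # structured priors live outside the objective
      xh <- hook(xn, it)
      if (!identical(xh, xn)) { xn <- xh; fn <- obj(xn); xc <- xn }
    }
    tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    z <- xn + (tmom / tnew) * (xc - xn) + ((tmom - 1) / tnew) * (xn - x)
    # candidate-based criterion: a rejected overshoot is not convergence
    rel <- abs(fx - fc) / max(abs(fx), .Machine$double.eps)
    x <- xn; fx <- fn; tmom <- tnew
    objs[it] <- fx
    if (it > 1 && rel < cfg$tol) { objs <- objs[seq_len(it)]; break }
  }
  list(x = x, objective = objs)
}

#' Compressed-sensing reconstruction
#'
#' Approximate minimizer of `0.5 * ||F_M x - y||^2 + lambda * ||Psi x||_1`
#' by monotone accelerated proximal gradient iteration. With a full mask and
#' `lambda_reg = 0` this reduces to the inverse Fourier transform of `y`.
#'
#' @param y a [kspace_measurement()].
#' @param cfg a [recon_config()].
#' @return an [image_volume()] (complex values).
#' @export
cs_reconstruct <- function(y, cfg = recon_config()) {
  stop_if_not(any(y$mask$mask), "mask must sample at least one location")
  res <- mfista(y, cfg)
  out <- image_volume(res$x, y$voxel_size_mm)
  attr(out, "objective") <- res$objective
  out
}

#' Sensor-weighted compressed-sensing reconstruction
#'
#' Minimizes `0.5 * ||W (F_M x - y)||^2 + lambda * ||Psi x||_1` with
#' per-sample confidence weights in [0, 1]. With unit weights this is
#' identical to [cs_reconstruct()]; zero weights remove samples from the
#' data term.
#'
#' @param y a [kspace_measurement()].
#' @param weights full-grid numeric matrix of weights in [0, 1] (values off
#'   the mask support are ignored).
#' @param cfg a [recon_config()].
#' @return an [image_volume()].
#' @export
weighted_reconstruct <- function(y, weights, cfg = recon_config()) {
  weights <- as.matrix(weights)
  stop_if_not(all(dim(weights) == dim(y$values)), "weights/k-space shape mismatch")
  stop_if_not(all(weights >= 0), "weights must be non-negative")
  stop_if_not(all(weights <= 1), "weights must not exceed 1")
  res <- mfista(y, cfg, weights = weights)
  out <- image_volume(res$x, y$voxel_size_mm)
  attr(out, "objective") <- res$objective
  out
}

#' Project an image onto the data-consistency set
#'
#' Replaces the Fourier coefficients of `x` at sampled k-space locations
#' with the measured values. Idempotent.
#'
#' @param x an [image_volume()].
#' @param y a [kspace_measurement()].
#' @return an [image_volume()].
#' @export
data_consistency_project <- function(x, y) {
  stop_if_not(all(dim(x$values) == dim(y$values)), "shape mismatch")
  ks <- fft2c(x$values)
  ks[y$mask$mask] <- y$values[y$mask$mask]
  image_volume(ifft2c(ks), x$voxel_size_mm)
}

#' Hankel structured low-rank projection of a 1-D signal block
#'
#' Lifts the block to a Hankel matrix with `window` rows, truncates to the
#' given rank by singular value decomposition, and de-lifts by anti-diagonal
#' averaging. Sums of `r` complex exponentials produce Hankel matrices of
#' rank `r`, so this acts as a structured denoiser.
#'
#' @param block numeric or complex vector.
#' @param window Hankel window length (rows of the lifted matrix), less than
#'   the block length.
#' @param rank truncation rank, at most `min(window, length(block)-window+1)`.
#' @return vector of the same length as `block`.
#' @export
hankel_lowrank_project <- function(block, window = 16, rank = 8) {
  n <- length(block)
  stop_if_not(window < n, "window must be smaller than the block length")
  ncols <- n - window + 1
  stop_if_not(rank <= min(window, ncols),
              "rank %d exceeds the minimum Hankel dimension %d",
              rank, min(window, ncols))
  H <- matrix(block[outer(seq_len(window), seq_len(ncols) - 1, "+")],
              window, ncols)
  sv <- svd(H)
  k <- seq_len(rank)
  Hr <- sv$u[, k, drop = FALSE] %*%
    (sv$d[k] * Conj(t(sv$v[, k, drop = FALSE])))
  # anti-diagonal averaging
  idx <- outer(seq_len(window), seq_len(ncols) - 1, "+")
  out <- as.vector(tapply(as.vector(Hr), as.vector(idx), sum))
  cnt <- as.vector(table(as.vector(idx)))
  out / cnt
}

# apply the Hankel projection along every image row and column
hankel_denoise_image <- function(x, window, rank) {
  n1 <- nrow(x); n2 <- ncol(x)
  for (i in seq_len(n1)) x[i, ] <- hankel_lowrank_project(x[i, ], window, rank)
  for (j in seq_len(n2)) x[, j] <- hankel_lowrank_project(x[, j], window, rank)
  x
}

#' Partial-Fourier completion by phase-corrected conjugate symmetry
#'
#' Estimates a low-resolution phase map from the fully sampled center band,
#' fills unsampled locations with phase-corrected conjugate-symmetric values
#' (followed by a few POCS iterations enforcing the smooth-phase constraint),
#' and leaves sampled locations untouched. For an exactly real image the
#' completion is exact.
#'
#' @param ks a [kspace_measurement()] acquired with a partial-Fourier mask.
#' @param phase_band_fraction minimum required center-band fraction.
#' @param pocs_iterations number of projection-onto-convex-sets refinements.
#' @return a [kspace_measurement()] with a full mask.
#' @export
partial_fourier_complete <- function(ks, phase_band_fraction = 0.08,
                                     pocs_iterations = 8) {
  n <- dim(ks$values)
  m <- ks$mask$mask
  if (all(m)) return(ks)
  rows <- ks$mask$center_rows
  if (length(rows) < max(1, floor(phase_band_fraction * n[1]))) {
    stop("missing center band: partial-Fourier completion requires a fully sampled low-frequency band",
         call. = FALSE)
  }
  # low-resolution phase estimate from a windowed center band; the window
  # must be symmetric about the DC row so that real images yield zero phase
  ctr <- floor(n[1] / 2) + 1
  # restrict to the symmetric subband so the window itself cannot introduce
  # spurious phase
  dsym <- min(ctr - min(rows), max(rows) - ctr)
  sym_rows <- (ctr - dsym):(ctr + dsym)
  wind <- matrix(0, n[1], n[2])
  wind[sym_rows, ] <- 0.54 + 0.46 * cos(pi * (sym_rows - ctr) / (dsym + 1))
  xlow <- ifft2c(ks$values * wind)
  phase <- Arg(xlow)
  # the raw low-resolution phase is biased where the magnitude varies
  # sharply; under the smooth-phase assumption a magnitude-weighted
  # low-order polynomial fit is far more accurate
  u <- as.vector((row(phase) - 1) / (n[1] - 1))
  v <- as.vector((col(phase) - 1) / (n[2] - 1))
  X <- cbind(1, u, v, u^2, u * v, v^2)
  wts <- as.vector(Mod(xlow))
  fit <- tryCatch(stats::lm.wfit(X, as.vector(phase), wts),
                  error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$coefficients))) {
    fitted <- matrix(X %*% fit$coefficients, n[1], n[2])
    # accept the smooth model only where it explains the weighted phase
    if (sqrt(sum(wts * (as.vector(fitted) - as.vector(phase))^2) / sum(wts)) < 0.5) {
      phase <- fitted
    }
  }
  eip <- exp(1i * phase)
  # initial conjugate-symmetric fill
  vals <- ks$values
  i1 <- conj_index(row(vals), n[1]); i2 <- conj_index(col(vals), n[2])
  fill <- which(!m)
  partner <- (i2[fill] - 1) * n[1] + i1[fill]
  ok <- m[partner]
  vals[fill[ok]] <- Conj(vals[partner[ok]])
  # POCS refinement under the smooth-phase constraint
  for (it in seq_len(pocs_iterations)) {
    x <- ifft2c(vals)
    x <- Re(x * Conj(eip)) * eip
    vals <- fft2c(x)
    vals[m] <- ks$values[m]
  }
  kspace_measurement(vals, full_mask(n, ks$mask$center_fraction),
                     ks$noise_sigma, ks$voxel_size_mm)
}

#' Full reconstruction with structured priors
#'
#' Composition of the compressed-sensing solver with the optional priors:
#' partial-Fourier completion (once, as initialization), patch-wise Hankel
#' low-rank projections interleaved every few iterations, and a final
#' data-consistency projection (applied when all weights are 1, so that the
#' sampled k-space of the output equals the measurements exactly).
#'
#' @param y a [kspace_measurement()].
#' @param cfg a [recon_config()].
#' @param weights optional full-grid weight matrix in [0, 1].
#' @return an [image_volume()].
#' @export
reconstruct_full <- function(y, cfg = recon_config(), weights = NULL) {
  x0 <- NULL
  if (isTRUE(cfg$pf$enabled) && length(y$mask$center_rows) > 0 &&
      !all(y$mask$mask)) {
    comp <- tryCatch(partial_fourier_complete(y, cfg$pf$phase_band_fraction),
                     error = function(e) NULL)
    if (!is.null(comp)) x0 <- ifft2c(comp$values)
  }
  hook <- NULL
  if (isTRUE(cfg$hankel$enabled)) {
    hook <- function(x, it) {
      if (it %% cfg$hankel$every == 0) {
        hankel_denoise_image(x, cfg$hankel$window, cfg$hankel$rank)
      } else x
    }
  }
  res <- mfista(y, cfg, weights = weights, hook = hook, x0 = x0)
  x <- image_volume(res$x, y$voxel_size_mm)
  if (is.null(weights) || all(weights[y$mask$mask] == 1)) {
    x <- data_consistency_project(x, y)
  }
  attr(x, "objective") <- res$objective
  x
}

#' Stochastic reconstruction ensemble
#'
#' Generates K reconstructions under controlled perturbations of the inverse
#' problem: i.i.d. complex Gaussian noise of std `perturb_scale * noise_sigma`
#' added to the measurements and a log-uniform +/-`lambda_jitter` jitter of
#' the regularization weight. The ensemble feeds the topology-level
#' uncertainty measure.
#'
#' @param y a [kspace_measurement()].
#' @param cfg a [recon_config()].
#' @param K ensemble size (>= 1).
#' @param perturb_scale noise perturbation scale (0 disables noise injection).
#' @param seed integer seed.
#' @param lambda_jitter relative jitter of `lambda_reg` (0 disables).
#' @param weights optional weight matrix passed to [reconstruct_full()].
#' @return an object of class `stochastic_ensemble`: list with `members`
#'   (list of [image_volume()]), `perturb_scale`, `seed`.
#' @export
stochastic_realizations <- function(y, cfg = recon_config(), K = 5,
                                    perturb_scale = 1, seed = 1,
                                    lambda_jitter = 0.2, weights = NULL) {
  stop_if_not(K >= 1, "K must be >= 1")
  m <- y$mask$mask
  sig0 <- y$noise_sigma
  if (sig0 <= 0) sig0 <- 0.02 * stats::sd(Mod(y$values[m]))
  members <- with_seed(seed, {
    lapply(seq_len(K), function(k) {
      vals <- y$values
      if (perturb_scale > 0) {
        s <- perturb_scale * sig0 / sqrt(2)
        eta <- complex(real = stats::rnorm(sum(m), 0, s),
                       imaginary = stats::rnorm(sum(m), 0, s))
        vals[m] <- vals[m] + eta
      }
      cfg_k <- cfg
      if (lambda_jitter > 0) {
        cfg_k$lambda_reg <- cfg$lambda_reg *
          exp(stats::runif(1, -1, 1) * log(1 + lambda_jitter))
      }
      yk <- kspace_measurement(vals, y$mask, y$noise_sigma, y$voxel_size_mm)
      reconstruct_full(yk, cfg_k, weights = weights)
    })
  })
  structure(list(members = members, perturb_scale = perturb_scale,
                 seed = seed),
            class = "stochastic_ensemble")
}

#' @export
print.stochastic_ensemble <- function(x, ...) {
  cat(sprintf("<stochastic_ensemble> K=%d, perturb_scale=%.2f\n",
              length(x$members), x$perturb_scale))
  invisible(x)
}
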