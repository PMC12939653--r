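# 1-D instances are represented as n x 1 matrices throughout.

make_spike_instance <- function(seed, n = 128, n_spikes = 3, accel = 0.5,
                                sigma = 0.0) {
  set.seed(seed)
  x <- matrix(0, n, 1)
  x[sample.int(n, n_spikes), 1] <- runif(n_spikes, 0.8, 1.5)
  m <- matrix(FALSE, n, 1)
  keep <- sample.int(n, round((1 - accel) * n))
  m[keep, 1] <- TRUE
  ctr <- floor(n / 2) + 1
  m[(ctr - 4):(ctr + 4), 1] <- TRUE
  mask <- sampling_mask(m)
  ks <- fft2c(x) * m
  if (sigma > 0) {
    ks <- ks + m * complex(real = rnorm(n, 0, sigma / sqrt(2)),
                           imaginary = rnorm(n, 0, sigma / sqrt(2)))
  }
  list(x = x, y = kspace_measurement(ks, mask))
}

# independent plain ISTA oracle (identity sparsifier)
ista_oracle <- function(y, lambda, iters = 4000) {
  m <- y$mask$mask
  x <- matrix(0i, nrow(m), ncol(m))
  soft <- function(z, t) {
    mo <- Mod(z)
    z * pmax(mo - t, 0) / pmax(mo, .Machine$double.eps)
  }
  for (k in seq_len(iters)) {
    grad <- ifft2c(m * (fft2c(x) - y$values))
    x <- soft(x - grad, lambda)
  }
  x
}

test_that("cs_reconstruct solves the degenerate cases exactly", {
  ph <- small_phantom(seed = 2)
  ks <- simulate_kspace(ph$image, noise_model(0), seed = 1)
  r <- cs_reconstruct(ks, recon_config(lambda_reg = 0, max_iterations = 5))
  expect_lt(max(Mod(r$values - ph$image$values)), 1e-9)

  y0 <- kspace_measurement(matrix(0i, 64, 64), full_mask(c(64, 64)))
  r0 <- cs_reconstruct(y0, recon_config(lambda_reg = 1e-3,
                                        max_iterations = 10))
  expect_lt(max(Mod(r0$values)), 1e-12)
})

test_that("cs_reconstruct matches an independent ISTA oracle on 1-D instances", {
  for (seed in 1:5) {
    inst <- make_spike_instance(seed)
    cfg <- recon_config(lambda_reg = 1e-3, transform = "identity",
                        max_iterations = 600, tol = 1e-14)
    ours <- cs_reconstruct(inst$y, cfg)$values
    oracle <- ista_oracle(inst$y, 1e-3)
    expect_lt(sqrt(sum(Mod(ours - oracle)^2) / sum(Mod(oracle)^2)), 1e-4)
    expect_lt(sqrt(sum(Mod(ours - inst$x)^2) / sum(Mod(inst$x)^2)), 0.05)
  }
})

test_that("objective is monotone and the step-size bound is enforced", {
  ph <- small_phantom(seed = 4)
  mask <- poisson_disc_mask(c(96, 96), 0.6, center_fraction = 0.08, seed = 1)
  y <- simulate_kspace(ph$image, noise_model(0.05), seed = 2, mask = mask)
  r <- cs_reconstruct(y, recon_config(lambda_reg = 2e-3, max_iterations = 40))
  obj <- attr(r, "objective")
  expect_true(all(diff(obj) <= 1e-9 * max(abs(obj))))
  expect_error(recon_config(step_size = 1.5), "convergence bound")
})

test_that("data-consistency projection is exact and idempotent", {
  ph <- small_phantom(seed = 6)
  mask <- poisson_disc_mask(c(96, 96), 0.65, center_fraction = 0.08, seed = 3)
  y <- simulate_kspace(ph$image, noise_model(0.02), seed = 4, mask = mask)
  set.seed(1)
  x <- image_volume(matrix(rnorm(96 * 96), 96, 96), 0.5)
  p1 <- data_consistency_project(x, y)
  p2 <- data_consistency_project(p1, y)
  expect_lt(max(Mod(p2$values - p1$values)), 1e-11)
  ksp <- fft2c(p1$values)
  expect_lt(max(Mod(ksp[mask$mask] - y$values[mask$mask])), 1e-11)
  # an already-consistent image is unchanged
  xc <- image_volume(ifft2c(y$values), 0.5)
  expect_lt(max(Mod(data_consistency_project(xc, y)$values - xc$values)), 1e-11)
})

test_that("hankel projection is exact at full rank and models exponentials", {
  set.seed(3)
  n <- 48
  t <- seq_len(n)
  block <- exp(2i * pi * 0.11 * t) + 0.7 * exp(2i * pi * 0.23 * t)
  # full rank reproduces the block
  pr <- hankel_lowrank_project(block, window = 12, rank = 12)
  expect_lt(max(Mod(pr - block)), 1e-10)
  # a 2-exponential signal lifts to a rank-2 Hankel matrix
  H <- matrix(block[outer(1:12, 0:(n - 12), "+")], 12, n - 11)
  sv <- svd(H)$d
  expect_lt(sv[3] / sv[1], 1e-8)
  # rank-2 truncation denoises below the input noise level
  noisy <- block + complex(real = rnorm(n, 0, 0.1),
                           imaginary = rnorm(n, 0, 0.1))
  den <- hankel_lowrank_project(noisy, window = 12, rank = 2)
  expect_lt(sqrt(mean(Mod(den - block)^2)), sqrt(mean(Mod(noisy - block)^2)))
  expect_error(hankel_lowrank_project(block, window = 12, rank = 13), "rank")
})

test_that("partial Fourier completion is exact for real images", {
  ph <- small_phantom(seed = 8)
  mask <- partial_fourier_mask(c(96, 96), 0.55, 0.1)
  y <- simulate_kspace(ph$image, noise_model(0), seed = 1, mask = mask)
  comp <- partial_fourier_complete(y, phase_band_fraction = 0.08)
  rec <- ifft2c(comp$values)
  expect_lt(sqrt(sum(Mod(rec - ph$image$values)^2) /
                   sum(Mod(ph$image$values)^2)), 1e-6)
  # sampled locations untouched
  expect_identical(comp$values[mask$mask], y$values[mask$mask])
  # full mask: unchanged
  yf <- simulate_kspace(ph$image, noise_model(0), seed = 1)
  expect_identical(partial_fourier_complete(yf, 0.05)$values, yf$values)
})

test_that("partial Fourier completion tolerates a smooth phase", {
  ph <- small_phantom(seed = 8)
  i <- row(ph$image$values) / 96; j <- col(ph$image$values) / 96
  phase <- 0.5 * (i + 0.6 * j - 0.4 * i * j)   # low-order polynomial
  xc <- ph$image$values * exp(1i * phase)
  mask <- partial_fourier_mask(c(96, 96), 0.6, 0.12)
  y <- kspace_measurement(fft2c(xc) * mask$mask, mask)
  comp <- partial_fourier_complete(y, phase_band_fraction = 0.08)
  rec <- ifft2c(comp$values)
  expect_lt(sqrt(sum(Mod(rec - xc)^2) / sum(Mod(xc)^2)), 0.02)
  expect_error(
    partial_fourier_complete(
      kspace_measurement(y$values, sampling_mask(mask$mask, 0)), 0.08),
    "center band")
})

test_that("weighted reconstruction reduces to the unweighted special cases", {
  ph <- small_phantom(seed = 10)
  mask <- poisson_disc_mask(c(96, 96), 0.6, center_fraction = 0.08, seed = 2)
  y <- simulate_kspace(ph$image, noise_model(0.03), seed = 3, mask = mask)
  cfg <- recon_config(lambda_reg = 1e-3, max_iterations = 25)
  w1 <- matrix(1, 96, 96)
  expect_equal(weighted_reconstruct(y, w1, cfg)$values,
               cs_reconstruct(y, cfg)$values, tolerance = 1e-12)
  # zero weight on a subset is identical to removing it from the mask
  drop <- which(mask$mask & !(row(mask$mask) %in% mask$center_rows))[1:200]
  w0 <- w1; w0[drop] <- 0
  m2 <- mask$mask; m2[drop] <- FALSE
  y2 <- kspace_measurement(y$values * m2, sampling_mask(m2, mask$center_fraction))
  expect_equal(weighted_reconstruct(y, w0, cfg)$values,
               cs_reconstruct(y2, cfg)$values, tolerance = 1e-10)
  expect_error(weighted_reconstruct(y, w1 - 2, cfg), "non-negative")
})

test_that("down-weighting a motion-corrupted block improves fidelity", {
  ph <- small_phantom(seed = 12)
  mask <- poisson_disc_mask(c(96, 96), 0.6, center_fraction = 0.08, seed = 5)
  y <- simulate_kspace(ph$image, noise_model(0.02), seed = 6, mask = mask)
  ycor <- apply_motion_perturbation(y, shift_mm = 1.5,
                                    affected_fraction = 0.25, seed = 7)
  cfg <- recon_config(lambda_reg = 2e-3, max_iterations = 40)
  # corrupted lines are known in this controlled instance
  corrupted_rows <- which(rowSums(Mod(ycor$values - y$values)) > 0)
  w <- matrix(1, 96, 96); w[corrupted_rows, ] <- 0.7
  nm_w <- nmse(ph$image$values, weighted_reconstruct(ycor, w, cfg)$values)
  nm_u <- nmse(ph$image$values, cs_reconstruct(ycor, cfg)$values)
  expect_lt(nm_w, nm_u)
})

test_that("reconstruct_full composes the priors faithfully", {
  ph <- small_phantom(seed = 14)
  mask <- poisson_disc_mask(c(96, 96), 0.7, center_fraction = 0.08, seed = 2,
                            pf_fraction = 0.65)
  y <- simulate_kspace(ph$image, noise_model(0.05), seed = 3, mask = mask)
  cfg_off <- recon_config(lambda_reg = 2e-3, max_iterations = 30)
  full_off <- reconstruct_full(y, cfg_off)
  # with priors off, only the final DC projection differs from plain CS
  expect_equal(full_off$values,
               data_consistency_project(cs_reconstruct(y, cfg_off), y)$values,
               tolerance = 1e-10)
  ksr <- fft2c(full_off$values)
  expect_lt(max(Mod(ksr[mask$mask] - y$values[mask$mask])), 1e-10)
})

test_that("structured priors improve fidelity on accelerated phantoms", {
  wins <- 0
  for (sd in 1:10) {
    ph <- small_phantom(seed = sd)
    mask <- poisson_disc_mask(c(96, 96), 0.7, center_fraction = 0.08,
                              seed = sd + 50, pf_fraction = 0.65)
    y <- simulate_kspace(ph$image, noise_model(0.05), seed = sd + 70,
                         mask = mask)
    cfg0 <- recon_config(lambda_reg = 2e-3, max_iterations = 60)
    cfgF <- recon_config(lambda_reg = 2e-3, max_iterations = 60,
                         pf = list(enabled = TRUE, phase_band_fraction = 0.06))
    p0 <- psnr(ph$image, cs_reconstruct(y, cfg0))
    pF <- psnr(ph$image, reconstruct_full(y, cfgF))
    wins <- wins + (pF >= p0)
  }
  expect_gte(wins, 8)
})

test_that("stochastic ensembles are seeded and calibrated", {
  ph <- small_phantom(seed = 16)
  mask <- poisson_disc_mask(c(96, 96), 0.6, center_fraction = 0.08, seed = 2)
  y <- simulate_kspace(ph$image, noise_model(0.05), seed = 3, mask = mask)
  cfg <- recon_config(lambda_reg = 2e-3, max_iterations = 20)
  # degenerate ensemble equals the deterministic reconstruction
  e0 <- stochastic_realizations(y, cfg, K = 1, perturb_scale = 0, seed = 1,
                                lambda_jitter = 0)
  expect_equal(e0$members[[1]]$values, reconstruct_full(y, cfg)$values,
               tolerance = 1e-12)
  # seeded determinism
  e1 <- stochastic_realizations(y, cfg, K = 3, perturb_scale = 1, seed = 9)
  e2 <- stochastic_realizations(y, cfg, K = 3, perturb_scale = 1, seed = 9)
  expect_equal(e1$members[[2]]$values, e2$members[[2]]$values)
  # ensemble variance grows with the perturbation scale
  vs <- vapply(c(0.5, 1, 2), function(ps) {
    e <- stochastic_realizations(y, cfg, K = 4, perturb_scale = ps, seed = 5,
                                 lambda_jitter = 0)
    arr <- array(unlist(lapply(e$members, function(m) Mod(m$values))),
                 dim = c(96, 96, 4))
    mean(apply(arr, c(1, 2), var))
  }, 0)
  expect_true(all(diff(vs) > 0))
})
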