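test_that("action selection handles the degenerate contracts", {
  m <- poisson_disc_mask(c(32, 32), 0.5, min_radius = 1, center_fraction = 0.1,
                         seed = 1)
  y <- kspace_measurement(matrix(0i, 32, 32) + m$mask, m)
  one <- list(list(locations = which(!m$mask)[1:4], cost = 4))
  sel <- select_next_action(y, m, one, recon_config(max_iterations = 2))
  expect_identical(sel$locations, one[[1]]$locations)
  expect_error(select_next_action(y, m, list(), recon_config()),
               "no candidate")
})

test_that("identical candidates resolve to the first by the tie-break", {
  ph <- small_phantom(seed = 2, grid = 64)
  m <- poisson_disc_mask(c(64, 64), 0.6, center_fraction = 0.1, seed = 1)
  y <- simulate_kspace(ph$image, noise_model(0.02), seed = 2, mask = m)
  y <- kspace_measurement(y$values * m$mask, m, 0.02, 0.5)
  a <- list(locations = which(!m$mask)[1:16], cost = 16)
  sel <- select_next_action(y, m, list(a, a, a),
                            recon_config(lambda_reg = 1e-3,
                                         max_iterations = 8),
                            policy_config(candidate_count = 3,
                                          batch_size = 16,
                                          surrogate_iterations = 6,
                                          n_realizations = 2, seed = 3),
                            topology_config(vesselness_threshold = 0.12))
  expect_identical(attr(sel, "index"), 1L)
  sc <- attr(sel, "scores")
  expect_true(all(abs(sc - sc[1]) < 1e-12))
})

test_that("the policy identifies the informative k-space annulus", {
  # vertical tube: ~98% of the spectral energy sits in the central k-space
  # columns, so sampling those at high spatial frequency must beat sampling
  # a spectrally empty region
  seg <- list(cbind(16, seq(4, 28, 0.25)))
  g <- vascular_graph(
    nodes = data.frame(id = 1:2, x_mm = 0, y_mm = 0, kind = "terminal"),
    edges = data.frame(from = 1, to = 2, length_mm = 1, diameter_mm = 1.0,
                       confidence = 1, conductance = 1),
    polylines = seg)
  img <- angiotopo:::rasterize_graph(g, c(64, 64), 0.5, 4)
  m <- matrix(FALSE, 64, 64)
  m[center_band_rows(64, 0.12), ] <- TRUE
  mask <- sampling_mask(m, 0.12)
  yfull <- simulate_kspace(img, noise_model(0.03), seed = 1)
  yt <- kspace_measurement(yfull$values * m, mask, 0.03, 0.5)
  ctr <- 33
  open_rows <- setdiff(seq_len(64), mask$center_rows)
  hi <- open_rows[abs(open_rows - ctr) > 8]
  locA <- as.vector(outer(hi, (ctr - 1):(ctr + 1),
                          function(i, j) (j - 1) * 64 + i))
  locB <- as.vector(outer(hi, (ctr + 19):(ctr + 21),
                          function(i, j) (j - 1) * 64 + i))
  candA <- list(locations = locA, cost = length(locA))
  candB <- list(locations = locB, cost = length(locB))
  rcfg <- recon_config(lambda_reg = 1e-3, max_iterations = 40)
  tcfg <- topology_config(vesselness_threshold = 0.12)
  # brute-force oracle: reveal the true measurements for each candidate and
  # evaluate with the full (non-surrogate) pipeline
  U_of <- function(loc) {
    m2 <- m; m2[loc] <- TRUE
    y2 <- kspace_measurement(yfull$values * m2, sampling_mask(m2, 0.12),
                             0.03, 0.5)
    xr <- reconstruct_full(y2, rcfg)
    ens <- stochastic_realizations(y2, rcfg, K = 3, perturb_scale = 1,
                                   seed = 7)
    topology_uncertainty(ens, xr, tcfg)
  }
  expect_lt(U_of(locA), U_of(locB))
  # the surrogate-based policy agrees with the oracle
  sel <- select_next_action(yt, mask, list(candA, candB), rcfg,
                            policy_config(candidate_count = 2,
                                          batch_size = length(locA),
                                          surrogate_iterations = 15,
                                          n_realizations = 3, seed = 2),
                            tcfg)
  expect_identical(attr(sel, "index"), 1L)
})

test_that("closed-loop budget and early stopping behave as specified", {
  ph <- small_phantom(seed = 23)
  init <- poisson_disc_mask(c(96, 96), 0.78, center_fraction = 0.08,
                            seed = 2, pf_fraction = 0.65)
  pol <- policy_config(candidate_count = 2, batch_size = 80,
                       surrogate_iterations = 6, n_realizations = 2, seed = 5)
  res1 <- run_closed_loop(ph, init, budget = 1,
                          recon_cfg = recon_config(lambda_reg = 2e-3,
                                                   max_iterations = 20),
                          policy_cfg = pol,
                          topo_cfg = topology_config(vesselness_threshold = 0.12),
                          noise = noise_model(0.05), seed = 3,
                          selector = "random")
  expect_identical(nrow(res1$log), 1L)
  expect_identical(sum(res1$mask$mask) - sum(init$mask), 80L)
  # a huge saturation tolerance stops right after the second iteration
  res2 <- run_closed_loop(ph, init, budget = 5,
                          recon_cfg = recon_config(lambda_reg = 2e-3,
                                                   max_iterations = 20),
                          policy_cfg = pol,
                          topo_cfg = topology_config(vesselness_threshold = 0.12),
                          noise = noise_model(0.05), seed = 3, tol_rel = 1e9,
                          selector = "random")
  expect_identical(nrow(res2$log), 2L)
})
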