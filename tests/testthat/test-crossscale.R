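test_that("edge conductance follows Poiseuille-type scaling", {
  expect_equal(edge_conductance(1, 1), 1 / (1 + 1e-6), tolerance = 1e-12)
  expect_equal(edge_conductance(2, 1) / edge_conductance(1, 1), 16,
               tolerance = 1e-9)
  g <- edge_conductance(1, c(1, 2, 5))
  expect_true(all(diff(g) < 0))
  expect_error(edge_conductance(-1, 1), "non-negative")
})

test_that("graph flow solves obey Ohm and Kirchhoff laws", {
  single <- toy_edge_graph()
  single$edges$conductance <- 2.5
  fs <- solve_graph_flow(single, inlets = 1, outlets = 2)
  expect_equal(fs$flows[1], 2.5, tolerance = 1e-12)

  # two parallel routes: flow splits in proportion to conductance
  par <- vascular_graph(
    nodes = data.frame(id = 1:2, x_mm = c(0, 10), y_mm = 0, kind = "terminal"),
    edges = data.frame(from = c(1, 1), to = c(2, 2), length_mm = 10,
                       diameter_mm = 1, confidence = 1,
                       conductance = c(3, 1)))
  fp <- solve_graph_flow(par, 1, 2)
  expect_equal(fp$flows[1] / fp$flows[2], 3, tolerance = 1e-9)

  # Kirchhoff balance at internal nodes of a random-ish phantom graph
  ph <- small_phantom(seed = 5)
  bnd <- select_boundary_nodes(ph$graph)
  sol <- solve_graph_flow(ph$graph, bnd$inlets, bnd$outlets)
  net <- stats::setNames(numeric(nrow(ph$graph$nodes)),
                         ph$graph$nodes$id)
  for (k in seq_len(nrow(ph$graph$edges))) {
    f <- sol$flows[k]
    net[as.character(ph$graph$edges$from[k])] <-
      net[as.character(ph$graph$edges$from[k])] - f
    net[as.character(ph$graph$edges$to[k])] <-
      net[as.character(ph$graph$edges$to[k])] + f
  }
  internal <- setdiff(ph$graph$nodes$id, c(bnd$inlets, bnd$outlets))
  inflow <- sum(abs(net[as.character(bnd$inlets)]))
  expect_lt(max(abs(net[as.character(internal)])), 1e-8 * inflow)

  # disconnected boundary pairs fail with a component message
  two <- vascular_graph(
    nodes = data.frame(id = 1:4, x_mm = c(0, 1, 5, 6), y_mm = 0,
                       kind = "terminal"),
    edges = data.frame(from = c(1, 3), to = c(2, 4), length_mm = 1,
                       diameter_mm = 1, confidence = 1, conductance = 1))
  expect_error(solve_graph_flow(two, 1, 4), "disconnected")
})

test_that("velocity rasterization is tangent-aligned and linear", {
  g <- toy_edge_graph(len = 20)
  g$edges$conductance <- 1
  fs <- solve_graph_flow(g, 1, 2)
  u <- graph_to_velocity_field(g, fs, c(64, 64), 0.5, smoothing_sigma_mm = 1)
  expect_lt(max(abs(u$uy)), 1e-6 * max(abs(u$ux)))
  # zero flows give a zero field
  fs0 <- fs; fs0$flows <- 0
  u0 <- graph_to_velocity_field(g, fs0, c(64, 64), 0.5)
  expect_true(all(u0$ux == 0) && all(u0$uy == 0))
  # scaling flows scales the field
  fs2 <- fs; fs2$flows <- 2 * fs$flows
  u2 <- graph_to_velocity_field(g, fs2, c(64, 64), 0.5, smoothing_sigma_mm = 1)
  expect_equal(u2$ux, 2 * u$ux, tolerance = 1e-12)
})

test_that("transport honours closed-form limits", {
  c0 <- matrix(0, 48, 48); c0[20:28, 20:28] <- 1
  # no dynamics: constant field
  pzero <- meso_params(diffusivity_mm2_s = 0, decay_rate_s = 0, dt_s = 0.1,
                       horizon_s = 5)
  s0 <- simulate_transport(NULL, pzero, c0, 0.5)
  expect_identical(s0$frames[[length(s0$frames)]], c0)

  # pure decay: mass ratio within 1% of exp(-lambda*T) at the standard values
  pdec <- meso_params(diffusivity_mm2_s = 0, decay_rate_s = 0.012, dt_s = 0.1,
                      horizon_s = 60)
  sd_ <- simulate_transport(NULL, pdec, c0, 0.5)
  ratio <- sd_$mass[length(sd_$mass)] / sd_$mass[1]
  expect_lt(abs(ratio - exp(-0.72)) / exp(-0.72), 0.01)

  # pure diffusion conserves mass to machine precision; peak non-increasing
  pdif <- meso_params(diffusivity_mm2_s = 0.80, decay_rate_s = 0,
                      dt_s = 0.05, horizon_s = 10)
  sdif <- simulate_transport(NULL, pdif, c0, 0.5)
  expect_lt(abs(sdif$mass[length(sdif$mass)] - sdif$mass[1]) / sdif$mass[1],
            1e-10)
  peaks <- vapply(sdif$frames, max, 0)
  expect_true(all(diff(peaks) <= 1e-12))

  # CFL violation names the admissible step
  expect_error(simulate_transport(NULL,
                                  meso_params(diffusivity_mm2_s = 0.80,
                                              dt_s = 0.1), c0, 0.5),
               "maximum admissible dt")
})

test_that("perfusion endpoints match hand-computed values", {
  tpts <- seq(0, 60, by = 2.5)
  tri <- pmax(0, 1 - abs(tpts - 5) / 5)       # triangular pulse peaking at 5 s
  frames <- lapply(seq_along(tpts), function(k) matrix(tri[k], 2, 2))
  series <- structure(list(times = tpts, frames = frames,
                           mass = vapply(frames, sum, 0) * 0.25,
                           voxel_size_mm = 0.5), class = "transport_series")
  ep <- perfusion_endpoints(series)
  expect_equal(ep$ttp[1, 1], 5)
  # constant curve: trapezoid is exact
  cframes <- lapply(tpts, function(t) matrix(1, 2, 2))
  cs <- structure(list(times = tpts, frames = cframes,
                       mass = rep(4 * 0.25, length(tpts)),
                       voxel_size_mm = 0.5), class = "transport_series")
  expect_equal(perfusion_endpoints(cs)$auc[1, 1], 60)
  # piecewise linear curve: hand trapezoid
  y <- c(0, 1, 3, 2, 0)
  tt <- c(0, 1, 2, 4, 6)
  pw <- structure(list(times = tt,
                       frames = lapply(y, function(v) matrix(v, 1, 1)),
                       mass = y * 0.25, voxel_size_mm = 0.5),
                  class = "transport_series")
  hand <- sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
  expect_equal(perfusion_endpoints(pw)$auc[1, 1], hand)
})

test_that("viability dynamics approach the analytic fixed point", {
  mp <- micro_params()
  phi <- matrix(1, 3, 3)
  horizon <- 5 / mp$gamma
  res <- simulate_viability(phi, mp, horizon_s = horizon, dt_s = 0.5,
                            demand = 1)
  efix <- (mp$alpha * 1 - mp$beta * 1) / mp$gamma
  expect_lt(max(abs(res$energy - efix)) / efix, 0.01)
  pfix <- 1 / (1 + exp(-mp$logistic_slope * (efix - mp$theta)))
  expect_equal(res$p_survival[1, 1], pfix, tolerance = 0.01)
  # logistic midpoint and range
  e_theta <- simulate_viability(matrix(0, 1, 1), mp, horizon_s = 0.5,
                                dt_s = 0.5, demand = 0)
  pmid <- 1 / (1 + exp(-mp$logistic_slope * (mp$theta - mp$theta)))
  expect_equal(pmid, 0.5)
  expect_true(all(res$p_survival > 0 & res$p_survival < 1))
  expect_error(simulate_viability(phi, mp, dt_s = 2 / mp$gamma + 1),
               "unstable")
})

test_that("risk region follows the perfusion-deficit definition", {
  set.seed(2)
  healthy <- matrix(runif(400, 0.8, 1.2), 20, 20)
  expect_false(any(define_risk_region(healthy, healthy)))
  lesioned <- healthy
  lesioned[1:10, ] <- lesioned[1:10, ] * 0.3
  m6 <- define_risk_region(healthy, lesioned, 0.6)
  m9 <- define_risk_region(healthy, lesioned, 0.9)
  expect_true(all(which(m6) %in% which(m9)))   # monotone nesting
  expect_true(any(m6))
})

test_that("an occlusion produces a downstream at-risk territory", {
  # trunk with a side branch; the lesion removes the side branch
  trunk <- cbind(seq(2, 30, 0.5), 16)
  branch <- cbind(16, seq(16, 28, 0.5))
  healthy_g <- vascular_graph(
    nodes = data.frame(id = 1:4, x_mm = c(2, 16, 30, 16),
                       y_mm = c(16, 16, 16, 28),
                       kind = c("terminal", "bifurcation", "terminal",
                                "terminal")),
    edges = data.frame(from = c(1, 2, 2), to = c(2, 3, 4),
                       length_mm = c(14, 14, 12), diameter_mm = c(2, 2, 1.5),
                       confidence = 1,
                       conductance = edge_conductance(c(2, 2, 1.5),
                                                     c(14, 14, 12))),
    polylines = list(trunk[trunk[, 1] <= 16, ], trunk[trunk[, 1] >= 16, ],
                     branch))
  lesioned_g <- vascular_graph(healthy_g$nodes[1:3, ],
                               healthy_g$edges[1:2, ],
                               healthy_g$polylines[1:2])
  hs <- simulate_cross_scale(healthy_g, c(64, 64), 0.5)
  ls <- simulate_cross_scale(lesioned_g, c(64, 64), 0.5)
  # tissue = perfused territory of the healthy network
  tissue <- hs$endpoints$auc > 0.05 * max(hs$endpoints$auc)
  risk <- define_risk_region(hs$endpoints$auc, ls$endpoints$auc, 0.6,
                             tissue_mask = tissue)
  expect_true(any(risk))
  # the lost branch territory is flagged much more densely than the
  # territory still fed by the surviving trunk
  branch_zone <- risk[28:36, 44:56]
  trunk_zone <- risk[28:36, 20:36]
  expect_gt(mean(branch_zone), 0.5)
  expect_gt(mean(branch_zone), mean(trunk_zone) + 0.25)
})

test_that("uncertainty propagation reports unbiased variances over the ensemble", {
  ph <- small_phantom(seed = 7, grid = 64)
  mask <- poisson_disc_mask(c(64, 64), 0.6, center_fraction = 0.1, seed = 1)
  y <- simulate_kspace(ph$image, noise_model(0.05), seed = 2, mask = mask)
  cfg <- recon_config(lambda_reg = 2e-3, max_iterations = 25)
  ens <- stochastic_realizations(y, cfg, K = 3, perturb_scale = 1, seed = 4)
  # identical members: all variances vanish
  ens0 <- ens
  ens0$members <- list(ens$members[[1]], ens$members[[1]])
  rep0 <- propagate_uncertainty(ens0,
                                topology_config(vesselness_threshold = 0.12),
                                grid_shape = c(64, 64), voxel_size_mm = 0.5)
  expect_true(all(rep0$U_meso == 0))
  expect_true(all(rep0$U_micro == 0))
  expect_equal(rep0$U_micro_mean, 0)
  # real ensemble: mean-over-risk recomputation matches
  rep1 <- propagate_uncertainty(ens,
                                topology_config(vesselness_threshold = 0.12),
                                grid_shape = c(64, 64), voxel_size_mm = 0.5)
  expect_equal(rep1$U_micro_mean, mean(rep1$U_micro[rep1$risk_mask]))
  expect_true(all(rep1$U_meso >= 0))
  expect_error(propagate_uncertainty(
    structure(list(members = ens$members[1], perturb_scale = 1, seed = 1),
              class = "stochastic_ensemble"),
    grid_shape = c(64, 64), voxel_size_mm = 0.5), "K >= 2")
})
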