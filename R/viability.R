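#' Micro-scale viability parameters
#'
#' Energy-based tissue viability proxy `dE/dt = alpha*Phi - beta*Gamma -
#' gamma*E` with survival probability `P = logistic(slope * (E - theta))`.
#' Defaults are the fixed configuration used across all experiments.
#'
#' @param alpha supply gain (1.10).
#' @param beta stress gain (0.85).
#' @param gamma relaxation rate (0.06).
#' @param theta logistic midpoint (0.20).
#' @param logistic_slope logistic steepness (8.0).
#' @param gamma_max cap of the bounded demand term (2).
#' @param kappa demand sensitivity to relative perfusion deficit (1).
#' @return an object of class `micro_params`.
#' @export
micro_params <- function(alpha = 1.10, beta = 0.85, gamma = 0.06,
                         theta = 0.20, logistic_slope = 8.0,
                         gamma_max = 2, kappa = 1) {
  stop_if_not(gamma > 0, "gamma must be > 0")
  stop_if_not(logistic_slope > 0, "logistic slope must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, theta = theta,
                 logistic_slope = logistic_slope, gamma_max = gamma_max,
                 kappa = kappa),
            class = "micro_params")
}

# bounded demand: Gamma = min(gamma_max, 1 + kappa * relative perfusion
# deficit), where the deficit is measured against a reference supply level
demand_from_deficit <- function(phi, params, phi_ref = NULL) {
  if (is.null(phi_ref)) {
    pos <- phi[phi > 0]
    phi_ref <- if (length(pos)) stats::median(pos) else 1
  }
  deficit <- pmax(0, 1 - phi / max(phi_ref, .Machine$double.eps))
  pmin(params$gamma_max, 1 + params$kappa * deficit)
}

#' Simulate tissue viability dynamics
#'
#' Forward-Euler integration of the voxelwise energy state from `E(0) = 0`
#' and the logistic survival map at the final time.
#'
#' @param phi perfusion-derived supply map (matrix).
#' @param params a [micro_params()].
#' @param horizon_s integration horizon in seconds.
#' @param dt_s time step; must satisfy `dt < 2 / gamma`.
#' @param demand either NULL (bounded perfusion-deficit demand), a constant
#'   matrix/scalar, or a function `demand(t)` returning a matrix.
#' @param n_keep number of intermediate energy frames to keep.
#' @return object of class `viability_result`: list with `energy` (final E
#'   map), `p_survival`, `times`, `energy_frames`.
#' @export
simulate_viability <- function(phi, params = micro_params(), horizon_s = 120,
                               dt_s = 0.5, demand = NULL, n_keep = 5) {
  stop_if_not(dt_s > 0 && dt_s < 2 / params$gamma,
              "unstable dt: require dt < 2 / gamma = %.3g s", 2 / params$gamma)
  phi <- as.matrix(phi)
  if (is.null(demand)) {
    gam_mat <- demand_from_deficit(phi, params)
    demand_fun <- function(t) gam_mat
  } else if (is.function(demand)) {
    demand_fun <- demand
  } else {
    dm <- if (length(demand) == 1) matrix(demand, nrow(phi), ncol(phi)) else as.matrix(demand)
    demand_fun <- function(t) dm
  }
  nt <- ceiling(horizon_s / dt_s)
  keep_at <- unique(pmax(1, round(seq(1, nt, length.out = n_keep))))
  E <- matrix(0, nrow(phi), ncol(phi))
  frames <- list(); times <- numeric()
  for (k in seq_len(nt)) {
    t <- k * dt_s
    gam <- pmin(demand_fun(t), params$gamma_max)
    E <- E + dt_s * (params$alpha * phi - params$beta * gam - params$gamma * E)
    if (k %in% keep_at) {
      frames[[length(frames) + 1]] <- E
      times[length(times) + 1] <- t
    }
  }
  P <- 1 / (1 + exp(-params$logistic_slope * (E - params$theta)))
  structure(list(energy = E, p_survival = P, times = times,
                 energy_frames = frames),
            class = "viability_result")
}

#' Define the at-risk territory
#'
#' Voxels whose area-under-curve perfusion proxy under the lesioned network
#' falls below `fraction` times the median of the healthy reference AUC
#' (within the tissue domain).
#'
#' @param healthy_auc,lesioned_auc AUC maps from [perfusion_endpoints()].
#' @param fraction deficit threshold in (0, 1).
#' @param tissue_mask optional logical matrix restricting the domain.
#' @return logical matrix.
#' @export
define_risk_region <- function(healthy_auc, lesioned_auc, fraction = 0.6,
                               tissue_mask = NULL) {
  stop_if_not(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  if (is.null(tissue_mask)) tissue_mask <- healthy_auc > 0
  med <- stats::median(healthy_auc[tissue_mask])
  lesioned_auc < fraction * med & tissue_mask
}

#' Cross-scale simulation of one vascular graph
#'
#' Macro-to-micro chain: boundary selection, Laplacian flow solve, velocity
#' rasterization, bolus transport, perfusion endpoints, and viability. The
#' transport step uses the configured time step unless the explicit
#' stability bound requires a smaller one.
#'
#' @param g a [vascular_graph()].
#' @param grid_shape simulation grid.
#' @param voxel_size_mm grid spacing in mm.
#' @param meso a [meso_params()].
#' @param micro a [micro_params()].
#' @param inlet_border image border feeding the network.
#' @param bolus_duration_s duration of the inlet bolus (s).
#' @param bolus_amplitude source rate during the bolus.
#' @param velocity_scale multiplies the rasterized velocity field (arbitrary
#'   flow units to mm/s).
#' @param phi_ref optional reference supply level for demand normalization.
#' @return list with `flow`, `velocity`, `series`, `endpoints`, `viability`,
#'   `graph`.
#' @export
simulate_cross_scale <- function(g, grid_shape, voxel_size_mm,
                                 meso = meso_params(), micro = micro_params(),
                                 inlet_border = "left",
                                 bolus_duration_s = 8, bolus_amplitude = 1,
                                 velocity_scale = NULL, phi_ref = NULL) {
  stop_if_not(nrow(g$edges) > 0, "graph has no edges")
  bnd <- select_boundary_nodes(g, inlet_border)
  flow <- solve_graph_flow(g, bnd$inlets, bnd$outlets)
  u <- graph_to_velocity_field(g, flow, grid_shape, voxel_size_mm,
                               smoothing_sigma_mm = 2 * voxel_size_mm)
  # scale the arbitrary-unit field to a stable advection speed
  umax <- max(abs(u$ux), abs(u$uy))
  if (is.null(velocity_scale)) {
    velocity_scale <- if (umax > 0) 1.5 / umax else 0
  }
  u$ux <- u$ux * velocity_scale; u$uy <- u$uy * velocity_scale
  # bolus source: Gaussian footprint around the inlet node(s)
  src <- matrix(0, grid_shape[1], grid_shape[2])
  for (id in bnd$inlets) {
    nd <- g$nodes[g$nodes$id == id, ]
    ii <- pmin(pmax(round(nd$x_mm / voxel_size_mm + 0.5), 1), grid_shape[1])
    jj <- pmin(pmax(round(nd$y_mm / voxel_size_mm + 0.5), 1), grid_shape[2])
    src[ii, jj] <- 1
  }
  src <- EBImage::gblur(src, sigma = max(2 / 0.5 * voxel_size_mm, 1))
  if (max(src) > 0) src <- src / max(src) * bolus_amplitude
  source_fun <- function(t) if (t <= bolus_duration_s) src else 0 * src
  ms <- meso
  dt_max <- transport_max_dt(ms, voxel_size_mm, u)
  if (ms$dt_s > dt_max) ms$dt_s <- 0.9 * dt_max
  series <- simulate_transport(u, ms, matrix(0, grid_shape[1], grid_shape[2]),
                               voxel_size_mm, source = source_fun)
  ep <- perfusion_endpoints(series)
  # supply proxy: AUC normalized by a reference level
  ref <- if (is.null(phi_ref)) {
    pos <- ep$auc[ep$auc > 1e-9]
    if (length(pos)) stats::median(pos) else 1
  } else phi_ref
  phi <- ep$auc / max(ref, .Machine$double.eps)
  viab <- simulate_viability(phi, micro, demand = NULL)
  list(flow = flow, velocity = u, series = series, endpoints = ep,
       viability = viab, graph = g, phi = phi, phi_ref = ref)
}

#' Propagate reconstruction uncertainty across scales
#'
#' Runs the graph-to-flow-to-transport-to-viability chain for every member
#' of a stochastic reconstruction ensemble and summarizes uncertainty as
#' unbiased sample variances: `U_meso` per perfusion endpoint (voxelwise
#' variance, spatially averaged), `U_micro` (voxelwise variance map of the
#' survival proxy) and its mean over the at-risk territory.
#'
#' @param ensemble a [stochastic_realizations()] ensemble (K >= 2).
#' @param topo_cfg a [topology_config()] used for graph extraction.
#' @param grid_shape,voxel_size_mm simulation grid.
#' @param meso,micro parameter sets.
#' @param risk_mask logical matrix defining the at-risk territory; when NULL
#'   it is derived from the ensemble-mean AUC via [define_risk_region()]
#'   against its own median (deficit fraction 0.6).
#' @param inlet_border image border feeding the network.
#' @return object of class `uncertainty_report`: list with `U_meso` (named
#'   per endpoint), `U_micro` (matrix), `U_micro_mean`, `risk_mask`, `K`.
#' @export
propagate_uncertainty <- function(ensemble, topo_cfg = topology_config(),
                                  grid_shape, voxel_size_mm,
                                  meso = meso_params(), micro = micro_params(),
                                  risk_mask = NULL, inlet_border = "left") {
  stop_if_not(inherits(ensemble, "stochastic_ensemble"), "need an ensemble")
  K <- length(ensemble$members)
  stop_if_not(K >= 2, "uncertainty propagation requires K >= 2 realizations")
  runs <- lapply(ensemble$members, function(m) {
    g <- extract_graph(m, topo_cfg$vesselness_threshold, topo_cfg$scales_mm,
                       min_length_mm = topo_cfg$min_length_mm)
    if (!nrow(g$edges)) return(NULL)
    tryCatch(simulate_cross_scale(g, grid_shape, voxel_size_mm, meso, micro,
                                  inlet_border),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, TRUE)
  stop_if_not(sum(ok) >= 2, "fewer than 2 realizations produced a usable vascular network")
  runs <- runs[ok]
  stack <- function(field) {
    array(unlist(lapply(runs, `[[`, field)), dim = c(grid_shape, length(runs)))
  }
  eps <- lapply(runs, `[[`, "endpoints")
  var_k <- function(get) {
    arr <- array(unlist(lapply(eps, get)), dim = c(grid_shape, length(runs)))
    apply(arr, c(1, 2), stats::var)    # unbiased (n-1)
  }
  v_peak <- var_k(function(e) e$peak)
  v_ttp <- var_k(function(e) e$ttp)
  v_auc <- var_k(function(e) e$auc)
  U_meso <- c(peak = mean(v_peak), ttp = mean(v_ttp), auc = mean(v_auc))
  parr <- array(unlist(lapply(runs, function(r) r$viability$p_survival)),
                dim = c(grid_shape, length(runs)))
  U_micro <- apply(parr, c(1, 2), stats::var)
  if (is.null(risk_mask)) {
    mean_auc <- apply(array(unlist(lapply(eps, function(e) e$auc)),
                            dim = c(grid_shape, length(runs))), c(1, 2), mean)
    risk_mask <- define_risk_region(mean_auc, mean_auc, fraction = 0.6,
                                    tissue_mask = mean_auc >= 0)
    if (!any(risk_mask)) risk_mask <- mean_auc < stats::median(mean_auc)
  }
  stop_if_not(any(risk_mask), "at-risk territory is empty")
  structure(list(U_meso = U_meso, U_micro = U_micro,
                 U_micro_mean = mean(U_micro[risk_mask]),
                 risk_mask = risk_mask, K = length(runs)),
            class = "uncertainty_report")
}
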