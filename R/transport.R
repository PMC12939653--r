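#' Meso-scale transport parameters
#'
#' Fixed parameters of the advection-diffusion-reaction tracer model
#' `dc/dt + div(u c) = D lap(c) - decay * c + S`. Defaults are the standard
#' configuration used across all experiments: diffusivity 0.80 mm^2/s,
#' clearance 0.012 /s, explicit time step 0.10 s, horizon 60 s.
#'
#' @param diffusivity_mm2_s effective dispersion D.
#' @param decay_rate_s clearance/decay rate.
#' @param dt_s explicit integration time step.
#' @param horizon_s simulation horizon T.
#' @return an object of class `meso_params`.
#' @export
meso_params <- function(diffusivity_mm2_s = 0.80, decay_rate_s = 0.012,
                        dt_s = 0.10, horizon_s = 60) {
  stop_if_not(diffusivity_mm2_s >= 0, "diffusivity must be >= 0")
  stop_if_not(decay_rate_s >= 0, "decay rate must be >= 0")
  stop_if_not(dt_s > 0 && horizon_s > 0, "dt and horizon must be > 0")
  structure(list(diffusivity_mm2_s = diffusivity_mm2_s,
                 decay_rate_s = decay_rate_s, dt_s = dt_s,
                 horizon_s = horizon_s),
            class = "meso_params")
}

# maximum admissible explicit time step on a grid with spacing h (2-D):
# joint bound for the combined diffusion + donor-cell advection + decay
# update, dt * (4D/h^2 + (|ux|+|uy|)/h + decay) <= 1
transport_max_dt <- function(params, h_mm, u = NULL) {
  rate <- 4 * params$diffusivity_mm2_s / h_mm^2 + params$decay_rate_s
  if (!is.null(u)) {
    rate <- rate + (max(abs(u$ux)) + max(abs(u$uy))) / h_mm
  }
  if (rate <= 0) return(Inf)
  1 / rate
}

#' Simulate tracer transport
#'
#' Explicit forward-Euler integration of the advection-diffusion-reaction
#' equation with donor-cell (upwind) advection fluxes, a 5-point diffusion
#' stencil in flux form, and zero-flux boundaries (mass is conserved exactly
#' when decay and source vanish). Fails if the time step violates the
#' explicit stability bound.
#'
#' @param u velocity field `list(ux, uy)` in mm/s (cell-centered), or NULL
#'   for pure diffusion/reaction.
#' @param params a [meso_params()].
#' @param c0 initial concentration matrix.
#' @param voxel_size_mm grid spacing in mm.
#' @param source either NULL or a function `source(t)` returning a source
#'   rate matrix (concentration per second).
#' @param output_times times (s) at which to record the field (defaults to
#'   ~20 frames up to the horizon).
#' @return an object of class `transport_series`: list with `times` and
#'   `frames` (list of matrices), plus `mass` (total concentration per frame,
#'   scaled by voxel area).
#' @export
simulate_transport <- function(u, params, c0, voxel_size_mm,
                               source = NULL, output_times = NULL) {
  h <- voxel_size_mm
  dt <- params$dt_s
  dt_max <- transport_max_dt(params, h, u)
  if (dt > dt_max + 1e-12) {
    stop(sprintf("time step %.4g s violates the explicit stability bound; maximum admissible dt is %.4g s",
                 dt, dt_max), call. = FALSE)
  }
  n1 <- nrow(c0); n2 <- ncol(c0)
  nt <- ceiling(params$horizon_s / dt)
  if (is.null(output_times)) {
    output_times <- seq(0, params$horizon_s, length.out = min(21, nt + 1))
  }
  cfield <- c0
  D <- params$diffusivity_mm2_s
  lam <- params$decay_rate_s
  ux <- if (is.null(u)) NULL else u$ux
  uy <- if (is.null(u)) NULL else u$uy
  frames <- list(); times <- numeric(); mass <- numeric()
  rec_idx <- 1
  record <- function(t) {
    frames[[length(frames) + 1]] <<- cfield
    times[length(times) + 1] <<- t
    mass[length(mass) + 1] <<- sum(cfield) * h^2
  }
  next_out <- output_times[1]
  if (abs(next_out) < 1e-12) { record(0); rec_idx <- 2 }
  for (k in seq_len(nt)) {
    t <- k * dt
    dc <- matrix(0, n1, n2)
    if (D > 0) {
      # flux form: D * (c[i+1] - c[i]) / h across interior faces
      fx <- D * (cfield[-1, , drop = FALSE] - cfield[-n1, , drop = FALSE]) / h
      fy <- D * (cfield[, -1, drop = FALSE] - cfield[, -n2, drop = FALSE]) / h
      dc[-n1, ] <- dc[-n1, ] + fx / h
      dc[-1, ] <- dc[-1, ] - fx / h
      dc[, -n2] <- dc[, -n2] + fy / h
      dc[, -1] <- dc[, -1] - fy / h
    }
    if (!is.null(ux)) {
      # donor-cell advective fluxes on interior faces, face velocity averaged
      ufx <- (ux[-1, , drop = FALSE] + ux[-n1, , drop = FALSE]) / 2
      adv_x <- ifelse(ufx > 0, ufx * cfield[-n1, , drop = FALSE],
                      ufx * cfield[-1, , drop = FALSE])
      ufy <- (uy[, -1, drop = FALSE] + uy[, -n2, drop = FALSE]) / 2
      adv_y <- ifelse(ufy > 0, ufy * cfield[, -n2, drop = FALSE],
                      ufy * cfield[, -1, drop = FALSE])
      dc[-n1, ] <- dc[-n1, ] - adv_x / h
      dc[-1, ] <- dc[-1, ] + adv_x / h
      dc[, -n2] <- dc[, -n2] - adv_y / h
      dc[, -1] <- dc[, -1] + adv_y / h
    }
    if (lam > 0) dc <- dc - lam * cfield
    if (!is.null(source)) dc <- dc + source(t)
    cfield <- cfield + dt * dc
    while (rec_idx <= length(output_times) &&
           t >= output_times[rec_idx] - 1e-9) {
      record(output_times[rec_idx])
      rec_idx <- rec_idx + 1
    }
  }
  structure(list(times = times, frames = frames, mass = mass,
                 voxel_size_mm = h),
            class = "transport_series")
}

#' Perfusion endpoints from a concentration time series
#'
#' Voxelwise peak concentration (blood-volume proxy), time-to-peak (first
#' occurrence on ties), and trapezoidal area under the curve (flow proxy).
#'
#' @param series a [simulate_transport()] result (>= 2 time points).
#' @return list of matrices `peak`, `ttp`, `auc`.
#' @export
perfusion_endpoints <- function(series) {
  stop_if_not(length(series$times) >= 2, "need at least two time points")
  nt <- length(series$times)
  arr <- array(unlist(series$frames),
               dim = c(dim(series$frames[[1]]), nt))
  peak <- apply(arr, c(1, 2), max)
  ttp_idx <- apply(arr, c(1, 2), which.max)
  ttp <- matrix(series$times[ttp_idx], nrow(peak), ncol(peak))
  dt <- diff(series$times)
  auc <- matrix(0, nrow(peak), ncol(peak))
  for (k in seq_len(nt - 1)) {
    auc <- auc + (arr[, , k] + arr[, , k + 1]) / 2 * dt[k]
  }
  list(peak = peak, ttp = ttp, auc = auc)
}
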