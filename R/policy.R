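#' Adaptive acquisition policy configuration
#'
#' @param candidate_count number of candidate actions proposed per iteration.
#' @param batch_size k-space locations added by each action.
#' @param surrogate_iterations iteration budget of the fast surrogate
#'   reconstructions used to score candidates.
#' @param n_realizations number of stochastic realizations (K) used for the
#'   topology-uncertainty estimate.
#' @param perturb_scale noise perturbation scale of the scoring ensembles.
#' @param seed integer seed.
#' @return an object of class `policy_config`.
#' @export
policy_config <- function(candidate_count = 8, batch_size = 64,
                          surrogate_iterations = 12, n_realizations = 3,
                          perturb_scale = 1, seed = 1) {
  stop_if_not(candidate_count >= 1 && surrogate_iterations >= 1 &&
                n_realizations >= 1,
              "policy settings must be positive")
  stop_if_not(is.null(batch_size) || batch_size >= 1,
              "batch_size must be positive (or NULL to derive it later)")
  structure(list(candidate_count = candidate_count, batch_size = batch_size,
                 surrogate_iterations = surrogate_iterations,
                 n_realizations = n_realizations,
                 perturb_scale = perturb_scale, seed = seed),
            class = "policy_config")
}

#' Propose candidate acquisition actions
#'
#' Each action adds `batch_size` currently unsampled k-space locations drawn
#' by variable-density sampling biased toward (a) radial annuli that are
#' under-covered by the current mask and (b) the Fourier support of an
#' image-space instability map (regions whose extracted topology varies
#' across stochastic reconstructions, dilated into a smooth weight map).
#'
#' @param current a [sampling_mask()].
#' @param cfg a [policy_config()].
#' @param uncertainty_map optional matrix (image space) of instability
#'   weights.
#' @param seed seed (defaults to `cfg$seed`).
#' @return list of actions, each a list with `locations` (linear indices
#'   into the k-space grid) and `cost`; empty list if the mask is full.
#' @export
propose_candidates <- function(current, cfg, uncertainty_map = NULL,
                               seed = cfg$seed) {
  m <- current$mask
  n1 <- nrow(m); n2 <- ncol(m)
  # feasible phase-encode lines: rows the acquisition already visits (this
  # keeps partial-Fourier row restrictions intact; their conjugates are
  # synthesized, so sampling them wastes budget)
  feas_rows <- which(rowSums(m) > 0)
  if (length(feas_rows) < 2) feas_rows <- seq_len(n1)
  open <- which(!m & (row(m) %in% feas_rows))
  if (!length(open)) open <- which(!m)
  if (!length(open)) return(list())
  ctr <- c(floor(n1 / 2) + 1, floor(n2 / 2) + 1)
  oi <- ((open - 1) %% n1) + 1
  oj <- ((open - 1) %/% n1) + 1
  rad <- sqrt((oi - ctr[1])^2 + (oj - ctr[2])^2)
  # annulus coverage: sampled fraction per radial bin
  all_r <- sqrt((row(m) - ctr[1])^2 + (col(m) - ctr[2])^2)
  bins <- pmin(floor(all_r / 4), 24)
  dens <- tapply(as.numeric(m), bins, mean)
  w_ann <- 1 - dens[as.character(pmin(floor(rad / 4), 24))]
  w_ann <- pmax(as.numeric(w_ann), 0.05)
  # topology-uncertainty bias through the Fourier support heuristic
  w_topo <- rep(1, length(open))
  if (!is.null(uncertainty_map) && max(uncertainty_map) > 0) {
    spec <- Mod(fft2c(as.matrix(uncertainty_map)))
    spec <- EBImage::gblur(spec, sigma = 2)
    spec <- spec / max(spec)
    w_topo <- 0.1 + spec[open]
  }
  w <- w_ann * w_topo
  batch <- min(cfg$batch_size, length(open))
  oi_open <- oi; oj_open <- oj
  min_r2 <- 1.2^2
  with_seed(seed, {
    lapply(seq_len(cfg$candidate_count), function(a) {
      # weighted draw with a blue-noise spacing constraint within the batch
      # and against the already-sampled set
      ord <- sample(seq_along(open), prob = w)
      chosen <- integer(0)
      ci <- numeric(0); cj <- numeric(0)
      for (q in ord) {
        i <- oi_open[q]; j <- oj_open[q]
        if (length(chosen)) {
          if (min((ci - i)^2 + (cj - j)^2) < min_r2) next
        }
        i0 <- max(1, i - 1):min(n1, i + 1)
        j0 <- max(1, j - 1):min(n2, j + 1)
        if (any(m[i0, j0])) next
        chosen <- c(chosen, open[q])
        ci <- c(ci, i); cj <- c(cj, j)
        if (length(chosen) == batch) break
      }
      if (length(chosen) < batch) {
        # relax the spacing constraint to fill the batch
        extra <- setdiff(open[ord], chosen)
        chosen <- c(chosen, extra[seq_len(batch - length(chosen))])
      }
      list(locations = sort(chosen), cost = batch)
    })
  })
}

# apply an action: reveal the action locations of a fully simulated k-space
apply_action <- function(y_full, current, action) {
  stop_if_not(!any(current$mask[action$locations]),
              "action locations must be disjoint from the current mask")
  m <- current$mask
  m[action$locations] <- TRUE
  newmask <- sampling_mask(m, current$center_fraction, current$seed)
  kspace_measurement(y_full$values * m, newmask, y_full$noise_sigma,
                     y_full$voxel_size_mm)
}

# uncertainty of a measurement under the surrogate settings
surrogate_uncertainty <- function(y, recon_cfg, cfg, topo_cfg, seed) {
  scfg <- recon_cfg
  scfg$max_iterations <- cfg$surrogate_iterations
  xref <- reconstruct_full(y, scfg)
  ens <- stochastic_realizations(y, scfg, K = cfg$n_realizations,
                                 perturb_scale = cfg$perturb_scale,
                                 seed = seed)
  topology_uncertainty(ens, xref, topo_cfg)
}

#' Select the next acquisition action
#'
#' Scores every candidate by the expected reduction in topology-aware
#' uncertainty and returns the maximizer (ties broken by lowest candidate
#' index). Candidate measurements are synthesized by the plug-in
#' approximation: the current reconstruction substitutes for the unknown
#' image when filling the action's k-space locations. Uncertainty is
#' estimated with fast surrogate reconstructions and a small stochastic
#' ensemble.
#'
#' @param yt current [kspace_measurement()].
#' @param current current [sampling_mask()].
#' @param candidates list of actions from [propose_candidates()].
#' @param recon_cfg a [recon_config()].
#' @param cfg a [policy_config()].
#' @param topo_cfg a [topology_config()].
#' @param U_current optionally the precomputed current uncertainty.
#' @return the selected action, with attributes `scores` (expected
#'   uncertainty reductions) and `index`.
#' @export
select_next_action <- function(yt, current, candidates, recon_cfg,
                               cfg = policy_config(),
                               topo_cfg = topology_config(),
                               U_current = NULL) {
  stop_if_not(length(candidates) >= 1, "no candidate actions supplied")
  if (length(candidates) == 1) {
    out <- candidates[[1]]
    attr(out, "index") <- 1L
    return(out)
  }
  scfg <- recon_cfg
  scfg$max_iterations <- cfg$surrogate_iterations
  xhat <- reconstruct_full(yt, scfg)
  if (is.null(U_current)) {
    U_current <- surrogate_uncertainty(yt, recon_cfg, cfg, topo_cfg,
                                       seed = cfg$seed + 101L)
  }
  ks_plug <- fft2c(xhat$values)
  scores <- vapply(seq_along(candidates), function(a) {
    act <- candidates[[a]]
    vals <- yt$values
    vals[act$locations] <- ks_plug[act$locations]
    m <- current$mask
    m[act$locations] <- TRUE
    ya <- kspace_measurement(vals, sampling_mask(m, current$center_fraction),
                             yt$noise_sigma, yt$voxel_size_mm)
    Ua <- surrogate_uncertainty(ya, recon_cfg, cfg, topo_cfg,
                                seed = cfg$seed + 101L)
    U_current - Ua
  }, 0)
  idx <- which.max(scores)
  out <- candidates[[idx]]
  attr(out, "scores") <- scores
  attr(out, "index") <- idx
  out
}

#' Run the closed acquisition-reconstruction loop
#'
#' Iterates acquire - reconstruct - extract topology - estimate uncertainty -
#' select action, growing the sampling mask from the initial mask until the
#' iteration budget is exhausted or the topology uncertainty saturates
#' (relative decrease below `tol_rel` between iterations).
#'
#' @param phantom output of [generate_vascular_phantom()] (or a list with
#'   `image`); the fully sampled noisy k-space is simulated once and actions
#'   reveal its entries.
#' @param initial_mask starting [sampling_mask()].
#' @param budget maximum number of acquisition actions (>= 1).
#' @param recon_cfg a [recon_config()].
#' @param policy_cfg a [policy_config()].
#' @param topo_cfg a [topology_config()].
#' @param noise a [noise_model()].
#' @param seed seed for the k-space simulation.
#' @param tol_rel early-stopping threshold on the relative decrease of U.
#' @param selector "adaptive" (uncertainty-driven) or "random" (uniform
#'   choice among candidates; baseline).
#' @param reference_graph optional [vascular_graph()] for the per-iteration
#'   Betti-deviation log (defaults to the extraction of the clean image).
#' @return list with `mask` (final mask), `reconstruction` (final
#'   [reconstruct_full()] output at full iteration budget), `log`
#'   (data.frame: iteration, U, acceleration, betti_deviation, action_size).
#' @export
run_closed_loop <- function(phantom, initial_mask, budget = 6,
                            recon_cfg = recon_config(),
                            policy_cfg = policy_config(),
                            topo_cfg = topology_config(),
                            noise = noise_model(0.05), seed = 1,
                            tol_rel = 0.01,
                            selector = c("adaptive", "random"),
                            reference_graph = NULL) {
  selector <- match.arg(selector)
  stop_if_not(budget >= 1, "budget must be >= 1")
  y_full <- simulate_kspace(phantom$image, noise, seed = seed)
  if (is.null(reference_graph)) {
    reference_graph <- extract_graph(phantom$image,
                                     topo_cfg$vesselness_threshold,
                                     topo_cfg$scales_mm,
                                     min_length_mm = topo_cfg$min_length_mm)
  }
  mask <- initial_mask
  yt <- kspace_measurement(y_full$values * mask$mask, mask,
                           y_full$noise_sigma, y_full$voxel_size_mm)
  log_rows <- list()
  U_prev <- NA_real_
  for (t in seq_len(budget)) {
    scfg <- recon_cfg
    scfg$max_iterations <- policy_cfg$surrogate_iterations
    xref <- reconstruct_full(yt, scfg)
    ens <- stochastic_realizations(yt, scfg, K = policy_cfg$n_realizations,
                                   perturb_scale = policy_cfg$perturb_scale,
                                   seed = policy_cfg$seed + 101L)
    U_t <- topology_uncertainty(ens, xref, topo_cfg)
    g_t <- extract_graph(xref, topo_cfg$vesselness_threshold,
                         topo_cfg$scales_mm,
                         min_length_mm = topo_cfg$min_length_mm)
    db <- betti_deviation(g_t, reference_graph)
    # instability map: voxelwise sd of the vesselness response across the
    # ensemble, a smooth image-space proxy for unstable graph neighborhoods
    vref <- lapply(ens$members, function(mm) {
      vesselness(mm, topo_cfg$scales_mm)$values
    })
    varr <- array(unlist(vref), dim = c(dim(mask$mask), length(vref)))
    umap <- apply(varr, c(1, 2), stats::sd)
    cands <- propose_candidates(mask, policy_cfg, uncertainty_map = umap,
                                seed = policy_cfg$seed + 7L * t)
    if (!length(cands)) break
    act <- if (selector == "adaptive") {
      select_next_action(yt, mask, cands, recon_cfg, policy_cfg, topo_cfg,
                         U_current = U_t)
    } else {
      with_seed(policy_cfg$seed + 13L * t,
                cands[[sample.int(length(cands), 1)]])
    }
    yt <- apply_action(y_full, mask, act)
    mask <- yt$mask
    log_rows[[t]] <- data.frame(iteration = t, U = U_t,
                                acceleration = mask$acceleration,
                                betti_deviation = db,
                                action_size = act$cost)
    if (!is.na(U_prev) &&
        (U_prev - U_t) < tol_rel * max(U_prev, .Machine$double.eps)) break
    U_prev <- U_t
  }
  final <- reconstruct_full(yt, recon_cfg)
  list(mask = mask, reconstruction = final, measurement = yt,
       log = do.call(rbind, log_rows), reference_graph = reference_graph)
}
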