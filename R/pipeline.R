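#' Experiment configuration
#'
#' Single configuration object tying all modules together; every random
#' component derives its stream from `seed`. Defaults are the desk-scale
#' study conditions: 96 x 96 phantom at 0.5 mm, 5 branches, 2 collateral
#' loops, ~70% acceleration with an 8% center band, Poisson-disc sampling
#' restricted to a 65% partial-Fourier region, k-space noise sigma 0.05.
#'
#' @param grid integer image grid (square).
#' @param voxel_size_mm voxel size.
#' @param n_main_branches,n_collateral_loops phantom structure.
#' @param diameter_range_mm phantom vessel diameters.
#' @param branch_contrast vessel-to-background ratio.
#' @param acceleration final undersampling fraction (locations not sampled).
#' @param center_fraction fully sampled center band.
#' @param pf_fraction partial-Fourier restriction of the random samples.
#' @param noise_sigma k-space complex noise std.
#' @param budget closed-loop acquisition actions.
#' @param recon a [recon_config()].
#' @param policy a [policy_config()].
#' @param topo a [topology_config()].
#' @param meso,micro cross-scale parameters.
#' @param run_crossscale logical; run the macro-meso-micro simulator.
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(grid = 96, voxel_size_mm = 0.5,
                              n_main_branches = 5, n_collateral_loops = 2,
                              diameter_range_mm = c(0.8, 2.5),
                              branch_contrast = 4,
                              acceleration = 0.7, center_fraction = 0.08,
                              pf_fraction = 0.65, noise_sigma = 0.05,
                              budget = 5,
                              recon = recon_config(lambda_reg = 2e-3,
                                                   max_iterations = 60,
                                                   pf = list(enabled = TRUE,
                                                             phase_band_fraction = 0.06)),
                              policy = policy_config(candidate_count = 6,
                                                     batch_size = NULL),
                              topo = topology_config(vesselness_threshold = 0.12),
                              meso = meso_params(), micro = micro_params(),
                              run_crossscale = FALSE, seed = 1) {
  if (is.null(policy$batch_size)) {
    # grow from accel+0.1 to the target acceleration across the budget
    policy$batch_size <- max(1L, round(0.1 * grid^2 / budget))
  }
  structure(list(grid = grid, voxel_size_mm = voxel_size_mm,
                 n_main_branches = n_main_branches,
                 n_collateral_loops = n_collateral_loops,
                 diameter_range_mm = diameter_range_mm,
                 branch_contrast = branch_contrast,
                 acceleration = acceleration,
                 center_fraction = center_fraction,
                 pf_fraction = pf_fraction,
                 noise_sigma = noise_sigma, budget = budget,
                 recon = recon, policy = policy, topo = topo,
                 meso = meso, micro = micro,
                 run_crossscale = run_crossscale, seed = seed),
            class = "experiment_config")
}

exp_phantom <- function(cfg) {
  generate_vascular_phantom(phantom_spec(
    grid_shape = c(cfg$grid, cfg$grid), voxel_size_mm = cfg$voxel_size_mm,
    n_main_branches = cfg$n_main_branches,
    n_collateral_loops = cfg$n_collateral_loops,
    diameter_range_mm = cfg$diameter_range_mm,
    branch_contrast = cfg$branch_contrast, seed = cfg$seed))
}

#' Generate and persist experiment fixtures
#'
#' Writes the phantom image (NIfTI), ground-truth graph (GraphML), sampling
#' mask (CSV), sensor streams (CSV + JSON sidecars) and a manifest JSON with
#' the configuration and file list. Deterministic given the configuration.
#'
#' @param cfg an [experiment_config()].
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
generate_fixtures <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ph <- exp_phantom(cfg)
  mask <- poisson_disc_mask(c(cfg$grid, cfg$grid), cfg$acceleration,
                            center_fraction = cfg$center_fraction,
                            seed = cfg$seed, pf_fraction = cfg$pf_fraction)
  streams <- generate_streams(10, seed = cfg$seed)
  files <- c(
    phantom = write_volume_nifti(ph$image, file.path(dir, "phantom.nii.gz")),
    graph = write_graph_graphml(ph$graph, file.path(dir, "graph_truth.graphml")),
    mask = write_mask_csv(mask, file.path(dir, "mask.csv")))
  files <- c(files, stream = write_streams_csv(streams, dir))
  manifest <- list(seed = cfg$seed, grid = cfg$grid,
                   acceleration = cfg$acceleration,
                   files = basename(unname(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Run one full experiment
#'
#' Executes the configured baselines on a seeded phantom: static
#' Poisson-disc compressed sensing ("cs"), static acquisition with
#' structured priors ("cs_priors"), and the full closed-loop adaptive
#' pipeline ("adaptive"), all at matched final acceleration. Reports image
#' fidelity and topology metrics per method.
#'
#' @param cfg an [experiment_config()].
#' @param methods subset of c("cs", "cs_priors", "adaptive").
#' @return list with `metrics` (data.frame), `phantom`, `reference_graph`,
#'   `recons`, and optionally `crossscale`.
#' @export
run_experiment <- function(cfg, methods = c("cs", "cs_priors", "adaptive")) {
  ph <- exp_phantom(cfg)
  shape <- c(cfg$grid, cfg$grid)
  noise <- noise_model(cfg$noise_sigma)
  ref_graph <- extract_graph(ph$image, cfg$topo$vesselness_threshold,
                             cfg$topo$scales_mm,
                             min_length_mm = cfg$topo$min_length_mm)
  static_mask <- poisson_disc_mask(shape, cfg$acceleration,
                                   center_fraction = cfg$center_fraction,
                                   seed = cfg$seed + 1L,
                                   pf_fraction = cfg$pf_fraction)
  y_static <- simulate_kspace(ph$image, noise, seed = cfg$seed + 2L,
                              mask = static_mask)
  recons <- list()
  rows <- list()
  eval_method <- function(name, img, mask_used) {
    g <- extract_graph(img, cfg$topo$vesselness_threshold,
                       cfg$topo$scales_mm,
                       min_length_mm = cfg$topo$min_length_mm)
    db <- betti_deviation(g, ref_graph)
    bc <- if (nrow(ref_graph$edges)) branch_completeness(g, ref_graph) else NA
    data.frame(method = name, seed = cfg$seed,
               acceleration = mask_used$acceleration,
               psnr_db = psnr(ph$image, img), ssim = ssim(ph$image, img),
               nmse = nmse(ph$image, img),
               betti_deviation = db, branch_completeness = bc)
  }
  if ("cs" %in% methods) {
    cfg_cs <- cfg$recon
    cfg_cs$pf$enabled <- FALSE; cfg_cs$hankel$enabled <- FALSE
    recons$cs <- cs_reconstruct(y_static, cfg_cs)
    rows$cs <- eval_method("cs", recons$cs, static_mask)
  }
  if ("cs_priors" %in% methods) {
    recons$cs_priors <- reconstruct_full(y_static, cfg$recon)
    rows$cs_priors <- eval_method("cs_priors", recons$cs_priors, static_mask)
  }
  loop <- NULL
  if ("adaptive" %in% methods) {
    init_accel <- min(cfg$acceleration + 0.1, 0.95)
    init_mask <- poisson_disc_mask(shape, init_accel,
                                   center_fraction = cfg$center_fraction,
                                   seed = cfg$seed + 1L,
                                   pf_fraction = cfg$pf_fraction)
    pol <- cfg$policy
    pol$seed <- cfg$seed + 3L
    pol$batch_size <- max(1L, round((init_accel - cfg$acceleration) *
                                      cfg$grid^2 / cfg$budget))
    loop <- run_closed_loop(ph, init_mask, budget = cfg$budget,
                            recon_cfg = cfg$recon, policy_cfg = pol,
                            topo_cfg = cfg$topo, noise = noise,
                            seed = cfg$seed + 2L, tol_rel = -Inf,
                            reference_graph = ref_graph)
    recons$adaptive <- loop$reconstruction
    rows$adaptive <- eval_method("adaptive", recons$adaptive, loop$mask)
  }
  out <- list(metrics = do.call(rbind, rows), phantom = ph,
              reference_graph = ref_graph, recons = recons, loop = loop)
  if (isTRUE(cfg$run_crossscale) && nrow(ref_graph$edges)) {
    out$crossscale <- tryCatch(
      simulate_cross_scale(ref_graph, shape, cfg$voxel_size_mm,
                           cfg$meso, cfg$micro),
      error = function(e) NULL)
  }
  rownames(out$metrics) <- NULL
  out
}

#' Benchmark across seeds
#'
#' Repeats [run_experiment()] over `n_seeds` seeds and aggregates per-method
#' mean and standard deviation of every metric. Partial failures are logged
#' and skipped.
#'
#' @param cfg an [experiment_config()] (its seed fields the first run).
#' @param n_seeds number of seeded replicates.
#' @param methods methods to run.
#' @return list with `runs` (per-seed metric rows) and `summary`
#'   (method-level mean/sd), plus `failures`.
#' @export
run_benchmark <- function(cfg, n_seeds = 5,
                          methods = c("cs", "cs_priors", "adaptive")) {
  runs <- list(); failures <- character()
  for (k in seq_len(n_seeds)) {
    ck <- cfg
    ck$seed <- cfg$seed + (k - 1L)
    res <- tryCatch(run_experiment(ck, methods),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("seed %d: %s", ck$seed, res))
    } else {
      runs[[length(runs) + 1]] <- res$metrics
    }
  }
  stop_if_not(length(runs) >= 1, "all benchmark runs failed")
  tab <- do.call(rbind, runs)
  num_cols <- setdiff(names(tab), c("method", "seed"))
  agg <- do.call(rbind, lapply(split(tab, tab$method), function(d) {
    means <- vapply(d[num_cols], mean, 0)
    sds <- vapply(d[num_cols], stats::sd, 0)
    data.frame(method = d$method[1], metric = num_cols,
               mean = unname(means), sd = unname(sds))
  }))
  rownames(agg) <- NULL
  list(runs = tab, summary = agg, failures = failures)
}
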