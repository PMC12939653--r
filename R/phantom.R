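#' Specification of a synthetic vascular phantom
#'
#' Describes a 2-D vascular phantom: a stochastic binary branching tree grown
#' from a root with random-walk centerlines, optional chords forming
#' collateral loops, tapering radii, and a Gaussian cross-sectional intensity
#' profile (FWHM equal to the local vessel diameter) on a bright-vessel /
#' unit-background image, emulating time-of-flight angiography contrast.
#'
#' @param grid_shape integer vector of length 2, image grid in voxels.
#' @param voxel_size_mm voxel edge length in mm.
#' @param n_main_branches total number of vessel branches grown (the main
#'   trunk counts as one).
#' @param n_collateral_loops number of collateral chords; each adds exactly
#'   one independent cycle to the ground-truth graph.
#' @param diameter_range_mm numeric `c(min, max)` vessel diameter in mm.
#' @param branch_contrast vessel-to-background intensity ratio (> 1).
#' @param seed integer seed; the generator is a pure function of (spec, seed).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(192, 192), voxel_size_mm = 0.5,
                         n_main_branches = 5, n_collateral_loops = 2,
                         diameter_range_mm = c(0.8, 2.5),
                         branch_contrast = 4, seed = 1) {
  stop_if_not(length(grid_shape) == 2 && all(grid_shape > 0),
              "grid_shape must be two positive integers")
  stop_if_not(voxel_size_mm > 0, "voxel_size_mm must be > 0")
  stop_if_not(n_main_branches >= 1, "need at least one branch")
  stop_if_not(n_collateral_loops >= 0, "n_collateral_loops must be >= 0")
  stop_if_not(all(diameter_range_mm > 0) &&
                diameter_range_mm[1] <= diameter_range_mm[2],
              "diameter_range_mm must be positive with min <= max")
  stop_if_not(branch_contrast > 1, "branch_contrast must exceed 1")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_main_branches = as.integer(n_main_branches),
                 n_collateral_loops = as.integer(n_collateral_loops),
                 diameter_range_mm = diameter_range_mm,
                 branch_contrast = branch_contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# random-walk centerline from point p0 with initial heading (unit vector),
# step in mm, staying inside [margin, limit - margin]^2; returns a polyline
rw_centerline <- function(p0, heading, length_mm, step_mm, lim_mm, margin_mm,
                          jitter_sd = 0.10) {
  n <- max(2L, ceiling(length_mm / step_mm))
  pts <- matrix(NA_real_, n + 1, 2)
  pts[1, ] <- p0
  th <- atan2(heading[2], heading[1])
  th0 <- th
  for (i in seq_len(n)) {
    th <- th + stats::rnorm(1, 0, jitter_sd) + 0.08 * (th0 - th)
    p <- pts[i, ] + step_mm * c(cos(th), sin(th))
    if (any(p < margin_mm) || any(p > lim_mm - margin_mm)) {
      pts <- pts[seq_len(i), , drop = FALSE]
      break
    }
    pts[i + 1, ] <- p
  }
  pts[!is.na(pts[, 1]), , drop = FALSE]
}

poly_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# cubic Bezier chord leaving both anchors along the given departure
# directions (unit vectors), sampled at roughly step_mm; perpendicular
# departure keeps the enclosed gap open right from the anchor points
bezier_chord <- function(p0, p3, step_mm, dir0, dir3, handle = 0.35) {
  len <- vnorm(p3 - p0)
  p1 <- p0 + handle * len * dir0
  p2 <- p3 + handle * len * dir3
  t <- seq(0, 1, length.out = max(4L, ceiling(2 * len / step_mm)))
  bx <- (1 - t)^3 * p0[1] + 3 * t * (1 - t)^2 * p1[1] +
    3 * t^2 * (1 - t) * p2[1] + t^3 * p3[1]
  by <- (1 - t)^3 * p0[2] + 3 * t * (1 - t)^2 * p1[2] +
    3 * t^2 * (1 - t) * p2[2] + t^3 * p3[2]
  cbind(bx, by)
}

#' Generate a vascular phantom with known ground-truth graph
#'
#' Grows a seeded stochastic branching tree (plus optional collateral
#' chords), rasterizes it into a bright-vessel intensity image and returns
#' the exact centerline graph. The ground-truth graph has one connected
#' component and cycle rank equal to `n_collateral_loops`.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `image` ([image_volume()]) and `graph`
#'   ([vascular_graph()]).
#' @export
generate_vascular_phantom <- function(spec) {
  stop_if_not(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  vox <- spec$voxel_size_mm
  lim <- spec$grid_shape * vox          # physical extent in mm (x, y)
  margin <- 3 * vox
  dmin <- spec$diameter_range_mm[1]
  dmax <- spec$diameter_range_mm[2]
  if (min(lim) < 10 * dmax || min(spec$grid_shape) < 32 ||
      min(lim) < 4 * margin) {
    stop(sprintf("grid too small to place requested branches (extent %.1f x %.1f mm, max diameter %.2f mm)",
                 lim[1], lim[2], dmax), call. = FALSE)
  }

  with_seed(spec$seed, {
    out <- NULL
    for (gen_attempt in seq_len(10)) {
    step <- vox
    # --- grow the tree ------------------------------------------------------
    # nodes: positions; edges: list(from, to, poly, diameter)
    nodes <- list()
    edges <- list()
    add_node <- function(p) { nodes[[length(nodes) + 1]] <<- p; length(nodes) }
    add_edge <- function(from, to, poly, diameter) {
      edges[[length(edges) + 1]] <<- list(from = from, to = to, poly = poly,
                                          diameter = diameter)
      length(edges)
    }
    # trunk: left border towards +x
    p0 <- c(margin + vox, lim[2] * stats::runif(1, 0.4, 0.6))
    trunk <- rw_centerline(p0, c(1, 0), 0.8 * lim[1], step, lim, margin)
    n1 <- add_node(trunk[1, ]); n2 <- add_node(trunk[nrow(trunk), ])
    add_edge(n1, n2, trunk, dmax)

    split_edge_at <- function(ei, k) {
      # split edge ei at polyline row k, return new node id
      e <- edges[[ei]]
      nn <- add_node(e$poly[k, ])
      edges[[ei]] <<- list(from = e$from, to = nn,
                           poly = e$poly[seq_len(k), , drop = FALSE],
                           diameter = e$diameter)
      add_edge(nn, e$to, e$poly[k:nrow(e$poly), , drop = FALSE], e$diameter)
      nn
    }

    # clearance check: truncate a new centerline where it approaches
    # existing vessels, so distinct graph edges stay spatially distinct
    all_points <- function() do.call(rbind, lapply(edges, `[[`, "poly"))
    truncate_at_clearance <- function(poly, clear_mm, skip_mm = 4) {
      cloud <- all_points()
      if (is.null(cloud) || !nrow(cloud)) return(poly)
      # exempt the neighbourhood of the branch point itself
      near_start <- (cloud[, 1] - poly[1, 1])^2 +
        (cloud[, 2] - poly[1, 2])^2 < skip_mm^2
      cloud <- cloud[!near_start, , drop = FALSE]
      if (!nrow(cloud)) return(poly)
      d2 <- outer(poly[, 1], cloud[, 1], "-")^2 +
        outer(poly[, 2], cloud[, 2], "-")^2
      bad <- which(sqrt(apply(d2, 1, min)) < clear_mm)
      if (!length(bad)) return(poly)
      poly[seq_len(max(2L, bad[1] - 1L)), , drop = FALSE]
    }

    n_grown <- 1L
    attempts <- 0L
    while (n_grown < spec$n_main_branches && attempts < 200L) {
      attempts <- attempts + 1L
      lens <- vapply(edges, function(e) poly_length(e$poly), 0)
      ei <- sample.int(length(edges), 1, prob = pmax(lens, 1e-6))
      e <- edges[[ei]]
      np <- nrow(e$poly)
      if (np < 6) next
      k <- sample(seq(max(2L, round(0.15 * np)), min(np - 1L, round(0.85 * np))), 1)
      tang <- e$poly[min(np, k + 1), ] - e$poly[max(1, k - 1), ]
      tang <- tang / max(vnorm(tang), 1e-9)
      ang <- sample(c(-1, 1), 1) * stats::runif(1, 35, 65) * pi / 180
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      dir <- as.numeric(rot %*% tang)
      child_d <- max(dmin, e$diameter * stats::runif(1, 0.65, 0.85))
      br_len <- stats::runif(1, 0.25, 0.55) * min(lim)
      start <- e$poly[k, ]
      poly <- rw_centerline(start, dir, br_len, step, lim, margin)
      poly <- truncate_at_clearance(poly, clear_mm = (dmax + child_d) / 2 + 1.8)
      if (poly_length(poly) < max(6 * vox, 4)) next
      nn <- split_edge_at(ei, k)
      nt <- add_node(poly[nrow(poly), ])
      add_edge(nn, nt, poly, child_d)
      n_grown <- n_grown + 1L
    }
    if (n_grown < spec$n_main_branches) next

    # --- collateral chords --------------------------------------------------
    n_loops <- 0L
    attempts <- 0L
    while (n_loops < spec$n_collateral_loops && attempts < 400L) {
      attempts <- attempts + 1L
      lens <- vapply(edges, function(e) poly_length(e$poly), 0)
      eis <- sample.int(length(edges), 2, prob = pmax(lens, 1e-6))
      if (eis[1] == eis[2]) next
      e1 <- edges[[eis[1]]]; e2 <- edges[[eis[2]]]
      if (nrow(e1$poly) < 6 || nrow(e2$poly) < 6) next
      k1 <- sample(seq(3L, nrow(e1$poly) - 2L), 1)
      k2 <- sample(seq(3L, nrow(e2$poly) - 2L), 1)
      pA <- e1$poly[k1, ]; pB <- e2$poly[k2, ]
      gap <- vnorm(pB - pA)
      if (gap < 12 * vox || gap > 0.6 * min(lim)) next
      # depart perpendicular to each parent, on the side facing the partner
      tangent_at <- function(e, k) {
        tg <- e$poly[min(nrow(e$poly), k + 1), ] - e$poly[max(1, k - 1), ]
        tg / max(vnorm(tg), 1e-9)
      }
      perp_toward <- function(tg, from, to) {
        nrm <- c(-tg[2], tg[1])
        if (sum(nrm * (to - from)) < 0) nrm <- -nrm
        nrm
      }
      tA <- tangent_at(e1, k1); tB <- tangent_at(e2, k2)
      chord <- bezier_chord(pA, pB, step,
                            perp_toward(tA, pA, pB), perp_toward(tB, pB, pA),
                            handle = stats::runif(1, 0.3, 0.45))
      if (any(chord < margin) || any(chord > rep(lim - margin, each = nrow(chord)))) next
      # loop resolvability: away from its anchor points the chord must stay
      # clear of existing vessels by more than the imaging point-spread so
      # the collateral reads as a cycle rather than a filled sliver
      cloud <- all_points()
      near_anchor <- (cloud[, 1] - pA[1])^2 + (cloud[, 2] - pA[2])^2 < 16 |
        (cloud[, 1] - pB[1])^2 + (cloud[, 2] - pB[2])^2 < 16
      far_cloud <- cloud[!near_anchor, , drop = FALSE]
      if (nrow(far_cloud)) {
        d2i <- outer(chord[, 1], far_cloud[, 1], "-")^2 +
          outer(chord[, 2], far_cloud[, 2], "-")^2
        if (min(d2i) < (dmax / 2 + 2.2)^2) next
      }
      nA <- split_edge_at(eis[1], k1)
      # e2's index is unchanged by the first split (a new edge was appended)
      nB <- split_edge_at(eis[2], k2)
      add_edge(nA, nB, chord,
               max(dmin, stats::runif(1, dmin, 0.5 * (dmin + dmax)) * 0.8))
      n_loops <- n_loops + 1L
    }
    if (n_loops < spec$n_collateral_loops) next

    # --- assemble graph -----------------------------------------------------
    node_pos <- do.call(rbind, nodes)
    deg <- integer(length(nodes))
    for (e in edges) { deg[e$from] <- deg[e$from] + 1L; deg[e$to] <- deg[e$to] + 1L }
    kind <- ifelse(deg == 1, "terminal", ifelse(deg == 3, "bifurcation", "junction"))
    nodes_df <- data.frame(id = seq_along(nodes), x_mm = node_pos[, 1],
                           y_mm = node_pos[, 2], kind = kind,
                           stringsAsFactors = FALSE)
    edges_df <- data.frame(
      from = vapply(edges, `[[`, 0L, "from"),
      to = vapply(edges, `[[`, 0L, "to"),
      length_mm = vapply(edges, function(e) poly_length(e$poly), 0),
      diameter_mm = vapply(edges, `[[`, 0, "diameter"),
      confidence = 1,
      stringsAsFactors = FALSE)
    edges_df$conductance <- edge_conductance(edges_df$diameter_mm,
                                             edges_df$length_mm)
    g <- vascular_graph(nodes_df, edges_df, lapply(edges, `[[`, "poly"))

    # --- rasterize and self-validate ----------------------------------------
    img <- rasterize_graph(g, spec$grid_shape, vox, spec$branch_contrast)
    # the rendered image must visually carry exactly the requested number of
    # collateral loops (holes of the half-maximum segmentation); otherwise
    # the draw produced sub-resolution geometry and is re-sampled
    seg <- img$values >= 1 + (spec$branch_contrast - 1) / 2
    bg <- matrix(1, nrow(seg) + 2, ncol(seg) + 2)
    bg[seq_len(nrow(seg)) + 1, seq_len(ncol(seg)) + 1] <- 1 - seg
    n_holes <- max(EBImage::bwlabel(bg)) - 1
    if (n_holes == spec$n_collateral_loops) {
      # stronger check: the toolkit's own default extraction of the clean
      # image must recover the ground-truth topology, so that the phantom's
      # Betti numbers are well defined at the imaging resolution
      b_chk <- betti_numbers(extract_graph(img, min_length_mm = 2.5))
      if (identical(unname(b_chk),
                    c(1L, as.integer(spec$n_collateral_loops)))) {
        out <- list(image = img, graph = g)
        break
      }
    }
    }
    if (is.null(out)) {
      stop("grid too small to place the requested branches and collateral loops at a resolvable scale",
           call. = FALSE)
    }
    out
  })
}

# draw Gaussian cross-section profiles (FWHM = diameter) along every edge
# polyline onto a unit background; intensities max-blended across vessels
rasterize_graph <- function(g, grid_shape, vox, contrast) {
  img <- matrix(1, grid_shape[1], grid_shape[2])
  amp <- contrast - 1
  for (ei in seq_len(nrow(g$edges))) {
    poly <- g$polylines[[ei]]
    if (is.null(poly) || nrow(poly) < 2) next
    sigma <- g$edges$diameter_mm[ei] / 2.3548  # FWHM -> sd
    w <- max(2L, ceiling(3 * sigma / vox))
    # resample polyline at half-voxel steps
    seglen <- sqrt(rowSums(diff(poly)^2))
    s <- c(0, cumsum(seglen))
    ss <- seq(0, s[length(s)], by = vox / 2)
    px <- stats::approx(s, poly[, 1], xout = ss)$y
    py <- stats::approx(s, poly[, 2], xout = ss)$y
    for (q in seq_along(ss)) {
      ci <- round(px[q] / vox + 0.5); cj <- round(py[q] / vox + 0.5)
      is <- max(1L, ci - w):min(grid_shape[1], ci + w)
      js <- max(1L, cj - w):min(grid_shape[2], cj + w)
      if (!length(is) || !length(js)) next
      gx <- ((is - 0.5) * vox - px[q])^2
      gy <- ((js - 0.5) * vox - py[q])^2
      prof <- 1 + amp * exp(-outer(gx, gy, "+") / (2 * sigma^2))
      img[is, js] <- pmax(img[is, js], prof)
    }
  }
  image_volume(img, vox)
}

#' Acquisition noise model
#'
#' Perturbation model for simulated k-space: additive complex Gaussian noise,
#' a rigid in-plane translation applied to a contiguous block of phase-encode
#' lines, and a fractional SNR reduction (signal attenuation), with ranges
#' matching motion of 0-2 mm and SNR loss of 0-30%.
#'
#' @param kspace_noise_sigma complex Gaussian noise std (absolute units),
#'   defined so that `sqrt(E|eta|^2) = sigma`.
#' @param motion_shift_mm rigid translation magnitude in mm (>= 0).
#' @param motion_fraction fraction of phase-encode lines affected by motion.
#' @param snr_reduction_fraction signal attenuation fraction in [0, 0.3].
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(kspace_noise_sigma = 0, motion_shift_mm = 0,
                        motion_fraction = 0.3, snr_reduction_fraction = 0) {
  stop_if_not(kspace_noise_sigma >= 0, "sigma must be >= 0")
  stop_if_not(motion_shift_mm >= 0, "motion shift must be >= 0")
  stop_if_not(motion_fraction >= 0 && motion_fraction <= 1,
              "motion_fraction must lie in [0,1]")
  stop_if_not(snr_reduction_fraction >= 0 && snr_reduction_fraction <= 0.3,
              "snr_reduction_fraction must lie in [0, 0.3]")
  structure(list(kspace_noise_sigma = kspace_noise_sigma,
                 motion_shift_mm = motion_shift_mm,
                 motion_fraction = motion_fraction,
                 snr_reduction_fraction = snr_reduction_fraction),
            class = "noise_model")
}

#' Simulate k-space acquisition of an image
#'
#' Centered unitary discrete Fourier transform of the image plus i.i.d.
#' complex Gaussian noise (`y = F x + eta`), with optional SNR reduction
#' (signal attenuation) and motion corruption per the noise model. The mask
#' defaults to full sampling.
#'
#' @param img an [image_volume()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the noise draw.
#' @param mask optional [sampling_mask()]; defaults to a full mask.
#' @return a [kspace_measurement()].
#' @export
simulate_kspace <- function(img, noise = noise_model(), seed = 1,
                            mask = NULL) {
  stop_if_not(inherits(img, "image_volume"), "img must be an image_volume")
  shape <- dim(img$values)
  if (is.null(mask)) mask <- full_mask(shape)
  vals <- img$values * (1 - noise$snr_reduction_fraction)
  ks <- fft2c(vals)
  with_seed(seed, {
    if (noise$kspace_noise_sigma > 0) {
      s <- noise$kspace_noise_sigma / sqrt(2)
      ks <- ks + complex(real = stats::rnorm(length(ks), 0, s),
                         imaginary = stats::rnorm(length(ks), 0, s))
    }
    km <- kspace_measurement(ks * mask$mask, mask,
                             noise_sigma = noise$kspace_noise_sigma,
                             voxel_size_mm = img$voxel_size_mm)
    if (noise$motion_shift_mm > 0 && noise$motion_fraction > 0) {
      km <- apply_motion_perturbation(km, noise$motion_shift_mm,
                                      noise$motion_fraction,
                                      seed = stats::runif(1, 1, 1e8))
    }
    km
  })
}

#' Apply a rigid-motion perturbation to k-space
#'
#' Multiplies a contiguous, randomly placed block of phase-encode lines
#' (matrix rows) by the linear phase ramp of an in-plane translation,
#' modelling subject motion during part of the acquisition.
#'
#' @param ks a [kspace_measurement()].
#' @param shift_mm translation magnitude in mm (>= 0).
#' @param affected_fraction fraction of phase-encode lines affected, in [0,1].
#' @param seed integer seed for the block placement.
#' @param direction unit-norm translation direction (default along the first
#'   image axis).
#' @return a [kspace_measurement()] with the perturbed values.
#' @export
apply_motion_perturbation <- function(ks, shift_mm, affected_fraction,
                                      seed = 1, direction = c(1, 0)) {
  stop_if_not(shift_mm >= 0, "shift_mm must be >= 0")
  stop_if_not(affected_fraction >= 0 && affected_fraction <= 1,
              "affected_fraction must lie in [0,1]")
  if (shift_mm == 0 || affected_fraction == 0) return(ks)
  n <- dim(ks$values)
  tvox <- shift_mm / ks$voxel_size_mm * direction / vnorm(direction)
  # centered frequency offsets per axis
  k1 <- (seq_len(n[1]) - 1) - floor(n[1] / 2)
  k2 <- (seq_len(n[2]) - 1) - floor(n[2] / 2)
  phase <- outer(k1 * tvox[1] / n[1], k2 * tvox[2] / n[2], "+")
  ramp <- exp(-2i * pi * phase)
  n_lines <- max(1L, round(affected_fraction * n[1]))
  start <- with_seed(seed, sample.int(n[1] - n_lines + 1L, 1))
  rows <- start:(start + n_lines - 1L)
  vals <- ks$values
  vals[rows, ] <- vals[rows, ] * ramp[rows, ]
  kspace_measurement(vals, ks$mask, ks$noise_sigma, ks$voxel_size_mm)
}
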