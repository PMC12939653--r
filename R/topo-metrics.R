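#' Topology pipeline configuration
#'
#' Settings shared by all graph-level topology computations so that every
#' realization and the reference are processed identically.
#'
#' @param vesselness_threshold segmentation threshold in (0, 1).
#' @param scales_mm vesselness scales in mm.
#' @param min_length_mm pruning length in mm.
#' @param q Wasserstein order.
#' @return an object of class `topology_config`.
#' @export
topology_config <- function(vesselness_threshold = 0.12,
                            scales_mm = c(0.5, 1, 1.5, 2),
                            min_length_mm = 2.5, q = 2) {
  structure(list(vesselness_threshold = vesselness_threshold,
                 scales_mm = scales_mm, min_length_mm = min_length_mm, q = q),
            class = "topology_config")
}

# image -> pruned graph + diagrams under a fixed topology_config
image_topology <- function(img, cfg = topology_config()) {
  g <- extract_graph(img, cfg$vesselness_threshold, cfg$scales_mm,
                     min_length_mm = cfg$min_length_mm)
  list(graph = g, diagrams = superlevel_persistence(g))
}

# summed dim-0 + dim-1 Wasserstein distance between two diagram pairs
diagram_pair_distance <- function(da, db, q = 2) {
  wasserstein_distance(da$dim0, db$dim0, q = q) +
    wasserstein_distance(da$dim1, db$dim1, q = q)
}

#' Topology-aware uncertainty of a reconstruction ensemble
#'
#' Mean over stochastic realizations of the summed (dimension 0 plus
#' dimension 1) Wasserstein distance between each realization's persistence
#' diagrams and the reference reconstruction's diagrams, all extracted with
#' identical threshold and pruning settings.
#'
#' @param ensemble a [stochastic_realizations()] ensemble, or a list of
#'   precomputed diagram pairs (each `list(dim0=, dim1=)`).
#' @param reference the reference [image_volume()], or a precomputed diagram
#'   pair when `ensemble` is a list of diagram pairs.
#' @param cfg a [topology_config()].
#' @return non-negative scalar U.
#' @export
topology_uncertainty <- function(ensemble, reference, cfg = topology_config()) {
  if (inherits(ensemble, "stochastic_ensemble")) {
    ref <- image_topology(reference, cfg)$diagrams
    ds <- lapply(ensemble$members, function(m) image_topology(m, cfg)$diagrams)
  } else {
    ref <- reference
    ds <- ensemble
  }
  mean(vapply(ds, function(d) diagram_pair_distance(d, ref, q = cfg$q), 0))
}

#' Betti deviation between a graph and a reference
#'
#' `(|beta0(g) - beta0(ref)| + |beta1(g) - beta1(ref)|)` normalized by the
#' reference Betti total (floored at 1), where `beta0` is the number of
#' connected components and `beta1` the cycle rank.
#'
#' @param g,ref [vascular_graph()] objects extracted with identical
#'   thresholds.
#' @return non-negative scalar.
#' @export
betti_deviation <- function(g, ref) {
  bg <- betti_numbers(g); br <- betti_numbers(ref)
  unname((abs(bg[1] - br[1]) + abs(bg[2] - br[2])) / max(1, br[1] + br[2]))
}

#' Branch completeness
#'
#' Fraction of reference edges recovered: a reference edge is matched when at
#' least `coverage` of its resampled centerline points lie within `tol_mm` of
#' some point of the reconstructed centerline. Coverage is evaluated against
#' the full reconstructed centerline point set because the reconstructed
#' graph need not partition the network into the same segments.
#'
#' @param g reconstructed [vascular_graph()].
#' @param ref reference [vascular_graph()] (must have edges).
#' @param tol_mm spatial tolerance in mm.
#' @param coverage required fraction of covered centerline points.
#' @return scalar in [0, 1].
#' @export
branch_completeness <- function(g, ref, tol_mm = 1.0, coverage = 0.8) {
  stop_if_not(tol_mm >= 0, "tol_mm must be >= 0")
  nref <- nrow(ref$edges)
  stop_if_not(nref > 0, "reference graph has no edges")
  if (!nrow(g$edges)) return(0)
  step <- tol_mm / 2
  resample <- function(poly) {
    if (is.null(poly) || nrow(poly) < 2) return(poly)
    s <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
    if (s[length(s)] == 0) return(poly[1, , drop = FALSE])
    ss <- seq(0, s[length(s)], by = max(step, 1e-6))
    cbind(stats::approx(s, poly[, 1], xout = ss)$y,
          stats::approx(s, poly[, 2], xout = ss)$y)
  }
  refp <- lapply(ref$polylines, resample)
  gall <- do.call(rbind, lapply(g$polylines, resample))
  if (is.null(gall) || !nrow(gall)) return(0)
  # a reference edge is matched when enough of its centerline lies within
  # tol_mm of the reconstructed centerline; the reconstructed edges need not
  # partition the network the same way, so coverage is measured against the
  # full centerline point set
  matched <- 0L
  for (i in seq_len(nref)) {
    pi_ <- refp[[i]]
    if (is.null(pi_) || !nrow(pi_)) next
    d2 <- outer(pi_[, 1], gall[, 1], "-")^2 + outer(pi_[, 2], gall[, 2], "-")^2
    if (mean(sqrt(apply(d2, 1, min)) <= tol_mm) >= coverage) {
      matched <- matched + 1L
    }
  }
  matched / nref
}

#' Persistence stability of an ensemble
#'
#' One minus the normalized topology uncertainty,
#' `1 - clamp(U / normalizer, 0, 1)`; the normalizer defaults to the total
#' persistence of the reference diagrams, floored at machine epsilon.
#'
#' @param ensemble,reference,cfg as in [topology_uncertainty()].
#' @param normalizer positive normalization constant (default: reference
#'   total persistence).
#' @param U optionally a precomputed uncertainty value (skips extraction).
#' @return scalar in [0, 1].
#' @export
persistence_stability <- function(ensemble = NULL, reference = NULL,
                                  cfg = topology_config(), normalizer = NULL,
                                  U = NULL) {
  if (is.null(U)) {
    U <- topology_uncertainty(ensemble, reference, cfg)
  }
  if (is.null(normalizer)) {
    ref <- if (inherits(reference, "image_volume")) {
      image_topology(reference, cfg)$diagrams
    } else reference
    normalizer <- total_persistence(ref)
  }
  normalizer <- max(normalizer, .Machine$double.eps)
  stop_if_not(normalizer > 0, "normalizer must be > 0")
  1 - min(max(U / normalizer, 0), 1)
}

#' Composite macro-scale topology uncertainty
#'
#' Weighted combination of diagram-level variation and graph-level
#' fragmentation: `w1 * U_w + w2 * (1 - BC) + w3 * delta_beta` with fixed
#' default weights (0.6, 0.25, 0.15).
#'
#' @param U_w ensemble Wasserstein uncertainty (>= 0).
#' @param BC branch completeness in [0, 1].
#' @param delta_beta Betti deviation (>= 0).
#' @param weights length-3 non-negative weights.
#' @return non-negative scalar.
#' @export
macro_uncertainty <- function(U_w, BC, delta_beta,
                              weights = c(0.6, 0.25, 0.15)) {
  stop_if_not(U_w >= 0 && delta_beta >= 0, "inputs must be non-negative")
  stop_if_not(BC >= 0 && BC <= 1, "BC must lie in [0, 1]")
  weights[1] * U_w + weights[2] * (1 - BC) + weights[3] * delta_beta
}

#' Threshold sensitivity of topology metrics
#'
#' Recomputes the extracted graph, Betti numbers, diagrams (and deviation
#' metrics against an optional reference) across a band of vesselness
#' thresholds, reporting one row per threshold plus range statistics.
#'
#' @param img an [image_volume()].
#' @param thresholds numeric vector (length >= 2) of thresholds in (0, 1).
#' @param cfg a [topology_config()] (its threshold field is ignored).
#' @param ref optional reference [vascular_graph()] for Betti deviation and
#'   branch completeness.
#' @return data.frame with one row per threshold and attribute `range`
#'   (per-metric min/max/spread).
#' @export
threshold_sensitivity <- function(img, thresholds, cfg = topology_config(),
                                  ref = NULL) {
  stop_if_not(length(thresholds) >= 2, "need at least two thresholds")
  vm <- vesselness(img, cfg$scales_mm)
  rows <- lapply(thresholds, function(th) {
    g <- extract_graph(img, th, cfg$scales_mm, vessel_map = vm,
                       min_length_mm = cfg$min_length_mm)
    b <- betti_numbers(g)
    pd <- superlevel_persistence(g)
    out <- data.frame(threshold = th, beta0 = b[1], beta1 = b[2],
                      n_edges = nrow(g$edges),
                      total_persistence = total_persistence(pd))
    if (!is.null(ref)) {
      out$betti_deviation <- betti_deviation(g, ref)
      out$branch_completeness <- if (nrow(ref$edges)) {
        branch_completeness(g, ref)
      } else NA_real_
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  num <- tab[, setdiff(names(tab), "threshold"), drop = FALSE]
  attr(tab, "range") <- data.frame(
    metric = names(num),
    min = vapply(num, min, 0), max = vapply(num, max, 0),
    spread = vapply(num, function(z) diff(range(z)), 0))
  tab
}
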