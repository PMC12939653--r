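#' Poiseuille-type edge conductance
#'
#' `g = d^4 / (l + eps)` with proportionality constant 1; the quartic
#' diameter dependence follows laminar-flow scaling and `eps` guards against
#' zero-length segments.
#'
#' @param diameter_mm vessel diameter(s) in mm (>= 0).
#' @param length_mm segment length(s) in mm (>= 0).
#' @param eps numerical stabilizer (default 1e-6).
#' @return conductance value(s) in arbitrary units.
#' @export
edge_conductance <- function(diameter_mm, length_mm, eps = 1e-6) {
  stop_if_not(all(diameter_mm >= 0) && all(length_mm >= 0),
              "diameter and length must be non-negative")
  diameter_mm^4 / (length_mm + eps)
}

#' Solve pressure-driven flow on a vascular graph
#'
#' Solves the conductance-weighted graph Laplacian system with Dirichlet
#' boundary conditions (inlet pressure 1, outlet pressure 0) and returns node
#' pressures and edge flows `g_e * (p_from - p_to)`. Flow is conserved at
#' every internal node.
#'
#' @param g a [vascular_graph()] with positive edge conductances.
#' @param inlets,outlets node ids held at pressure 1 and 0.
#' @return an object of class `flow_solution`: list with `pressures` (named
#'   by node id), `flows` (per edge), `inlets`, `outlets`.
#' @export
solve_graph_flow <- function(g, inlets, outlets) {
  stop_if_not(length(inlets) >= 1 && length(outlets) >= 1,
              "need at least one inlet and one outlet")
  ids <- g$nodes$id
  stop_if_not(all(c(inlets, outlets) %in% ids), "unknown boundary node id")
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(ig)$membership
  ci <- comp[as.character(inlets)]; co <- comp[as.character(outlets)]
  if (!any(ci %in% co)) {
    stop(sprintf("inlets (component %s) and outlets (component %s) are disconnected",
                 paste(unique(ci), collapse = ","),
                 paste(unique(co), collapse = ",")), call. = FALSE)
  }
  n <- length(ids)
  idx <- match(c(g$edges$from, g$edges$to), ids)
  fi <- match(g$edges$from, ids); ti <- match(g$edges$to, ids)
  keep <- g$edges$from != g$edges$to   # self-loops carry no net flow
  gcond <- g$edges$conductance
  L <- Matrix::sparseMatrix(
    i = c(fi[keep], ti[keep], fi[keep], ti[keep]),
    j = c(ti[keep], fi[keep], fi[keep], ti[keep]),
    x = c(-gcond[keep], -gcond[keep], gcond[keep], gcond[keep]),
    dims = c(n, n))
  p <- numeric(n)
  bnd <- match(unique(c(inlets, outlets)), ids)
  p[match(inlets, ids)] <- 1
  p[match(outlets, ids)] <- 0
  interior <- setdiff(seq_len(n), bnd)
  if (length(interior)) {
    rhs <- -L[interior, bnd, drop = FALSE] %*% p[bnd]
    Lii <- L[interior, interior, drop = FALSE]
    # nodes in components without boundary conditions are grounded
    diag_fix <- Matrix::rowSums(abs(Lii)) == 0 &
      abs(rhs) == 0
    if (any(diag_fix)) Lii <- Lii + Matrix::Diagonal(length(interior),
                                                     as.numeric(diag_fix))
    p[interior] <- as.numeric(Matrix::solve(Lii, rhs))
  }
  flows <- ifelse(keep, gcond * (p[fi] - p[ti]), 0)
  structure(list(pressures = stats::setNames(p, ids), flows = flows,
                 inlets = inlets, outlets = outlets),
            class = "flow_solution")
}

#' Default inlet/outlet selection
#'
#' Terminal (degree-1) nodes closest to the declared inlet border become
#' inlets; all other terminal nodes are outlets.
#'
#' @param g a [vascular_graph()].
#' @param border which image border feeds the network
#'   ("left" = minimal x).
#' @param n_inlets number of inlet nodes.
#' @return list with `inlets` and `outlets` (node ids).
#' @export
select_boundary_nodes <- function(g, border = c("left", "right", "bottom", "top"),
                                  n_inlets = 1) {
  border <- match.arg(border)
  deg <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$id))
  term <- g$nodes[deg[as.character(g$nodes$id)] == 1, , drop = FALSE]
  stop_if_not(nrow(term) >= 2, "graph needs at least two terminal nodes")
  key <- switch(border, left = term$x_mm, right = -term$x_mm,
                bottom = term$y_mm, top = -term$y_mm)
  ord <- order(key)
  inl <- term$id[ord[seq_len(min(n_inlets, nrow(term) - 1))]]
  list(inlets = inl, outlets = setdiff(term$id, inl))
}

#' Rasterize graph flow into a smooth voxel velocity field
#'
#' Deposits `flow * unit-tangent` along every edge centerline into the voxel
#' grid and Gaussian-smooths each component; the mapping is linear in the
#' edge flows.
#'
#' @param g a [vascular_graph()].
#' @param flow a [solve_graph_flow()] solution for `g`.
#' @param grid_shape image grid (rows, cols).
#' @param voxel_size_mm voxel size in mm.
#' @param smoothing_sigma_mm Gaussian smoothing in mm (>= 0).
#' @return list with matrices `ux`, `uy` (mm/s per unit pressure drop,
#'   arbitrary flow units).
#' @export
graph_to_velocity_field <- function(g, flow, grid_shape, voxel_size_mm,
                                    smoothing_sigma_mm = 1) {
  stop_if_not(smoothing_sigma_mm >= 0, "smoothing sigma must be >= 0")
  ux <- matrix(0, grid_shape[1], grid_shape[2])
  uy <- matrix(0, grid_shape[1], grid_shape[2])
  cnt <- matrix(0, grid_shape[1], grid_shape[2])
  vox <- voxel_size_mm
  for (k in seq_len(nrow(g$edges))) {
    poly <- g$polylines[[k]]
    if (is.null(poly) || nrow(poly) < 2) next
    f <- flow$flows[k]
    if (f == 0) next
    s <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
    if (s[length(s)] == 0) next
    ss <- seq(0, s[length(s)], by = vox / 2)
    px <- stats::approx(s, poly[, 1], xout = ss)$y
    py <- stats::approx(s, poly[, 2], xout = ss)$y
    np <- length(ss)
    tx <- c(px[2] - px[1], diff(px)); ty <- c(py[2] - py[1], diff(py))
    tn <- pmax(sqrt(tx^2 + ty^2), 1e-12)
    tx <- tx / tn; ty <- ty / tn
    ii <- pmin(pmax(round(px / vox + 0.5), 1), grid_shape[1])
    jj <- pmin(pmax(round(py / vox + 0.5), 1), grid_shape[2])
    for (q in seq_len(np)) {
      ux[ii[q], jj[q]] <- ux[ii[q], jj[q]] + f * tx[q]
      uy[ii[q], jj[q]] <- uy[ii[q], jj[q]] + f * ty[q]
      cnt[ii[q], jj[q]] <- cnt[ii[q], jj[q]] + 1
    }
  }
  nz <- cnt > 0
  ux[nz] <- ux[nz] / cnt[nz]; uy[nz] <- uy[nz] / cnt[nz]
  if (smoothing_sigma_mm > 0) {
    s_px <- max(smoothing_sigma_mm / vox, 0.5)
    ux <- EBImage::gblur(ux, sigma = s_px)
    uy <- EBImage::gblur(uy, sigma = s_px)
  }
  list(ux = ux, uy = uy)
}
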