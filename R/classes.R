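#' Image volume on a regular grid
#'
#' Container for a real- or complex-valued image with physical voxel spacing.
#'
#' @param values numeric or complex matrix.
#' @param voxel_size_mm positive voxel edge length in mm.
#' @param origin_mm physical coordinate of the first voxel center (length 2).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(values, voxel_size_mm = 0.5, origin_mm = c(0, 0)) {
  values <- as.matrix(values)
  stop_if_not(all(is.finite(Re(values))) && all(is.finite(Im(values))),
              "image values must be finite")
  stop_if_not(voxel_size_mm > 0, "voxel_size_mm must be > 0")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %d x %d, voxel %.3g mm, %s\n",
              nrow(x$values), ncol(x$values), x$voxel_size_mm,
              if (is.complex(x$values)) "complex" else "real"))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' k-space measurement
#'
#' Fourier samples on the centered k-space grid. `values` is a full-grid
#' complex matrix that is only meaningful on the support of `mask`.
#'
#' @param values complex matrix (full grid, zero off the mask support).
#' @param mask a [sampling_mask()].
#' @param noise_sigma estimated complex-Gaussian noise std of the samples.
#' @param voxel_size_mm voxel size of the underlying image grid.
#' @return an object of class `kspace_measurement`.
#' @export
kspace_measurement <- function(values, mask, noise_sigma = 0,
                               voxel_size_mm = 0.5) {
  values <- as.matrix(values)
  stop_if_not(inherits(mask, "sampling_mask"), "mask must be a sampling_mask")
  stop_if_not(all(dim(values) == dim(mask$mask)), "value/mask shape mismatch")
  values[!mask$mask] <- 0 + 0i
  structure(list(values = values, mask = mask, noise_sigma = noise_sigma,
                 voxel_size_mm = voxel_size_mm),
            class = "kspace_measurement")
}

#' @export
print.kspace_measurement <- function(x, ...) {
  cat(sprintf("<kspace_measurement> %d x %d, %.1f%% sampled, sigma=%.3g\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$mask$mask), x$noise_sigma))
  invisible(x)
}

#' Vascular graph
#'
#' Spatial graph of a vessel network. Nodes are bifurcations, junctions or
#' terminals with positions in mm; edges are vessel segments annotated with
#' centerline polylines, length, mean diameter, confidence in [0,1] and a
#' Poiseuille-type conductance.
#'
#' @param nodes data.frame with columns `id`, `x_mm`, `y_mm`, `kind`.
#' @param edges data.frame with columns `from`, `to`, `length_mm`,
#'   `diameter_mm`, `confidence`, `conductance`.
#' @param polylines list (one per edge) of 2-column matrices of mm coordinates.
#' @return an object of class `vascular_graph`.
#' @export
vascular_graph <- function(nodes, edges, polylines = NULL) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stop_if_not(all(edges$length_mm >= 0), "edge lengths must be >= 0")
    stop_if_not(all(edges$confidence >= 0 & edges$confidence <= 1),
                "edge confidence must lie in [0,1]")
    stop_if_not(!any(edges$from == edges$to & edges$length_mm == 0),
                "zero-length self-loops are not allowed")
  }
  if (is.null(polylines)) polylines <- vector("list", nrow(edges))
  structure(list(nodes = nodes, edges = edges, polylines = polylines),
            class = "vascular_graph")
}

#' @export
print.vascular_graph <- function(x, ...) {
  b <- betti_numbers(x)
  cat(sprintf("<vascular_graph> %d nodes, %d edges, beta0=%d, beta1=%d\n",
              nrow(x$nodes), nrow(x$edges), b[1], b[2]))
  invisible(x)
}

#' Betti numbers of a vascular graph
#'
#' `beta0` is the number of connected components and `beta1` the cycle rank
#' `|E| - |V| + beta0` of the graph viewed as a 1-complex.
#'
#' @param g a [vascular_graph()].
#' @return integer vector `c(beta0, beta1)`.
#' @export
betti_numbers <- function(g) {
  if (nrow(g$nodes) == 0) return(c(beta0 = 0L, beta1 = 0L))
  ig <- igraph::graph_from_data_frame(
    d = if (nrow(g$edges)) g$edges[, c("from", "to")] else
      data.frame(from = integer(), to = integer()),
    directed = FALSE,
    vertices = data.frame(name = g$nodes$id))
  b0 <- igraph::count_components(ig)
  b1 <- nrow(g$edges) - nrow(g$nodes) + b0
  c(beta0 = as.integer(b0), beta1 = as.integer(b1))
}

#' Persistence diagram
#'
#' Birth-death pairs of a superlevel-set filtration in one homology
#' dimension. Under the superlevel (decreasing threshold) convention
#' `birth >= death` for every finite pair; essential classes never die and
#' carry `death = -Inf`.
#'
#' @param birth,death numeric vectors.
#' @param dim homology dimension, 0 or 1.
#' @return an object of class `persistence_diagram` (a data.frame with
#'   columns `birth`, `death`, `essential` and attribute `dim`).
#' @export
persistence_diagram <- function(birth = numeric(), death = numeric(), dim = 0) {
  essential <- is.infinite(death) & death < 0
  fin <- !essential
  stop_if_not(all(birth[fin] >= death[fin]),
              "superlevel diagrams require birth >= death")
  d <- data.frame(birth = as.numeric(birth), death = as.numeric(death),
                  essential = essential)
  attr(d, "homdim") <- as.integer(dim)
  class(d) <- c("persistence_diagram", "data.frame")
  d
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> dim %d, %d pairs (%d essential)\n",
              attr(x, "homdim"), nrow(x), sum(x$essential)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
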