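# Shared fixtures, all generated in code.

small_phantom <- function(seed = 3, loops = 2, grid = 96) {
  generate_vascular_phantom(phantom_spec(
    grid_shape = c(grid, grid), voxel_size_mm = 0.5, n_main_branches = 5,
    n_collateral_loops = loops, diameter_range_mm = c(0.8, 2.5),
    branch_contrast = 4, seed = seed))
}

# hand-built toy graphs ------------------------------------------------------

# single straight edge with given confidence
toy_edge_graph <- function(conf = 0.9, len = 10) {
  vascular_graph(
    nodes = data.frame(id = 1:2, x_mm = c(0, len), y_mm = 0,
                       kind = "terminal"),
    edges = data.frame(from = 1, to = 2, length_mm = len, diameter_mm = 1,
                       confidence = conf, conductance = 1),
    polylines = list(cbind(c(0, len), c(0, 0))))
}

# two disjoint edges joined by a low-confidence bridge
toy_bridge_graph <- function(confs = c(0.9, 0.8, 0.4)) {
  vascular_graph(
    nodes = data.frame(id = 1:4, x_mm = c(0, 1, 2, 3), y_mm = 0,
                       kind = c("terminal", "junction", "junction", "terminal")),
    edges = data.frame(from = c(1, 3, 2), to = c(2, 4, 3), length_mm = 1,
                       diameter_mm = 1,
                       confidence = confs, conductance = 1),
    polylines = list(cbind(0:1, 0), cbind(2:3, 0), cbind(1:2, 0)))
}

# triangle (single cycle)
toy_triangle_graph <- function(confs = c(0.9, 0.8, 0.5)) {
  vascular_graph(
    nodes = data.frame(id = 1:3, x_mm = c(0, 1, 0.5), y_mm = c(0, 0, 1),
                       kind = "junction"),
    edges = data.frame(from = c(1, 2, 3), to = c(2, 3, 1), length_mm = 1,
                       diameter_mm = 1, confidence = confs, conductance = 1),
    polylines = list(cbind(c(0, 1), c(0, 0)), cbind(c(1, 0.5), c(0, 1)),
                     cbind(c(0.5, 0), c(1, 0))))
}

# random small graph with random confidences (possibly several components)
random_toy_graph <- function(n_nodes = 6, n_edges = 8, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(n_nodes, 2))
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ,
                drop = FALSE]
  vascular_graph(
    nodes = data.frame(id = seq_len(n_nodes),
                       x_mm = runif(n_nodes, 0, 10),
                       y_mm = runif(n_nodes, 0, 10), kind = "junction"),
    edges = data.frame(from = pick[, 1], to = pick[, 2],
                       length_mm = runif(nrow(pick), 1, 5),
                       diameter_mm = 1,
                       confidence = round(runif(nrow(pick), 0.1, 0.99), 3),
                       conductance = 1))
}

random_diagram <- function(n = 3, seed = 1, dim = 0) {
  set.seed(seed)
  b <- runif(n, 0.3, 1)
  d <- b - runif(n, 0.01, 0.3)
  persistence_diagram(b, d, dim = dim)
}

# brute-force oracles --------------------------------------------------------

# components and cycle rank of the superlevel subgraph at threshold t
subgraph_betti_at <- function(g, t) {
  keep <- g$edges$confidence >= t
  e <- g$edges[keep, , drop = FALSE]
  used <- unique(c(e$from, e$to))
  if (!length(used)) return(c(0L, 0L))
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                      vertices = data.frame(name = used))
  b0 <- igraph::count_components(ig)
  c(b0, nrow(e) - length(used) + b0)
}

# exhaustive Wasserstein for diagrams with <= 2 finite points each:
# enumerate all partial matchings (points matched across or to the diagonal)
brute_wasserstein_finite <- function(d1, d2, q = 2) {
  f1 <- d1[!d1$essential, c("birth", "death"), drop = FALSE]
  f2 <- d2[!d2$essential, c("birth", "death"), drop = FALSE]
  n <- nrow(f1); m <- nrow(f2)
  dd <- function(p) abs(p[1] - p[2]) / 2
  dpt <- function(p1, p2) max(abs(p1[1] - p2[1]), abs(p1[2] - p2[2]))
  best <- Inf
  # enumerate injective partial maps from subsets of 1..n into 1..m
  subsets <- function(v) {
    if (!length(v)) return(list(integer()))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (S in subsets(seq_len(n))) {
    if (length(S) > m) next
    targets <- if (m) utils::combn(m, length(S), simplify = FALSE) else list(integer())
    if (!length(S)) targets <- list(integer())
    for (Tset in targets) {
      for (Tp in perms(Tset)) {
        cost <- 0
        for (k in seq_along(S)) {
          cost <- cost + dpt(as.numeric(f1[S[k], ]), as.numeric(f2[Tp[k], ]))^q
        }
        for (i in setdiff(seq_len(n), S)) cost <- cost + dd(as.numeric(f1[i, ]))^q
        for (j in setdiff(seq_len(m), Tp)) cost <- cost + dd(as.numeric(f2[j, ]))^q
        best <- min(best, cost)
      }
    }
  }
  best^(1 / q)
}
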