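#' Superlevel-set persistence of a vascular graph
#'
#' Computes dimension-0 and dimension-1 persistence diagrams of the
#' superlevel-set filtration of edge confidence on the graph viewed as a
#' 1-complex: as the threshold decreases from 1, each edge enters at its
#' confidence and nodes enter with their first incident edge. Components are
#' paired by the elder rule (at a merge the component with the higher birth
#' survives; ties broken by lowest entering edge index); each independent
#' cycle creates an essential dimension-1 class born at the minimum
#' confidence along the cycle. Surviving components are essential
#' dimension-0 classes (death `-Inf`).
#'
#' @param g a [vascular_graph()] with edge confidences in [0, 1].
#' @return list with elements `dim0` and `dim1`, both
#'   [persistence_diagram()] objects.
#' @export
superlevel_persistence <- function(g) {
  ne <- nrow(g$edges)
  if (ne == 0) {
    return(list(dim0 = persistence_diagram(dim = 0),
                dim1 = persistence_diagram(dim = 1)))
  }
  conf <- g$edges$confidence
  ord <- order(-conf, seq_len(ne))        # decreasing confidence, index ties
  ids <- g$nodes$id
  parent <- seq_along(ids)
  birth_val <- rep(NA_real_, length(ids))  # component birth (confidence)
  birth_idx <- rep(NA_integer_, length(ids))
  node_row <- match(ids, ids)
  names(parent) <- ids
  lookup <- function(id) match(id, ids)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  b0_birth <- numeric(); b0_death <- numeric()
  b1_birth <- numeric()
  for (k in ord) {
    t <- conf[k]
    a <- lookup(g$edges$from[k]); b <- lookup(g$edges$to[k])
    # nodes enter with their first incident edge
    if (is.na(birth_val[find(a)])) { birth_val[a] <- t; birth_idx[a] <- k }
    if (is.na(birth_val[find(b)])) { birth_val[b] <- t; birth_idx[b] <- k }
    ra <- find(a); rb <- find(b)
    if (ra == rb) {
      # closing edge of an independent cycle: essential class born here
      b1_birth <- c(b1_birth, t)
    } else {
      # elder rule: keep the older (higher birth) component
      elder_a <- (birth_val[ra] > birth_val[rb]) ||
        (birth_val[ra] == birth_val[rb] && birth_idx[ra] <= birth_idx[rb])
      if (!elder_a) { tmp <- ra; ra <- rb; rb <- tmp }
      b0_birth <- c(b0_birth, birth_val[rb])
      b0_death <- c(b0_death, t)
      parent[rb] <- ra
    }
  }
  roots <- unique(vapply(seq_along(ids), function(i) find(i), 0L))
  roots <- roots[!is.na(birth_val[roots])]
  # drop zero-persistence pairs (both endpoints entering with the merging
  # edge create a component that dies instantly)
  keep <- b0_birth > b0_death
  d0 <- persistence_diagram(
    birth = c(b0_birth[keep], birth_val[roots]),
    death = c(b0_death[keep], rep(-Inf, length(roots))),
    dim = 0)
  d1 <- persistence_diagram(birth = b1_birth,
                            death = rep(-Inf, length(b1_birth)), dim = 1)
  list(dim0 = d0, dim1 = d1)
}

#' Total persistence of a diagram
#'
#' Sum of `|birth - death|` over finite pairs plus the births of essential
#' classes; used as the default normalizer of [persistence_stability()].
#'
#' @param d a [persistence_diagram()] or list of diagrams.
#' @return non-negative scalar.
#' @export
total_persistence <- function(d) {
  if (!inherits(d, "persistence_diagram") && is.list(d)) {
    return(sum(vapply(d, total_persistence, 0)))
  }
  if (!nrow(d)) return(0)
  sum(ifelse(d$essential, abs(d$birth), abs(d$birth - d$death)))
}
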