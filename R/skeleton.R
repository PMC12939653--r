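# Morphological skeletonization and skeleton-to-graph tracing.

# zero-padded shift of a logical/numeric matrix
shiftm <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  si <- max(1, 1 + di):min(n1, n1 + di)
  sj <- max(1, 1 + dj):min(n2, n2 + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
# with rows = first axis (i increasing "south")
zs_offsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

#' Skeletonize a binary segmentation
#'
#' Zhang-Suen thinning to a one-pixel-wide 8-connected centerline.
#'
#' @param seg logical matrix (foreground TRUE).
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(seg) {
  img <- matrix(as.numeric(seg), nrow(seg), ncol(seg))
  for (iter in seq_len(200)) {
    changed <- FALSE
    for (pass in 1:2) {
      p <- lapply(zs_offsets, function(o) shiftm(img, -o[1], -o[2]))
      B <- Reduce(`+`, p)
      seqp <- c(p, p[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k) {
        (seqp[[k]] == 0) & (seqp[[k + 1]] == 1)
      }))
      if (pass == 1) {
        c3 <- p[[1]] * p[[3]] * p[[5]] == 0   # P2*P4*P6
        c4 <- p[[3]] * p[[5]] * p[[7]] == 0   # P4*P6*P8
      } else {
        c3 <- p[[1]] * p[[3]] * p[[7]] == 0   # P2*P4*P8
        c4 <- p[[1]] * p[[5]] * p[[7]] == 0   # P2*P6*P8
      }
      del <- img == 1 & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) { img[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1
}

# label 8-connected components of a sparse logical mask by BFS
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  px <- which(mask, arr.ind = TRUE)
  nextlab <- 0L
  n1 <- nrow(mask); n2 <- ncol(mask)
  for (q in seq_len(nrow(px))) {
    i0 <- px[q, 1]; j0 <- px[q, 2]
    if (lab[i0, j0] > 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nextlab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in zs_offsets) {
        ii <- p[1] + o[1]; jj <- p[2] + o[2]
        if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 &&
            mask[ii, jj] && lab[ii, jj] == 0) {
          lab[ii, jj] <- nextlab
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  list(labels = lab, n = nextlab)
}

skel_neighbors <- function(skel, i, j) {
  n1 <- nrow(skel); n2 <- ncol(skel)
  out <- list()
  for (o in zs_offsets) {
    ii <- i + o[1]; jj <- j + o[2]
    if (ii >= 1 && ii <= n1 && jj >= 1 && jj <= n2 && skel[ii, jj]) {
      out[[length(out) + 1]] <- c(ii, jj)
    }
  }
  out
}

#' Extract a vascular graph from an intensity image
#'
#' Pipeline: multi-scale vesselness, threshold segmentation, thinning to a
#' centerline skeleton, and tracing into a spatial graph. Nodes are skeleton
#' pixels of degree not equal to 2 (merged into clusters at junctions);
#' edges carry the centerline polyline, arclength, diameter (twice the mean
#' distance-transform value along the centerline) and confidence (mean
#' vesselness along the centerline).
#'
#' @param img an [image_volume()].
#' @param vesselness_threshold threshold in (0, 1) applied to the normalized
#'   vesselness response.
#' @param scales_mm vesselness scales (passed to [vesselness()]).
#' @param vessel_map optionally a precomputed [vesselness()] response to
#'   avoid recomputation.
#' @param min_length_mm if positive, the result is pruned with
#'   [prune_graph()].
#' @param low_fraction hysteresis: pixels above `low_fraction *
#'   vesselness_threshold` are kept when connected to an above-threshold
#'   region.
#' @return a [vascular_graph()] (empty if the segmentation is empty).
#' @export
extract_graph <- function(img, vesselness_threshold = 0.12,
                          scales_mm = c(0.5, 1, 1.5, 2), vessel_map = NULL,
                          min_length_mm = 0, low_fraction = 0.5) {
  stop_if_not(vesselness_threshold > 0 && vesselness_threshold < 1,
              "vesselness_threshold must lie in (0, 1)")
  vox <- img$voxel_size_mm
  v <- if (is.null(vessel_map)) vesselness(img, scales_mm) else vessel_map
  # hysteresis segmentation: keep weaker responses only when connected to a
  # confidently vascular region, which stabilizes the graph against small
  # perturbations of the response around a single threshold
  seg_low <- v$values >= low_fraction * vesselness_threshold
  if (any(seg_low)) {
    lab <- EBImage::bwlabel(matrix(as.numeric(seg_low), nrow(seg_low),
                                   ncol(seg_low)))
    # a component needs a multi-pixel strong core, not a single pixel
    # grazing the threshold, to count as vascular
    strong_lab <- lab[v$values >= vesselness_threshold]
    counts <- table(strong_lab[strong_lab > 0])
    strong <- as.integer(names(counts)[counts >= 3])
    seg <- matrix(lab %in% strong, nrow(seg_low), ncol(seg_low))
  } else {
    seg <- seg_low
  }
  empty <- vascular_graph(
    data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
               kind = character()),
    data.frame(from = integer(), to = integer(), length_mm = numeric(),
               diameter_mm = numeric(), confidence = numeric(),
               conductance = numeric()))
  if (!any(seg)) return(empty)
  skel <- skeletonize(seg)
  if (!any(skel)) return(empty)
  dist_px <- as.matrix(EBImage::distmap(matrix(as.numeric(seg),
                                               nrow(seg), ncol(seg))))
  g <- trace_skeleton(skel, vox, v$values, dist_px)
  if (min_length_mm > 0) g <- prune_graph(g, min_length_mm)
  g
}

# convert a skeleton into nodes (degree != 2 pixel clusters) and traced edges
trace_skeleton <- function(skel, vox, vmap, dist_px) {
  n1 <- nrow(skel); n2 <- ncol(skel)
  # crossing number: 0->1 transitions in the 8-neighbour ring, i.e. the
  # number of distinct branches leaving the pixel (robust to staircases)
  pn <- lapply(zs_offsets, function(o) shiftm(skel * 1, -o[1], -o[2]))
  seqp <- c(pn, pn[1])
  cross <- Reduce(`+`, lapply(seq_len(8), function(k) {
    (seqp[[k]] == 0) & (seqp[[k + 1]] == 1)
  }))
  node_mask <- skel & cross != 2
  lab8 <- label8(node_mask)
  labels <- lab8$labels
  n_clust <- lab8$n
  visited <- matrix(FALSE, n1, n2)
  edges <- list()
  add_edge <- function(c1, c2, path) {
    pts <- do.call(rbind, path)
    poly <- cbind((pts[, 1] - 0.5) * vox, (pts[, 2] - 0.5) * vox)
    len <- poly_length(poly)
    # mild interior smoothing removes the pixel staircase from the
    # centerline geometry (endpoints kept fixed)
    if (nrow(poly) >= 5) {
      int <- 2:(nrow(poly) - 1)
      poly[int, 1] <- (poly[int - 1, 1] + poly[int, 1] + poly[int + 1, 1]) / 3
      poly[int, 2] <- (poly[int - 1, 2] + poly[int, 2] + poly[int + 1, 2]) / 3
    }
    dia <- 2 * mean(dist_px[pts]) * vox
    conf <- min(1, mean(vmap[pts]))
    edges[[length(edges) + 1]] <<- list(from = c1, to = c2, poly = poly,
                                        length_mm = len, diameter_mm = dia,
                                        confidence = conf)
  }
  direct_pairs <- character()

  node_px <- which(node_mask, arr.ind = TRUE)
  for (q in seq_len(nrow(node_px))) {
    i <- node_px[q, 1]; j <- node_px[q, 2]
    c1 <- labels[i, j]
    for (p in skel_neighbors(skel, i, j)) {
      lp <- labels[p[1], p[2]]
      if (lp > 0) {
        if (lp != c1) {   # direct cluster-to-cluster adjacency
          key <- paste(sort(c(c1, lp)), collapse = "-")
          if (!(key %in% direct_pairs)) {
            direct_pairs <- c(direct_pairs, key)
            add_edge(c1, lp, list(c(i, j), p))
          }
        }
        next
      }
      if (visited[p[1], p[2]]) next
      # walk along degree-2 pixels until the next node cluster
      path <- list(c(i, j), p)
      prev <- c(i, j); cur <- p
      end_walk <- function() {
        # dead end: promote the last pixel to a terminal node
        if (labels[cur[1], cur[2]] == 0) {
          n_clust <<- n_clust + 1L
          labels[cur[1], cur[2]] <<- n_clust
          node_mask[cur[1], cur[2]] <<- TRUE
        }
        add_edge(c1, labels[cur[1], cur[2]], path)
      }
      repeat {
        visited[cur[1], cur[2]] <- TRUE
        nbrs <- skel_neighbors(skel, cur[1], cur[2])
        nbrs <- Filter(function(z) !(z[1] == prev[1] && z[2] == prev[2]), nbrs)
        # drop neighbours already on the recent path (8-connectivity slack)
        if (length(path) >= 2) {
          pen <- path[[length(path) - 1]]
          nbrs <- Filter(function(z) !(z[1] == pen[1] && z[2] == pen[2]), nbrs)
        }
        if (!length(nbrs)) { end_walk(); break }
        labs <- vapply(nbrs, function(z) labels[z[1], z[2]], 0L)
        term <- which(labs > 0 & (labs != c1 | length(path) >= 4))
        if (length(term)) {
          e <- nbrs[[term[1]]]
          path[[length(path) + 1]] <- e
          add_edge(c1, labs[term[1]], path)
          break
        }
        nxt_i <- which(labs == 0 & !vapply(nbrs, function(z) visited[z[1], z[2]], TRUE))
        if (!length(nxt_i)) { end_walk(); break }
        cand <- nbrs[nxt_i]
        orth <- vapply(cand, function(z) sum(abs(z - cur)) == 1, TRUE)
        nxt <- if (any(orth)) cand[orth][[1]] else cand[[1]]
        path[[length(path) + 1]] <- nxt
        prev <- cur; cur <- nxt
      }
    }
  }

  # pure cycles: untouched degree-2 pixels form rings with no nodes
  remaining <- skel & !node_mask & !visited
  rem_px <- which(remaining, arr.ind = TRUE)
  for (q in seq_len(nrow(rem_px))) {
    i <- rem_px[q, 1]; j <- rem_px[q, 2]
    if (visited[i, j]) next
    n_clust <- n_clust + 1L
    labels[i, j] <- n_clust
    node_mask[i, j] <- TRUE
    start <- c(i, j)
    nbrs <- skel_neighbors(skel, i, j)
    nbrs <- Filter(function(z) labels[z[1], z[2]] == 0 && !visited[z[1], z[2]], nbrs)
    if (!length(nbrs)) next
    path <- list(start, nbrs[[1]])
    prev <- start; cur <- nbrs[[1]]
    repeat {
      visited[cur[1], cur[2]] <- TRUE
      nbrs2 <- skel_neighbors(skel, cur[1], cur[2])
      nbrs2 <- Filter(function(z) !(z[1] == prev[1] && z[2] == prev[2]), nbrs2)
      if (length(path) >= 2) {
        pen <- path[[length(path) - 1]]
        nbrs2 <- Filter(function(z) !(z[1] == pen[1] && z[2] == pen[2]), nbrs2)
      }
      back <- vapply(nbrs2, function(z) z[1] == start[1] && z[2] == start[2],
                     TRUE)
      if (any(back) && length(path) >= 4) {
        path[[length(path) + 1]] <- start
        add_edge(n_clust, n_clust, path)
        break
      }
      cand <- nbrs2[!vapply(nbrs2, function(z) visited[z[1], z[2]], TRUE)]
      if (!length(cand)) {
        # open arc: keep it as an edge to a new terminal cluster
        if (length(path) >= 3 && labels[cur[1], cur[2]] == 0) {
          n_clust <- n_clust + 1L
          labels[cur[1], cur[2]] <- n_clust
          node_mask[cur[1], cur[2]] <- TRUE
          add_edge(labels[start[1], start[2]], n_clust, path)
        }
        break
      }
      # prefer 4-adjacent steps to avoid diagonal shortcuts across the path
      orth <- vapply(cand, function(z) sum(abs(z - cur)) == 1, TRUE)
      nxt <- if (any(orth)) cand[orth][[1]] else cand[[1]]
      path[[length(path) + 1]] <- nxt
      prev <- cur; cur <- nxt
    }
  }

  # assemble node table from cluster centroids
  if (!length(edges)) {
    return(vascular_graph(
      data.frame(id = integer(), x_mm = numeric(), y_mm = numeric(),
                 kind = character()),
      data.frame(from = integer(), to = integer(), length_mm = numeric(),
                 diameter_mm = numeric(), confidence = numeric(),
                 conductance = numeric())))
  }
  used <- sort(unique(c(vapply(edges, `[[`, 0L, "from"),
                        vapply(edges, `[[`, 0L, "to"))))
  cent <- matrix(NA_real_, n_clust, 2)
  for (cid in used) {
    px <- which(labels == cid, arr.ind = TRUE)
    cent[cid, ] <- c(mean((px[, 1] - 0.5) * vox), mean((px[, 2] - 0.5) * vox))
  }
  deg <- integer(n_clust)
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  kind <- ifelse(deg <= 1, "terminal", ifelse(deg == 3, "bifurcation", "junction"))
  nodes_df <- data.frame(id = used, x_mm = cent[used, 1], y_mm = cent[used, 2],
                         kind = kind[used], stringsAsFactors = FALSE)
  if (length(edges)) {
    edges_df <- data.frame(
      from = vapply(edges, `[[`, 0L, "from"),
      to = vapply(edges, `[[`, 0L, "to"),
      length_mm = vapply(edges, `[[`, 0, "length_mm"),
      diameter_mm = vapply(edges, `[[`, 0, "diameter_mm"),
      confidence = vapply(edges, `[[`, 0, "confidence"))
    edges_df$conductance <- edge_conductance(edges_df$diameter_mm,
                                             edges_df$length_mm)
    polys <- lapply(edges, `[[`, "poly")
  } else {
    edges_df <- data.frame(from = integer(), to = integer(),
                           length_mm = numeric(), diameter_mm = numeric(),
                           confidence = numeric(), conductance = numeric())
    polys <- list()
  }
  vascular_graph(nodes_df, edges_df, polys)
}

#' Prune short spurs and small components from a vascular graph
#'
#' Iteratively removes terminal spur edges shorter than `min_length_mm` and
#' connected components whose total length is below the threshold, repeating
#' to a fixpoint. Edges participating in cycles are never removed.
#'
#' @param g a [vascular_graph()].
#' @param min_length_mm physical pruning length (default 2.5 mm).
#' @return the pruned [vascular_graph()].
#' @export
prune_graph <- function(g, min_length_mm = 2.5) {
  stop_if_not(min_length_mm >= 0, "min_length_mm must be >= 0")
  repeat {
    if (!nrow(g$edges)) break
    deg <- integer(max(g$nodes$id))
    for (k in seq_len(nrow(g$edges))) {
      deg[g$edges$from[k]] <- deg[g$edges$from[k]] + 1L
      deg[g$edges$to[k]] <- deg[g$edges$to[k]] + 1L
    }
    is_spur <- (deg[g$edges$from] == 1 | deg[g$edges$to] == 1) &
      g$edges$length_mm < min_length_mm & g$edges$from != g$edges$to
    # skeletonization artifacts: short self-loops and the shorter member of
    # short parallel edge pairs form sub-threshold cycles, not collaterals
    tiny_self <- g$edges$from == g$edges$to & g$edges$length_mm < min_length_mm
    tiny_par <- rep(FALSE, nrow(g$edges))
    key <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
    for (kk in unique(key[duplicated(key)])) {
      grp <- which(key == kk)
      ord_g <- grp[order(g$edges$length_mm[grp])]
      cyc_len <- g$edges$length_mm[ord_g[1]] + min(g$edges$length_mm[ord_g[-1]])
      if (cyc_len < 2 * min_length_mm) tiny_par[ord_g[seq_len(length(ord_g) - 1)]] <- TRUE
    }
    is_spur <- is_spur | tiny_self | tiny_par
    # components with total length below threshold
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        directed = FALSE,
                                        vertices = data.frame(name = g$nodes$id))
    comp <- igraph::components(ig)$membership
    ecomp <- comp[as.character(g$edges$from)]
    comp_len <- tapply(g$edges$length_mm, ecomp, sum)
    # cycle rank per component: components carrying cycles are never removed
    comp_edges <- tapply(seq_along(ecomp), ecomp, length)
    comp_nodes <- table(comp)
    cyc <- comp_edges - comp_nodes[names(comp_edges)] + 1
    small_comp <- names(comp_len)[comp_len < min_length_mm &
                                    cyc[names(comp_len)] <= 0]
    in_small <- ecomp %in% as.integer(small_comp)
    drop <- is_spur | in_small
    if (!any(drop)) break
    g <- subset_graph(g, !drop)
  }
  g
}

# keep edges by logical index, dropping now-isolated nodes and refreshing
# node kinds from the new degrees
subset_graph <- function(g, keep) {
  edges <- g$edges[keep, , drop = FALSE]
  polys <- g$polylines[keep]
  used <- sort(unique(c(edges$from, edges$to)))
  nodes <- g$nodes[g$nodes$id %in% used, , drop = FALSE]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$kind <- ifelse(deg[as.character(nodes$id)] <= 1, "terminal",
                       ifelse(deg[as.character(nodes$id)] == 3,
                              "bifurcation", "junction"))
  rownames(edges) <- NULL; rownames(nodes) <- NULL
  vascular_graph(nodes, edges, polys)
}
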