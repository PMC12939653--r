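# Exact linear assignment (square cost matrix) by shortest augmenting paths
# (Jonker-Volgenant style). Used for optimal partial matching of persistence
# diagrams; cost matrices here are small (tens of points).
lap_solve <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(list(assignment = integer(), cost = 0))
  stopifnot(ncol(cost) == n)
  BIG <- max(cost[is.finite(cost)], 0) * n + 1
  cost[!is.finite(cost)] <- BIG * 2
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1               # columns are offset by 1 (index 1 = virtual)
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in seq_len(n) + 1) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n) + 1) if (p[j] > 0) assignment[p[j]] <- j - 1
  total <- sum(cost[cbind(seq_len(n), assignment)])
  list(assignment = assignment, cost = total)
}

# L-infinity ground distance between diagram points
linf_dist <- function(p1, p2) pmax(abs(p1[1] - p2[1]), abs(p1[2] - p2[2]))

#' Wasserstein distance between persistence diagrams
#'
#' Optimal partial matching between two diagrams of the same homology
#' dimension: finite points may be matched to each other or to the diagonal
#' (at L-infinity cost `|birth - death| / 2`), with matching cost aggregated
#' by the q-norm. Essential classes are matched separately by birth in
#' decreasing order; unmatched essential classes are penalized by their
#' birth distance to `essential_penalty_ref` (default 0).
#'
#' @param d1,d2 [persistence_diagram()] objects of the same dimension.
#' @param q matching order (q-norm aggregation), default 2.
#' @param essential_penalty_ref reference value for unmatched essential
#'   classes.
#' @return non-negative scalar; 0 iff the diagrams are equal.
#' @export
wasserstein_distance <- function(d1, d2, q = 2, essential_penalty_ref = 0) {
  stop_if_not(attr(d1, "homdim") == attr(d2, "homdim"),
              "diagrams have different homology dimensions")
  # essential classes: match by decreasing birth
  e1 <- sort(d1$birth[d1$essential], decreasing = TRUE)
  e2 <- sort(d2$birth[d2$essential], decreasing = TRUE)
  nmin <- min(length(e1), length(e2))
  ecosts <- abs(e1[seq_len(nmin)] - e2[seq_len(nmin)])
  if (length(e1) > nmin) ecosts <- c(ecosts, abs(e1[-seq_len(nmin)] - essential_penalty_ref))
  if (length(e2) > nmin) ecosts <- c(ecosts, abs(e2[-seq_len(nmin)] - essential_penalty_ref))
  # finite points: optimal partial matching with the diagonal
  f1 <- d1[!d1$essential, c("birth", "death"), drop = FALSE]
  f2 <- d2[!d2$essential, c("birth", "death"), drop = FALSE]
  n <- nrow(f1); m <- nrow(f2)
  fcost <- 0
  if (n + m > 0) {
    size <- n + m
    C <- matrix(0, size, size)
    if (n > 0 && m > 0) {
      for (i in seq_len(n)) for (j in seq_len(m)) {
        C[i, j] <- linf_dist(as.numeric(f1[i, ]), as.numeric(f2[j, ]))^q
      }
    }
    diag1 <- abs(f1$birth - f1$death) / 2
    diag2 <- abs(f2$birth - f2$death) / 2
    if (n > 0) {
      C[seq_len(n), m + seq_len(n)] <- Inf
      C[cbind(seq_len(n), m + seq_len(n))] <- diag1^q
    }
    if (m > 0) {
      C[n + seq_len(m), seq_len(m)] <- Inf
      C[cbind(n + seq_len(m), seq_len(m))] <- diag2^q
    }
    # diagonal-to-diagonal pairs cost 0 (bottom-right block already 0)
    fcost <- lap_solve(C)$cost
  }
  (fcost + sum(ecosts^q))^(1 / q)
}
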