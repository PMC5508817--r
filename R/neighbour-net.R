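#' Neighbour-net circular taxon ordering
#'
#' Agglomerative selection after Bryant & Moulton: clusters (initially
#' singletons, afterwards linked node pairs) are repeatedly merged by the
#' neighbour-joining Q-criterion computed on cluster-averaged distances;
#' within the chosen cluster pair the nodes to link are picked by a second
#' Q-criterion over the expanded element set, and three linked nodes are
#' reduced to two with the standard 2/3-1/3 distance-reduction scheme.
#' Expansion of the surviving path yields a circular ordering of all taxa.
#' Ties are broken toward the lowest pair index.
#'
#' @param d an [osm_dist] (n >= 2; for n <= 3 the input order is returned).
#' @return integer permutation of taxon indices (the circular order).
#' @export
nnet_ordering <- function(d) {
  v <- d$values
  if (anyNA(v)) stop("neighbour-net requires fully defined distances",
                     call. = FALSE)
  n <- length(d$taxa)
  if (n <= 3L) return(seq_len(n))
  work <- v                       # node-level distances, grows obsolete slots
  CL <- as.list(seq_len(n))       # path-end nodes per cluster (length <= 2)
  paths <- as.list(seq_len(n))    # expanded taxon path per cluster
  DM <- v                         # cluster-averaged distances
  while (length(CL) > 1L) {
    m <- nrow(DM)
    if (m > 2L) {
      r <- rowSums(DM) / (m - 2)
      q <- DM - outer(r, r, "+")
      diag(q) <- Inf
      sel <- which(q == min(q), arr.ind = TRUE)
      sel <- sel[order(pmin(sel[, 1], sel[, 2]), pmax(sel[, 1], sel[, 2])), ,
                 drop = FALSE]
      e1 <- min(sel[1, ]); e2 <- max(sel[1, ])
    } else {
      e1 <- 1L; e2 <- 2L
    }
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])
    if (n1 == 1L && n2 == 1L) {
      new_nodes <- c(CL[[e1]], CL[[e2]])
      new_path <- c(paths[[e1]], paths[[e2]])
    } else {
      # second selection: nodes of both clusters individually, all other
      # clusters as averaged units
      nodes <- c(CL[[e1]], CL[[e2]])
      others <- CL[-c(e1, e2)]
      m2 <- length(nodes) + length(others)
      rr <- node_net_divergence(work, nodes, others)
      if (m2 > 2L) rr <- rr / (m2 - 2)
      qn <- work[nodes, nodes, drop = FALSE] - outer(rr, rr, "+")
      sub <- qn[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
      pick <- which.min(sub)            # column-major: ties -> lowest index
      a <- (pick - 1L) %% n1 + 1L       # node position in CL[[e1]]
      b <- (pick - 1L) %/% n1 + 1L      # node position in CL[[e2]]
      # orient both paths so the linked nodes are adjacent, then reduce the
      # merged path back to two end nodes
      x <- CL[[e1]]; y <- CL[[e2]]
      px <- paths[[e1]]; py <- paths[[e2]]
      if (n1 == 2L && a == 1L) { x <- rev(x); px <- rev(px) }
      if (n2 == 2L && b == 2L) { y <- rev(y); py <- rev(py) }
      new_path <- c(px, py)
      if (n1 + n2 == 3L) {
        mid <- if (n1 == 2L) x[2] else y[1]
        ends <- c(if (n1 == 2L) x[1] else x, if (n2 == 2L) y[2] else y)
        work <- reduce_triple(work, ends[1], mid, ends[2])
        new_nodes <- ends
      } else {                          # 2 + 2: reduce twice
        work <- reduce_triple(work, x[1], x[2], y[1])
        work <- reduce_triple(work, x[1], y[1], y[2])
        new_nodes <- c(x[1], y[2])
      }
    }
    CL[[e1]] <- new_nodes
    paths[[e1]] <- new_path
    CL <- CL[-e2]
    paths <- paths[-e2]
    DM <- DM[-e2, -e2, drop = FALSE]
    j <- if (e2 < e1) e1 - 1L else e1
    for (i in seq_along(CL)) {
      DM[i, j] <- DM[j, i] <- mean(work[CL[[i]], CL[[j]]])
    }
    DM[j, j] <- 0
  }
  paths[[1L]]
}

# net divergence of each listed node against the other nodes plus the
# cluster-averaged remainder
node_net_divergence <- function(work, nodes, others) {
  vapply(seq_along(nodes), function(i) {
    xi <- nodes[i]
    s <- sum(work[xi, nodes[-i]])
    if (length(others)) {
      s <- s + sum(vapply(others, function(cl) mean(work[xi, cl]),
                          numeric(1)))
    }
    s
  }, numeric(1))
}

# replace path x - y - z by two nodes kept in slots x and z
reduce_triple <- function(d, x, y, z) {
  u <- (2 / 3) * d[x, ] + d[y, ] / 3
  v <- (2 / 3) * d[z, ] + d[y, ] / 3
  uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
  d[x, ] <- u; d[, x] <- u
  d[z, ] <- v; d[, z] <- v
  d[y, ] <- 0; d[, y] <- 0
  d[x, z] <- d[z, x] <- uv
  d[x, x] <- d[z, z] <- 0
  d
}

#' Non-negative least-squares split weights for a circular ordering
#'
#' Builds the `n(n-1)/2` candidate interval splits of the ordering, fits
#' non-negative weights by least squares against the observed distances
#' (active-set algorithm), and drops splits whose weight falls at or below
#' `threshold`.
#'
#' @param d an [osm_dist].
#' @param order circular ordering (integer permutation), e.g. from
#'   [nnet_ordering].
#' @param threshold minimum retained weight (default 1e-8).
#' @return a circular [split_system]; the fitted residual norm is attached
#'   as attribute `rss`.
#' @export
estimate_split_weights <- function(d, order = nnet_ordering(d),
                                   threshold = 1e-8) {
  n <- length(d$taxa)
  cand <- circular_interval_splits(order)
  A <- splits_design_matrix(cand, n)
  y <- d$values[lower.tri(d$values)]
  if (anyNA(y)) stop("undefined distances; cannot fit split weights",
                     call. = FALSE)
  w <- nnls_fit(A, y)
  rss <- sum((y - A %*% w)^2)
  keep <- which(w > threshold)
  s <- split_system(d$taxa, cand[keep], w[keep], kind = "circular",
                    cycle = order)
  attr(s, "rss") <- rss
  s
}

#' Infer a neighbour-net split system from distances
#'
#' Convenience wrapper: [nnet_ordering] followed by
#' [estimate_split_weights].
#'
#' @inheritParams estimate_split_weights
#' @return a circular [split_system].
#' @export
neighbour_net <- function(d, threshold = 1e-8) {
  estimate_split_weights(d, nnet_ordering(d), threshold)
}

# rows = taxon pairs (lower triangle order), columns = splits;
# 1 where the split separates the pair
splits_design_matrix <- function(splits, n) {
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), length(splits))
  for (s in seq_along(splits)) {
    side <- logical(n)
    side[splits[[s]]] <- TRUE
    A[, s] <- side[pairs[, 1]] != side[pairs[, 2]]
  }
  A
}

# Lawson-Hanson active-set non-negative least squares
nnls_fit <- function(A, b, tol = NULL, max_iter = NULL) {
  p <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * p
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  x <- numeric(p)
  passive <- logical(p)
  w <- Atb - AtA %*% x
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(p)
      z[P] <- solve(AtA[P, P, drop = FALSE] +
                      diag(1e-12, length(P)), Atb[P])
      if (all(z[P] > 0)) break
      neg <- P[z[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- Atb - AtA %*% x
  }
  pmax(x, 0)
}

#' Distances induced by a split system
#'
#' The split metric: `d(i, j)` is the total weight of splits separating
#' `i` and `j`.  For a frequency-kind system this reads as the expected
#' bootstrap disagreement between the two taxa.
#'
#' @param s a [split_system].
#' @return an [osm_dist].
#' @export
splits_to_distance <- function(s) {
  n <- length(s$taxa)
  v <- matrix(0, n, n, dimnames = list(s$taxa, s$taxa))
  for (i in seq_along(s$splits)) {
    side <- logical(n)
    side[s$splits[[i]]] <- TRUE
    sep <- outer(side, side, "!=")
    v <- v + s$weights[i] * sep
  }
  osm_dist(v)
}
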