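#' BioNJ distance tree
#'
#' Variance-weighted neighbour joining (the BioNJ modification of NJ),
#' delegated to the reference implementation in \pkg{ape}.  Negative branch
#' length estimates are clamped to zero; the number of clamped edges is
#' attached as attribute `clamped`.
#'
#' @param d an [osm_dist] with fully defined distances over >= 3 taxa.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
bionj <- function(d) {
  if (anyNA(d$values)) stop("BioNJ requires fully defined distances",
                            call. = FALSE)
  if (length(d$taxa) < 3L) stop("BioNJ needs at least 3 taxa", call. = FALSE)
  tr <- ape::bionj(stats::as.dist(d$values))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "clamped") <- clamped
  tr
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of unordered state changes needed to explain every
#' character on the tree.  Missing cells contribute the character's full
#' state set, ambiguous cells their stated subset; invariant characters
#' contribute zero.  State sets are propagated as bitmasks in a post-order
#' pass, so the score is invariant under re-rooting.
#'
#' @param tree a `phylo` tree whose tip labels equal the matrix taxa.
#' @param matrix an [osm_matrix].
#' @return integer parsimony length.
#' @export
fitch_score <- function(tree, matrix) {
  if (!setequal(tree$tip.label, matrix$taxa)) {
    stop("tree leaves and matrix taxa differ", call. = FALSE)
  }
  nt <- length(tree$tip.label)
  nchr <- n_char(matrix)
  full <- bitwShiftL(1L, matrix$characters$max_state + 1L) - 1L
  # tip state sets as bitmasks, tips x characters
  masks <- matrix(rep(full, each = nt), nt, nchr)
  cells <- matrix$cells[tree$tip.label, , drop = FALSE]
  defined <- !is.na(cells)
  for (j in seq_len(nchr)) {
    idx <- which(defined[, j])
    if (!length(idx)) next
    masks[idx, j] <- vapply(strsplit(cells[idx, j], ""), function(s) {
      sum(bitwShiftL(1L, as.integer(s)))
    }, integer(1))
  }
  tr <- stats::reorder(tree, "postorder")
  nnode <- nt + tr$Nnode
  node_mask <- matrix(0L, nnode, nchr)
  node_mask[seq_len(nt), ] <- masks
  seen <- c(rep(TRUE, nt), rep(FALSE, tr$Nnode))
  changes <- integer(nchr)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    cm <- node_mask[child, ]
    if (!seen[parent]) {
      node_mask[parent, ] <- cm
      seen[parent] <- TRUE
    } else {
      inter <- bitwAnd(node_mask[parent, ], cm)
      empty <- inter == 0L
      changes <- changes + empty
      node_mask[parent, ] <- ifelse(empty,
                                    bitwOr(node_mask[parent, ], cm), inter)
    }
  }
  sum(changes)
}

#' Heuristic parsimony search by NNI hill-climbing
#'
#' Starting from `start` (default: BioNJ on the mean Hamming distances),
#' repeatedly applies the first nearest-neighbour-interchange move that
#' lowers the Fitch score, visiting moves in a seed-controlled random order,
#' until no move improves.  Returns a single tree, as in single-tree-per-
#' replicate bootstrap searches.  NNI neighbourhoods have local optima;
#' `restarts > 1` adds seeded random starting topologies and keeps the best
#' final tree.
#'
#' @param matrix an [osm_matrix].
#' @param start optional starting `phylo` tree (first restart only).
#' @param seed integer seed for move order and restart topologies.
#' @param restarts number of hill-climbs (default 1).
#' @return a `phylo` tree with the final parsimony length in attribute
#'   `pscore`.
#' @export
parsimony_search <- function(matrix, start = NULL, seed = 1, restarts = 1) {
  if (is.null(start)) start <- bionj(mean_hamming(matrix))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    tree <- if (r == 1L) ape::unroot(start) else
      ape::unroot(ape::rtree(n_taxa(matrix), tip.label = sample(matrix$taxa)))
    score <- fitch_score(tree, matrix)
    repeat {
      nbs <- phangorn::nni(tree)
      ord <- sample.int(length(nbs))
      improved <- FALSE
      for (i in ord) {
        s <- fitch_score(nbs[[i]], matrix)
        if (s < score) {
          tree <- nbs[[i]]
          score <- s
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (is.null(best) || score < attr(best, "pscore")) {
      attr(tree, "pscore") <- score
      best <- tree
    }
  }
  best
}

#' Non-trivial splits of a tree
#'
#' One bipartition per internal edge, in canonical orientation with respect
#' to `taxa` (defaults to the tree's own tip order); trivial splits are
#' excluded.
#'
#' @param tree a `phylo` tree.
#' @param taxa taxon labels fixing the index space of the splits.
#' @return list of sorted integer vectors.
#' @export
tree_splits <- function(tree, taxa = sort(tree$tip.label)) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  n <- length(taxa)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree contains leaves absent from 'taxa'",
                       call. = FALSE)
  tr <- stats::reorder(tree, "postorder")
  below <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) below[[i]] <- idx[i]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    below[[parent]] <- c(below[[parent]], below[[tr$edge[e, 2]]])
  }
  internal <- tr$edge[, 2] > nt
  out <- list()
  seen <- character(0)
  for (e in which(internal)) {
    side <- below[[tr$edge[e, 2]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    side <- canonical_split(side, n)
    key <- paste(side, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- side
    }
  }
  out
}
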