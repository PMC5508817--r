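#' Simulate a binary tree for matrix generation
#'
#' Seeded random binary trees with exponential branch lengths (mean 1).
#' Shapes: `random_coalescent_like` (random coalescent topology),
#' `balanced` (recursive halving of the taxon set), `caterpillar` (pectinate
#' ladder).
#'
#' @param n_taxa number of leaves (>= 4).
#' @param tree_shape one of `"random_coalescent_like"`, `"balanced"`,
#'   `"caterpillar"`.
#' @param branch_lengths `"exponential"` (mean 1; the default, mimicking the
#'   strong rate heterogeneity of fossil morphology), `"uniform"` (0.5-1.5),
#'   or `"equal"` (all 1; the clock-like regime in which distance methods
#'   can recover the topology reliably -- near-zero internal edges drawn
#'   from the exponential law are unresolvable in principle).
#' @param seed integer seed.
#' @return a rooted binary `phylo` tree with `n_taxa` leaves labelled
#'   `t1 ... tn`.
#' @export
simulate_tree <- function(n_taxa,
                          tree_shape = c("random_coalescent_like",
                                         "balanced", "caterpillar"),
                          branch_lengths = c("exponential", "uniform",
                                             "equal"),
                          seed = 1) {
  tree_shape <- match.arg(tree_shape)
  branch_lengths <- match.arg(branch_lengths)
  if (n_taxa < 4L) stop("need at least 4 taxa", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labels <- paste0("t", seq_len(n_taxa))
  tree <- switch(tree_shape,
    random_coalescent_like = ape::rcoal(n_taxa, tip.label = labels),
    balanced = balanced_tree(labels),
    caterpillar = ape::stree(n_taxa, type = "left", tip.label = labels))
  tree <- ape::makeNodeLabel(tree)
  tree$edge.length <- switch(branch_lengths,
    exponential = stats::rexp(nrow(tree$edge), rate = 1),
    uniform = stats::runif(nrow(tree$edge), 0.5, 1.5),
    equal = rep(1, nrow(tree$edge)))
  tree
}

balanced_tree <- function(labels) {
  build <- function(lab) {
    if (length(lab) == 1L) return(lab)
    half <- ceiling(length(lab) / 2)
    paste0("(", build(lab[seq_len(half)]), ",",
           build(lab[-seq_len(half)]), ")")
  }
  ape::read.tree(text = paste0(build(labels), ";"))
}

#' Simulate a categorical character matrix on a known tree
#'
#' Characters evolve independently under a symmetric k-state Markov model
#' (Poisson change events along branches, each event drawing a different
#' state uniformly; root state uniform).  `change_rate` fixes the expected
#' number of change events per character summed over the whole tree.  A
#' `homoplasy_boost` fraction of characters is replaced by pure noise (leaf
#' states redrawn independently).  Missing cells are masked per taxon at the
#' requested rates.  The generating tree, its splits, per-character change
#' counts, and the missing mask are returned as the simulation truth.
#'
#' Defaults mirror the structure of published axis-anatomy matrices in this
#' group: a few dozen binary/ternary characters over tens of taxa, with
#' substantial per-taxon missingness.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_characters number of characters.
#' @param ternary_fraction fraction of three-state characters (default 0.45;
#'   the rest are binary).
#' @param tree_shape passed to [simulate_tree].
#' @param branch_lengths passed to [simulate_tree].
#' @param change_rate expected change events per character across the tree
#'   (default 3).
#' @param homoplasy_boost fraction of pure-noise characters in `[0, 1]`
#'   (default 0).
#' @param missing_fraction per-taxon missing-cell probability, scalar or
#'   vector of length `n_taxa`, each in `[0, 0.9]` (default 0).
#' @param seed integer seed.
#' @param tree optional `phylo` tree to reuse instead of simulating one.
#' @return list with `matrix` (an [osm_matrix]) and `truth` (list: `tree`,
#'   `true_splits`, `change_counts`, `noise_characters`, `missing_mask`).
#' @export
simulate_matrix <- function(n_taxa, n_characters, ternary_fraction = 0.45,
                            tree_shape = "random_coalescent_like",
                            branch_lengths = "exponential",
                            change_rate = 3, homoplasy_boost = 0,
                            missing_fraction = 0, seed = 1, tree = NULL) {
  stopifnot(homoplasy_boost >= 0, homoplasy_boost <= 1,
            all(missing_fraction >= 0), all(missing_fraction <= 0.9))
  if (is.null(tree)) tree <- simulate_tree(n_taxa, tree_shape,
                                           branch_lengths, seed = seed)
  n_taxa <- length(tree$tip.label)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  rate <- change_rate / sum(tree$edge.length)
  k_states <- ifelse(stats::runif(n_characters) < ternary_fraction, 3L, 2L)
  tr <- stats::reorder(tree, "cladewise")
  nt <- n_taxa
  root <- nt + 1L
  cells <- matrix(NA_character_, nt, n_characters,
                  dimnames = list(tree$tip.label, NULL))
  change_counts <- integer(n_characters)
  states <- matrix(0L, nt + tr$Nnode, n_characters)
  for (j in seq_len(n_characters)) {
    k <- k_states[j]
    states[root, j] <- sample.int(k, 1L) - 1L
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    n_events <- stats::rpois(n_characters, rate * len)
    st <- states[parent, ]
    hit <- which(n_events > 0L)
    for (j in hit) {
      k <- k_states[j]
      s <- st[j]
      for (ev in seq_len(n_events[j])) {
        s <- (s + sample.int(k - 1L, 1L)) %% k
      }
      st[j] <- s
    }
    change_counts <- change_counts + n_events
    states[child, ] <- st
  }
  cells[] <- as.character(states[seq_len(nt), ])
  noise <- which(stats::runif(n_characters) < homoplasy_boost)
  for (j in noise) {
    cells[, j] <- as.character(sample.int(k_states[j], nt,
                                          replace = TRUE) - 1L)
  }
  # the missing-rate vector is indexed by taxon number (t1 ... tn), not by
  # the tree's internal tip order
  miss_p <- rep_len(missing_fraction, nt)
  tip_num <- match(tree$tip.label, paste0("t", seq_len(nt)))
  if (!anyNA(tip_num)) miss_p <- miss_p[tip_num]
  mask <- matrix(stats::runif(nt * n_characters) <
                   rep(miss_p, n_characters), nt, n_characters,
                 dimnames = list(tree$tip.label, NULL))
  cells[mask] <- NA_character_
  chars <- data.frame(index = seq_len(n_characters),
                      label = paste0("char", seq_len(n_characters)),
                      max_state = k_states - 1L,
                      stringsAsFactors = FALSE)
  list(matrix = osm_matrix(cells, characters = chars),
       truth = list(tree = tree,
                    true_splits = tree_splits(tree, sort(tree$tip.label)),
                    change_counts = change_counts,
                    noise_characters = noise,
                    missing_mask = mask))
}

#' Deterministic named fixtures for the test surface
#'
#' Small constructed matrices exercising every pipeline stage:
#' `perfect8` (8 taxa, 30 mutually compatible binary characters echoing the
#' five internal splits of a balanced tree), `conflict6` (two 15-character
#' blocks supporting incompatible splits), `sparse8` (`perfect8` with one
#' taxon pushed above the 60% missing threshold), and `circular6` (a
#' distance matrix forward-constructed from 9 weighted interval splits of a
#' known circular ordering).
#'
#' @param seed integer seed (fixtures are deterministic given the seed).
#' @return named list; matrix fixtures are lists with `matrix` and `truth`,
#'   `circular6` has `dist`, `order`, and `splits`.
#' @export
fixture_suite <- function(seed = 42) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()

  tree8 <- balanced_tree(paste0("t", 1:8))
  tree8$edge.length <- rep(1, nrow(tree8$edge))
  splits8 <- tree_splits(tree8, sort(tree8$tip.label))
  cells <- matrix("0", 8, 30, dimnames = list(sort(tree8$tip.label), NULL))
  for (j in seq_len(30)) {
    side <- splits8[[((j - 1L) %% length(splits8)) + 1L]]
    cells[side, j] <- "1"
  }
  out$perfect8 <- list(matrix = osm_matrix(cells),
                       truth = list(tree = tree8, true_splits = splits8))

  taxa6 <- paste0("t", 1:6)
  cellsc <- matrix("0", 6, 30, dimnames = list(taxa6, NULL))
  cellsc[1:3, 1:15] <- "1"      # split {t1 t2 t3}
  cellsc[c(1, 2, 4), 16:30] <- "1"  # incompatible split {t1 t2 t4}
  out$conflict6 <- list(matrix = osm_matrix(cellsc),
                        truth = list(block_splits = list(c(1L, 2L, 3L),
                                                         c(1L, 2L, 4L))))

  sp <- cells
  miss <- sample.int(30, 19)   # 19/30 = 63% missing for one taxon
  sp["t8", miss] <- NA_character_
  out$sparse8 <- list(matrix = osm_matrix(sp),
                      truth = list(sparse_taxon = "t8",
                                   missing_fraction = 19 / 30))

  ord <- 1:6
  csplits <- circular_interval_splits(ord)
  pick <- csplits[c(1:6, 8, 11, 13)]   # 6 trivial + 3 internal intervals
  wts <- c(stats::runif(6, 0.5, 1.5), stats::runif(3, 0.3, 1))
  sys <- split_system(paste0("t", 1:6), pick, wts, cycle = ord)
  out$circular6 <- list(dist = splits_to_distance(sys), order = ord,
                        splits = sys)
  out
}
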