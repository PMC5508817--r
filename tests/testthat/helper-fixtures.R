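# Shared builders and independent brute-force oracles.  Oracles are written
# as plainly as possible (double loops, full enumeration) and never call the
# code paths they check.

toy_cells <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# distance matrix of an ape tree restricted to sorted tip order
tree_metric <- function(tree) {
  v <- ape::cophenetic.phylo(tree)
  taxa <- sort(tree$tip.label)
  osm_dist(v[taxa, taxa])
}

random_matrix_with_missing <- function(n_taxa, n_char, p_missing = 0.2,
                                       p_ambig = 0.05, states = 0:2,
                                       seed = 1) {
  set.seed(seed)
  cells <- matrix(as.character(sample(states, n_taxa * n_char,
                                      replace = TRUE)),
                  n_taxa, n_char,
                  dimnames = list(paste0("tx", seq_len(n_taxa)), NULL))
  cells[matrix(runif(length(cells)) < p_missing, n_taxa, n_char)] <-
    NA_character_
  amb <- which(matrix(runif(length(cells)) < p_ambig, n_taxa, n_char) &
                 !is.na(cells))
  cells[amb] <- "01"
  osm_matrix(cells)
}

# --- oracle: pairwise mean Hamming distance, naive double loop -------------
oracle_mean_hamming <- function(m) {
  n <- nrow(m$cells)
  out <- matrix(0, n, n, dimnames = list(m$taxa, m$taxa))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mism <- comp <- 0
      for (c in seq_len(ncol(m$cells))) {
        a <- m$cells[i, c]; b <- m$cells[j, c]
        if (is.na(a) || is.na(b) || nchar(a) > 1 || nchar(b) > 1) next
        comp <- comp + 1
        if (a != b) mism <- mism + 1
      }
      out[i, j] <- if (comp > 0) mism / comp else NA_real_
    }
  }
  out
}

# --- oracle: delta values by naive quartet enumeration ---------------------
oracle_delta <- function(values) {
  n <- nrow(values)
  qs <- utils::combn(n, 4)
  deltas <- numeric(0)
  per_taxon <- vector("list", n)
  for (q in seq_len(ncol(qs))) {
    x <- qs[1, q]; y <- qs[2, q]; z <- qs[3, q]; w <- qs[4, q]
    s <- c(values[x, y] + values[z, w],
           values[x, z] + values[y, w],
           values[x, w] + values[y, z])
    if (anyNA(s)) next
    s <- sort(s, decreasing = TRUE)
    del <- if (s[1] - s[3] < 1e-12) 0 else (s[1] - s[2]) / (s[1] - s[3])
    deltas <- c(deltas, del)
    for (t in c(x, y, z, w)) per_taxon[[t]] <- c(per_taxon[[t]], del)
  }
  list(mdv = mean(deltas),
       idv = vapply(per_taxon, function(v) mean(v), numeric(1)),
       n = length(deltas))
}

# --- oracle: parsimony length by exhaustive internal-state enumeration -----
oracle_parsimony <- function(tree, m) {
  tr <- ape::unroot(tree)
  nt <- length(tr$tip.label)
  n_int <- tr$Nnode
  total <- 0
  for (ch in seq_len(ncol(m$cells))) {
    k <- m$characters$max_state[ch] + 1L
    cell_states <- function(x) {
      if (is.na(x)) 0:(k - 1) else as.integer(strsplit(x, "")[[1]])
    }
    tip_sets <- lapply(m$cells[tr$tip.label, ch], cell_states)
    grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), n_int)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign_int <- grid[g, ]
      # tips may take any state in their set; pick the per-edge cheapest
      cost <- 0
      for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1]; c2 <- tr$edge[e, 2]
        ps <- assign_int[p - nt]
        cs <- if (c2 <= nt) tip_sets[[c2]] else assign_int[c2 - nt]
        cost <- cost + min(as.integer(!cs %in% ps))
      }
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# state counts 0/1 columns supporting each split of a tree
perfect_matrix_for <- function(tree, reps_per_split = 4) {
  taxa <- sort(tree$tip.label)
  splits <- tree_splits(tree, taxa)
  cells <- matrix("0", length(taxa), length(splits) * reps_per_split,
                  dimnames = list(taxa, NULL))
  j <- 0
  for (r in seq_len(reps_per_split)) {
    for (s in splits) {
      j <- j + 1
      cells[s, j] <- "1"
    }
  }
  osm_matrix(cells)
}

expect_same_split_set <- function(a, b, n) {
  keya <- sort(vapply(a, function(s) paste(osmundnet:::canonical_split(s, n),
                                           collapse = ","), character(1)))
  keyb <- sort(vapply(b, function(s) paste(osmundnet:::canonical_split(s, n),
                                           collapse = ","), character(1)))
  expect_identical(keya, keyb)
}
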