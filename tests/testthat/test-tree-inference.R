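test_that("bionj recovers additive trees exactly", {
  set.seed(6)
  for (seed in 1:3) {
    set.seed(seed)
    tr <- ape::rtree(5)
    tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
    d <- tree_metric(tr)
    fit <- bionj(d)
    expect_equal(phangorn::RF.dist(fit, ape::unroot(tr)), 0)
    dm <- ape::cophenetic.phylo(fit)[d$taxa, d$taxa]
    expect_lt(max(abs(dm - d$values)), 1e-6)
  }
})

test_that("bionj handles 3 taxa and rejects undefined distances", {
  v <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- bionj(osm_dist(v))
  expect_equal(sort(tr$tip.label), letters[1:3])
  expect_equal(sum(tr$edge.length), 5)  # star fit of an additive triple
  v[1, 2] <- v[2, 1] <- NA
  expect_error(bionj(osm_dist(v)), "defined")
})

test_that("bionj topology is robust to small perturbations", {
  set.seed(31)
  tr <- ape::rtree(7)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  d <- tree_metric(tr)
  noisy <- d$values + matrix(rnorm(49, sd = 0.01), 7, 7)
  noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0
  fit <- bionj(osm_dist(abs(noisy)))
  expect_equal(phangorn::RF.dist(fit, ape::unroot(tr)), 0)
})

test_that("fitch scores the congruent, missing, and ambiguous cases", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  m1 <- osm_matrix(toy_cells(a = "1", b = "1", c = "0", d = "0"))
  expect_equal(fitch_score(tr, m1), 1)
  m0 <- osm_matrix(toy_cells(a = NA, b = NA, c = NA, d = NA),
                   characters = data.frame(index = 1, label = "c1",
                                           max_state = 1))
  expect_equal(fitch_score(tr, m0), 0)
  # ambiguity absorbs a change
  m2 <- osm_matrix(toy_cells(a = "1", b = "01", c = "0", d = "0"))
  expect_equal(fitch_score(tr, m2), 1)
  expect_error(fitch_score(tr, osm_matrix(toy_cells(a = "1", x = "0",
                                                    c = "1", d = "0"))),
               "differ")
})

test_that("fitch equals the exhaustive state-assignment oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    tr <- ape::rtree(6)
    m <- random_matrix_with_missing(6, 5, p_missing = 0.2, p_ambig = 0.1,
                                    seed = seed)
    rownames(m$cells) <- m$taxa <- tr$tip.label
    expect_equal(fitch_score(tr, m), oracle_parsimony(tr, m),
                 info = paste("seed", seed))
  }
})

test_that("fitch is invariant under re-rooting and leaf permutation", {
  set.seed(17)
  tr <- ape::rtree(7)
  m <- random_matrix_with_missing(7, 8, seed = 3)
  rownames(m$cells) <- m$taxa <- tr$tip.label
  s0 <- fitch_score(tr, m)
  for (node in c(3, 5, 7)) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[node],
                          resolve.root = TRUE)
    expect_equal(fitch_score(rerooted, m), s0)
  }
  perm <- sample(m$taxa)
  m2 <- osm_matrix(m$cells[perm, , drop = FALSE],
                   characters = m$characters)
  expect_equal(fitch_score(tr, m2), s0)
})

test_that("parsimony search attains a perfect phylogeny", {
  set.seed(2)
  tr <- ape::rtree(7)
  m <- perfect_matrix_for(tr, reps_per_split = 3)
  best <- parsimony_search(m, seed = 5)
  expect_equal(attr(best, "pscore"), n_char(m))  # one change per column
  expect_same_split_set(tree_splits(best, m$taxa), tree_splits(tr, m$taxa),
                        n_taxa(m))
})

test_that("search never worsens the start tree and is seed-deterministic", {
  m <- random_matrix_with_missing(6, 12, p_missing = 0.1, seed = 8)
  start <- bionj(mean_hamming(m))
  s_start <- fitch_score(start, m)
  t1 <- parsimony_search(m, start = start, seed = 4)
  t2 <- parsimony_search(m, start = start, seed = 4)
  expect_lte(attr(t1, "pscore"), s_start)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("NNI hill-climb usually finds the global optimum (6 taxa)", {
  m <- random_matrix_with_missing(6, 10, p_missing = 0.1, seed = 12)
  all_trees <- phangorn::allTrees(6, rooted = FALSE, tip.label = m$taxa)
  global <- min(vapply(all_trees, fitch_score, numeric(1), matrix = m))
  hits <- vapply(1:20, function(s) {
    attr(parsimony_search(m, seed = s, restarts = 6), "pscore")
  }, numeric(1))
  expect_gte(mean(hits == global), 0.95)
})

test_that("tree splits: counts and canonical orientation", {
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  s4 <- tree_splits(tr4)
  expect_length(s4, 1)
  expect_identical(s4[[1]], c(1L, 2L))  # side containing taxon 1 ('a')

  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_length(tree_splits(star), 0)

  set.seed(23)
  tr8 <- ape::rtree(8)
  expect_length(tree_splits(tr8), 8 - 3)
})
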