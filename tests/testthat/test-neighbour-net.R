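# forward-construct a circular-decomposable metric from known split weights;
# the inversion route (ordering + NNLS) must recover it exactly
random_circular_system <- function(n, n_internal = NULL, seed = 1) {
  set.seed(seed)
  ord <- sample(n)
  cand <- osmundnet:::circular_interval_splits(ord)
  sizes <- lengths(cand)
  internal <- which(sizes >= 2 & sizes <= n - 2)
  trivial <- which(sizes == 1 | sizes == n - 1)
  if (is.null(n_internal)) {
    # "rich" system: every interval split weighted, so the circular
    # ordering is uniquely determined (up to rotation/reflection)
    pick <- c(trivial, internal)
    n_internal <- length(internal)
  } else {
    pick <- c(trivial, sample(internal, n_internal))
  }
  split_system(paste0("t", seq_len(n)), cand[pick],
               c(runif(length(trivial), 0.4, 1.2),
                 runif(n_internal, 0.2, 0.8)),
               cycle = ord)
}

same_cycle <- function(a, b) {
  n <- length(a)
  rots <- lapply(seq_len(n), function(k) c(b[k:n], b[seq_len(k - 1)]))
  any(vapply(rots, function(r) all(r == a) || all(rev(r) == a), logical(1)))
}

test_that("ordering recovers a generating circular order (5 and 7 taxa)", {
  for (n in c(5, 7)) {
    for (seed in 1:3) {
      sys <- random_circular_system(n, seed = seed * 10 + n)
      d <- splits_to_distance(sys)
      ord <- nnet_ordering(d)
      expect_true(same_cycle(sys$cycle, ord),
                  info = sprintf("n=%d seed=%d", n, seed))
    }
  }
})

test_that("ordering places cherries of an additive quartet adjacently", {
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  d <- tree_metric(tr)
  ord <- nnet_ordering(d)
  lab <- d$taxa[ord]
  pos <- function(x) which(lab == x)
  adjacent <- function(x, y) {
    abs(pos(x) - pos(y)) %in% c(1, 3)  # cyclic adjacency on 4 taxa
  }
  expect_true(adjacent("a", "b"))
  expect_true(adjacent("c", "d"))
})

test_that("degenerate sizes return the input order", {
  v <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_identical(nnet_ordering(osm_dist(v)), 1:2)
  v3 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(v3) <- 0
  expect_identical(nnet_ordering(osm_dist(v3)), 1:3)
})

test_that("weights of a forward-constructed system are recovered", {
  for (seed in 1:4) {
    sys <- random_circular_system(6, 3, seed)
    d <- splits_to_distance(sys)
    fit <- estimate_split_weights(d, order = sys$cycle)
    expect_lt(attr(fit, "rss"), 1e-10)
    n <- 6
    want <- stats::setNames(sys$weights,
                            vapply(sys$splits, paste, character(1),
                                   collapse = ","))
    got <- stats::setNames(fit$weights,
                           vapply(fit$splits, paste, character(1),
                                  collapse = ","))
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-6)
  }
})

test_that("an additive 4-leaf tree yields its 5 branches as splits", {
  # terminals 1, internal 1 + 1 = 2 across the root
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d <- tree_metric(tr)
  net <- neighbour_net(d)
  expect_equal(length(net$splits), 5)
  keys <- vapply(net$splits, paste, character(1), collapse = ",")
  w <- stats::setNames(net$weights, keys)
  expect_equal(unname(w[nchar(keys) == 1 | lengths(net$splits) == 3]),
               rep(1, 4), tolerance = 1e-8)
  internal <- w[lengths(net$splits) == 2]
  expect_length(internal, 1)
  expect_equal(unname(internal), 2, tolerance = 1e-8)
})

test_that("neighbour-net of an additive metric returns the tree splits", {
  set.seed(14)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 2)
  d <- tree_metric(tr)
  net <- neighbour_net(d)
  got <- net$splits[lengths(net$splits) >= 2 &
                      lengths(net$splits) <= length(d$taxa) - 2]
  expect_same_split_set(got, tree_splits(tr), length(d$taxa))
  expect_lt(max(abs(splits_to_distance(net)$values - d$values)), 1e-6)
})

test_that("round-trip residual vanishes on circular-decomposable input", {
  for (seed in 5:8) {
    sys <- random_circular_system(7, 4, seed)
    d <- splits_to_distance(sys)
    net <- neighbour_net(d)
    expect_lt(max(abs(splits_to_distance(net)$values - d$values)), 1e-6)
    # structural: every emitted split is an interval of the circular order
    for (s in net$splits) {
      expect_true(osmundnet:::is_interval_of_cycle(s, net$cycle))
    }
  }
})

test_that("zero distances yield no positive splits", {
  v <- matrix(0, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  net <- neighbour_net(osm_dist(v))
  expect_length(net$splits, 0)
})

test_that("non-symmetric or undefined input is rejected", {
  v <- matrix(runif(16), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(osm_dist(v), "symmetric")
  v2 <- (v + t(v)) / 2; diag(v2) <- 0
  v2[1, 2] <- v2[2, 1] <- NA
  expect_error(nnet_ordering(osm_dist(v2)), "defined")
})

test_that("single-split systems induce the expected metric", {
  s <- split_system(letters[1:4], list(c(1L, 2L)), 1)
  d <- splits_to_distance(s)
  expect_equal(d$values["a", "b"], 0)
  expect_equal(d$values["a", "c"], 1)
  expect_equal(d$values["c", "d"], 0)
})
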