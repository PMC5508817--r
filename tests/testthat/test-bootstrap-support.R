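test_that("character resampling: identity, determinism, inclusion rate", {
  m1 <- osm_matrix(toy_cells(a = "0", b = "1"))
  set.seed(1)
  expect_identical(resample_characters(m1)$cells, m1$cells)

  m <- random_matrix_with_missing(4, 5, p_missing = 0, seed = 2)
  set.seed(99); r1 <- attr(resample_characters(m), "source_indices")
  set.seed(99); r2 <- attr(resample_characters(m), "source_indices")
  expect_identical(r1, r2)

  # expected fraction of distinct source columns ~ 1 - 1/e
  mp <- random_matrix_with_missing(3, 50, p_missing = 0, seed = 3)
  set.seed(7)
  fr <- vapply(1:2000, function(i) {
    length(unique(attr(resample_characters(mp), "source_indices"))) / 50
  }, numeric(1))
  expect_equal(mean(fr), 1 - (1 - 1 / 50)^50, tolerance = 0.01)
  expect_equal(mean(fr), 0.632, tolerance = 0.02)
})

test_that("clean compatible signal puts every true split near 1", {
  fx <- fixture_suite(1)
  m <- fx$perfect8$matrix
  bt <- bootstrap_supports(m, replicates = 200, seed = 3)
  truth <- fx$perfect8$truth$true_splits
  for (s in truth) {
    expect_gte(support_for(bt, s), 0.95)
  }
  expect_equal(bt$replicates_completed, 200)
  expect_equal(bt$replicates_skipped, 0)
})

test_that("an identical taxon pair forms a near-certain cherry", {
  set.seed(5)
  sim <- simulate_matrix(6, 40, change_rate = 4, seed = 9)
  m <- sim$matrix
  cells <- rbind(m$cells, m$cells["t1", , drop = FALSE])
  rownames(cells) <- c(m$taxa, "t1b")
  m2 <- osm_matrix(cells, characters = m$characters)
  bt <- bootstrap_supports(m2, replicates = 150, seed = 2)
  expect_gte(support_for(bt, c("t1", "t1b")), 0.95)
})

test_that("fixed seed reproduces the support table bit-for-bit", {
  m <- fixture_suite(1)$conflict6$matrix
  b1 <- bootstrap_supports(m, replicates = 80, seed = 11)
  b2 <- bootstrap_supports(m, replicates = 80, seed = 11)
  expect_identical(b1$frequencies, b2$frequencies)
  b3 <- bootstrap_supports(m, replicates = 80, seed = 12)
  expect_false(identical(b1$frequencies, b3$frequencies))
})

test_that("rival splits from conflicting blocks share the probability mass", {
  m <- fixture_suite(1)$conflict6$matrix
  bt <- bootstrap_supports(m, replicates = 300, seed = 5)
  f1 <- support_for(bt, c("t1", "t2", "t3"))
  f2 <- support_for(bt, c("t1", "t2", "t4"))
  expect_gt(f1, 0.2); expect_gt(f2, 0.2)
  expect_equal(f1 + f2, 1, tolerance = 0.05)
  # mutually incompatible splits cannot both exceed half
  expect_lte(min(f1, f2), 0.5 + 1 / bt$replicates_completed)
})

test_that("support lookup canonicalises, rejects trivial splits", {
  m <- fixture_suite(1)$perfect8$matrix
  bt <- bootstrap_supports(m, replicates = 50, seed = 1)
  f_a <- support_for(bt, c("t1", "t2"))
  f_b <- support_for(bt, setdiff(m$taxa, c("t1", "t2")))  # complement
  expect_identical(f_a, f_b)
  expect_equal(support_for(bt, c("t1", "t3", "t5", "t7")), 0)  # never seen
  expect_error(support_for(bt, "t1"), "non-trivial")
  expect_error(support_for(bt, c("t1", "nope")), "unknown taxon")
})

test_that("replicates with incomparable pairs are skipped or abort the run", {
  # two taxa overlap in a single character: resampling loses it in
  # ~(1 - 1/p)^p of replicates, far above the 10% tolerance
  cells <- toy_cells(a = c("0", rep(NA, 9)),
                     b = c("1", "0", "1", "0", "1", "0", "1", "0", "1", "0"),
                     c = rep(c("0", "1"), 5),
                     d = rep(c("1", "0"), 5))
  m <- osm_matrix(cells)
  expect_error(bootstrap_supports(m, replicates = 100, seed = 3),
               "too sparse")
})

test_that("consensus network honours the frequency filter", {
  m <- fixture_suite(1)$conflict6$matrix
  bt <- bootstrap_supports(m, replicates = 200, seed = 7)
  cn10 <- consensus_network(bt, 0.10)
  keys <- vapply(cn10$splits, paste, character(1), collapse = ",")
  expect_true("1,2,3" %in% keys && "1,2,4" %in% keys)  # both rivals retained
  expect_true(all(cn10$weights <= 1))
  # all 6 trivial splits present (canonical orientation stores the side
  # containing taxon 1, so 5 of them appear as their size-5 complements)
  n6 <- length(cn10$taxa)
  expect_equal(sum(lengths(cn10$splits) == 1 |
                     lengths(cn10$splits) == n6 - 1), 6)

  cn100 <- consensus_network(bt, 1.0)  # strict consensus
  internal100 <- cn100$splits[lengths(cn100$splits) >= 2 &
                                lengths(cn100$splits) <= n6 - 2]
  expect_true(all(vapply(internal100, function(s) {
    support_for(bt, s) == 1
  }, logical(1))))

  f <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(cn10, f)
  expect_true(any(grepl("Splits", readLines(f))))
})

test_that("support tables serialise as delimited text", {
  m <- fixture_suite(1)$perfect8$matrix
  bt <- bootstrap_supports(m, replicates = 40, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_support_table(bt, f)
  lines <- readLines(f)
  expect_match(lines[1], "criterion=nj_ls")
  expect_match(lines[2], "frequency\tcount\tsplit")
  expect_gte(length(lines), 3)
})

test_that("parsimony criterion runs and finds the clean signal", {
  m <- fixture_suite(1)$perfect8$matrix
  bt <- bootstrap_supports(m, replicates = 20, criterion = "parsimony",
                           seed = 4)
  expect_equal(bt$criterion, "parsimony")
  for (s in fixture_suite(1)$perfect8$truth$true_splits) {
    expect_gte(support_for(bt, s), 0.9)
  }
})
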