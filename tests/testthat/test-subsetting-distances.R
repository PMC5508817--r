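test_that("missing fraction excludes ambiguity and honours the strict rule", {
  m <- osm_matrix(toy_cells(a = c("0", "1", "01", "2", "0"),
                            b = c(NA, NA, NA, "1", "0"),
                            c = c("0", "0", "0", "0", "0")))
  expect_equal(missing_fraction(m, "a"), 0)     # ambiguous is not missing
  expect_equal(missing_fraction(m, "b"), 0.6)
  expect_error(missing_fraction(m, "zz"), "unknown taxon")

  # strict >: a taxon exactly at the threshold stays
  kept <- exclude_sparse_taxa(m, 0.6)
  expect_identical(kept$dropped_taxa, character(0))
  expect_identical(exclude_sparse_taxa(m, 1.0)$dropped_taxa, character(0))

  m2 <- osm_matrix(rbind(m$cells,
                         d = c(NA, NA, NA, NA, "0")))  # 80% missing
  ex <- exclude_sparse_taxa(m2, 0.6)
  expect_identical(ex$dropped_taxa, "d")
  expect_identical(ex$matrix$taxa, c("a", "b", "c"))
})

test_that("variable characters need two distinct defined singleton states", {
  m <- osm_matrix(toy_cells(a = c("0", "0", "0", "01", "1"),
                            b = c("0", NA,  "1", "1",  "1"),
                            c = c("0", "0", NA,  "0",  "1")))
  vc <- variable_characters(m)
  expect_true(3 %in% vc)            # {0, 1, ?} is variable
  expect_false(1 %in% vc)           # constant column
  expect_false(5 %in% vc)           # constant column
  expect_true(4 %in% vc)            # defined 1 vs 0; ambiguity ignored
  vc_ab <- variable_characters(m, c("a", "c"))
  expect_false(4 %in% vc_ab)        # only "01" and "0": not established
})

test_that("build_subset filters sparsity first, then invariants", {
  cells <- toy_cells(a = c("0", "1", "0", "0"),
                     b = c("0", "1", "1", "0"),
                     c = c("0", "0", "1", "0"),
                     d = c(NA, NA, NA, "1"))
  m <- osm_matrix(cells)
  # 3 retained taxa: the <4-taxa warning is expected here
  s <- suppressWarnings(build_subset(m, sparsity_threshold = 0.6))
  expect_identical(s$dropped_taxa, "d")
  # char1 constant among a,b,c; char4 variable only because of d -> dropped
  expect_identical(s$dropped_characters, c(1L, 4L))
  expect_equal(n_char(s$matrix), 2)

  # idempotence: re-running on the output changes nothing
  s2 <- suppressWarnings(build_subset(s$matrix, sparsity_threshold = 0.6))
  expect_identical(s2$matrix$cells, s$matrix$cells)
  expect_identical(s2$dropped_taxa, character(0))
  expect_identical(s2$dropped_characters, integer(0))

  expect_error(build_subset(m, taxa = c("a", "zz")), "unknown taxon")
  expect_warning(build_subset(m, taxa = c("a", "b", "c")), "quartet")
})

test_that("mean Hamming matches the naive oracle on random fixtures", {
  for (seed in 1:6) {
    m <- random_matrix_with_missing(6, 10, p_missing = 0.25, p_ambig = 0.1,
                                    seed = seed)
    ref <- oracle_mean_hamming(m)
    if (anyNA(ref)) next  # oracle says some pair is incomparable
    d <- mean_hamming(m)
    expect_equal(d$values, ref, tolerance = 1e-12)
    expect_true(all(d$values >= 0 & d$values <= 1))
    expect_equal(d$values, t(d$values))
    expect_true(all(diag(d$values) == 0))
    expect_true(all(d$comparable[upper.tri(d$comparable)] >= 1))
  }
})

test_that("identical rows give zero distance; worked 6/14 case", {
  m <- osm_matrix(toy_cells(a = c("0", "1", "2"),
                            b = c("0", "1", "2"),
                            c = c("1", "1", "0")))
  d <- mean_hamming(m)
  expect_equal(d$values["a", "b"], 0)
  expect_equal(d$values["a", "c"], 2 / 3)

  # two taxa sharing 14 comparable characters, 6 mismatching
  cells <- rbind(x = c(rep("0", 14), rep(NA, 6)),
                 y = c(rep("0", 8), rep("1", 6), rep("0", 6)))
  d2 <- mean_hamming(osm_matrix(cells))
  expect_equal(d2$comparable["x", "y"], 14)
  expect_equal(round(d2$values["x", "y"], 2), 0.43)
  expect_equal(floor(d2$values["x", "y"] * 100) / 100, 0.42)  # as printed
})

test_that("a pair with no comparable characters raises a named error", {
  m <- osm_matrix(toy_cells(a = c("0", NA), b = c(NA, "1"),
                            c = c("0", "1")))
  expect_error(mean_hamming(m), "'a' / 'b'")
})

test_that("invariant characters shift distances only via the denominator", {
  for (seed in 1:4) {
    m <- random_matrix_with_missing(5, 12, p_missing = 0.15, p_ambig = 0,
                                    states = 0:1, seed = seed)
    vc <- variable_characters(m)
    if (length(vc) < 2) next
    stripped <- subset_matrix(m, chars = vc)
    d_strip <- try(mean_hamming(stripped), silent = TRUE)
    if (inherits(d_strip, "try-error")) next
    # mismatch counts agree with the full matrix: invariant columns never
    # mismatch, so only the comparable counts (denominators) change
    d_full <- mean_hamming(m)
    mism_full <- d_full$values * d_full$comparable
    mism_strip <- d_strip$values * d_strip$comparable
    expect_equal(round(mism_full, 9), round(mism_strip, 9))
  }
})

test_that("distance summary censuses extremes and zero pairs", {
  v <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  s0 <- distance_summary(osm_dist(v))
  expect_equal(s0$max, 0)
  expect_equal(s0$n_zero, 3)

  v["a", "c"] <- v["c", "a"] <- 0.81
  v["b", "c"] <- v["c", "b"] <- 0.3
  s1 <- distance_summary(osm_dist(v))
  expect_equal(s1$max, 0.81)
  expect_setequal(s1$max_pair, c("a", "c"))
  expect_equal(s1$n_zero, 1)
  expect_setequal(as.vector(s1$zero_pairs), c("a", "b"))
})
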