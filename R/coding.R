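#' Perforations per millimetre of stele perimeter (PmmS)
#'
#' The density of complete leaf-gap perforations around the stelar xylem
#' cylinder: the maximum number of complete perforations seen in one
#' transverse section divided by the stele perimeter (diameter times pi).
#' Used, together with the raw perforation count, to code the degree of
#' stele perforation as a three-state character.
#'
#' @param n_cp_max maximum number of complete perforations in a transverse
#'   section (non-negative integer).
#' @param d_stele_max maximum stele diameter in mm (> 0).
#' @return perforations per mm (1/mm).
#' @seealso [code_perforation_state], [rtc]
#' @export
pmms <- function(n_cp_max, d_stele_max) {
  if (any(d_stele_max <= 0, na.rm = TRUE)) {
    stop("stele diameter must be positive", call. = FALSE)
  }
  if (any(n_cp_max < 0, na.rm = TRUE)) {
    stop("perforation count must be non-negative", call. = FALSE)
  }
  n_cp_max / (d_stele_max * pi)
}

#' Relative cortex thickness (RTC)
#'
#' The thickness of the cortex relative to the stele:
#' `(stem diameter - stele diameter) / stele diameter`, both taken at their
#' maxima.  Zero means no cortex; large values indicate a thin stele inside
#' a massive stem.
#'
#' @param d_stem_max maximum stem diameter in mm.
#' @param d_stele_max maximum stele diameter in mm (> 0, and not larger than
#'   the stem diameter; a stele wider than its stem usually signals confusion
#'   of the terms "stem" and "stele" in the source description).
#' @return dimensionless ratio >= 0.
#' @export
rtc <- function(d_stem_max, d_stele_max) {
  if (any(d_stele_max <= 0, na.rm = TRUE)) {
    stop("stele diameter must be positive", call. = FALSE)
  }
  if (any(d_stem_max < d_stele_max, na.rm = TRUE)) {
    stop("stele diameter exceeds stem diameter; check for stem/stele ",
         "term confusion in the source data", call. = FALSE)
  }
  (d_stem_max - d_stele_max) / d_stele_max
}

#' One-dimensional k-median clustering
#'
#' Partitions real values into `k` clusters minimising the total absolute
#' deviation from cluster medians.  Restarted Lloyd-style iterations from
#' random distinct seed values; for 1-D data the optimum is an interval
#' partition of the sorted values, so cluster boundaries are reported as
#' midpoints between adjacent clusters' extreme members.  Assignment ties
#' are broken toward the lower-median cluster.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of clusters.
#' @param restarts number of random restarts (default 1000).
#' @param seed integer seed controlling the restarts.
#' @return a `k_medians` list: `k`, `medians` (sorted), `assignments`
#'   (cluster index per input value), `objective`, `boundaries` (k-1
#'   thresholds).
#' @seealso [k_medians_interval] for the exhaustive interval-partition search
#'   used as an independent check.
#' @export
k_medians_1d <- function(values, k, restarts = 1000, seed = 1) {
  values <- as.numeric(values)
  distinct <- sort(unique(values))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(distinct) < k) {
    stop("k = ", k, " exceeds the ", length(distinct), " distinct values",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    med <- sort(sample(distinct, k))
    for (it in 1:100) {
      assign_idx <- assign_to_medians(values, med)
      new_med <- vapply(seq_len(k), function(c) {
        stats::median(values[assign_idx == c])
      }, numeric(1))
      if (anyNA(new_med)) break  # empty cluster: abandon this restart
      new_med <- sort(new_med)
      if (isTRUE(all.equal(new_med, med))) break
      med <- new_med
    }
    if (anyNA(new_med)) next
    obj <- sum(abs(values - med[assign_idx]))
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(medians = med, assignments = assign_idx, objective = obj)
    }
  }
  if (is.null(best)) stop("clustering failed to produce k non-empty clusters",
                          call. = FALSE)
  finish_k_medians(values, k, best)
}

assign_to_medians <- function(values, med) {
  dist <- abs(outer(values, med, "-"))
  # max.col(ties.method = "first") on negated distances prefers the
  # lower-median cluster on ties
  max.col(-dist, ties.method = "first")
}

finish_k_medians <- function(values, k, best) {
  boundaries <- if (k > 1) {
    vapply(seq_len(k - 1L), function(c) {
      hi <- max(values[best$assignments == c])
      lo <- min(values[best$assignments == c + 1L])
      (hi + lo) / 2
    }, numeric(1))
  } else numeric(0)
  structure(list(k = k, medians = best$medians,
                 assignments = best$assignments,
                 objective = best$objective, boundaries = boundaries),
            class = "k_medians")
}

#' @export
print.k_medians <- function(x, ...) {
  cat("<k_medians> k=", x$k, " medians=",
      paste(format(x$medians, digits = 4), collapse = ", "),
      " objective=", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Exhaustive 1-D k-median over interval partitions
#'
#' Enumerates all ways of cutting the sorted values into `k` contiguous
#' blocks and returns the partition with the smallest total absolute
#' deviation.  Exact for 1-D k-median (the optimum is always an interval
#' partition), so it serves as the independent reference for
#' [k_medians_1d]; cost grows as `choose(n-1, k-1)`.
#'
#' @inheritParams k_medians_1d
#' @return a `k_medians` object.
#' @export
k_medians_interval <- function(values, k) {
  values <- as.numeric(values)
  n <- length(values)
  if (length(unique(values)) < k) {
    stop("k = ", k, " exceeds the distinct value count", call. = FALSE)
  }
  ord <- order(values)
  sorted <- values[ord]
  cost <- function(i, j) sum(abs(sorted[i:j] - stats::median(sorted[i:j])))
  cuts <- utils::combn(n - 1L, k - 1L)
  if (k == 1L) cuts <- matrix(integer(0), nrow = 0, ncol = 1)
  best_obj <- Inf
  best_lab <- NULL
  for (c in seq_len(ncol(cuts))) {
    edges <- c(0L, cuts[, c], n)
    obj <- 0
    lab <- integer(n)
    ok <- TRUE
    for (b in seq_len(k)) {
      i <- edges[b] + 1L; j <- edges[b + 1L]
      if (i > j) { ok <- FALSE; break }
      obj <- obj + cost(i, j)
      lab[i:j] <- b
    }
    if (ok && obj < best_obj - 1e-12) {
      best_obj <- obj
      best_lab <- lab
    }
  }
  assignments <- integer(n)
  assignments[ord] <- best_lab
  med <- vapply(seq_len(k), function(c) {
    stats::median(values[assignments == c])
  }, numeric(1))
  finish_k_medians(values, k,
                   list(medians = med, assignments = assignments,
                        objective = best_obj))
}

#' Code the degree of stele perforation (three states)
#'
#' State 0 ("(nearly) imperforate"): at most 3 complete perforations.
#' State 2 ("highly perforated"): at least 16 complete perforations *and*
#' a perforation density [pmms] of at least 0.30/mm.  Everything else is
#' state 1 ("moderately to densely perforated"), which captures both
#' overrides in the published rule: few-perforation axes with high density
#' stay moderate, and many-perforation axes with low density (very large
#' steles) drop back to moderate.
#'
#' @param n_cp_max maximum complete perforation count.
#' @param pmms perforation density in 1/mm (see [pmms]).
#' @return integer state 0, 1, or 2 (`NA` when either input is `NA`).
#' @export
code_perforation_state <- function(n_cp_max, pmms) {
  stopifnot(all(n_cp_max >= 0, na.rm = TRUE), all(pmms >= 0, na.rm = TRUE))
  out <- ifelse(n_cp_max <= 3, 0L,
                ifelse(n_cp_max >= 16 & pmms >= 0.30, 2L, 1L))
  out[is.na(n_cp_max) | (is.na(pmms) & n_cp_max > 3)] <- NA_integer_
  out
}

#' Code relative cortex thickness (three states)
#'
#' Thresholds from the k=3 median clustering of the observed RTC values:
#' state 0 below 1.2, state 1 in the closed interval \[1.2, 2.8\], state 2
#' above 2.8.
#'
#' @param rtc dimensionless relative cortex thickness (see [rtc]).
#' @return integer state 0, 1, or 2 (`NA` propagates).
#' @export
code_rtc_state <- function(rtc) {
  stopifnot(all(rtc >= 0, na.rm = TRUE))
  ifelse(rtc < 1.2, 0L, ifelse(rtc <= 2.8, 1L, 2L))
}

#' Derive the two quantitative characters from axis measurements
#'
#' Computes [pmms] and [rtc] per taxon and codes the perforation-degree and
#' cortex-thickness character states.  Missing measurements yield missing
#' derived values and states, never zeros.
#'
#' @param measurements data frame with columns `taxon`, `n_cp_max`,
#'   `d_stele_max`, `d_stem_max` (diameters in mm).
#' @return data frame with columns `taxon`, `pmms`, `rtc`,
#'   `perforation_state`, `rtc_state`.
#' @export
derive_axis_characters <- function(measurements) {
  req <- c("taxon", "n_cp_max", "d_stele_max", "d_stem_max")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("measurement table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  p <- ifelse(is.na(measurements$n_cp_max) | is.na(measurements$d_stele_max),
              NA_real_,
              measurements$n_cp_max / (measurements$d_stele_max * pi))
  r <- ifelse(is.na(measurements$d_stem_max) | is.na(measurements$d_stele_max),
              NA_real_,
              (measurements$d_stem_max - measurements$d_stele_max) /
                measurements$d_stele_max)
  if (any(r < 0, na.rm = TRUE)) {
    stop("stele diameter exceeds stem diameter for taxon '",
         measurements$taxon[which(r < 0)[1]], "'", call. = FALSE)
  }
  data.frame(taxon = measurements$taxon,
             pmms = p, rtc = r,
             perforation_state = code_perforation_state(measurements$n_cp_max,
                                                        p),
             rtc_state = code_rtc_state(r),
             stringsAsFactors = FALSE)
}

#' Read an axis-measurement table
#'
#' @param path delimited text file (comma or tab separated) with columns
#'   `taxon`, `n_cp_max`, `d_stele_max`, `d_stem_max`.
#' @return data frame.
#' @export
read_measurements <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
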