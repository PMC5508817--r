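#' Pairwise distance matrices with comparable-character counts
#'
#' @param values symmetric numeric matrix of pairwise distances in `[0, 1]`
#'   with labelled dimnames; `NA` marks an undefined pair.
#' @param comparable optional symmetric integer matrix giving the number of
#'   characters compared for each pair.
#' @return an object of class `osm_dist` with elements `taxa`, `values`,
#'   `comparable`.
#' @export
osm_dist <- function(values, comparable = NULL) {
  values <- as.matrix(values)
  taxa <- rownames(values)
  if (is.null(taxa)) stop("distance matrix needs row names", call. = FALSE)
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  diag(values) <- 0
  structure(list(taxa = taxa, values = values, comparable = comparable),
            class = "osm_dist")
}

#' @export
print.osm_dist <- function(x, ...) {
  cat("<osm_dist> ", length(x$taxa), " taxa; max off-diagonal ",
      format(max(x$values[upper.tri(x$values)], na.rm = TRUE), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Fraction of missing cells for one taxon
#'
#' Ambiguous cells count as observed here: only truly missing (including
#' gap-coded) cells enter the numerator.  The denominator is the full
#' character count of the matrix.
#'
#' @param matrix an [osm_matrix].
#' @param taxon taxon label.
#' @return fraction in `[0, 1]`.
#' @export
missing_fraction <- function(matrix, taxon) {
  if (!taxon %in% matrix$taxa) {
    stop("unknown taxon '", taxon, "'", call. = FALSE)
  }
  mean(is.na(matrix$cells[taxon, ]))
}

missing_fractions <- function(matrix) {
  rowMeans(is.na(matrix$cells))
}

#' Drop taxa exceeding a missing-data threshold
#'
#' Removes every taxon whose missing fraction is strictly greater than
#' `threshold` (taxa exactly at the threshold are retained).
#'
#' @param matrix an [osm_matrix].
#' @param threshold maximum tolerated missing fraction (default 0.6).
#' @return a `subset_result`: list with `matrix`, `dropped_taxa`,
#'   `dropped_characters`, `parent_taxa`.
#' @export
exclude_sparse_taxa <- function(matrix, threshold = 0.6) {
  frac <- missing_fractions(matrix)
  drop <- names(frac)[frac > threshold]
  keep <- setdiff(matrix$taxa, drop)
  if (!length(keep)) {
    stop("all taxa exceed the ", threshold, " missing-data threshold",
         call. = FALSE)
  }
  structure(list(matrix = subset_matrix(matrix, keep),
                 dropped_taxa = drop,
                 dropped_characters = integer(0),
                 parent_taxa = matrix$taxa),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("<subset_result> ", n_taxa(x$matrix), " taxa x ", n_char(x$matrix),
      " characters (dropped ", length(x$dropped_taxa), " taxa, ",
      length(x$dropped_characters), " characters)\n", sep = "")
  invisible(x)
}

#' Characters variable within a taxon set
#'
#' A character is retained when at least two distinct defined singleton
#' states occur among the listed taxa; missing and ambiguous cells do not
#' establish variability.
#'
#' @param matrix an [osm_matrix].
#' @param taxa taxon labels to consider (default: all).
#' @return integer vector of (column) character indices.
#' @export
variable_characters <- function(matrix, taxa = matrix$taxa) {
  miss <- setdiff(taxa, matrix$taxa)
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cells <- matrix$cells[taxa, , drop = FALSE]
  keep <- apply(cells, 2, function(col) {
    def <- col[!is.na(col) & nchar(col) == 1L]
    length(unique(def)) >= 2L
  })
  which(keep)
}

#' Build an analysis subset: sparsity exclusion then invariant removal
#'
#' Applies the two filters in the order the pipeline prescribes: taxa are
#' first dropped by the missing-data rule (assessed against the full parent
#' character set), then characters invariant within the retained taxon set
#' are removed.
#'
#' @param matrix parent [osm_matrix].
#' @param taxa taxon labels defining the subset (default: all taxa).
#' @param name optional subset label carried in the result.
#' @param sparsity_threshold missing-fraction cut-off (default 0.6).
#' @return a `subset_result` whose `matrix` holds only retained taxa and
#'   variable characters.
#' @export
build_subset <- function(matrix, taxa = matrix$taxa, name = NULL,
                         sparsity_threshold = 0.6) {
  miss <- setdiff(taxa, matrix$taxa)
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  sub <- subset_matrix(matrix, taxa)
  step1 <- exclude_sparse_taxa(sub, sparsity_threshold)
  kept <- step1$matrix$taxa
  if (length(kept) < 2L) {
    stop("fewer than 2 taxa retained in subset", call. = FALSE)
  }
  if (length(kept) < 4L) {
    warning("fewer than 4 taxa retained; quartet statistics are undefined",
            call. = FALSE)
  }
  vc <- variable_characters(step1$matrix)
  structure(list(matrix = subset_matrix(step1$matrix, kept, vc),
                 dropped_taxa = step1$dropped_taxa,
                 dropped_characters =
                   step1$matrix$characters$index[setdiff(
                     seq_len(n_char(step1$matrix)), vc)],
                 parent_taxa = taxa,
                 name = name),
            class = "subset_result")
}

#' Mean Hamming distances with pairwise deletion
#'
#' For each pair of taxa the comparable character set consists of characters
#' where both taxa carry a defined singleton state (missing and ambiguous
#' cells are incomparable); the distance is the mismatch fraction over that
#' set.  A pair with no comparable characters is an error naming the pair.
#'
#' @param matrix an [osm_matrix] with at least two taxa.
#' @return an [osm_dist] with `comparable` counts filled in.
#' @export
mean_hamming <- function(matrix) {
  n <- n_taxa(matrix)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  cells <- matrix$cells
  def <- defined_cells(matrix)
  vals <- matrix(0, n, n, dimnames = list(matrix$taxa, matrix$taxa))
  comp <- matrix(0L, n, n, dimnames = dimnames(vals))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- def[i, ] & def[j, ]
      m <- sum(both)
      if (m == 0L) {
        stop("no comparable characters for pair '", matrix$taxa[i], "' / '",
             matrix$taxa[j], "'", call. = FALSE)
      }
      mism <- sum(cells[i, both] != cells[j, both])
      vals[i, j] <- vals[j, i] <- mism / m
      comp[i, j] <- comp[j, i] <- m
    }
  }
  osm_dist(vals, comp)
}

#' Summary statistics of a distance matrix
#'
#' @param d an [osm_dist].
#' @return list with `max` (largest off-diagonal distance), `max_pair`
#'   (labels), `zero_pairs` (two-column label matrix of zero-distance pairs),
#'   `n_zero`, and `n_pairs`.
#' @export
distance_summary <- function(d) {
  v <- d$values
  ut <- upper.tri(v)
  idx <- which(ut, arr.ind = TRUE)
  off <- v[ut]
  imax <- which.max(off)
  zero <- idx[!is.na(off) & off == 0, , drop = FALSE]
  list(max = off[imax],
       max_pair = c(d$taxa[idx[imax, 1]], d$taxa[idx[imax, 2]]),
       zero_pairs = cbind(d$taxa[zero[, 1]], d$taxa[zero[, 2]]),
       n_zero = nrow(zero),
       n_pairs = sum(!is.na(off)))
}
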