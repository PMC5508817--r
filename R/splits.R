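#' Weighted split systems
#'
#' A split is a bipartition of the taxon set; a split system is a weighted
#' collection of splits, either `circular` (every split an interval of one
#' circular taxon ordering, the output class of the neighbour-net) or
#' `frequency` (weights are bootstrap split frequencies in `[0, 1]`).
#' Splits are stored as sorted integer vectors naming one side of the
#' bipartition in canonical orientation: the side containing taxon 1.
#'
#' @param taxa character vector of taxon labels.
#' @param splits list of integer vectors (taxon indices of one side).
#' @param weights numeric vector of non-negative split weights.
#' @param kind `"circular"` or `"frequency"`.
#' @param cycle optional circular ordering (permutation of taxon indices).
#' @return an object of class `split_system`.
#' @export
split_system <- function(taxa, splits, weights, kind = "circular",
                         cycle = NULL) {
  n <- length(taxa)
  splits <- lapply(splits, canonical_split, n = n)
  sizes <- lengths(splits)
  if (any(sizes < 1L | sizes > n - 1L)) {
    stop("splits must be proper non-empty subsets of the taxon set",
         call. = FALSE)
  }
  if (any(unlist(splits) > n)) {
    stop("split references a taxon index above ", n, call. = FALSE)
  }
  if (length(weights) != length(splits)) stop("one weight per split")
  if (any(weights < 0)) stop("split weights must be non-negative")
  structure(list(taxa = taxa, splits = splits, weights = as.numeric(weights),
                 kind = kind, cycle = cycle),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat("<split_system> ", length(x$splits), " splits over ", length(x$taxa),
      " taxa (", x$kind, ")\n", sep = "")
  invisible(x)
}

# orient a split so that its recorded side contains taxon index 1
canonical_split <- function(side, n) {
  side <- sort(unique(as.integer(side)))
  if (!1L %in% side) side <- setdiff(seq_len(n), side)
  side
}

split_key <- function(side, n) {
  paste(canonical_split(side, n), collapse = ",")
}

#' Number of non-trivial splits in a system
#' @param s a [split_system].
#' @return integer count of splits with both sides of size >= 2.
#' @export
n_internal_splits <- function(s) {
  n <- length(s$taxa)
  sum(lengths(s$splits) >= 2 & lengths(s$splits) <= n - 2)
}

# all distinct interval splits of a circular ordering (n*(n-1)/2 of them)
circular_interval_splits <- function(order) {
  n <- length(order)
  seen <- character(0)
  out <- list()
  for (size in seq_len(n %/% 2)) {
    for (start in seq_len(n)) {
      idx <- order[((start - 1L + seq_len(size) - 1L) %% n) + 1L]
      key <- split_key(idx, n)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- canonical_split(idx, n)
      }
    }
  }
  out
}

# TRUE when a split is an interval of the circular order
is_interval_of_cycle <- function(side, order) {
  n <- length(order)
  pos <- sort(match(side, order))
  if (length(pos) == n || length(pos) == 0) return(FALSE)
  gaps <- diff(c(pos, pos[1] + n))
  sum(gaps > 1L) <= 1L
}

# TRUE when two canonical splits are compatible (could sit in one tree)
splits_compatible <- function(a, b, n) {
  ac <- setdiff(seq_len(n), a)
  bc <- setdiff(seq_len(n), b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}
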