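#' Resample characters with replacement
#'
#' Non-parametric bootstrap draw: the same taxa, with characters sampled
#' with replacement to the original count.  Source column indices are
#' recorded in attribute `source_indices`.
#'
#' @param matrix an [osm_matrix] with >= 1 character.
#' @return an [osm_matrix] of identical dimensions.
#' @export
resample_characters <- function(matrix) {
  p <- n_char(matrix)
  if (p < 1L) stop("matrix has no characters", call. = FALSE)
  idx <- sample.int(p, p, replace = TRUE)
  chars <- matrix$characters[idx, , drop = FALSE]
  chars$index <- seq_len(p)   # renumber; source indices kept as provenance
  out <- osm_matrix(matrix$cells[, idx, drop = FALSE], taxa = matrix$taxa,
                    characters = chars)
  attr(out, "source_indices") <- idx
  out
}

#' Bootstrap split supports
#'
#' Per replicate: resample characters, rebuild a tree under the requested
#' criterion (`nj_ls`: mean Hamming distances + BioNJ; `parsimony`: NNI
#' hill-climb from the replicate's BioNJ tree), and tally the tree's
#' non-trivial splits.  Support is the fraction of completed replicates
#' containing the split.  Replicates in which some taxon pair has no
#' comparable characters are skipped and counted; more than 10% skips is an
#' error (the resampled signal is too sparse to interpret).
#'
#' Randomness is driven by one master seed from which an independent
#' per-replicate seed is drawn, so any single replicate can be reproduced
#' in isolation.
#'
#' @param matrix an [osm_matrix] (typically a subset with invariant
#'   characters already removed).
#' @param replicates number of pseudoreplicates (default 10000).
#' @param criterion `"nj_ls"` or `"parsimony"`.
#' @param seed master seed.
#' @return a `support_table`: list with `taxa`, `frequencies` (named numeric,
#'   keys are canonical split index strings), `splits` (list of integer
#'   vectors), `replicates_completed`, `replicates_skipped`, `criterion`.
#' @export
bootstrap_supports <- function(matrix, replicates = 10000,
                               criterion = c("nj_ls", "parsimony"),
                               seed = 1) {
  criterion <- match.arg(criterion)
  taxa <- matrix$taxa
  n <- length(taxa)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  counts <- new.env(parent = emptyenv())
  completed <- 0L
  skipped <- 0L
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    boot <- resample_characters(matrix)
    dist <- tryCatch(mean_hamming(boot), error = function(e) NULL)
    if (is.null(dist)) {
      skipped <- skipped + 1L
      next
    }
    tree <- bionj(dist)
    if (criterion == "parsimony") {
      tree <- parsimony_search(boot, start = tree, seed = rep_seeds[r])
    }
    for (side in tree_splits(tree, taxa)) {
      key <- paste(side, collapse = ",")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
    completed <- completed + 1L
  }
  if (skipped > 0.10 * replicates) {
    stop(skipped, " of ", replicates, " replicates had incomparable taxon ",
         "pairs; signal too sparse for bootstrapping", call. = FALSE)
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1)) / completed
  splits <- lapply(strsplit(keys, ","), as.integer)
  structure(list(taxa = taxa, frequencies = stats::setNames(freq, keys),
                 splits = splits, replicates_completed = completed,
                 replicates_skipped = skipped, criterion = criterion),
            class = "support_table")
}

#' @export
print.support_table <- function(x, ...) {
  cat("<support_table> ", length(x$frequencies), " splits from ",
      x$replicates_completed, " replicates (", x$criterion, "; ",
      x$replicates_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Look up the bootstrap support of a split
#'
#' @param table a `support_table` from [bootstrap_supports].
#' @param side_a taxon labels (or indices) of one side of the queried split.
#' @return frequency in `[0, 1]`; 0 when the split never occurred.
#' @export
support_for <- function(table, side_a) {
  n <- length(table$taxa)
  idx <- if (is.character(side_a)) match(side_a, table$taxa) else
    as.integer(side_a)
  if (anyNA(idx)) {
    stop("unknown taxon in split query: ",
         paste(side_a[is.na(match(side_a, table$taxa))], collapse = ", "),
         call. = FALSE)
  }
  if (length(idx) < 2L || length(idx) > n - 2L) {
    stop("only non-trivial splits are tabulated (side size 2 .. n-2)",
         call. = FALSE)
  }
  key <- split_key(idx, n)
  f <- table$frequencies[key]
  if (is.na(f)) 0 else unname(f)
}

#' Frequency-weighted consensus (bipartition) network
#'
#' Collects the splits whose bootstrap frequency reaches `min_freq` into a
#' frequency-kind split system with the frequency as weight; trivial
#' one-taxon splits are added at weight 1 so the system stays drawable.
#'
#' @param table a `support_table`.
#' @param min_freq minimum retained frequency (default 0.10, the usual
#'   display filter for bootstrap consensus networks).
#' @return a [split_system] of kind `"frequency"`.
#' @export
consensus_network <- function(table, min_freq = 0.10) {
  n <- length(table$taxa)
  keep <- which(table$frequencies >= min_freq)
  splits <- c(table$splits[keep], as.list(seq_len(n)))
  weights <- c(unname(table$frequencies[keep]), rep(1, n))
  split_system(table$taxa, splits, weights, kind = "frequency")
}

#' Write a support table as delimited text
#'
#' @param table a `support_table`.
#' @param path output path (tab separated: frequency, count, taxon list).
#' @return `path`, invisibly.
#' @export
write_support_table <- function(table, path) {
  ord <- order(table$frequencies, decreasing = TRUE)
  lines <- vapply(ord, function(i) {
    sprintf("%.4f\t%d\t%s", table$frequencies[i],
            round(table$frequencies[i] * table$replicates_completed),
            paste(table$taxa[table$splits[[i]]], collapse = " "))
  }, character(1))
  writeLines(c(sprintf("# criterion=%s replicates=%d skipped=%d",
                       table$criterion, table$replicates_completed,
                       table$replicates_skipped),
               "frequency\tcount\tsplit", lines), path)
  invisible(path)
}
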