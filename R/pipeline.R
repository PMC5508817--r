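#' Run the full network-analysis pipeline on a matrix or subset
#'
#' Fixed stage order: taxon-sparsity exclusion, invariant-character removal,
#' mean Hamming distances, delta report, neighbour-net, split-system export,
#' bootstrap supports per criterion, consensus networks.  All artifacts are
#' written under `out_dir` together with a machine-readable `report.json`;
#' the run is deterministic given `seed`.
#'
#' @param matrix an [osm_matrix], or the path of a NEXUS matrix file.
#' @param taxa optional taxon labels defining the analysis subset (default:
#'   all taxa).
#' @param name label for the analysis (used in file names and the report).
#' @param sparsity_threshold missing-fraction cut-off (default 0.6).
#' @param bootstrap_criteria character vector from `c("nj_ls", "parsimony")`;
#'   empty to skip bootstrapping.
#' @param replicates bootstrap pseudoreplicates (default 10000).
#' @param min_freq consensus-network frequency filter (default 0.10).
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param delta compute the delta report (default TRUE; quadratic-plus cost).
#' @param nnet compute the neighbour-net (default TRUE).
#' @return an `analysis_report` list (also serialised to
#'   `<out_dir>/<name>_report.json`).
#' @export
run_analysis <- function(matrix, taxa = NULL, name = "analysis",
                         sparsity_threshold = 0.6,
                         bootstrap_criteria = "nj_ls", replicates = 10000,
                         min_freq = 0.10, seed = 1, out_dir = tempfile(),
                         delta = TRUE, nnet = TRUE) {
  if (is.character(matrix)) matrix <- read_nexus_matrix(matrix)
  if (is.null(taxa)) taxa <- matrix$taxa
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path_of <- function(suffix) file.path(out_dir, paste0(name, "_", suffix))

  sub <- build_subset(matrix, taxa, name = name,
                      sparsity_threshold = sparsity_threshold)
  report <- list(
    name = name,
    n_taxa_input = length(taxa),
    n_taxa_analysed = n_taxa(sub$matrix),
    n_characters_variable = n_char(sub$matrix),
    dropped_taxa = sub$dropped_taxa,
    dropped_characters = sub$dropped_characters,
    seed = seed)

  d <- mean_hamming(sub$matrix)
  write_distance_matrix(d, path_of("distances.phy"))
  ds <- distance_summary(d)
  report$distance_summary <- list(
    max = ds$max, max_pair = ds$max_pair, n_zero_pairs = ds$n_zero,
    zero_pairs = apply(ds$zero_pairs, 1, paste, collapse = " | "),
    n_pairs = ds$n_pairs)

  if (delta && n_taxa(sub$matrix) >= 4) {
    dr <- delta_report(d)
    write_delta_report(dr, path_of("delta.tsv"))
    report$delta <- list(mdv = dr$mdv,
                         idv_min = min(dr$idv, na.rm = TRUE),
                         idv_min_taxon = names(which.min(dr$idv)),
                         idv_max = max(dr$idv, na.rm = TRUE),
                         idv_max_taxon = names(which.max(dr$idv)),
                         quartets_evaluated = dr$quartets_evaluated,
                         quartets_skipped = dr$quartets_skipped)
  }

  if (nnet && n_taxa(sub$matrix) >= 4) {
    net <- neighbour_net(d)
    write_splits_nexus(net, path_of("nnet.nex"))
    report$neighbour_net <- list(n_splits = length(net$splits),
                                 rss = attr(net, "rss"),
                                 path = paste0(name, "_nnet.nex"))
  }

  report$bootstrap <- list()
  for (crit in bootstrap_criteria) {
    bt <- bootstrap_supports(sub$matrix, replicates = replicates,
                             criterion = crit, seed = seed)
    write_support_table(bt, path_of(paste0("supports_", crit, ".tsv")))
    cn <- consensus_network(bt, min_freq)
    write_splits_nexus(cn, path_of(paste0("consensus_", crit, ".nex")))
    report$bootstrap[[crit]] <-
      list(replicates = bt$replicates_completed,
           skipped = bt$replicates_skipped,
           n_splits_seen = length(bt$frequencies),
           n_splits_consensus = n_internal_splits(cn),
           supports = paste0(name, "_supports_", crit, ".tsv"))
    report$bootstrap[[crit]]$table <- bt
  }

  json <- report
  for (crit in names(json$bootstrap)) json$bootstrap[[crit]]$table <- NULL
  jsonlite::write_json(json, path_of("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$subset <- sub
  report$distances <- d
  report$out_dir <- out_dir
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> '", x$name, "': ", x$n_taxa_analysed, " taxa, ",
      x$n_characters_variable, " variable characters\n", sep = "")
  cat("  max distance ", format(x$distance_summary$max, digits = 3),
      " (", paste(x$distance_summary$max_pair, collapse = " | "), "); ",
      x$distance_summary$n_zero_pairs, " zero pairs\n", sep = "")
  if (!is.null(x$delta)) {
    cat("  mDV ", format(x$delta$mdv, digits = 3), "; iDV ",
        format(x$delta$idv_min, digits = 3), " (", x$delta$idv_min_taxon,
        ") - ", format(x$delta$idv_max, digits = 3), " (",
        x$delta$idv_max_taxon, ")\n", sep = "")
  }
  for (crit in names(x$bootstrap)) {
    cat("  bootstrap ", crit, ": ", x$bootstrap[[crit]]$replicates,
        " replicates, ", x$bootstrap[[crit]]$n_splits_consensus,
        " consensus splits\n", sep = "")
  }
  invisible(x)
}

#' Place a newly scored taxon into existing analyses
#'
#' Appends the new row to the matrix, re-runs the distance stage for each
#' target subset that retains the taxon, and reports nearest neighbours,
#' the taxon's individual delta value, and bootstrap supports for splits
#' grouping it with each candidate genus (label prefix before the first
#' underscore or space).
#'
#' @param matrix parent [osm_matrix].
#' @param taxon label of the new operational unit.
#' @param row cell vector conforming to the matrix schema (see [add_taxon]).
#' @param target_subsets named list of taxon-label vectors (the subsets to
#'   re-run); default: the whole matrix as subset `"all"`.
#' @param sparsity_threshold missing-fraction rule applied to the new row.
#' @param replicates bootstrap replicates per subset (default 1000).
#' @param seed master seed.
#' @param n_neighbours how many nearest neighbours to report (default 5).
#' @return a `placement_report`: per-subset list with `neighbours`
#'   (data frame), `idv`, and `genus_supports` (data frame).
#' @export
place_new_taxon <- function(matrix, taxon, row, target_subsets = NULL,
                            sparsity_threshold = 0.6, replicates = 1000,
                            seed = 1, n_neighbours = 5) {
  aug <- add_taxon(matrix, taxon, row)
  if (missing_fraction(aug, taxon) > sparsity_threshold) {
    stop("new taxon '", taxon, "' exceeds the ",
         round(100 * sparsity_threshold), "% missing-data rule (",
         round(100 * missing_fraction(aug, taxon)), "% missing)",
         call. = FALSE)
  }
  if (is.null(target_subsets)) target_subsets <- list(all = matrix$taxa)
  out <- list()
  for (nm in names(target_subsets)) {
    sub <- build_subset(aug, c(target_subsets[[nm]], taxon), name = nm,
                        sparsity_threshold = sparsity_threshold)
    d <- mean_hamming(sub$matrix)
    others <- setdiff(sub$matrix$taxa, taxon)
    dv <- d$values[taxon, others]
    ord <- order(dv)[seq_len(min(n_neighbours, length(others)))]
    neighbours <- data.frame(taxon = others[ord], distance = unname(dv[ord]),
                             stringsAsFactors = FALSE)
    idv <- if (n_taxa(sub$matrix) >= 4) delta_report(d)$idv[[taxon]] else
      NA_real_
    genera <- unique(sub("[_ ].*$", "", others))
    bt <- bootstrap_supports(sub$matrix, replicates = replicates,
                             criterion = "nj_ls", seed = seed)
    gsupp <- do.call(rbind, lapply(genera, function(g) {
      members <- others[sub("[_ ].*$", "", others) == g]
      side <- c(taxon, members)
      supp <- if (length(side) >= 2 &&
                  length(side) <= n_taxa(sub$matrix) - 2)
        support_for(bt, side) else NA_real_
      data.frame(genus = g, n_members = length(members), support = supp,
                 stringsAsFactors = FALSE)
    }))
    out[[nm]] <- list(neighbours = neighbours, idv = idv,
                      genus_supports = gsupp[order(-gsupp$support), ],
                      n_taxa = n_taxa(sub$matrix),
                      n_characters = n_char(sub$matrix))
  }
  structure(list(taxon = taxon, subsets = out), class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat("<placement_report> '", x$taxon, "'\n", sep = "")
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    cat("  [", nm, "] ", s$n_taxa, " taxa, ", s$n_characters,
        " characters; iDV ", format(s$idv, digits = 3), "\n", sep = "")
    cat("    nearest: ",
        paste(sprintf("%s (%.2f)", s$neighbours$taxon,
                      s$neighbours$distance), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Distance ranges and split supports for named grouping hypotheses
#'
#' For each hypothesis (a named taxon set) reports the range of pairwise
#' distances within the set, the range from the set to all other analysed
#' taxa, and the bootstrap support of the corresponding split under each
#' supplied criterion -- the structure of published sister-pair support
#' tables.
#'
#' @param d an [osm_dist] for the analysed subset.
#' @param support_tables named list of `support_table` objects (name =
#'   criterion), possibly empty.
#' @param hypotheses named list of taxon-label vectors.
#' @return data frame with one row per hypothesis.
#' @export
hypothesis_supports <- function(d, support_tables, hypotheses) {
  rows <- lapply(names(hypotheses), function(nm) {
    side <- hypotheses[[nm]]
    miss <- setdiff(side, d$taxa)
    if (length(miss)) stop("unknown taxon in hypothesis '", nm, "': ",
                           paste(miss, collapse = ", "), call. = FALSE)
    other <- setdiff(d$taxa, side)
    if (!length(other)) {
      row <- data.frame(hypothesis = nm, internal_min = NA_real_,
                        internal_max = NA_real_, external_min = NA_real_,
                        external_max = NA_real_, stringsAsFactors = FALSE)
    } else {
      within <- d$values[side, side][upper.tri(diag(length(side)))]
      between <- d$values[side, other, drop = FALSE]
      row <- data.frame(
        hypothesis = nm,
        internal_min = if (length(within)) min(within) else NA_real_,
        internal_max = if (length(within)) max(within) else NA_real_,
        external_min = min(between), external_max = max(between),
        stringsAsFactors = FALSE)
    }
    for (crit in names(support_tables)) {
      supp <- if (length(side) >= 2 && length(side) <= length(d$taxa) - 2)
        support_for(support_tables[[crit]], side) else NA_real_
      row[[paste0("bs_", crit)]] <- supp
    }
    row
  })
  do.call(rbind, rows)
}

#' Read a named-subset configuration file
#'
#' Plain-text format: `[subset_name]` section headers followed by one taxon
#' label per line; `#` starts a comment.  The packaged
#' `extdata/osmundales_subsets.conf` reconstructs the published
#' genus/clade membership lists.
#'
#' @param path configuration file path.
#' @return named list of character vectors.
#' @export
read_subset_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      current <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[current]] <- character(0)
    } else {
      if (is.null(current)) stop("taxon line before any [subset] header",
                                 call. = FALSE)
      out[[current]] <- c(out[[current]], ln)
    }
  }
  out
}
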