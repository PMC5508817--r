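#' Categorical character matrices
#'
#' An `osm_matrix` holds a taxa-by-characters grid of categorical
#' (unordered, unweighted) character states, the substrate of every analysis
#' in this package.  Cells are stored as strings of state symbols:
#' `"1"` for a defined singleton state, `"02"` for an ambiguous
#' (polymorphic/uncertain) cell covering states 0 and 2, and `NA` for a
#' missing cell.  Gap-coded cells are treated as missing throughout, since the
#' analyses distinguish only defined from undefined observations.
#'
#' @param cells character matrix (rows = taxa, columns = characters); each
#'   entry `NA`, a single state symbol, or a sorted string of >= 2 symbols.
#' @param taxa character vector of unique taxon labels; defaults to
#'   `rownames(cells)`.
#' @param characters optional data frame describing the character schema with
#'   columns `index` (1-based), `label`, and `max_state` (1 = binary,
#'   2 = ternary).  Defaults to an anonymous schema with `max_state` taken
#'   from the observed states (at least 1).
#' @param provenance optional free-text annotations (same shape as `cells`).
#' @return an object of class `osm_matrix` with elements `taxa`,
#'   `characters`, `cells`, and `provenance`.
#' @examples
#' m <- osm_matrix(rbind(t1 = c("0", "1", NA), t2 = c("1", "01", "2")))
#' n_taxa(m)
#' @export
osm_matrix <- function(cells, taxa = rownames(cells), characters = NULL,
                       provenance = NULL) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(taxa)) stop("taxon labels are required", call. = FALSE)
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) != nrow(cells)) {
    stop("cell grid has ", nrow(cells), " rows but ", length(taxa),
         " taxon labels", call. = FALSE)
  }
  rownames(cells) <- taxa
  cells[] <- vapply(cells, normalize_cell, character(1), USE.NAMES = FALSE)
  if (is.null(characters)) {
    max_obs <- apply(cells, 2, function(col) {
      st <- unlist(strsplit(col[!is.na(col)], ""))
      if (!length(st)) 1L else max(as.integer(st), 1L)
    })
    characters <- data.frame(index = seq_len(ncol(cells)),
                             label = paste0("char", seq_len(ncol(cells))),
                             max_state = as.integer(max_obs),
                             stringsAsFactors = FALSE)
  }
  if (anyDuplicated(characters$index)) {
    stop("character indices must be unique", call. = FALSE)
  }
  if (nrow(characters) != ncol(cells)) {
    stop("schema describes ", nrow(characters), " characters but grid has ",
         ncol(cells), " columns", call. = FALSE)
  }
  bad <- validate_states(cells, characters$max_state)
  if (!is.null(bad)) {
    stop("state above declared maximum for taxon '", taxa[bad[1]],
         "', character ", bad[2], call. = FALSE)
  }
  structure(list(taxa = taxa, characters = characters, cells = cells,
                 provenance = provenance),
            class = "osm_matrix")
}

# canonical cell form: NA for missing, sorted unique symbols otherwise
normalize_cell <- function(x) {
  if (is.na(x) || x %in% c("?", "-", "")) return(NA_character_)
  s <- sort(unique(strsplit(x, "")[[1]]))
  if (!all(grepl("^[0-9]$", s))) {
    stop("invalid state symbol in cell '", x, "'", call. = FALSE)
  }
  paste(s, collapse = "")
}

validate_states <- function(cells, max_state) {
  for (j in seq_len(ncol(cells))) {
    col <- cells[, j]
    st <- strsplit(col[!is.na(col)], "")
    hi <- vapply(st, function(s) max(as.integer(s)), integer(1))
    if (length(hi) && any(hi > max_state[j])) {
      i <- which(!is.na(col))[which(hi > max_state[j])[1]]
      return(c(i, j))
    }
  }
  NULL
}

#' @export
print.osm_matrix <- function(x, ...) {
  cat("<osm_matrix> ", n_taxa(x), " taxa x ", n_char(x), " characters; ",
      sum(is.na(x$cells)), " missing, ",
      sum(nchar(x$cells) > 1, na.rm = TRUE), " ambiguous cells\n", sep = "")
  invisible(x)
}

#' @rdname osm_matrix
#' @param x an `osm_matrix`.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname osm_matrix
#' @export
n_char <- function(x) ncol(x$cells)

#' Restrict a matrix to a set of taxa and/or characters
#'
#' @param x an `osm_matrix`.
#' @param taxa taxon labels (or indices) to keep, in the requested order.
#' @param chars character indices to keep.
#' @return an `osm_matrix`.
#' @export
subset_matrix <- function(x, taxa = x$taxa, chars = seq_len(n_char(x))) {
  if (is.character(taxa)) {
    miss <- setdiff(taxa, x$taxa)
    if (length(miss)) {
      stop("unknown taxon: ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  osm_matrix(x$cells[taxa, chars, drop = FALSE],
             characters = x$characters[chars, , drop = FALSE],
             provenance = if (!is.null(x$provenance))
               x$provenance[taxa, chars, drop = FALSE])
}

# TRUE where the cell carries exactly one defined state
defined_cells <- function(x) {
  !is.na(x$cells) & nchar(x$cells) == 1L
}

#' Append one taxon row to a matrix
#'
#' @param x an `osm_matrix`.
#' @param taxon new taxon label.
#' @param row character vector of cells, length `n_char(x)`; `"?"`/`NA` for
#'   missing, multi-symbol strings for ambiguous entries.
#' @return an `osm_matrix` with the taxon appended.
#' @export
add_taxon <- function(x, taxon, row) {
  if (length(row) != n_char(x)) {
    stop("new row has ", length(row), " cells; matrix has ", n_char(x),
         " characters", call. = FALSE)
  }
  row <- vapply(as.character(row), normalize_cell, character(1),
                USE.NAMES = FALSE)
  st <- strsplit(row[!is.na(row)], "")
  hi <- vapply(st, function(s) max(as.integer(s)), integer(1))
  over <- which(hi > x$characters$max_state[!is.na(row)])
  if (length(over)) {
    idx <- which(!is.na(row))[over]
    stop("states exceed declared maximum for character(s) ",
         paste(idx, collapse = ", "), call. = FALSE)
  }
  cells <- rbind(x$cells, row)
  rownames(cells) <- c(x$taxa, taxon)
  osm_matrix(cells, characters = x$characters)
}
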