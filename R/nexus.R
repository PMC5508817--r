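#' Read a categorical character matrix from a NEXUS file
#'
#' Parses the `DATA` (or `CHARACTERS`) block of a NEXUS file: `DIMENSIONS`,
#' `FORMAT` (with `SYMBOLS`, `MISSING`, `GAP`) and `MATRIX`.  Both the
#' declared missing and gap symbols map to missing cells; parenthesised or
#' braced multistate entries such as `(01)` or `{01}` become ambiguous cells.
#' Interleaved matrices are read; taxon order is preserved.
#'
#' @param path path to a NEXUS file.
#' @param dialect `"tolerant"` (default) skips unrecognised commands;
#'   `"strict"` fails on anything unexpected inside the data block.
#' @return an [osm_matrix].
#' @export
read_nexus_matrix <- function(path, dialect = c("tolerant", "strict")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  txt <- strip_nexus_comments(paste(lines, collapse = "\n"))
  if (!grepl("^\\s*#nexus", txt, ignore.case = TRUE)) {
    stop("parse error at line 1: missing #NEXUS header in '", path, "'",
         call. = FALSE)
  }
  block <- extract_nexus_block(txt, c("data", "characters"))
  if (is.null(block)) {
    stop("parse error: no DATA or CHARACTERS block in '", path, "'",
         call. = FALSE)
  }
  cmds <- split_nexus_commands(block)
  ntax <- nchar_decl <- NA_integer_
  missing_sym <- "?"; gap_sym <- "-"; symbols <- c("0", "1", "2")
  matrix_cmd <- NULL
  for (cmd in cmds) {
    kw <- tolower(sub("^\\s*(\\S+).*$", "\\1", cmd))
    if (kw == "dimensions") {
      ntax <- nexus_keyval(cmd, "ntax", ntax)
      nchar_decl <- nexus_keyval(cmd, "nchar", nchar_decl)
    } else if (kw == "format") {
      m <- regmatches(cmd, regexec("missing\\s*=\\s*(\\S)", cmd,
                                   ignore.case = TRUE))[[1]]
      if (length(m)) missing_sym <- m[2]
      g <- regmatches(cmd, regexec("gap\\s*=\\s*(\\S)", cmd,
                                   ignore.case = TRUE))[[1]]
      if (length(g)) gap_sym <- g[2]
      s <- regmatches(cmd, regexec("symbols\\s*=\\s*\"([^\"]*)\"", cmd,
                                   ignore.case = TRUE))[[1]]
      if (length(s)) symbols <- strsplit(gsub("\\s", "", s[2]), "")[[1]]
    } else if (kw == "matrix") {
      matrix_cmd <- sub("^\\s*matrix", "", cmd, ignore.case = TRUE)
    } else if (dialect == "strict" && !kw %in% c("taxlabels", "charlabels",
                                                "charstatelabels", "")) {
      stop("parse error: unexpected command '", kw, "' in data block",
           call. = FALSE)
    }
  }
  if (is.na(ntax) || is.na(nchar_decl)) {
    stop("parse error: DIMENSIONS must declare NTAX and NCHAR", call. = FALSE)
  }
  if (is.null(matrix_cmd)) {
    stop("parse error: data block has no MATRIX command", call. = FALSE)
  }

  rows <- parse_nexus_matrix_rows(matrix_cmd, nchar_decl, missing_sym,
                                  gap_sym, symbols)
  taxa <- names(rows)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label '", taxa[duplicated(taxa)][1], "' in '",
         path, "'", call. = FALSE)
  }
  if (length(taxa) != ntax) {
    stop("parse error: NTAX=", ntax, " but ", length(taxa), " rows read",
         call. = FALSE)
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa
  max_state <- max(as.integer(symbols))
  chars <- data.frame(index = seq_len(nchar_decl),
                      label = paste0("char", seq_len(nchar_decl)),
                      max_state = rep(max_state, nchar_decl),
                      stringsAsFactors = FALSE)
  # tighten max_state per character to the declared symbol range but not
  # below the observed states; binary columns keep max_state 1
  obs <- apply(cells, 2, function(col) {
    st <- unlist(strsplit(col[!is.na(col)], ""))
    if (!length(st)) 1L else max(as.integer(st), 1L)
  })
  chars$max_state <- pmin(chars$max_state, pmax(obs, 1L))
  osm_matrix(cells, characters = chars)
}

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

extract_nexus_block <- function(txt, names) {
  pat <- paste0("(?is)begin\\s+(", paste(names, collapse = "|"),
                ")\\s*;(.*?)end\\s*;")
  m <- regmatches(txt, regexec(pat, txt, perl = TRUE))[[1]]
  if (length(m) < 3) NULL else m[3]
}

split_nexus_commands <- function(block) {
  cmds <- strsplit(block, ";", fixed = TRUE)[[1]]
  trimws(cmds)
}

nexus_keyval <- function(cmd, key, default) {
  m <- regmatches(cmd, regexec(paste0(key, "\\s*=\\s*(\\d+)"), cmd,
                               ignore.case = TRUE))[[1]]
  if (length(m)) as.integer(m[2]) else default
}

parse_nexus_matrix_rows <- function(matrix_cmd, nchar_decl, missing_sym,
                                    gap_sym, symbols) {
  lines <- strsplit(matrix_cmd, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (ln in lines) {
    if (grepl("^'", ln)) {
      m <- regmatches(ln, regexec("^'([^']*)'\\s*(.*)$", ln))[[1]]
      label <- m[2]; body <- m[3]
    } else {
      m <- regmatches(ln, regexec("^(\\S+)\\s*(.*)$", ln))[[1]]
      label <- m[2]; body <- m[3]
    }
    if (!nzchar(body) && !is.null(rows[[label]])) next
    cells <- tokenize_states(body, missing_sym, gap_sym, symbols, label)
    if (!is.null(rows[[label]]) && length(rows[[label]]) >= nchar_decl) {
      # a complete row seen again: duplicate, not interleaved continuation
      stop("duplicate taxon label '", label, "'", call. = FALSE)
    }
    rows[[label]] <- c(rows[[label]], cells)
  }
  n_bad <- vapply(rows, length, integer(1)) != nchar_decl
  if (any(n_bad)) {
    stop("parse error: row '", names(rows)[n_bad][1], "' has ",
         length(rows[n_bad][[1]]), " cells, expected ", nchar_decl,
         call. = FALSE)
  }
  rows
}

tokenize_states <- function(body, missing_sym, gap_sym, symbols, label) {
  body <- gsub("\\s", "", body)
  out <- character(0)
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- regexpr(close, substr(body, i, n), fixed = TRUE)
      if (j < 0) {
        stop("parse error: unterminated multistate entry for taxon '",
             label, "'", call. = FALSE)
      }
      states <- strsplit(substr(body, i + 1L, i + j - 2L), "")[[1]]
      check_symbols(states, symbols, label)
      out <- c(out, paste(sort(unique(states)), collapse = ""))
      i <- i + j
    } else if (ch == missing_sym || ch == gap_sym) {
      out <- c(out, NA_character_)
      i <- i + 1L
    } else {
      check_symbols(ch, symbols, label)
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

check_symbols <- function(states, symbols, label) {
  bad <- setdiff(states, symbols)
  if (length(bad)) {
    stop("undeclared state symbol '", bad[1], "' in row of taxon '", label,
         "'", call. = FALSE)
  }
}

#' Write a character matrix as a NEXUS DATA block
#'
#' Cells are emitted with `?` for missing data and `(..)` for ambiguous
#' entries; [read_nexus_matrix] reproduces the matrix cell-for-cell.
#'
#' @param matrix an [osm_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(matrix, path) {
  if (!inherits(matrix, "osm_matrix")) stop("expected an osm_matrix")
  if (n_taxa(matrix) == 0L) stop("cannot write a matrix with no taxa",
                                 call. = FALSE)
  symbols <- paste(0:max(matrix$characters$max_state), collapse = "")
  fmt_cell <- function(x) {
    ifelse(is.na(x), "?", ifelse(nchar(x) > 1L, paste0("(", x, ")"), x))
  }
  body <- apply(matrix$cells, 1, function(r) paste(fmt_cell(r), collapse = ""))
  labels <- quote_nexus_label(matrix$taxa)
  pad <- max(nchar(labels)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(matrix), n_char(matrix)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            symbols),
    "  MATRIX",
    sprintf("    %-*s%s", pad, labels, body),
    "  ;",
    "END;"), con)
  invisible(path)
}

quote_nexus_label <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.]", x)
  x[needs] <- paste0("'", x[needs], "'")
  x
}

#' Write a distance matrix
#'
#' @param d an [osm_dist] distance matrix.
#' @param path output file path.
#' @param format `"phylip_square"` (label + full row, `%.8g` precision) or
#'   `"nexus_distances"` (NEXUS TAXA + DISTANCES blocks, square).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path,
                                  format = c("phylip_square",
                                             "nexus_distances")) {
  format <- match.arg(format)
  stopifnot(inherits(d, "osm_dist"))
  v <- format(d$values, digits = 8, trim = TRUE, scientific = FALSE)
  rows <- apply(v, 1, paste, collapse = " ")
  labels <- gsub("[[:space:]]", "_", d$taxa)
  if (format == "phylip_square") {
    writeLines(c(sprintf("%d", length(d$taxa)),
                 paste(formatC(labels, width = -12), rows)), path)
  } else {
    writeLines(c(
      "#NEXUS",
      "BEGIN TAXA;",
      sprintf("  DIMENSIONS NTAX=%d;", length(d$taxa)),
      paste0("  TAXLABELS ",
             paste(quote_nexus_label(d$taxa), collapse = " "), ";"),
      "END;",
      "BEGIN DISTANCES;",
      "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
      "  MATRIX",
      sprintf("    %s %s", formatC(quote_nexus_label(d$taxa), width = -12),
              rows),
      "  ;",
      "END;"), path)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Companion reader for [write_distance_matrix]; used for round-trip checks
#' and for importing externally computed distances.
#'
#' @param path path to a PHYLIP square distance file.
#' @return an [osm_dist].
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[-1]), "\\s+")
  toks <- toks[vapply(toks, length, integer(1)) > 0]
  labels <- vapply(toks, `[`, character(1), 1)
  vals <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(n)))
  dimnames(vals) <- list(labels, labels)
  osm_dist(vals)
}

#' Write a split system as a SplitsTree-compatible NEXUS file
#'
#' Emits a `TAXA` block and a `SPLITS` block (the `st_splits` dialect with
#' `CYCLE` and `MATRIX` entries) that loads in splits-graph viewers.
#'
#' @param splits a [split_system].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_splits_nexus <- function(splits, path) {
  stopifnot(inherits(splits, "split_system"))
  n <- length(splits$taxa)
  cyc <- splits$cycle
  if (is.null(cyc)) cyc <- seq_len(n)
  rows <- vapply(seq_along(splits$splits), function(i) {
    sprintf("[%d, size=%d]\t%.10g\t%s,", i, length(splits$splits[[i]]),
            splits$weights[i], paste(splits$splits[[i]], collapse = " "))
  }, character(1))
  writeLines(c(
    "#NEXUS",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "TAXLABELS",
    sprintf("[%d] '%s'", seq_len(n), splits$taxa),
    ";",
    "END; [Taxa]",
    "BEGIN Splits;",
    sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(splits$splits)),
    "FORMAT labels=no weights=yes confidences=no intervals=no;",
    sprintf("CYCLE %s;", paste(cyc, collapse = " ")),
    "MATRIX",
    rows,
    ";",
    "END; [Splits]"), path)
  invisible(path)
}
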