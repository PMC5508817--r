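#' Delta value of a single quartet
#'
#' For four taxa the three pairings of the six pairwise distances give sums
#' `s1 = d(x,y) + d(z,w)`, `s2 = d(x,z) + d(y,w)`, `s3 = d(x,w) + d(y,z)`.
#' With the sums ordered `m1 >= m2 >= m3`, the delta value is
#' `(m1 - m2) / (m1 - m3)`, and 0 by convention when `m1 = m3`.  A tree
#' metric satisfies the four-point condition (the two largest sums equal),
#' giving delta 0; delta near 1 marks maximally conflicting signal.
#'
#' @param d an [osm_dist].
#' @param quartet four taxon labels or indices.
#' @return delta in `[0, 1]`, or `NA` when any of the six distances is
#'   undefined.
#' @export
quartet_delta <- function(d, quartet) {
  idx <- if (is.character(quartet)) match(quartet, d$taxa) else quartet
  if (length(idx) != 4L || anyNA(idx)) {
    stop("quartet must name four taxa of the matrix", call. = FALSE)
  }
  v <- d$values
  i <- idx[1]; j <- idx[2]; k <- idx[3]; l <- idx[4]
  s <- c(v[i, j] + v[k, l], v[i, k] + v[j, l], v[i, l] + v[j, k])
  if (anyNA(s)) return(NA_real_)
  s <- sort(s, decreasing = TRUE)
  if (s[1] - s[3] < 1e-12) return(0)
  (s[1] - s[2]) / (s[1] - s[3])
}

#' Matrix and individual delta values
#'
#' Enumerates all `choose(n, 4)` quartets of the distance matrix.  The
#' matrix delta value (mDV) is the mean quartet delta; the individual delta
#' value (iDV) of a taxon is the mean over the quartets containing it.
#' Quartets involving an undefined pair distance are skipped (excluded from
#' both averages) and counted.
#'
#' @param d an [osm_dist] over at least 4 taxa.
#' @return a `delta_report`: list with `mdv`, `idv` (named vector),
#'   `quartets_evaluated`, `quartets_skipped`.
#' @export
delta_report <- function(d) {
  n <- length(d$taxa)
  if (n < 4L) stop("delta values need at least 4 taxa", call. = FALSE)
  v <- d$values
  # pairs (k < l) among indices strictly above j, precomputed per j
  pairs_after <- vector("list", n)
  for (j in seq_len(n - 2L)) {
    kk <- (j + 1L):(n - 1L)
    pk <- rep.int(kk, n - kk)
    pl <- unlist(lapply(kk, function(k) (k + 1L):n), use.names = FALSE)
    pairs_after[[j]] <- cbind(pk, pl)
  }
  total <- 0
  count <- 0L
  skipped <- 0L
  idv_sum <- numeric(n)
  idv_n <- numeric(n)
  for (i in seq_len(n - 3L)) {
    for (j in (i + 1L):(n - 2L)) {
      p <- pairs_after[[j]]
      k <- p[, 1L]; l <- p[, 2L]
      s1 <- v[i, j] + v[cbind(k, l)]
      s2 <- v[cbind(i, k)] + v[cbind(j, l)]
      s3 <- v[cbind(i, l)] + v[cbind(j, k)]
      m1 <- pmax(s1, s2, s3)
      m3 <- pmin(s1, s2, s3)
      m2 <- s1 + s2 + s3 - m1 - m3
      rng <- m1 - m3
      delta <- ifelse(rng < 1e-12, 0, (m1 - m2) / rng)
      ok <- !is.na(delta)
      nok <- sum(ok)
      skipped <- skipped + sum(!ok)
      if (!nok) next
      delta <- delta[ok]
      k <- k[ok]; l <- l[ok]
      total <- total + sum(delta)
      count <- count + nok
      idv_sum[i] <- idv_sum[i] + sum(delta)
      idv_sum[j] <- idv_sum[j] + sum(delta)
      idv_n[i] <- idv_n[i] + nok
      idv_n[j] <- idv_n[j] + nok
      sk <- rowsum(delta, k)
      idv_sum[as.integer(rownames(sk))] <-
        idv_sum[as.integer(rownames(sk))] + sk[, 1L]
      nk <- rowsum(rep(1, length(k)), k)
      idv_n[as.integer(rownames(nk))] <-
        idv_n[as.integer(rownames(nk))] + nk[, 1L]
      sl <- rowsum(delta, l)
      idv_sum[as.integer(rownames(sl))] <-
        idv_sum[as.integer(rownames(sl))] + sl[, 1L]
      nl <- rowsum(rep(1, length(l)), l)
      idv_n[as.integer(rownames(nl))] <-
        idv_n[as.integer(rownames(nl))] + nl[, 1L]
    }
  }
  idv <- ifelse(idv_n > 0, idv_sum / idv_n, NA_real_)
  names(idv) <- d$taxa
  structure(list(mdv = if (count) total / count else NA_real_,
                 idv = idv,
                 quartets_evaluated = count,
                 quartets_skipped = skipped),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, ...) {
  cat("<delta_report> mDV = ", format(x$mdv, digits = 3), " over ",
      x$quartets_evaluated, " quartets (", x$quartets_skipped,
      " skipped); iDV range ", format(min(x$idv, na.rm = TRUE), digits = 3),
      " - ", format(max(x$idv, na.rm = TRUE), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write a delta report as delimited text
#'
#' @param report a `delta_report`.
#' @param path output path (tab separated; one row per taxon plus an `mDV`
#'   summary comment line).
#' @return `path`, invisibly.
#' @export
write_delta_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mDV\t%.6f\t(quartets evaluated %d, skipped %d)",
                     report$mdv, report$quartets_evaluated,
                     report$quartets_skipped), con)
  writeLines("taxon\tidv", con)
  writeLines(sprintf("%s\t%.6f", names(report$idv), report$idv), con)
  invisible(path)
}
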