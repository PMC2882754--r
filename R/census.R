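# Per-motif presence and pairwise co-occurrence over a tail set.
#
# Presence is "at least one copy": a tail with several copies of a motif
# counts once, so copy number never inflates the table. The pairwise entry
# for two motifs is the number of tails carrying both, and the diagonal
# repeats the single-motif counts.

#' Census of motif presence and co-occurrence
#'
#' @param tails list of [cytoplasmic_tail()] objects or a character vector of
#'   tail sequences.
#' @param motifs named list of `motif_pattern` objects (non-empty), e.g.
#'   [builtin_motifs()].
#' @return object of class `census_table`: list with `motifs` (names, in
#'   registry order), `n_tails`, `singles` (named integer vector of tails with
#'   at least one copy), `pairs` (symmetric integer matrix; `pairs[a, b]` =
#'   tails with both `a` and `b`; diagonal = `singles`) and `presence` (the
#'   underlying tails-by-motifs logical matrix).
#' @examples
#' run_census(c("YAALAA", "EAAALL", "YAALEAAALL"),
#'            builtin_motifs()[c("YXXphi", "dileucine")])
#' @export
run_census <- function(tails, motifs = builtin_motifs()) {
  stopifnot(length(motifs) > 0L)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    names(motifs) <- vapply(motifs, `[[`, "", "name")
  }
  tails <- as_tail_list(tails)
  n <- length(tails)
  presence <- matrix(FALSE, nrow = n, ncol = length(motifs),
                     dimnames = list(NULL, names(motifs)))
  for (j in seq_along(motifs)) {
    presence[, j] <- vapply(tails, has_motif, TRUE, pattern = motifs[[j]])
  }
  pm <- matrix(as.integer(presence), nrow = n, ncol = length(motifs))
  pairs <- t(pm) %*% pm
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(names(motifs), names(motifs))
  structure(list(motifs = names(motifs), n_tails = n,
                 singles = stats::setNames(as.integer(diag(pairs)),
                                           names(motifs)),
                 pairs = pairs, presence = presence),
            class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat("<census_table> ", x$n_tails, " tails x ", length(x$motifs),
      " motifs\n", sep = "")
  tab <- x$pairs
  if (x$n_tails > 0L) {
    pct <- round(100 * x$singles / x$n_tails)
    cat("presence: ",
        paste0(x$motifs, " ", x$singles, " (", pct, "%)", collapse = ", "),
        "\n", sep = "")
  }
  print(tab)
  invisible(x)
}

#' Fraction of motif-a tails that also carry motif b
#'
#' `pairs[a, b] / singles[a]`, the conditional co-occurrence used to report
#' statements such as "93% of the tails with the anchor motif also have a
#' YXXphi".
#'
#' @param table a `census_table`.
#' @param a,b motif names in the table.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(table, a, b) {
  stopifnot(inherits(table, "census_table"),
            a %in% table$motifs, b %in% table$motifs)
  if (table$singles[[a]] == 0L) {
    stop("overlap_fraction undefined: no tails carry motif '", a, "'")
  }
  unname(table$pairs[a, b] / table$singles[[a]])
}

#' Tails with an anchor motif, and how many also carry any of a set of others
#'
#' @param tails tail collection as in [run_census()].
#' @param anchor_motif a `motif_pattern`.
#' @param others list of `motif_pattern` objects (may be empty).
#' @return integer vector `c(with_anchor = ..., with_any_other = ...)`;
#'   the second count is over tails that carry the anchor and at least one of
#'   `others`.
#' @export
any_of_overlap <- function(tails, anchor_motif, others) {
  stopifnot(inherits(anchor_motif, "motif_pattern"))
  tails <- as_tail_list(tails)
  has_anchor <- vapply(tails, has_motif, TRUE, pattern = anchor_motif)
  if (length(others) == 0L) {
    return(c(with_anchor = sum(has_anchor), with_any_other = 0L))
  }
  has_other <- rep(FALSE, length(tails))
  for (p in others) {
    has_other <- has_other | vapply(tails, has_motif, TRUE, pattern = p)
  }
  c(with_anchor = sum(has_anchor),
    with_any_other = sum(has_anchor & has_other))
}

#' Fraction of tails carrying none of a set of signals
#'
#' @param tails non-empty tail collection.
#' @param signal_set list of `motif_pattern` objects; an empty set yields 1.
#' @return fraction in \[0, 1\].
#' @examples
#' no_signal_fraction(c("AAAA", "YAAL"), classical_motifs())  # 0.5
#' @export
no_signal_fraction <- function(tails, signal_set) {
  tails <- as_tail_list(tails)
  if (length(tails) == 0L) stop("no_signal_fraction: empty tail set")
  if (length(signal_set) == 0L) return(1)
  has_any <- rep(FALSE, length(tails))
  for (p in signal_set) {
    has_any <- has_any | vapply(tails, has_motif, TRUE, pattern = p)
  }
  mean(!has_any)
}

#' Write a census table as TSV
#'
#' Layout mirrors the motif-by-motif co-occurrence table: first column is the
#' motif name, remaining columns the pairwise counts (diagonal = tails with at
#' least one copy of that motif), plus `n_tails` attached as a comment line.
#'
#' @param table a `census_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(table, path) {
  stopifnot(inherits(table, "census_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_tails=", table$n_tails), con)
  df <- data.frame(motif = table$motifs, table$pairs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
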