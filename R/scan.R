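# Scanning amino-acid tails for motif pattern matches.

# residues that may appear in sequences but match wildcards only
AA_UNKNOWN <- c("X", "B", "Z", "U", "J", "O")

tail_sequence <- function(tail) {
  if (inherits(tail, "cytoplasmic_tail")) tail$sequence else as.character(tail)
}

tail_identifier <- function(tail, default = "tail") {
  if (inherits(tail, "cytoplasmic_tail")) tail$protein_id else default
}

#' Scan a cytoplasmic tail for a motif
#'
#' Reports every window of the tail (including overlapping ones) whose
#' residues satisfy all position specs of the pattern, subject to the
#' pattern's C-terminal anchor if it has one. Scanning is case-insensitive.
#' Unknown residue codes (X, B, Z, U, J, O) match wildcards only, never exact
#' residues or classes. A tail shorter than the pattern yields no hits.
#'
#' @param tail a [cytoplasmic_tail()] or a plain amino-acid string.
#' @param pattern a `motif_pattern` from [compile_pattern()] or
#'   [builtin_motifs()].
#' @param tail_id identifier used in the output when `tail` is a plain string.
#' @return data frame with columns `tail_id`, `motif`, `start`, `end`
#'   (1-based, inclusive, N-to-C) and `match` (the matched slice), ordered by
#'   `start`.
#' @examples
#' scan_tail("RYRRSLNHK", builtin_motifs()$YXXXphiN)
#' @export
scan_tail <- function(tail, pattern, tail_id = tail_identifier(tail)) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- toupper(tail_sequence(tail))
  m <- length(pattern$elements)
  L <- nchar(seq)
  empty <- data.frame(tail_id = character(), motif = character(),
                      start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (L < m) return(empty)
  chars <- seq_chars(seq)
  n_pos <- L - m + 1L
  ok <- rep(TRUE, n_pos)
  for (j in seq_len(m)) {
    el <- pattern$elements[[j]]
    if (el$type == "wildcard") next
    ok <- ok & chars[seq_len(n_pos) + (j - 1L)] %in% el$residues
  }
  starts <- which(ok)
  if (!is.na(pattern$max_after)) {
    # anchor: at most max_after residues strictly after the final position
    starts <- starts[L - (starts + m - 1L) <= pattern$max_after]
  }
  if (length(starts) == 0L) return(empty)
  data.frame(tail_id = tail_id, motif = pattern$name,
             start = starts, end = starts + m - 1L,
             match = substring(seq, starts, starts + m - 1L),
             stringsAsFactors = FALSE)
}

#' Does a tail contain at least one copy of a motif?
#'
#' @inheritParams scan_tail
#' @return `TRUE` iff [scan_tail()] reports one or more hits.
#' @export
has_motif <- function(tail, pattern) {
  nrow(scan_tail(tail, pattern)) > 0L
}

#' Scan many tails against a motif registry
#'
#' @param tails list of [cytoplasmic_tail()] objects or a (possibly named)
#'   character vector of tail sequences.
#' @param motifs named list of `motif_pattern` objects, e.g.
#'   [builtin_motifs()].
#' @return data frame of hits in the [scan_tail()] layout, ordered by tail,
#'   then motif (registry order), then start.
#' @export
scan_tails <- function(tails, motifs = builtin_motifs()) {
  stopifnot(length(motifs) > 0L)
  tails <- as_tail_list(tails)
  out <- vector("list", length(tails) * length(motifs))
  k <- 0L
  for (tl in tails) {
    for (p in motifs) {
      k <- k + 1L
      out[[k]] <- scan_tail(tl, p)
    }
  }
  do.call(rbind, out)
}

# coerce character vectors / lists into a list of cytoplasmic_tail objects
as_tail_list <- function(tails) {
  if (inherits(tails, "cytoplasmic_tail")) return(list(tails))
  if (is.character(tails)) {
    ids <- names(tails) %||% paste0("tail", seq_along(tails))
    if (is.null(names(tails))) names(ids) <- NULL
    return(mapply(function(s, id) cytoplasmic_tail(id, s),
                  tails, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(is.list(tails),
            all(vapply(tails, inherits, TRUE, "cytoplasmic_tail")))
  tails
}
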