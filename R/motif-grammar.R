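# Positional pattern mini-language for short linear sorting motifs.
#
# A pattern is written as whitespace-separated position tokens, N to C:
#   A          exact residue (any single one-letter code)
#   x          wildcard (matches any residue, including unknowns)
#   [DE]       alternative set of exact residues
#   {Phi}      named residue class, looked up in a class registry
# and may end with an anchor token `@C<=k`, meaning at most k residues of the
# tail may follow the final matched position (k = 0 pins the match to the
# C-terminus). Example: "D x x L L @C<=3" is the GGA-binding DXXLL signal
# restricted to within three residues of the C-terminus.

#' Define a residue class
#'
#' A residue class is a named set of one-letter amino-acid codes, referenced
#' from patterns as `{name}`. The stock class `Phi` is the conventional bulky
#' hydrophobic set \{L, I, M, F, V\} used by tyrosine-based sorting signals.
#'
#' @param name identifier for the class.
#' @param members character vector of one-letter codes drawn from the 20
#'   standard amino acids; must be non-empty.
#' @return an object of class `residue_class`.
#' @examples
#' residue_class("Phi", c("L", "I", "M", "F", "V"))
#' @export
residue_class <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- toupper(unique(as.character(members)))
  if (length(members) == 0L) {
    stop("residue class '", name, "' must have at least one member")
  }
  bad <- setdiff(members, AA_STANDARD)
  if (length(bad) > 0L) {
    stop("residue class '", name, "' contains non-standard codes: ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, members = members), class = "residue_class")
}

#' Default residue-class registry
#'
#' Contains the single class `Phi` = \{L, I, M, F, V\}, the bulky hydrophobic
#' residues recognised in the Y-x-x-Phi position of tyrosine-based motifs.
#' The set is configurable: pass a modified registry to [compile_pattern()].
#'
#' @return named list of [residue_class()] objects.
#' @export
default_classes <- function() {
  list(Phi = residue_class("Phi", c("L", "I", "M", "F", "V")))
}

#' Compile a motif pattern from the mini-language
#'
#' @param spec pattern string (see the package vignette for the grammar).
#' @param name name to give the motif; defaults to the spec string.
#' @param classes named list of [residue_class()] objects available to
#'   `{class}` tokens; defaults to [default_classes()].
#' @return an object of class `motif_pattern` with fields `name`, `elements`
#'   (list of position specs) and `max_after` (anchor: maximum number of tail
#'   residues allowed after the match, or `NA` for unanchored patterns).
#' @examples
#' compile_pattern("Y x x {Phi}", name = "YXXphi")
#' compile_pattern("D x x L L @C<=3", name = "DXXLL")
#' @export
compile_pattern <- function(spec, name = spec, classes = default_classes()) {
  stopifnot(is.character(spec), length(spec) == 1L)
  tokens <- strsplit(trimws(spec), "[[:space:]]+")[[1L]]
  if (length(tokens) == 0L || !nzchar(tokens[1L])) {
    stop("empty pattern spec")
  }
  max_after <- NA_integer_
  last <- tokens[length(tokens)]
  if (startsWith(last, "@")) {
    m <- regmatches(last, regexec("^@C<=([0-9]+)$", last))[[1L]]
    if (length(m) != 2L) {
      stop("malformed anchor token: '", last, "' (expected @C<=k)")
    }
    max_after <- as.integer(m[2L])
    tokens <- tokens[-length(tokens)]
  }
  if (length(tokens) < 2L) {
    stop("pattern must have at least 2 positions, got ", length(tokens))
  }
  elements <- lapply(tokens, function(tok) {
    if (tok == "x" || tok == "X") {
      list(type = "wildcard", residues = NULL, token = "x")
    } else if (grepl("^[A-WYZa-wyz]$", tok)) {
      r <- toupper(tok)
      if (!r %in% AA_STANDARD) {
        stop("unknown residue token: '", tok, "'")
      }
      list(type = "exact", residues = r, token = r)
    } else if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      rs <- toupper(seq_chars(substr(tok, 2L, nchar(tok) - 1L)))
      bad <- setdiff(rs, AA_STANDARD)
      if (length(bad) > 0L) {
        stop("non-standard residues in alternative set '", tok, "': ",
             paste(bad, collapse = ", "))
      }
      if (length(rs) == 0L) stop("empty alternative set: '", tok, "'")
      list(type = "set", residues = unique(rs),
           token = paste0("[", paste(unique(rs), collapse = ""), "]"))
    } else if (grepl("^\\{[A-Za-z][A-Za-z0-9_]*\\}$", tok)) {
      cls <- substr(tok, 2L, nchar(tok) - 1L)
      if (is.null(classes[[cls]])) {
        stop("unknown residue class: '", cls, "'")
      }
      list(type = "class", residues = classes[[cls]]$members,
           token = paste0("{", cls, "}"))
    } else if (tok == "[]" || grepl("^\\[\\]$", tok)) {
      stop("empty alternative set: '", tok, "'")
    } else {
      stop("cannot parse pattern token: '", tok, "'")
    }
  })
  structure(list(name = name, elements = elements, max_after = max_after),
            class = "motif_pattern")
}

#' Format a compiled pattern back to its mini-language spec
#'
#' `compile_pattern(format_pattern(p))` reproduces the scan semantics of `p`.
#'
#' @param pattern a `motif_pattern`.
#' @return pattern spec string.
#' @export
format_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  spec <- paste(vapply(pattern$elements, `[[`, "", "token"), collapse = " ")
  if (!is.na(pattern$max_after)) {
    spec <- paste0(spec, " @C<=", pattern$max_after)
  }
  spec
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, ": ", format_pattern(x),
      " (", length(x$elements), " positions",
      if (!is.na(x$max_after)) paste0(", anchored @C<=", x$max_after),
      ")\n", sep = "")
  invisible(x)
}

#' Built-in endocytic and trafficking motif registry
#'
#' Returns the six stock motifs, compiled against `classes`:
#' \describe{
#'   \item{YXXphi}{tyrosine-based internalization signal Y-x-x-Phi, bound by
#'     the mu2 subunit of AP-2.}
#'   \item{dileucine}{acidic dileucine \[D/E\]xxxL\[L/I\], bound mainly by the
#'     sigma2 subunit of AP-2.}
#'   \item{FXNPXY}{F-x-N-P-x-Y, recognised by PTB-domain alternative adaptors
#'     (Dab2, ARH, Numb).}
#'   \item{YXXXphiN}{the novel tyrosine-based signal Y-x-x-x-Phi-N.}
#'   \item{DXXLL}{GGA-binding signal, functional only within three residues of
#'     the C-terminus (anchored `@C<=3`).}
#'   \item{KKXX}{dibasic COPI/ER-retrieval signal with the lysines pinned at
#'     the -4 and -3 positions from the C-terminus (anchored `@C<=0`).}
#' }
#'
#' @param classes residue-class registry, default [default_classes()].
#' @return named list of `motif_pattern` objects, in the order above.
#' @examples
#' names(builtin_motifs())
#' @export
builtin_motifs <- function(classes = default_classes()) {
  specs <- c(
    YXXphi    = "Y x x {Phi}",
    dileucine = "[DE] x x x L [LI]",
    FXNPXY    = "F x N P x Y",
    YXXXphiN  = "Y x x x {Phi} N",
    DXXLL     = "D x x L L @C<=3",
    KKXX      = "K K x x @C<=0"
  )
  out <- lapply(names(specs), function(nm) {
    compile_pattern(specs[[nm]], name = nm, classes = classes)
  })
  names(out) <- names(specs)
  out
}

#' The three classical internalization signals
#'
#' The well-characterised subset of [builtin_motifs()] shown to be necessary
#' and sufficient for uptake into clathrin-coated vesicles: YXXphi, the acidic
#' dileucine, and FXNPXY.
#'
#' @inheritParams builtin_motifs
#' @return named list of three `motif_pattern` objects.
#' @export
classical_motifs <- function(classes = default_classes()) {
  builtin_motifs(classes)[c("YXXphi", "dileucine", "FXNPXY")]
}
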