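# Single-pass membrane protein records and topology-aware tail extraction.
#
# Coordinates are 1-based and inclusive throughout, matching the residue
# numbering convention of the motif reports. A record carries exactly one
# transmembrane domain (TMD). For type I topology the C-terminus is
# cytoplasmic (tail = residues tmd_end+1 .. L); for type II the N-terminus is
# cytoplasmic (tail = residues 1 .. tmd_start-1, kept N-to-C as stored).

#' Construct a membrane protein record
#'
#' @param id unique identifier.
#' @param sequence amino-acid sequence.
#' @param tmd_start,tmd_end 1-based inclusive TMD coordinates.
#' @param topology `"I"` or `"II"`.
#' @param source_note free-text provenance note.
#' @return object of class `membrane_protein_record`.
#' @export
membrane_protein_record <- function(id, sequence, tmd_start, tmd_end,
                                    topology, source_note = "") {
  sequence <- toupper(as.character(sequence))
  tmd_start <- as.integer(tmd_start)
  tmd_end <- as.integer(tmd_end)
  topology <- as.character(topology)
  if (!topology %in% c("I", "II")) {
    stop("record '", id, "': topology must be 'I' or 'II', got '",
         topology, "'")
  }
  L <- nchar(sequence)
  if (is.na(tmd_start) || is.na(tmd_end) ||
      tmd_start < 1L || tmd_end < tmd_start || tmd_end > L) {
    stop("record '", id, "': invalid TMD coordinates [", tmd_start, ", ",
         tmd_end, "] for sequence of length ", L)
  }
  structure(list(id = as.character(id), sequence = sequence,
                 tmd_start = tmd_start, tmd_end = tmd_end,
                 topology = topology, source_note = source_note),
            class = "membrane_protein_record")
}

#' Construct a cytoplasmic tail object
#'
#' @param protein_id identifier of the source protein.
#' @param sequence amino-acid string, N to C.
#' @param empty flag set when the source record has no cytoplasmic residues.
#' @return object of class `cytoplasmic_tail` with fields `protein_id`,
#'   `sequence`, `length` and `empty`.
#' @export
cytoplasmic_tail <- function(protein_id, sequence, empty = nchar(sequence) == 0L) {
  sequence <- toupper(as.character(sequence))
  structure(list(protein_id = as.character(protein_id), sequence = sequence,
                 length = nchar(sequence), empty = isTRUE(empty)),
            class = "cytoplasmic_tail")
}

#' @export
print.cytoplasmic_tail <- function(x, ...) {
  cat("<cytoplasmic_tail> ", x$protein_id, " (", x$length, " aa): ",
      if (x$length > 40L) paste0(substr(x$sequence, 1L, 40L), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Read a membrane-protein table
#'
#' Expects a TSV with header columns `id`, `topology`, `tmd_start`, `tmd_end`,
#' `sequence` (any order; extra columns are kept as `source_note` when a
#' `source_note` column is present). Every row is validated against the
#' single-TMD record invariants; offending rows are reported with their file
#' line numbers and duplicate ids are rejected.
#'
#' @param path path to the TSV file.
#' @return list of [membrane_protein_record()] objects, named by id.
#' @export
read_protein_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("id", "topology", "tmd_start", "tmd_end", "sequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("protein table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    dups <- unique(tab$id[duplicated(tab$id)])
    stop("duplicate protein ids: ", paste(dups, collapse = ", "))
  }
  ts <- suppressWarnings(as.integer(tab$tmd_start))
  te <- suppressWarnings(as.integer(tab$tmd_end))
  if (anyNA(ts) || anyNA(te)) {
    bad <- which(is.na(ts) | is.na(te))
    stop("non-integer TMD coordinates at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    rec <- tryCatch(
      membrane_protein_record(tab$id[i], tab$sequence[i], ts[i], te[i],
                              tab$topology[i],
                              source_note = tab$source_note[i] %||% ""),
      error = function(e) {
        stop("line ", i + 1L, ": ", conditionMessage(e), call. = FALSE)
      })
    records[[i]] <- rec
  }
  names(records) <- tab$id
  records
}

#' Extract the cytoplasmic tail of a record by topology
#'
#' Type I proteins have a cytoplasmic C-terminus, so the tail is everything
#' after the TMD; type II proteins have a cytoplasmic N-terminus, so the tail
#' is everything before the TMD, kept in N-to-C orientation as stored.
#' Records whose TMD abuts the relevant terminus yield a zero-length tail
#' flagged `empty`.
#'
#' @param record a [membrane_protein_record()].
#' @return a [cytoplasmic_tail()].
#' @examples
#' r <- membrane_protein_record("p1", strrep("A", 150), 100, 120, "I")
#' extract_tail(r)$length  # 30
#' @export
extract_tail <- function(record) {
  stopifnot(inherits(record, "membrane_protein_record"))
  L <- nchar(record$sequence)
  seq <- if (record$topology == "I") {
    if (record$tmd_end >= L) "" else substr(record$sequence,
                                            record$tmd_end + 1L, L)
  } else {
    if (record$tmd_start <= 1L) "" else substr(record$sequence, 1L,
                                               record$tmd_start - 1L)
  }
  cytoplasmic_tail(record$id, seq)
}

#' Extract tails from a record collection, filtered by topology
#'
#' @param records list of records, e.g. from [read_protein_table()].
#' @param topology `"I"`, `"II"`, or `"both"`. Default `"I"`: the census is
#'   run over type I tails unless asked otherwise.
#' @return list of [cytoplasmic_tail()] objects.
#' @export
extract_tails <- function(records, topology = c("I", "II", "both")) {
  topology <- match.arg(topology)
  keep <- if (topology == "both") records else {
    Filter(function(r) r$topology == topology, records)
  }
  lapply(keep, extract_tail)
}

#' Write cytoplasmic tails to FASTA
#'
#' Headers are `<protein_id> length=<n>`; round-trips losslessly through
#' [read_tail_fasta()]. Zero-length tails are skipped with a warning (FASTA
#' has no standard representation for an empty sequence).
#'
#' @param tails list of [cytoplasmic_tail()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tail_fasta <- function(tails, path) {
  tails <- as_tail_list(tails)
  empty <- vapply(tails, function(t) t$length == 0L, TRUE)
  if (any(empty)) {
    warning(sum(empty), " zero-length tail(s) skipped in FASTA output")
    tails <- tails[!empty]
  }
  seqs <- Biostrings::AAStringSet(vapply(tails, `[[`, "", "sequence"))
  names(seqs) <- vapply(tails, function(t) {
    paste0(t$protein_id, " length=", t$length)
  }, "")
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read cytoplasmic tails from FASTA
#'
#' @param path FASTA path (as written by [write_tail_fasta()], or any plain
#'   amino-acid FASTA; the id is the first whitespace-delimited header word).
#' @return list of [cytoplasmic_tail()] objects.
#' @export
read_tail_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, "", 1L)
  mapply(cytoplasmic_tail, ids, as.character(seqs),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
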