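# Independent brute-force motif matcher used as an oracle. Deliberately
# naive: it examines every window with explicit per-position loops and its
# own anchor arithmetic, sharing no code with the package scan path.

oracle_match_starts <- function(sequence, pattern) {
  seq <- toupper(sequence)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(pattern$elements)
  L <- length(chars)
  starts <- integer(0)
  if (L < m) return(starts)
  for (s in 1:(L - m + 1)) {
    match_ok <- TRUE
    for (j in 1:m) {
      el <- pattern$elements[[j]]
      ch <- chars[s + j - 1]
      ok <- if (el$type == "wildcard") TRUE else ch %in% el$residues
      if (!ok) { match_ok <- FALSE; break }
    }
    if (match_ok && !is.na(pattern$max_after)) {
      residues_after <- L - (s + m - 1)
      if (residues_after > pattern$max_after) match_ok <- FALSE
    }
    if (match_ok) starts <- c(starts, s)
  }
  starts
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_tail_seq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
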