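# In-silico construction of the random-tail reporter library.
#
# The wet protocol being modelled: genomic DNA is digested with Sau3AI
# (cuts ^GATC, leaving a BamHI-compatible 5' GATC overhang), 50-100 bp
# fragments are gel purified and ligated into the BamHI site of a reporter
# plasmid whose empty cytoplasmic tail translates to KRLKRRRI-PISTFHDDR
# (dash = insertion point). Fragment bookkeeping is single-stranded on the
# forward strand: a fragment's sequence includes its leading GATC once, so
# concatenating a digest reconstructs the genome and no junction nucleotide
# is double-counted when splicing into the vector.

#' Construct a genome object
#'
#' @param sequence DNA string over A/C/G/T.
#' @param id identifier.
#' @param circular is the molecule circular?
#' @return object of class `genome`.
#' @export
genome <- function(sequence, id = "genome", circular = FALSE) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("genome must have length >= 1")
  if (grepl("[^ACGT]", sequence)) {
    stop("genome contains non-ACGT characters")
  }
  structure(list(id = as.character(id), sequence = sequence,
                 circular = isTRUE(circular)), class = "genome")
}

#' Restriction digestion at a palindromic site
#'
#' Cuts immediately 5' of every occurrence of `site` on the forward strand
#' (Sau3AI semantics: ^GATC), so every internal fragment begins with the
#' recognition site, which is its 5' overhang. Linear molecules yield
#' terminal fragments lacking the overhang on their outer end; on circular
#' molecules every fragment carries both overhangs (the fragment spanning the
#' origin is read with wraparound). Concatenating the fragment sequences in
#' order reconstructs the genome (or a rotation of it when circular).
#'
#' @param g a [genome()].
#' @param site recognition site; must equal its own reverse complement
#'   (asserted). Default `"GATC"`.
#' @return data frame of class `digest_result` with columns `fragment_id`,
#'   `start`, `end` (1-based inclusive on the source; `end` may exceed the
#'   genome length for a circular wraparound fragment), `sequence`,
#'   `left_overhang_present`, `right_overhang_present`.
#' @examples
#' digest(genome("AAGATCTTGATCAA"))$sequence  # "AA" "GATCTT" "GATCAA"
#' @export
digest <- function(g, site = "GATC") {
  stopifnot(inherits(g, "genome"))
  site <- toupper(site)
  if (grepl("[^ACGT]", site)) stop("site contains non-ACGT characters")
  if (site != revcomp(site)) {
    stop("recognition site '", site, "' is not palindromic")
  }
  seq <- g$sequence
  L <- nchar(seq)
  hits <- gregexpr(site, seq, fixed = TRUE)[[1L]]
  cuts <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  frag <- function(start, end, seqs, left, right, id) {
    data.frame(fragment_id = id, start = start, end = end, sequence = seqs,
               left_overhang_present = left, right_overhang_present = right,
               stringsAsFactors = FALSE)
  }
  if (!g$circular) {
    bounds <- c(1L, cuts, L + 1L)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    keep <- ends >= starts  # drop the empty lead fragment when a site is at 1
    starts <- starts[keep]; ends <- ends[keep]
    n <- length(starts)
    out <- frag(starts, ends, substring(seq, starts, ends),
                left = starts %in% cuts,
                right = (ends + 1L) %in% cuts,
                id = paste0(g$id, "_f", seq_len(n)))
  } else {
    if (length(cuts) == 0L) {
      out <- frag(1L, L, seq, FALSE, FALSE, paste0(g$id, "_f1"))
    } else {
      starts <- cuts
      ends <- c(cuts[-1L] - 1L, cuts[1L] - 1L + L)  # wraparound for the last
      seqs <- ifelse(ends <= L, substring(seq, starts, ends),
                     paste0(substring(seq, starts, L),
                            substring(seq, 1L, ends - L)))
      out <- frag(starts, ends, seqs, TRUE, TRUE,
                  paste0(g$id, "_f", seq_along(starts)))
    }
  }
  class(out) <- c("digest_result", class(out))
  attr(out, "site") <- site
  attr(out, "genome_id") <- g$id
  out
}

#' Gel size selection of restriction fragments
#'
#' Retains fragments with `min_bp <= length <= max_bp` (both bounds
#' inclusive), preserving order.
#'
#' @param fragments a digest data frame from [digest()].
#' @param min_bp,max_bp inclusive length bounds; defaults 50 and 100 bp.
#' @return the retained subset, same columns.
#' @export
size_select <- function(fragments, min_bp = 50L, max_bp = 100L) {
  stopifnot(min_bp <= max_bp)
  len <- nchar(fragments$sequence)
  fragments[len >= min_bp & len <= max_bp, , drop = FALSE]
}

#' The default reporter vector context
#'
#' The published vector is specified only by its empty-tail peptide
#' KRLKRRRI-PISTFHDDR (dash = BamHI insertion point), not by its DNA, so a
#' concrete coding sequence is supplied here and is configurable. It is
#' designed so that (a) the religated empty vector translates exactly to
#' KRLKRRRIPISTFHDDR followed by a stop, and (b) the ATC inside the insert's
#' leading GATC overhang codes the invariant isoleucine 8, so every construct
#' peptide begins KRLKRRRI and every in-frame, stop-free construct ends
#' ...IPISTFHDDR.
#'
#' @param upstream_coding DNA ending at the insertion point.
#' @param downstream_coding DNA from the insertion point through the stop
#'   codon.
#' @return object of class `vector_context` with fields `upstream_coding`,
#'   `downstream_coding`, `frame_offset` (bases of the codon left open at the
#'   insertion point).
#' @examples
#' vector_context()$frame_offset
#' @export
vector_context <- function(
    upstream_coding = "AAAAGACTGAAGCGCCGTCG",
    downstream_coding = "GATCCCAATTTCTACTTTTCATGATGACCGTTAA") {
  up <- toupper(upstream_coding)
  down <- toupper(downstream_coding)
  empty <- translate_cds(paste0(up, down))
  if (empty$peptide != "KRLKRRRIPISTFHDDR" || is.na(empty$stop_at)) {
    stop("invalid vector context: religated empty vector must translate to ",
         "KRLKRRRIPISTFHDDR followed by a stop; got '", empty$peptide, "'")
  }
  structure(list(upstream_coding = up, downstream_coding = down,
                 frame_offset = nchar(up) %% 3L),
            class = "vector_context")
}

#' Ligate a fragment into the vector and translate the tail
#'
#' The insert (reverse-complemented into its opposite ligation orientation if
#' `orientation = "reverse"`: the duplex flips, so the top strand becomes
#' GATC + revcomp(core)) is spliced between the vector arms, reconstituting
#' the hybrid BamHI/Sau3AI junctions, and the tail is translated from the
#' vector's frame. A stop codon inside the insert, or one induced by a
#' frameshift, truncates the peptide.
#'
#' @param fragment one row of a [digest()] result (or any list with a
#'   `sequence` starting with the overhang and both overhang flags TRUE), or
#'   `NULL` for the religated empty vector.
#' @param orientation `"forward"` or `"reverse"`.
#' @param vector a [vector_context()].
#' @return object of class `tail_construct`: list with `fragment_id`,
#'   `orientation`, `insert_length`, `tail_peptide`, `insert_peptide` (the
#'   insert-encoded residues between the invariant KRLKRRRI and the vector
#'   C-terminus; the construct's name in reporter nomenclature is its first
#'   three residues), `truncated_by_stop` and `vector_cterm_in_frame`.
#' @examples
#' ligate_and_translate(NULL)$tail_peptide  # "KRLKRRRIPISTFHDDR"
#' @export
ligate_and_translate <- function(fragment, orientation = c("forward", "reverse"),
                                 vector = vector_context()) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(vector, "vector_context"))
  if (is.null(fragment)) {
    insert <- ""
    fragment_id <- "empty"
  } else {
    if (is.data.frame(fragment)) {
      stopifnot(nrow(fragment) == 1L)
      fragment <- as.list(fragment)
    }
    if (!isTRUE(fragment$left_overhang_present) ||
        !isTRUE(fragment$right_overhang_present)) {
      stop("fragment '", fragment$fragment_id,
           "' lacks the 5' overhangs required for ligation")
    }
    insert <- toupper(fragment$sequence)
    if (!startsWith(insert, "GATC")) {
      stop("fragment '", fragment$fragment_id,
           "' does not begin with its GATC overhang")
    }
    if (orientation == "reverse") {
      core <- substr(insert, 5L, nchar(insert))
      insert <- paste0("GATC", revcomp(core))
    }
    fragment_id <- fragment$fragment_id %||% "fragment"
  }
  cds <- paste0(vector$upstream_coding, insert, vector$downstream_coding)
  tr <- translate_cds(cds)
  n_codon_full <- nchar(cds) %/% 3L
  # the stop is "the vector's own" only if it is the last whole codon read
  truncated <- !is.na(tr$stop_at) && tr$stop_at < n_codon_full
  if (is.na(tr$stop_at)) truncated <- TRUE  # frameshift ran off the end
  in_frame <- nchar(insert) %% 3L == 0L
  peptide <- tr$peptide
  insert_pep <- if (!truncated && in_frame) {
    # KRLKRRRI (8 aa) ... IPISTFHDDR (10 aa) bracket the insert residues
    substr(peptide, 9L, nchar(peptide) - 10L)
  } else if (nchar(peptide) > 8L) {
    substr(peptide, 9L, nchar(peptide))
  } else {
    ""
  }
  structure(list(fragment_id = fragment_id, orientation = orientation,
                 insert_length = nchar(insert), tail_peptide = peptide,
                 insert_peptide = insert_pep,
                 truncated_by_stop = truncated,
                 vector_cterm_in_frame = in_frame),
            class = "tail_construct")
}

#' Build all constructs from a size-selected digest
#'
#' Each ligatable fragment is ligated in both orientations (both are equally
#' likely in the wet protocol). Fragments lacking an overhang on either end
#' (the termini of a linear source molecule) cannot ligate into the vector
#' and are dropped.
#'
#' @param fragments digest rows (already size-selected).
#' @param vector a [vector_context()].
#' @return list of `tail_construct` objects, length twice the number of
#'   ligatable fragments.
#' @export
build_constructs <- function(fragments, vector = vector_context()) {
  fragments <- fragments[fragments$left_overhang_present &
                           fragments$right_overhang_present, , drop = FALSE]
  out <- rep(list(NULL), 2L * nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    out[[2L * i - 1L]] <- ligate_and_translate(fragments[i, ], "forward", vector)
    out[[2L * i]] <- ligate_and_translate(fragments[i, ], "reverse", vector)
  }
  out
}

#' Sample a clone library from a construct pool
#'
#' Clones are drawn with replacement, weighted by `weights` (default: equal
#' per pool entry, so fragments appearing multiple times in the source digest
#' — e.g. genomic repeats — are proportionally overrepresented, as observed
#' in the wet library). Reproducible under `seed`.
#'
#' @param constructs non-empty list of `tail_construct` objects.
#' @param n number of clones to draw.
#' @param seed integer seed.
#' @param weights optional non-negative sampling weights, one per construct.
#' @return list of class `clone_sample`: `clones` (sampled constructs),
#'   `index` (sampled pool indices), `seed`.
#' @export
sample_library <- function(constructs, n, seed, weights = NULL) {
  if (length(constructs) == 0L) stop("empty construct pool")
  stopifnot(n >= 1L)
  if (!is.null(weights)) stopifnot(length(weights) == length(constructs))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  idx <- sample.int(length(constructs), size = n, replace = TRUE,
                    prob = weights)
  structure(list(clones = constructs[idx], index = idx,
                 seed = as.integer(seed)),
            class = "clone_sample")
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Clone-diversity and composition statistics for a library sample
#'
#' Distinct and singleton counts are over insert peptide sequences (clone
#' identity). Observed amino-acid frequencies are tallied over insert-encoded
#' residues; expected frequencies come from reading every fragment of the
#' eligible (size-selected) pool in the ligation frame, i.e. from the pool's
#' codon usage. The goodness of fit is Pearson's chi-square over the amino
#' acids with non-zero expectation (degrees of freedom = categories - 1;
#' df = 19 when all 20 residues are expected).
#'
#' @param sample a `clone_sample` from [sample_library()].
#' @param pool optional list of `tail_construct` objects defining the
#'   expected composition; defaults to the distinct constructs in `sample`.
#' @return object of class `library_stats`: `n_clones`, `n_distinct`,
#'   `n_singletons`, `aa_freq_observed`, `aa_freq_expected` (named numeric
#'   vectors over the 20 residues, each summing to 1), `gof_statistic`,
#'   `gof_df`, `gof_p`.
#' @export
library_stats <- function(sample, pool = NULL) {
  stopifnot(inherits(sample, "clone_sample"), length(sample$clones) > 0L)
  peps <- vapply(sample$clones, `[[`, "", "insert_peptide")
  tab <- table(peps)
  n_clones <- length(peps)
  n_distinct <- length(tab)
  n_singletons <- sum(tab == 1L)
  count_aa <- function(peptides) {
    chars <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
    chars <- chars[chars %in% AA_STANDARD]
    counts <- table(factor(chars, levels = AA_STANDARD))
    as.numeric(counts)
  }
  obs_counts <- count_aa(peps)
  pool_peps <- if (is.null(pool)) {
    names(tab)
  } else {
    vapply(pool, `[[`, "", "insert_peptide")
  }
  exp_counts <- count_aa(pool_peps)
  norm <- function(x) if (sum(x) > 0) x / sum(x) else x
  obs_freq <- stats::setNames(norm(obs_counts), AA_STANDARD)
  exp_freq <- stats::setNames(norm(exp_counts), AA_STANDARD)
  use <- exp_freq > 0
  n_obs <- sum(obs_counts)
  if (n_obs > 0 && sum(use) > 1L) {
    expected <- exp_freq[use] / sum(exp_freq[use]) * n_obs
    gof <- sum((obs_counts[use] - expected)^2 / expected)
    df <- sum(use) - 1L
    p <- stats::pchisq(gof, df = df, lower.tail = FALSE)
  } else {
    gof <- NA_real_; df <- NA_integer_; p <- NA_real_
  }
  structure(list(n_clones = n_clones, n_distinct = n_distinct,
                 n_singletons = n_singletons,
                 aa_freq_observed = obs_freq, aa_freq_expected = exp_freq,
                 gof_statistic = gof, gof_df = df, gof_p = p),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat("<library_stats> ", x$n_clones, " clones, ", x$n_distinct,
      " distinct, ", x$n_singletons, " singletons; chi-square ",
      signif(x$gof_statistic, 4), " on ", x$gof_df, " df (p = ",
      signif(x$gof_p, 3), ")\n", sep = "")
  invisible(x)
}
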