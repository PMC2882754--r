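# Seeded generators of synthetic proteomes and genomes, so every pipeline
# stage (tail extraction, motif census, library construction, screen) can be
# exercised end-to-end without external data.

# average vertebrate proteome residue frequencies (approximate), used as the
# default background tail composition
AA_BACKGROUND_FREQ <- c(
  A = 0.071, C = 0.023, D = 0.047, E = 0.071, F = 0.036, G = 0.066,
  H = 0.026, I = 0.044, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.012, Y = 0.027)

#' Specification for a synthetic single-pass proteome
#'
#' Defaults emulate the scale of the real tail database the census was run
#' on: 1266 type I and 3528 type II single-pass proteins (fraction type I
#' 0.264) with log-normally distributed tail lengths. By default no motifs
#' are planted: motif occurrences then arise only incidentally from the
#' background composition, as in natural tails; planting rates are raised
#' explicitly in recovery experiments.
#'
#' @param n_proteins number of proteins.
#' @param topology_mix fraction of type I records.
#' @param tail_length_distribution list with `dist` (`"lognormal"`,
#'   `"geometric"` or `"fixed"`) and its parameters (`meanlog`/`sdlog`,
#'   `mean`, or `length`); lengths are clamped to \[1, 500\].
#' @param background_composition named per-residue frequencies over the 20
#'   standard codes, summing to 1.
#' @param plant_rates named per-motif planting probabilities (names must be
#'   motif names of the registry in use); motifs absent from the vector get
#'   rate 0.
#' @param seed integer seed.
#' @return object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins = 500L,
                          topology_mix = 0.264,
                          tail_length_distribution = list(
                            dist = "lognormal", meanlog = log(35), sdlog = 0.8),
                          background_composition = AA_BACKGROUND_FREQ,
                          plant_rates = numeric(0),
                          seed = 1L) {
  stopifnot(n_proteins >= 1L, topology_mix >= 0, topology_mix <= 1,
            all(plant_rates >= 0), all(plant_rates <= 1))
  comp <- background_composition[AA_STANDARD]
  if (anyNA(comp) || abs(sum(comp) - 1) > 1e-6) {
    stop("background_composition must cover the 20 standard residues and sum to 1")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 topology_mix = topology_mix,
                 tail_length_distribution = tail_length_distribution,
                 background_composition = comp,
                 plant_rates = plant_rates, seed = as.integer(seed)),
            class = "proteome_spec")
}

draw_tail_lengths <- function(dist_spec, n) {
  d <- dist_spec$dist %||% "lognormal"
  len <- switch(d,
    lognormal = round(stats::rlnorm(n, dist_spec$meanlog %||% log(35),
                                    dist_spec$sdlog %||% 0.8)),
    geometric = 1L + stats::rgeom(n, prob = 1 / (dist_spec$mean %||% 35)),
    fixed = rep(as.integer(dist_spec$length), n),
    stop("unknown tail length distribution: ", d))
  pmin(pmax(as.integer(len), 1L), 500L)
}

random_residues <- function(n, comp) {
  if (n <= 0L) return("")
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# realize one concrete instance of a pattern, wildcards/classes drawn from comp
realize_motif <- function(pattern, comp) {
  paste(vapply(pattern$elements, function(el) {
    switch(el$type,
           wildcard = sample(names(comp), 1L, prob = comp),
           exact = el$residues,
           sample(el$residues, 1L))
  }, ""), collapse = "")
}

# valid 1-based start positions for planting `pattern` into a tail of length L
plant_positions <- function(pattern, L) {
  m <- length(pattern$elements)
  if (L < m) return(integer(0))
  lo <- 1L
  hi <- L - m + 1L
  if (!is.na(pattern$max_after)) {
    lo <- max(1L, L - pattern$max_after - m + 1L)
  }
  if (lo > hi) integer(0) else lo:hi
}

#' Generate a synthetic single-pass proteome with planted motifs
#'
#' Each protein gets a random ectodomain, a 21-residue hydrophobic TMD, and a
#' background-composition tail; for each motif in `motifs` named in the
#' spec's `plant_rates`, an instance is written into the tail at a random
#' valid position with the given probability (C-terminally anchored motifs
#' are planted at anchor-respecting positions; a tail too short for a chosen
#' motif is re-drawn, up to 20 retries). The returned truth is a full
#' post-hoc scan of every generated tail, so it includes incidental
#' occurrences arising from the background as well as planted ones —
#' downstream recovery is compared against realized, not intended, truth.
#'
#' @param spec a [proteome_spec()].
#' @param motifs motif registry used both for planting and for the truth
#'   scan; default [builtin_motifs()].
#' @return list with `records` (list of [membrane_protein_record()]),
#'   `tails` (list of [cytoplasmic_tail()], all topologies, in record order),
#'   `truth` (logical tails-by-motifs presence matrix from the post-hoc
#'   scan), `planted` (logical matrix of where planting was attempted) and
#'   `spec`.
#' @export
synth_proteome <- function(spec = proteome_spec(), motifs = builtin_motifs()) {
  stopifnot(inherits(spec, "proteome_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_proteins
  comp <- spec$background_composition
  rate_of <- function(nm) unname(spec$plant_rates[nm] %|na|% 0)
  plant_rates <- vapply(names(motifs), rate_of, 0)
  tmd_pool <- c(A = 0.12, I = 0.16, L = 0.30, F = 0.12, V = 0.16, M = 0.05,
                G = 0.06, W = 0.03)
  topo <- ifelse(stats::runif(n) < spec$topology_mix, "I", "II")
  lens <- draw_tail_lengths(spec$tail_length_distribution, n)
  records <- vector("list", n)
  planted <- matrix(FALSE, n, length(motifs),
                    dimnames = list(NULL, names(motifs)))
  for (i in seq_len(n)) {
    plant_here <- stats::runif(length(motifs)) < plant_rates
    L <- lens[i]
    tail_seq <- NULL
    for (try in 1:20) {
      ok <- TRUE
      for (j in which(plant_here)) {
        if (length(plant_positions(motifs[[j]], L)) == 0L) { ok <- FALSE; break }
      }
      if (ok) break
      L <- draw_tail_lengths(spec$tail_length_distribution, 1L)
      if (try == 20L) plant_here[] <- plant_here &
          vapply(motifs, function(p) length(plant_positions(p, L)) > 0L, TRUE)
    }
    tail_seq <- seq_chars(random_residues(L, comp))
    for (j in which(plant_here)) {
      pos <- plant_positions(motifs[[j]], L)
      if (length(pos) == 0L) next
      s <- if (length(pos) == 1L) pos else sample(pos, 1L)
      inst <- seq_chars(realize_motif(motifs[[j]], comp))
      tail_seq[s:(s + length(inst) - 1L)] <- inst
      planted[i, j] <- TRUE
    }
    tail_str <- paste(tail_seq, collapse = "")
    tmd <- random_residues(21L, tmd_pool / sum(tmd_pool))
    ecto_len <- max(30L, round(stats::rlnorm(1, log(150), 0.5)))
    ecto <- random_residues(ecto_len, comp)
    id <- sprintf("synth%05d", i)
    records[[i]] <- if (topo[i] == "I") {
      membrane_protein_record(id, paste0(ecto, tmd, tail_str),
                              ecto_len + 1L, ecto_len + 21L, "I",
                              source_note = "synthetic")
    } else {
      membrane_protein_record(id, paste0(tail_str, tmd, ecto),
                              L + 1L, L + 21L, "II",
                              source_note = "synthetic")
    }
  }
  tails <- lapply(records, extract_tail)
  truth <- matrix(FALSE, n, length(motifs),
                  dimnames = list(vapply(tails, `[[`, "", "protein_id"),
                                  names(motifs)))
  for (j in seq_along(motifs)) {
    truth[, j] <- vapply(tails, has_motif, TRUE, pattern = motifs[[j]])
  }
  list(records = records, tails = tails, truth = truth, planted = planted,
       spec = spec)
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Write a synthetic proteome as a protein table TSV
#'
#' Emits the `id`/`topology`/`tmd_start`/`tmd_end`/`sequence` schema read by
#' [read_protein_table()].
#'
#' @param proteome result of [synth_proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteome, path) {
  recs <- proteome$records
  df <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    topology = vapply(recs, `[[`, "", "topology"),
    tmd_start = vapply(recs, `[[`, 0L, "tmd_start"),
    tmd_end = vapply(recs, `[[`, 0L, "tmd_end"),
    sequence = vapply(recs, `[[`, "", "sequence"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Specification for a synthetic genome with controlled GATC spacing
#'
#' @param length target genome length in bp.
#' @param mean_gap mean inter-site gap (bp) of the geometric spacing model;
#'   the default 75 centres fragment lengths on the 50-100 bp gel window.
#' @param codon_usage named per-codon frequencies over the 64 codons, summing
#'   to 1; default uniform. Inter-site sequence is drawn codon-wise from this
#'   distribution (segments containing an incidental GATC are re-drawn, so
#'   site spacing stays under the spacing model's control).
#' @param circular generate a circular molecule?
#' @param seed integer seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(length = 50000L, mean_gap = 75, codon_usage = NULL,
                        circular = FALSE, seed = 1L) {
  stopifnot(length >= 1L, mean_gap > 0)
  if (is.null(codon_usage)) {
    codons <- as.vector(outer(outer(DNA_ALPHABET, DNA_ALPHABET, paste0),
                              DNA_ALPHABET, paste0))
    codon_usage <- stats::setNames(rep(1 / 64, 64), sort(codons))
  }
  if (abs(sum(codon_usage) - 1) > 1e-6) {
    stop("codon_usage must sum to 1")
  }
  structure(list(length = as.integer(length), mean_gap = mean_gap,
                 codon_usage = codon_usage, circular = isTRUE(circular),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# a GATC-free stretch of ~len bases sampled codon-wise from `usage`
random_gap <- function(len, usage) {
  if (len <= 0L) return("")
  for (try in 1:50) {
    n_codon <- ceiling(len / 3)
    s <- paste(sample(names(usage), n_codon, replace = TRUE, prob = usage),
               collapse = "")
    s <- substr(s, 1L, len)
    if (!grepl("GATC", s, fixed = TRUE)) return(s)
  }
  gsub("GATC", "GATG", s, fixed = TRUE)  # last resort after 50 rejections
}

#' Generate a synthetic genome
#'
#' The genome is an alternation of GATC sites and GATC-free gaps whose
#' lengths are geometric with mean `mean_gap`, truncated to the requested
#' total length; gap sequence follows the spec's codon usage.
#'
#' @param spec a [genome_spec()].
#' @return a [genome()].
#' @export
synth_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  parts <- character(0)
  total <- 0L
  # first gap, then site+gap repeats
  repeat {
    gap_len <- stats::rgeom(1L, prob = 1 / (spec$mean_gap + 1))
    gap <- random_gap(gap_len, spec$codon_usage)
    if (total == 0L) {
      parts <- gap
      total <- nchar(gap)
    } else {
      parts <- c(parts, "GATC", gap)
      total <- total + 4L + nchar(gap)
    }
    if (total >= spec$length) break
    if (total == 0L) total <- 1L  # guard: empty first gap, force progress
  }
  seq <- substr(paste(parts, collapse = ""), 1L, spec$length)
  if (nchar(seq) < spec$length) {
    seq <- paste0(seq, random_gap(spec$length - nchar(seq), spec$codon_usage))
  }
  genome(seq, id = paste0("synth_genome_seed", spec$seed),
         circular = spec$circular)
}
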