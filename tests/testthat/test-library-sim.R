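test_that("digestion cuts 5' of every GATC with hand-checked fragments", {
  expect_identical(digest(genome("AAGATCTTGATCAA"))$sequence,
                   c("AA", "GATCTT", "GATCAA"))
  # no site: single fragment, no overhangs
  d <- digest(genome("AATTCCGG"))
  expect_identical(d$sequence, "AATTCCGG")
  expect_false(d$left_overhang_present)
  expect_false(d$right_overhang_present)
  # circular: wraparound, every fragment overhang-bearing
  dc <- digest(genome("GATCAAGATCTT", circular = TRUE))
  expect_identical(dc$sequence, c("GATCAA", "GATCTT"))
  expect_true(all(dc$left_overhang_present))
  expect_true(all(dc$right_overhang_present))
  # non-palindromic site rejected
  expect_error(digest(genome("AAAA"), site = "GACC"), "palindromic")
})

test_that("digest output reassembles the genome and flags overhangs correctly", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(50:400, 1))
    g <- genome(s)
    d <- digest(g)
    expect_identical(paste(d$sequence, collapse = ""), s)
    internal <- d$left_overhang_present
    expect_true(all(startsWith(d$sequence[internal], "GATC")))
    # site count = fragment count - 1 on a linear molecule (no site at pos 1)
    n_sites <- length(gregexpr("GATC", s, fixed = TRUE)[[1]])
    if (gregexpr("GATC", s, fixed = TRUE)[[1]][1] == -1) n_sites <- 0L
    if (!startsWith(s, "GATC")) {
      expect_identical(nrow(d), n_sites + 1L)
    }
    # circular reassembly is a rotation of the genome
    gc <- genome(s, circular = TRUE)
    dcirc <- digest(gc)
    expect_true(grepl(paste(dcirc$sequence, collapse = ""),
                      paste0(s, s), fixed = TRUE))
  }
})

test_that("digesting the reverse complement mirrors the fragment multiset", {
  set.seed(77)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (i in 1:10) {
    s <- random_dna(300)
    d_fwd <- digest(genome(s))
    d_rev <- digest(genome(rc(s)))
    # the same duplex is cut at the same palindromic sites read from either
    # strand: an internal double-overhang fragment GATC+core reappears in the
    # opposite digest as GATC+revcomp(core)
    internal <- function(d) d$left_overhang_present & d$right_overhang_present
    fwd_int <- d_fwd$sequence[internal(d_fwd)]
    rev_int <- d_rev$sequence[internal(d_rev)]
    mirrored <- vapply(fwd_int, function(f) {
      paste0("GATC", rc(substring(f, 5)))
    }, "", USE.NAMES = FALSE)
    expect_identical(sort(rev_int), sort(mirrored))
  }
})

test_that("size selection keeps the inclusive 50-100 bp window in order", {
  frags <- data.frame(
    fragment_id = paste0("f", 1:4),
    start = 1L, end = 1L,
    sequence = vapply(c(49, 50, 100, 101), random_dna, ""),
    left_overhang_present = TRUE, right_overhang_present = TRUE,
    stringsAsFactors = FALSE)
  kept <- size_select(frags)
  expect_identical(kept$fragment_id, c("f2", "f3"))
  expect_identical(nrow(size_select(frags[0, ])), 0L)
  allin <- frags[2:3, ]
  expect_identical(size_select(allin), allin)
  expect_error(size_select(frags, min_bp = 10, max_bp = 5))
})

test_that("the religated empty vector translates to the published tail peptide", {
  cons <- ligate_and_translate(NULL)
  expect_identical(cons$tail_peptide, "KRLKRRRIPISTFHDDR")
  expect_false(cons$truncated_by_stop)
  expect_true(cons$vector_cterm_in_frame)
})

test_that("in-frame stop-free inserts keep the vector C-terminus in frame", {
  v <- vector_context()
  set.seed(13)
  found_in_frame <- 0
  for (i in 1:60) {
    core_len <- sample(c(2, 5, 8, 11, 26, 47), 1)  # GATC + core = 3k
    core <- random_dna(core_len)
    frag <- list(fragment_id = paste0("r", i),
                 sequence = paste0("GATC", core),
                 left_overhang_present = TRUE, right_overhang_present = TRUE)
    cons <- ligate_and_translate(frag, "forward", v)
    expect_true(startsWith(cons$tail_peptide, "KRLKRRRI"))
    expect_identical(cons$vector_cterm_in_frame, (core_len + 4) %% 3 == 0)
    if (cons$vector_cterm_in_frame && !cons$truncated_by_stop) {
      found_in_frame <- found_in_frame + 1
      expect_true(endsWith(cons$tail_peptide, "PISTFHDDR"))
      expect_identical(
        cons$tail_peptide,
        paste0("KRLKRRRI", cons$insert_peptide, "IPISTFHDDR"))
    }
  }
  expect_gt(found_in_frame, 0)
})

test_that("an in-frame stop inside the insert truncates the peptide", {
  # GATC + codons GCT TAA GCT: TAA is read in frame
  frag <- list(fragment_id = "stop", sequence = "GATCGCTTAAGCT",
               left_overhang_present = TRUE, right_overhang_present = TRUE)
  cons <- ligate_and_translate(frag, "forward")
  expect_true(cons$truncated_by_stop)
  expect_false(endsWith(cons$tail_peptide, "PISTFHDDR"))
  expect_identical(cons$tail_peptide, "KRLKRRRIA")
})

test_that("reverse orientation reverse-complements the core behind the overhang", {
  frag <- list(fragment_id = "f", sequence = "GATCGCTAA",
               left_overhang_present = TRUE, right_overhang_present = TRUE)
  fwd <- ligate_and_translate(frag, "forward")
  rev <- ligate_and_translate(frag, "reverse")
  expect_identical(fwd$insert_length, rev$insert_length)
  expect_false(fwd$truncated_by_stop)
  expect_false(rev$truncated_by_stop)
  # forward core GCTAA reads GCT-AAg -> AK; reverse top strand is
  # GATC + revcomp(GCTAA) = GATCTTAGC, reading TTA-GCg -> LA
  expect_identical(fwd$insert_peptide, "AK")
  expect_identical(rev$insert_peptide, "LA")
})

test_that("fragments without both overhangs are refused ligation", {
  frag <- list(fragment_id = "end", sequence = "GATCAAA",
               left_overhang_present = TRUE, right_overhang_present = FALSE)
  expect_error(ligate_and_translate(frag), "overhang")
})

test_that("library sampling is seeded, reproducible and weight-sensitive", {
  frags <- data.frame(
    fragment_id = paste0("f", 1:3), start = 1L, end = 1L,
    sequence = c("GATCGCTAAA", "GATCCCTTTT", "GATCGGGAAA"),
    left_overhang_present = TRUE, right_overhang_present = TRUE,
    stringsAsFactors = FALSE)
  pool <- build_constructs(frags)
  s1 <- sample_library(pool, n = 40, seed = 9)
  s2 <- sample_library(pool, n = 40, seed = 9)
  expect_identical(s1$index, s2$index)
  expect_error(sample_library(list(), 5, 1), "empty")
  one <- sample_library(pool[1], n = 10, seed = 3)
  expect_identical(library_stats(one)$n_distinct, 1L)
  # heavy weight on entry 1 overrepresents it
  w <- c(50, rep(1, length(pool) - 1))
  sw <- sample_library(pool, n = 500, seed = 4, weights = w)
  expect_gt(mean(sw$index == 1), 0.5)
})

test_that("clone statistics reproduce the published 30-clone complexity example", {
  # 30 sequenced clones: one sequence six times, two three times, one twice,
  # sixteen once -> 20 distinct, 16 unique
  set.seed(2)
  peps <- replicate(20, paste(sample(AA20, 8, replace = TRUE), collapse = ""))
  mult <- c(6, 3, 3, 2, rep(1, 16))
  clones <- lapply(rep(seq_along(peps), mult), function(i) {
    structure(list(fragment_id = paste0("c", i), orientation = "forward",
                   insert_length = 28L, tail_peptide = peps[i],
                   insert_peptide = peps[i], truncated_by_stop = FALSE,
                   vector_cterm_in_frame = TRUE), class = "tail_construct")
  })
  sample <- structure(list(clones = clones, index = seq_along(clones),
                           seed = 1L), class = "clone_sample")
  st <- library_stats(sample)
  expect_identical(st$n_clones, 30L)
  expect_identical(st$n_distinct, 20L)
  expect_identical(st$n_singletons, 16L)
  # all-unique sample: singletons = distinct = clones
  su <- structure(list(clones = clones[!duplicated(peps[rep(seq_along(peps), mult)])],
                       index = 1:20, seed = 1L), class = "clone_sample")
  stu <- library_stats(su)
  expect_identical(stu$n_singletons, stu$n_distinct)
  expect_identical(stu$n_distinct, stu$n_clones)
})

test_that("amino-acid frequencies of a uniform-genome library match expectation", {
  g <- synth_genome(genome_spec(length = 60000, mean_gap = 75, seed = 8))
  frags <- size_select(digest(g))
  pool <- build_constructs(frags)
  pool <- Filter(function(cc) nchar(cc$insert_peptide) > 0, pool)
  smp <- sample_library(pool, n = 400, seed = 21)
  st <- library_stats(smp, pool = pool)
  expect_equal(sum(st$aa_freq_observed), 1, tolerance = 1e-9)
  expect_equal(sum(st$aa_freq_expected), 1, tolerance = 1e-9)
  # observed counts within 3 binomial SE of pool expectation, per residue
  n_obs <- sum(nchar(vapply(smp$clones, `[[`, "", "insert_peptide")))
  for (aa in names(st$aa_freq_expected)) {
    p <- st$aa_freq_expected[[aa]]
    se <- sqrt(p * (1 - p) / n_obs)
    expect_lte(abs(st$aa_freq_observed[[aa]] - p), 3 * se + 1e-12)
  }
  expect_identical(st$gof_df, sum(st$aa_freq_expected > 0) - 1L)
})
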