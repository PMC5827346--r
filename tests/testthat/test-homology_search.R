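# The affine-gap aligner and six-frame translated search.

test_that("local alignment reproduces known scores and degenerate cases", {
  s <- default_score_scheme()
  # M/M + K/K + C/C = 5 + 5 + 9 under the standard table
  h <- local_align("MKC", "MKC", s)
  expect_equal(h$score, 19)
  expect_equal(h$identity, 1)
  expect_equal(h$query_span, c(0, 3))
  h0 <- local_align("AAAA", "CCCC", s)
  expect_equal(h0$score, 0)
  expect_equal(h0$target_span, c(0, 0)) # empty spans
})

test_that("local and global scores equal exhaustive path enumeration", {
  s <- default_score_scheme()
  set.seed(11)
  for (i in 1:40) {
    a <- rand_protein(sample(1:8, 1))
    b <- rand_protein(sample(1:8, 1))
    ea <- edclocus:::.encode_protein(a)
    eb <- edclocus:::.encode_protein(b)
    expect_equal(local_align(a, b, s)$score,
                 edclocus:::cpp_enum_local_score(ea, eb, s$matrix,
                                                 s$gap_open, s$gap_extend),
                 info = paste(a, b))
    expect_equal(global_align(a, b, s)$score,
                 edclocus:::cpp_enum_global_score(ea, eb, s$matrix,
                                                  s$gap_open, s$gap_extend),
                 info = paste(a, b))
  }
})

test_that("alignment scores agree with an independent implementation", {
  s <- default_score_scheme()
  set.seed(23)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (i in 1:10) {
    a <- rand_protein(sample(5:30, 1))
    b <- rand_protein(sample(5:30, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(local_align(a, b, s)$score, max(0, ref))
    refg <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b, s)$score, refg)
  }
})

test_that("local alignment is symmetric and monotone under extension", {
  s <- default_score_scheme()
  set.seed(5)
  for (i in 1:15) {
    a <- rand_protein(sample(3:12, 1))
    b <- rand_protein(sample(3:12, 1))
    expect_equal(local_align(a, b, s)$score, local_align(b, a, s)$score)
    # appending residues never decreases the optimal local score
    expect_gte(local_align(paste0(a, "W"), paste0(b, "M"), s)$score,
               local_align(a, b, s)$score)
  }
})

test_that("global alignment handles identity and terminal gaps", {
  s <- default_score_scheme()
  g <- global_align("MKCW", "MKCW", s)
  expect_equal(g$identity, 1)
  expect_false(grepl("-", g$aligned_a))
  g2 <- global_align("MK", "M", s)
  expect_equal(g2$aligned_a, "MK")
  expect_equal(g2$aligned_b, "M-") # exactly one terminal gap
})

test_that("translated search finds frames, strands and hit coordinates", {
  s <- default_score_scheme()
  set.seed(9)
  dna <- paste0("AT", paste0(sample(c("A","C","G","T"), 90, TRUE),
                             collapse = ""), "C")
  prot <- translate(dna, 2, "+")
  prot <- gsub("\\*", "W", prot) # stop-free query
  # query equal to a frame translation: top hit in that frame, strand +
  q <- translate(paste0("ATG", "AAATGCTGGCATAAGGAATTGATG"), 0, "+")
  target <- paste0("CCG", "ATG", "AAATGCTGGCATAAGGAATTGATG", "TTACC")
  hits <- translated_search(q, target, s, min_score = 20)
  expect_equal(hits[[1]]$identity, 1)
  expect_equal(hits[[1]]$frame, 0)
  expect_equal(hits[[1]]$strand, "+")
  expect_equal(hits[[1]]$target_span, c(3, 3 + 3 * nchar(q)))
  # reverse-complemented target: same score on the minus strand
  hits_rc <- translated_search(q, reverse_complement(target), s,
                               min_score = 20)
  expect_equal(hits_rc[[1]]$score, hits[[1]]$score)
  expect_equal(hits_rc[[1]]$strand, "-")
  expect_error(translated_search(q, target, s, min_score = 0), "min_score")
})

test_that("best translated hit equals the max over six local alignments", {
  s <- default_score_scheme()
  set.seed(31)
  for (i in 1:5) {
    q <- rand_protein(12)
    t <- paste0(sample(c("A","C","G","T"), 120, TRUE), collapse = "")
    hits <- translated_search(q, t, s, min_score = 1)
    best_direct <- max(vapply(seq_len(6), function(k) {
      sf <- six_frame_translate(t)
      local_align(q, sf$protein[k], s)$score
    }, numeric(1)))
    expect_equal(hits[[1]]$score, best_direct)
  }
})

test_that("translated search recovers every planted gene at identity 1", {
  loc <- cached_locus(1)
  tr <- loc$truth
  sc <- loc$scaffolds[[1]]
  genes <- intersect(names(tr$proteins),
                     c("EDC1", "EDC2", "CBP1", "S100A12", "CRNN"))
  for (g in genes) {
    hits <- translated_search(protein_record(g, tr$proteins[[g]]), sc,
                              min_score = 40)
    expect_gt(length(hits), 0)
    top <- hits[[1]]
    m <- tr$models[[g]]
    expect_equal(top$strand, m$strand, info = g)
    span <- c(min(m$coding_span[, 1]), max(m$coding_span[, 2]))
    expect_true(top$target_span[1] < span[2] && top$target_span[2] > span[1],
                info = g)
    if (nrow(m$coding_span) == 1L) # single-exon genes align end to end
      expect_equal(top$identity, 1, info = g)
  }
})

test_that("iterated masking yields one hit per tandem family copy", {
  loc <- cached_locus(1)
  tr <- loc$truth
  hits <- translated_search(protein_record("CBP1", tr$proteins[["CBP1"]]),
                            loc$scaffolds[[1]], min_score = 100)
  cbp_models <- Filter(function(m) m$category == "CBP", tr$models)
  hit_in <- function(m) any(vapply(hits, function(h)
    h$strand == m$strand && h$target_span[1] < m$coding_span[1, 2] &&
      h$target_span[2] > m$coding_span[1, 1], logical(1)))
  expect_true(all(vapply(cbp_models, hit_in, logical(1))))
})
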