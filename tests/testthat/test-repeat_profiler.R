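# Degenerate tandem-repeat detection and ortholog architecture comparison.

test_that("the pattern grammar parses the EDCRP motif and rejects junk", {
  pat <- parse_motif_pattern("CCDPCQ(K|-)(T|P)(V|-)")
  expect_length(pat, 9L)
  expect_equal(pat[[1]], "C")
  expect_setequal(pat[[7]], c("K", ""))
  expect_setequal(pat[[8]], c("T", "P"))
  expect_error(parse_motif_pattern("CC(K|-"), "unbalanced")
  expect_error(parse_motif_pattern("C(Z|K)CC"), "invalid")
  expect_error(parse_motif_pattern("(K|-)(T|-)(V|-)"), "non-optional")
})

test_that("exact tandem arrays are counted by construction", {
  pat <- "CCDPCQ(K|-)(T|P)(V|-)"
  expect_equal(count_motif_copies(strrep("CCDPCQKTV", 3), pat)$copies, 3L)
  for (k in c(1L, 2L, 10L, 50L, 100L))
    expect_equal(count_motif_copies(strrep("CCDPCQKTV", k), pat)$copies, k,
                 info = k)
  # optional positions absent still count as copies
  expect_equal(count_motif_copies(strrep("CCDPCQTP", 4), pat)$copies, 4L)
  expect_null(count_motif_copies("MGGGGSSSSAAAA", pat))
})

test_that("copy counting is invariant to non-matching flanks", {
  pat <- "CCDPCQ(K|-)(T|P)(V|-)"
  core <- strrep("CCDPCQKTV", 5)
  base <- count_motif_copies(core, pat)
  flanked <- count_motif_copies(paste0("MGHWSA", core, "LEEWHG"), pat)
  expect_equal(flanked$copies, base$copies)
  expect_equal(flanked$span[2] - flanked$span[1],
               base$span[2] - base$span[1])
})

test_that("copy counts equal exhaustive tandem decomposition", {
  pat <- "CCDPCQ(K|-)(T|P)(V|-)"
  set.seed(19)
  mutate_unit <- function() {
    u <- strsplit(sample(c("CCDPCQKTV", "CCDPCQTP", "CCDPCQKV",
                           "CCDPCQ"), 1), "")[[1]]
    k <- sample(0:2, 1)
    if (k > 0) u[sample(length(u), k)] <- sample(edclocus:::.AA20, k, TRUE)
    paste0(u, collapse = "")
  }
  n_checked <- 0L
  for (i in 1:50) {
    parts <- replicate(sample(2:6, 1), if (runif(1) < 0.6) mutate_unit()
                       else rand_protein(sample(1:5, 1)))
    p <- substr(paste0(parts, collapse = ""), 1, 60)
    if (nchar(p) < 9) next
    got <- count_motif_copies(p, pat)
    want <- brute_repeat_copies(p, pat)
    expect_equal(if (is.null(got)) 0L else got$copies, want, info = p)
    if (want > 0L) n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 10L) # the fixtures must actually contain arrays
})

test_that("per-copy deviations respect the mismatch allowance", {
  pat <- "CCDPCQ(K|-)(T|P)(V|-)"
  # one mismatch in the second copy (D -> E)
  p <- paste0("CCDPCQKTV", "CCEPCQKTV", "CCDPCQKTV")
  r <- count_motif_copies(p, pat, max_mismatch = 1)
  expect_equal(r$copies, 3L)
  expect_equal(r$per_copy$deviations, c(0L, 1L, 0L))
  # two mismatches in a copy break the array at max_mismatch = 1
  p2 <- paste0("CCDPCQKTV", "CCEECQKTV", "CCDPCQKTV")
  r2 <- count_motif_copies(p2, pat, max_mismatch = 1)
  expect_lt(r2$copies, 3L)
  r3 <- count_motif_copies(p2, pat, max_mismatch = 2)
  expect_equal(r3$copies, 3L)
})

test_that("de novo discovery finds planted units and ignores noise", {
  d <- discover_tandem_repeats("GSGSGSGSGS", min_unit = 2, min_copies = 3)
  expect_length(d, 1L)
  expect_equal(d[[1]]$unit, "GS")
  expect_equal(d[[1]]$copies, 5L)
  # seed-fixed aperiodic protein: no repeats
  set.seed(8)
  noise <- rand_protein(60)
  expect_length(discover_tandem_repeats(noise, min_unit = 3,
                                        min_copies = 3), 0L)
  # a planted 12-copy unit inside flanks is recovered
  unit <- "CQPKGS"
  p <- paste0(rand_protein(20), strrep(unit, 12), rand_protein(20))
  d2 <- discover_tandem_repeats(p, min_unit = 3, min_copies = 3)
  expect_gte(length(d2), 1L)
  expect_equal(d2[[1]]$copies, 12L)
  # consensus is a rotation of the planted unit
  doubled <- paste0(unit, unit)
  expect_true(grepl(d2[[1]]$unit, doubled, fixed = TRUE))
})

test_that("discovery and pattern counting agree on planted units", {
  unit <- "CQPKGS"
  p <- paste0("MAAA", strrep(unit, 8), "WEEE")
  d <- discover_tandem_repeats(p, min_unit = 3, min_copies = 3)[[1]]
  cnt <- count_motif_copies(p, parse_motif_pattern(d$unit),
                            max_mismatch = 0, max_spacer = 0)
  expect_equal(cnt$copies, d$copies)
})

test_that("ortholog architecture comparison reports signed expansion", {
  pat <- "CCDPCQ(K|-)(T|P)(V|-)"
  p <- paste0("MHWLE", strrep("CCDPCQKTV", 4), "WLEHG")
  same <- compare_ortholog_architecture(p, p, pat)
  expect_equal(same$terminal_identity, 100)
  expect_equal(same$expansion, 0L)
  # generator pair with a planted 50-copy expansion
  pair <- generate_ortholog_pair(synthetic_config(seed = 51, n_sedc = 3,
                                                  n_cbp_cluster = 0,
                                                  n_pseudogenes = 0),
                                 divergence = 0, repeat_expansion = 50)
  a <- pair$locus_a$truth$proteins[["EDCRP"]]
  b <- pair$locus_b$truth$proteins[["EDCRP"]]
  cmp <- compare_ortholog_architecture(a, b, pat)
  expect_equal(cmp$expansion, 50L)
  expect_equal(cmp$copies_a, 3L)
  expect_equal(cmp$copies_b, 53L)
  expect_gt(cmp$terminal_identity, 99)
  # the avian-like protein against a repeat-free crocodilian-like protein
  croc_like <- paste0(substr(a, 1, 25), substring(a, nchar(a) - 24))
  cmp2 <- compare_ortholog_architecture(b, croc_like, pat)
  expect_equal(cmp2$copies_b, 0L)
  expect_lte(cmp2$expansion, -53L)
})
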