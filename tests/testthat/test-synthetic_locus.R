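# The ground-truthed locus generator: structure, determinism, composition,
# divergence model and read simulation.

test_that("the generator emits the configured gene complement", {
  loc <- cached_locus(1)
  tr <- loc$truth
  cats <- table(vapply(tr$models, `[[`, "", "category"))
  expect_equal(unname(cats["SEDC"]), 20L)
  expect_equal(unname(cats["SFTP"]), 2L)
  expect_equal(unname(cats["CBP"]), 6L)
  expect_equal(unname(cats["pseudogene"]), 4L)
  for (m in tr$models) {
    if (m$category %in% c("SEDC", "CBP"))
      expect_equal(nrow(m$coding_span), 1L, info = m$id)
    if (m$category == "SFTP")
      expect_equal(nrow(m$coding_span), 2L, info = m$id)
  }
  # markers flank the EDC genes in locus order
  ord <- tr$gene_order
  expect_lt(which(ord == "S100A12"),
            min(which(ord %in% names(Filter(function(m)
              m$category == "SEDC", tr$models)))))
})

test_that("generation is deterministic and truth passes the validators", {
  a <- generate_edc_locus(synthetic_config(seed = 99, n_sedc = 5,
                                           n_cbp_cluster = 0,
                                           n_pseudogenes = 1))
  b <- generate_edc_locus(synthetic_config(seed = 99, n_sedc = 5,
                                           n_cbp_cluster = 0,
                                           n_pseudogenes = 1))
  expect_identical(a$scaffolds[[1]]$sequence, b$scaffolds[[1]]$sequence)
  expect_identical(a$truth$proteins, b$truth$proteins)
  loc <- cached_locus(1)
  for (m in loc$truth$models)
    expect_true(validate_gene_model(m, loc$scaffolds[[1]]), info = m$id)
  # truth proteins equal the translation of the truth coding spans
  for (g in names(loc$truth$proteins))
    expect_equal(gene_protein(loc$truth$models[[g]], loc$scaffolds[[1]]),
                 loc$truth$proteins[[g]], info = g)
})

test_that("coding composition follows the configured bias", {
  loc <- generate_edc_locus(synthetic_config(
    seed = 21, n_sedc = 30, n_sftp = 0, n_cbp_cluster = 0,
    n_pseudogenes = 0, composition_bias = c(C = 0.25)))
  prots <- loc$truth$proteins
  sedc <- prots[startsWith(names(prots), "EDC")]
  cys_frac <- vapply(sedc, function(p) {
    ch <- strsplit(p, "")[[1]]
    mean(ch == "C")
  }, numeric(1))
  n_res <- sum(nchar(sedc))
  # binomial sampling error around 0.25 (minus the fixed initiator M)
  se <- sqrt(0.25 * 0.75 / n_res)
  expect_lt(abs(mean(cys_frac) - 0.25), 4 * se + 1 / mean(nchar(sedc)))
})

test_that("pseudogenes never translate to a long stop-free ORF", {
  loc <- cached_locus(1)
  sc <- loc$scaffolds[[1]]
  pseudo <- Filter(function(m) m$category == "pseudogene", loc$truth$models)
  expect_equal(length(pseudo), 4L)
  for (m in pseudo) {
    prot <- translate(gene_cds(m, sc))
    body <- sub("\\*$", "", prot)
    # disrupted: an internal stop or a shifted frame, never a clean CDS
    expect_true(grepl("\\*", body) ||
                  nchar(gene_cds(m, sc)) %% 3 != 0, info = m$id)
    # no residual ATG-initiated stop-free run of 50+ codons in any sense frame
    spans <- lapply(0:2, function(f) translate(gene_cds(m, sc), f, "+"))
    runs <- unlist(lapply(spans, function(p) {
      parts <- strsplit(p, "\\*")[[1]]
      vapply(parts, function(x) {
        mpos <- regexpr("M", x)
        if (mpos < 0) 0L else nchar(x) - as.integer(mpos) + 1L
      }, integer(1))
    }))
    expect_true(all(runs < 50L), info = m$id)
  }
})

test_that("ortholog pairs honor divergence 0 and planted repeat expansion", {
  pair <- generate_ortholog_pair(synthetic_config(seed = 31, n_sedc = 6,
                                                  n_cbp_cluster = 0,
                                                  n_pseudogenes = 0),
                                 divergence = 0)
  expect_identical(pair$locus_a$scaffolds[[1]]$sequence,
                   pair$locus_b$scaffolds[[1]]$sequence)
  expect_equal(pair$ortholog_map$gene_a, pair$ortholog_map$gene_b)
  pair2 <- generate_ortholog_pair(synthetic_config(seed = 32, n_sedc = 4,
                                                   n_cbp_cluster = 0,
                                                   n_pseudogenes = 0),
                                  divergence = 0, repeat_expansion = 50)
  ri_a <- pair2$locus_a$truth$repeat_info
  ri_b <- pair2$locus_b$truth$repeat_info
  expect_equal(ri_b$copies - ri_a$copies, 50L)
  a <- pair2$locus_a$truth$proteins[["EDCRP"]]
  b <- pair2$locus_b$truth$proteins[["EDCRP"]]
  expect_equal(nchar(b) - nchar(a), sum(nchar(ri_b$copy_seqs)) -
                 sum(nchar(ri_a$copy_seqs)))
  expect_error(generate_ortholog_pair(synthetic_config(seed = 1),
                                      divergence = 0.9), "divergence")
})

test_that("observed protein identity matches the substitution-model expectation", {
  d <- 0.1
  pair <- generate_ortholog_pair(synthetic_config(seed = 33),
                                 divergence = d)
  pa <- pair$locus_a$truth$proteins
  pb <- pair$locus_b$truth$proteins
  sc_a <- pair$locus_a$scaffolds[[1]]
  obs <- c(); expd <- c()
  for (g in names(pa)) {
    m <- pair$locus_a$truth$models[[g]]
    if (nchar(pa[[g]]) != nchar(pb[[g]])) next # repeat gene grows
    ca <- strsplit(pa[[g]], "")[[1]]
    cb <- strsplit(pb[[g]], "")[[1]]
    obs <- c(obs, mean(ca == cb))
    cds <- gene_cds(m, sc_a)
    codons <- substring(cds, seq(1, nchar(cds) - 3, 3),
                        seq(3, nchar(cds), 3))
    codons <- codons[seq_len(nchar(pa[[g]]))]
    # first and last codons are protected from mutation
    pid <- vapply(codons[-1], expected_codon_identity, numeric(1), d = d)
    expd <- c(expd, (1 + sum(pid)) / length(codons))
  }
  expect_gt(length(obs), 15)
  expect_lt(abs(mean(obs) - mean(expd)), 0.02)
})

test_that("tissue reads are exact transcript substrings with the right biases", {
  loc <- cached_locus(1)
  cfg <- loc$truth$config
  rd <- generate_tissue_reads(loc, cfg)
  expect_equal(length(rd$reads), sum(cfg$reads_per_tissue))
  sc <- loc$scaffolds[[1]]
  # every read is a perfect substring of its source transcript
  reads_by_id <- stats::setNames(rd$reads,
                                 vapply(rd$reads, `[[`, "", "id"))
  set.seed(1)
  some <- rd$table[sample(nrow(rd$table), 50), ]
  for (i in seq_len(nrow(some))) {
    tx <- gene_transcript(loc$truth$models[[some$gene[i]]], sc)
    expect_true(grepl(reads_by_id[[some$read_id[i]]]$sequence, tx,
                      fixed = TRUE))
  }
  # EDC genes are skin-only in the default profile
  edc_genes <- names(Filter(function(m)
    m$category %in% c("SEDC", "SFTP", "CBP"), loc$truth$models))
  off_tissue <- rd$table[rd$table$gene %in% edc_genes &
                           rd$table$tissue != "skin", ]
  expect_equal(nrow(off_tissue), 0L)
  # the housekeeping stand-in draws its multinomial share in every tissue:
  # expected count in tissue t is N_t / (sum of expressed weights in t)
  alas <- table(factor(rd$table$tissue[rd$table$gene == "ALAS1"],
                       levels = names(cfg$reads_per_tissue)))
  n_expressed_skin <- length(edc_genes) + 3L # + ALAS1 and two markers
  expected <- c(skin = cfg$reads_per_tissue[["skin"]] / n_expressed_skin,
                heart = cfg$reads_per_tissue[["heart"]] / 3,
                liver = cfg$reads_per_tissue[["liver"]] / 3)
  expected <- expected[names(alas)]
  p <- stats::chisq.test(as.integer(alas),
                         p = expected / sum(expected))$p.value
  expect_gt(p, 1e-4)
})
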