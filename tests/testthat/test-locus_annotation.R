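# Locus delimitation, scaffold ordering, gene prediction, status triage and
# read validation against generator ground truth.

test_that("the inter-marker region matches the planted locus", {
  loc <- cached_locus(1)
  tr <- loc$truth
  reg <- cached_region(1)
  expect_length(reg$segments, 1L)
  expect_length(reg$discontinuity, 0L)
  iv <- reg$segments[[1]]$interval
  m12 <- tr$models[["S100A12"]]; m11 <- tr$models[["S100A11"]]
  # region runs from the 5' marker CDS to the 3' marker CDS; the aligned
  # marker spans exclude the stop codon, so allow a few codons of slop
  expect_lt(abs(iv[1] - unname(m12$coding_span[1, 2])), 10)
  expect_lt(abs(iv[2] - unname(m11$coding_span[1, 1])), 10)
  # every EDC gene lies inside the region, the markers outside
  for (m in tr$models) {
    if (m$category == "marker") next
    expect_gte(min(m$exons), iv[1])
    expect_lte(max(m$exons), iv[2])
  }
})

test_that("missing markers are a hard error", {
  loc <- cached_locus(1)
  fake <- list(protein_record("m1", rand_protein(90)),
               protein_record("m2", rand_protein(90)))
  # a threshold above the chance-hit level of unrelated sequence; planted
  # markers score far higher (hundreds)
  expect_error(find_flanked_region(loc$scaffolds, fake, min_score = 150),
               "no hit")
  expect_error(find_flanked_region(loc$scaffolds, fake[1]), "two marker")
})

test_that("fragmentation between the markers yields flagged segments", {
  base <- cached_locus(41, n_sedc = 6, n_cbp_cluster = 0, n_pseudogenes = 0)
  # cut halfway between the markers
  tr <- base$truth
  cut <- floor((tr$models[["EDC3"]]$exons[1, 1] +
                  tr$models[["EDC4"]]$exons[1, 1]) / 2)
  loc <- generate_edc_locus(synthetic_config(seed = 41, n_sedc = 6,
                                             n_cbp_cluster = 0,
                                             n_pseudogenes = 0,
                                             fragmentation = cut))
  expect_length(loc$scaffolds, 2L)
  markers <- list(
    protein_record("S100A12", loc$truth$proteins[["S100A12"]]),
    protein_record("S100A11", loc$truth$proteins[["S100A11"]]))
  reg <- find_flanked_region(loc$scaffolds, markers)
  expect_length(reg$segments, 2L)
  expect_equal(reg$discontinuity, TRUE)
})

test_that("scaffold ordering recovers the reference gene order", {
  loc <- cached_locus(13, fragmentation = 3)
  tr <- loc$truth
  segs <- lapply(loc$scaffolds, function(s)
    list(scaffold_id = s$id, interval = c(0, nchar(s$sequence)),
         orientation = "+"))
  hits <- list()
  for (g in names(tr$proteins)) {
    q <- protein_record(g, tr$proteins[[g]])
    for (s in loc$scaffolds)
      hits <- c(hits, translated_search(q, s, min_score = 60,
                                        max_hits_per_frame = 1L))
  }
  # single segment returns unchanged
  one <- order_scaffolds(segs[1], tr$gene_order, hits)
  expect_equal(one$segments[[1]]$scaffold_id, segs[[1]]$scaffold_id)
  # shuffled segments come back in truth order
  set.seed(2)
  shuffled <- segs[sample(length(segs))]
  reg <- order_scaffolds(shuffled, tr$gene_order, hits)
  got <- vapply(reg$segments, `[[`, "", "scaffold_id")
  expect_equal(got, vapply(segs, `[[`, "", "scaffold_id"))
  expect_true(all(reg$discontinuity))
  # a hit-free segment is appended and flagged
  extra <- c(segs, list(list(scaffold_id = "zzz_orphan",
                             interval = c(0, 500), orientation = "+")))
  reg2 <- order_scaffolds(extra, tr$gene_order, hits)
  expect_equal(tail(vapply(reg2$segments, `[[`, "", "scaffold_id"), 1),
               "zzz_orphan")
  expect_equal(tail(reg2$notes, 1), "unplaced")
})

test_that("SEDC prediction recovers planted genes with exact coding spans", {
  loc <- cached_locus(1)
  tr <- loc$truth
  reg <- cached_region(1)
  preds <- predict_sedc_genes(reg, loc$scaffolds)
  ev <- evaluate_sedc_predictions(preds, tr)
  expect_gte(ev$recall, 0.95)
  expect_gte(ev$precision, 0.95)
  expect_gte(ev$exactness, 0.85) # single-seed floor; sweep tested in acceptance
  # every prediction passes the model validator
  for (p in preds)
    expect_true(validate_gene_model(p$model), info = p$model$id)
  # ORFs below min_codons are never reported
  lens <- vapply(preds, function(p)
    (p$model$coding_span[1, 2] - p$model$coding_span[1, 1]) / 3 - 1,
    numeric(1))
  expect_true(all(lens >= 50))
})

test_that("TATA ablation suppresses the 5' noncoding exon", {
  loc <- generate_edc_locus(synthetic_config(seed = 17, n_sedc = 6,
                                             n_cbp_cluster = 0,
                                             n_pseudogenes = 0,
                                             tata_ablation = "EDC2"))
  tr <- loc$truth
  expect_null(tr$features[["EDC2"]]$tata)
  markers <- list(protein_record("S100A12", tr$proteins[["S100A12"]]),
                  protein_record("S100A11", tr$proteins[["S100A11"]]))
  reg <- find_flanked_region(loc$scaffolds, markers)
  preds <- predict_sedc_genes(reg, loc$scaffolds)
  cs <- tr$models[["EDC2"]]$coding_span[1, ]
  hit <- Filter(function(p) p$model$strand == tr$models[["EDC2"]]$strand &&
                  p$model$coding_span[1, 1] < cs[2] &&
                  p$model$coding_span[1, 2] > cs[1], preds)
  expect_length(hit, 1L)
  expect_equal(nrow(hit[[1]]$model$exons), 1L) # no noncoding exon attached
  expect_null(hit[[1]]$evidence$tata_position)
})

test_that("SFTP genes are recovered on two coding exons, exactly", {
  loc <- cached_locus(1)
  tr <- loc$truth
  reg <- cached_region(1)
  q <- list(protein_record("CRNN", tr$proteins[["CRNN"]]),
            protein_record("SCFN", tr$proteins[["SCFN"]]))
  preds <- predict_sftp_genes(reg, loc$scaffolds, q)
  expect_length(preds, 2L)
  for (g in c("CRNN", "SCFN")) {
    m <- tr$models[[g]]
    match <- Filter(function(p) p$model$strand == m$strand &&
                      nrow(p$model$coding_span) == 2L &&
                      all(p$model$coding_span == m$coding_span), preds)
    expect_length(match, 1L)
    # splice sites are canonical GT..AG by construction of the joiner
    ss <- match[[1]]$evidence$splice_sites
    sc <- loc$scaffolds[[1]]
    intron <- substr(sc$sequence, ss[1] + 1, ss[2])
    if (m$strand == "-") intron <- reverse_complement(intron)
    expect_equal(substr(intron, 1, 2), "GT")
    expect_equal(substring(intron, nchar(intron) - 1), "AG")
  }
})

test_that("mutated splice sites abolish the SFTP join", {
  loc <- cached_locus(22, n_sedc = 2, n_cbp_cluster = 0, n_pseudogenes = 0)
  tr <- loc$truth
  m <- tr$models[["CRNN"]]
  sc <- loc$scaffolds[[1]]
  # scrub every potential GT donor across the whole gene span so that no
  # canonical intron can be assembled on either strand
  gap <- c(min(m$exons), max(m$exons))
  chars <- strsplit(sc$sequence, "")[[1]]
  repeat {
    changed <- FALSE
    for (i in (gap[1] + 1):(gap[2] - 1)) {
      pair <- paste0(chars[i:(i + 1)], collapse = "")
      if (pair %in% c("GT", "AC")) { # kill donors on both strands
        chars[i] <- "C"; chars[i + 1] <- "C"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mut <- scaffold_record(sc$id, paste0(chars, collapse = ""), sc$species)
  markers <- list(protein_record("S100A12", tr$proteins[["S100A12"]]),
                  protein_record("S100A11", tr$proteins[["S100A11"]]))
  reg <- find_flanked_region(list(mut), markers)
  preds <- predict_sftp_genes(reg, list(mut),
                              list(protein_record("CRNN",
                                                  tr$proteins[["CRNN"]])))
  overlapping <- Filter(function(p)
    p$model$coding_span[1, 1] < max(m$coding_span) &&
      max(p$model$coding_span) > min(m$coding_span), preds)
  expect_length(overlapping, 0L)
})

test_that("gene status triage distinguishes complete, partial, pseudogene", {
  loc <- cached_locus(1)
  tr <- loc$truth
  sc <- loc$scaffolds[[1]]
  intact <- tr$models[["EDC1"]]
  expect_equal(classify_gene_status(intact, loc$scaffolds), "complete")
  pseudo <- Filter(function(m) m$category == "pseudogene", tr$models)[[1]]
  expect_equal(classify_gene_status(pseudo, loc$scaffolds), "pseudogene")
  # a CDS running into a scaffold break is partial
  cs <- tr$models[["EDC2"]]$coding_span[1, ]
  cut <- floor(mean(cs))
  locf <- generate_edc_locus(synthetic_config(seed = 1,
                                              fragmentation = cut))
  m2 <- locf$truth$models[["EDC2"]]
  expect_equal(m2$completeness, "partial")
  expect_equal(classify_gene_status(m2, locf$scaffolds), "partial")
  # invariant to scaffold naming
  ren <- scaffold_record("renamed", sc$sequence, sc$species)
  m_ren <- intact; m_ren$scaffold_id <- "renamed"
  expect_equal(classify_gene_status(m_ren, list(ren)), "complete")
})

test_that("read validation reproduces truth read counts and junction reads", {
  loc <- cached_locus(1)
  tr <- loc$truth
  cfg <- tr$config
  rd <- generate_tissue_reads(loc, cfg)
  reg <- cached_region(1)
  preds <- predict_sedc_genes(reg, loc$scaffolds)
  checked <- 0L
  for (g in names(tr$models)) {
    m <- tr$models[[g]]
    if (m$category != "SEDC") next
    sel <- Filter(function(p) p$model$strand == m$strand &&
                    all(p$model$coding_span[1, ] == m$coding_span[1, ]),
                  preds)
    if (length(sel) != 1L) next
    p <- validate_with_reads(sel[[1]], loc$scaffolds, rd$reads)
    expect_equal(p$evidence$read_support, sum(rd$table$gene == g), info = g)
    expect_lte(p$evidence$intron_spanning_reads, p$evidence$read_support)
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)
  # a gene with zero expression in the profile has zero support
  cfg0 <- synthetic_config(seed = 1,
                           expression_profile = list(
                             EDC1 = c(skin = 1, heart = 0, liver = 0),
                             ALAS1 = c(skin = 1, heart = 1, liver = 1)))
  rd0 <- generate_tissue_reads(loc, cfg0)
  sel2 <- Filter(function(p) p$model$strand == tr$models[["EDC2"]]$strand &&
                   all(p$model$coding_span[1, ] ==
                         tr$models[["EDC2"]]$coding_span[1, ]), preds)
  p0 <- validate_with_reads(sel2[[1]], loc$scaffolds, rd0$reads)
  expect_equal(p0$evidence$read_support, 0L)
})

test_that("intron-spanning reads honor the overhang threshold", {
  loc <- cached_locus(1)
  tr <- loc$truth
  m <- tr$models[["EDC1"]]
  sc <- loc$scaffolds[[1]]
  tx <- gene_transcript(m, sc)
  ex_tx <- if (m$strand == "+") m$exons else
    m$exons[rev(seq_len(nrow(m$exons))), , drop = FALSE]
  e1 <- ex_tx[1, 2] - ex_tx[1, 1]
  # reads straddling the junction with exactly 10-nt overhangs on each side
  rl <- 75L
  reads <- lapply(1:3, function(i)
    read_record(paste0("j", i),
                substr(tx, e1 - 10 + 1, e1 - 10 + rl), "skin"))
  reg <- cached_region(1)
  preds <- predict_sedc_genes(reg, loc$scaffolds)
  sel <- Filter(function(p) p$model$strand == m$strand &&
                  all(p$model$coding_span[1, ] == m$coding_span[1, ]),
                preds)[[1]]
  out <- validate_with_reads(sel, loc$scaffolds, reads,
                             params = sedc_params(min_overhang = 5L))
  expect_equal(out$evidence$read_support, 3L)
  expect_equal(out$evidence$intron_spanning_reads, 3L)
})
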