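# Orthology, family census, Dollo gain/loss and the comparative locus map.

test_that("identical protein sets map to themselves by RBH", {
  loc <- cached_locus(1)
  prots <- head(loc$truth$proteins, 8)
  omap <- reciprocal_best_hits(prots, prots)
  expect_equal(nrow(omap), length(prots))
  expect_equal(omap$gene_a, omap$gene_b)
  expect_true(all(omap$identity == 1))
})

test_that("RBH is symmetric and respects the synteny constraint", {
  pair <- generate_ortholog_pair(synthetic_config(seed = 61, n_sedc = 6,
                                                  n_cbp_cluster = 3,
                                                  n_pseudogenes = 0),
                                 divergence = 0.1)
  pa <- pair$locus_a$truth$proteins
  pb <- pair$locus_b$truth$proteins
  ab <- reciprocal_best_hits(pa, pb)
  ba <- reciprocal_best_hits(pb, pa)
  expect_equal(ab[order(ab$gene_a), c("gene_a", "gene_b")],
               stats::setNames(ba[order(ba$gene_b), c("gene_b", "gene_a")],
                               c("gene_a", "gene_b")),
               ignore_attr = TRUE)
  # recovery of the positional truth map
  correct <- sum(ab$gene_a == ab$gene_b)
  expect_gte(correct / length(pa), 0.9)
  # the rank constraint excludes far-apart pairings even of identical genes
  dup <- c(a1 = "MKCWHG", a2 = "MGGGGG", a3 = "MPPPPP", a4 = "MLLLLL",
           a5 = "MSSSSS", a6 = "MKCWHG")
  other <- c(b1 = "MKCWHG")
  m2 <- reciprocal_best_hits(dup, other, max_rank_delta = 3)
  expect_true(nrow(m2) <= 1)
  if (nrow(m2) == 1) expect_equal(m2$gene_a, "a1")
})

test_that("the family census splits counts by status and conserves totals", {
  ann <- list(
    sppA = data.frame(gene = sprintf("a%d", 1:6),
                      family = c("EDCH", "EDCH", "EDCH", "EDPQ", "CBP", "CBP"),
                      status = c("complete", "complete", "pseudogene",
                                 "complete", "partial", "complete")),
    sppB = data.frame(gene = sprintf("b%d", 1:3),
                      family = c("EDCH", "EDCH", "CBP"),
                      status = c("complete", "partial", "complete")))
  cen <- family_census(ann)
  expect_s3_class(cen, "family_census")
  g <- function(sp, fam) cen[cen$species == sp & cen$family == fam, ]
  expect_equal(g("sppA", "EDCH")$complete, 2)
  expect_equal(g("sppA", "EDCH")$pseudogene, 1)
  expect_equal(g("sppB", "EDPQ")$complete, 0) # explicit zero
  expect_equal(g("sppA", "CBP")$partial, 1)
  # census totals equal annotated gene counts per species
  for (sp in names(ann))
    expect_equal(sum(cen[cen$species == sp,
                         c("complete", "partial", "pseudogene")]),
                 nrow(ann[[sp]]))
})

test_that("family assignment reports scores and never drops genes", {
  loc <- cached_locus(1)
  prots <- loc$truth$proteins
  exemplars <- c(CBP = unname(prots[["CBP1"]]),
                 SEDC1 = unname(prots[["EDC1"]]))
  asg <- assign_families(prots[c("CBP2", "CBP3", "EDC1", "S100A12")],
                         exemplars)
  expect_equal(nrow(asg), 4L)
  expect_equal(asg$family[asg$gene %in% c("CBP2", "CBP3")],
               c("CBP", "CBP"))
  expect_equal(asg$family[asg$gene == "EDC1"], "SEDC1")
  expect_equal(asg$family[asg$gene == "S100A12"], "unclassified")
})

test_that("Dollo maps the archosaur gain and avian loss pattern", {
  tree <- ape::read.tree(text = paste0(
    "(squamate:1,(turtle:1,((croc1:1,croc2:1)croc:1,",
    "(bird1:1,bird2:1)birds:1)archosaur:1)archelosaur:1);"))
  ann <- list(
    squamate = data.frame(gene = character(), family = character(),
                          status = character()),
    turtle = data.frame(gene = c("t1", "t0"), family = c("EDPQ", "other"),
                        status = "complete"),
    croc1 = data.frame(gene = c("c1", "c2", "c0"),
                       family = c("EDPQ", "EDPQ", "other"),
                       status = "complete"),
    croc2 = data.frame(gene = c("d1", "d0"), family = c("EDPQ", "other"),
                       status = "complete"),
    bird1 = data.frame(gene = character(), family = character(),
                       status = character()),
    bird2 = data.frame(gene = character(), family = character(),
                       status = character()))
  # give every species at least one row so the census covers them
  ann$squamate <- data.frame(gene = "s0", family = "other",
                             status = "complete")
  ann$bird1 <- data.frame(gene = "b0", family = "other", status = "complete")
  ann$bird2 <- data.frame(gene = "b0b", family = "other", status = "complete")
  cen <- family_census(ann)
  ev <- dollo_gain_loss(cen, tree)
  edpq <- ev[ev$family == "EDPQ", ]
  expect_equal(edpq$branch[edpq$type == "gain"], "archelosaur")
  expect_equal(edpq$branch[edpq$type == "loss"], "birds")
  # a family present in all tips gains at the root with no losses
  other <- ev[ev$family == "other", ]
  expect_equal(other$branch[other$type == "gain"], "root")
  expect_equal(sum(other$type == "loss"), 0L)
})

test_that("Dollo events equal exhaustive minimal-change enumeration", {
  set.seed(27)
  for (ntips in 4:6) {
    tree <- ape::rtree(ntips, rooted = TRUE)
    tree$tip.label <- paste0("sp", seq_len(ntips))
    for (mask in 1:(2^ntips - 1L)) {
      pres <- as.logical(intToBits(mask)[seq_len(ntips)])
      names(pres) <- tree$tip.label
      ann <- lapply(stats::setNames(tree$tip.label, tree$tip.label),
                    function(sp)
        if (pres[sp]) data.frame(gene = paste0(sp, "_g"), family = "F",
                                 status = "complete")
        else data.frame(gene = paste0(sp, "_x"), family = "other",
                        status = "complete"))
      cen <- family_census(ann)
      ev <- dollo_gain_loss(cen, tree)
      evf <- ev[ev$family == "F", ]
      oracle <- dollo_oracle(tree, pres)
      ntip <- length(tree$tip.label)
      node_name <- function(v) {
        if (v <= ntip) tree$tip.label[v]
        else if (v == ntip + 1L) "root"
        else paste0("node", v)
      }
      expect_equal(evf$branch[evf$type == "gain"], node_name(oracle$gain))
      expect_setequal(evf$branch[evf$type == "loss"],
                      vapply(oracle$losses, node_name, ""))
      # no presence is ever inferred on a branch without descendant presence
      expect_true(all(evf$type %in% c("gain", "loss")))
    }
  }
})

test_that("reconstructed counts emit expansion events at the fold threshold", {
  tree <- ape::read.tree(text =
    "((croc1:1,croc2:1)crocs:1,(bird1:1,bird2:1)birds:1);")
  mk <- function(n, sp) if (n == 0)
    data.frame(gene = paste0(sp, "_o"), family = "other",
               status = "complete")
  else
    rbind(data.frame(gene = paste0(sp, "_", seq_len(n)), family = "EDCH",
                     status = "complete"),
          data.frame(gene = paste0(sp, "_o"), family = "other",
                     status = "complete"))
  ann <- list(croc1 = mk(20, "c1"), croc2 = mk(18, "c2"),
              bird1 = mk(4, "b1"), bird2 = mk(3, "b2"))
  cen <- family_census(ann)
  ev <- dollo_gain_loss(cen, tree, expansion_fold = 4)
  ex <- ev[ev$family == "EDCH" & ev$type == "expansion", ]
  expect_equal(ex$branch, "crocs")
  expect_gte(ex$magnitude, 14)
})

test_that("the locus map draws cluster boxes, strands and discontinuities", {
  ann <- list(
    sppA = data.frame(gene = c("S100A12", paste0("CBP", 1:6), "EDCH1"),
                      family = c("S100", rep("CBP", 6), "EDCH"),
                      strand = c("+", rep("+", 6), "-")),
    sppB = data.frame(gene = c("S100A12", "CBP1", "EDCH1"),
                      family = c("S100", "CBP", "EDCH"),
                      strand = c("+", "+", "-")))
  omap <- list(data.frame(gene_a = c("S100A12", "EDCH1"),
                          gene_b = c("S100A12", "EDCH1")))
  regB <- locus_region(list(
    list(scaffold_id = "f1", interval = c(0, 100), orientation = "+"),
    list(scaffold_id = "f2", interval = c(0, 100), orientation = "+")),
    discontinuity = TRUE)
  lm <- build_locus_map(ann, omap, regions = list(sppB = regB))
  toksA <- lm$tracks$sppA$tokens
  kinds <- vapply(toksA, `[[`, "", "kind")
  expect_true("box" %in% kinds) # 6-member CBP run is boxed
  box <- toksA[[which(kinds == "box")[1]]]
  expect_equal(box$n, 6L)
  # 3-member runs are not boxed
  expect_false(any(vapply(lm$tracks$sppB$tokens, `[[`, "", "kind") == "box"))
  expect_true(lm$tracks$sppB$discontinuity)
  out <- capture.output(print(lm))
  expect_true(any(grepl("\\[CBP#6\\]", out)))
  expect_true(any(grepl("<EDCH1", out)))   # minus-strand arrow
  expect_true(any(grepl("~", out)))        # discontinuity mark
})
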