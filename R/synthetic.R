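# Ground-truthed synthetic EDC loci. The generator emulates the genomic
# architecture the annotation stages assume: a locus flanked by two S100A
# marker stand-ins, single-coding-exon (SEDC) genes with a TATA box, a 5'
# noncoding exon and a canonical GT..AG intron, two-coding-exon SFTP genes,
# a tandem CBP-like cluster, pseudogenes with disrupted reading frames,
# optional scaffold fragmentation, an internally repetitive EDCRP-like gene,
# and tissue-biased error-free reads. Everything is deterministic given the
# seed, and every emitted model passes the gene-model validator.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codons_for_aa <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), as.character(code))
})

#' Configuration for the synthetic-locus generator
#'
#' Defaults describe a locus of 20 SEDC genes, 2 SFTP genes, a 6-member
#' CBP-like tandem cluster and 4 pseudogenes, with coding composition
#' biased toward G, S, P, K, C and Q as in real EDC proteins.
#'
#' @param seed mandatory integer seed; identical seeds give byte-identical
#'   output.
#' @param n_sedc,n_sftp,n_cbp_cluster,n_pseudogenes gene counts (>= 0).
#' @param composition_bias named per-residue target fractions for SEDC/CBP
#'   coding sequence; remaining mass is spread uniformly over the other
#'   residues. Fractions must sum to <= 1.
#' @param intergenic_length_range nt range between gene cassettes.
#' @param tata_offset_range nt range from TATA-box start to transcription
#'   start.
#' @param noncoding_exon_range nt range for the 5' noncoding exon.
#' @param intron_length_range nt range for GT..AG introns.
#' @param utr5_range,utr3_range nt ranges for untranslated parts of the
#'   coding exon.
#' @param cds_codon_range protein length range (residues incl. initiator M).
#' @param repeat_gene optional list `(unit, copies)`: plants an EDCRP-like
#'   gene whose protein carries `copies` tandem copies of the motif `unit`
#'   (pattern grammar of [parse_motif_pattern()]).
#' @param fragmentation `NULL`, an integer number of cuts placed in
#'   intergenic gaps, or explicit nt cut positions (which may fall inside
#'   genes, truncating them to partial models).
#' @param read_length read length for [generate_tissue_reads()].
#' @param reads_per_tissue named integer vector of read counts per tissue.
#' @param expression_profile optional list gene name -> named tissue
#'   weights; default: EDC genes are skin-specific, the ALAS1 stand-in and
#'   the markers are expressed uniformly.
#' @param tata_ablation character vector of gene names whose TATA box (and
#'   any spurious TATA-like motif upstream of the intron) is scrambled.
#' @param strand_mix place each EDC gene on a random strand (markers and
#'   the ALAS1 stand-in stay on plus).
#' @param error_rate per-base substitution rate for reads (default 0:
#'   error-free, matching the 100%-identity counting rule downstream).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
    n_sedc = 20L, n_sftp = 2L, n_cbp_cluster = 6L, n_pseudogenes = 4L,
    composition_bias = c(G = 0.14, S = 0.14, P = 0.11,
                         K = 0.09, C = 0.09, Q = 0.08),
    intergenic_length_range = c(300L, 800L),
    tata_offset_range = c(25L, 35L),
    noncoding_exon_range = c(30L, 80L),
    intron_length_range = c(80L, 200L),
    utr5_range = c(3L, 20L),
    utr3_range = c(30L, 100L),
    cds_codon_range = c(50L, 150L),
    repeat_gene = NULL,
    fragmentation = NULL,
    read_length = 75L,
    reads_per_tissue = c(skin = 300L, heart = 200L, liver = 200L),
    expression_profile = NULL,
    tata_ablation = character(),
    strand_mix = TRUE,
    error_rate = 0) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  counts <- c(n_sedc, n_sftp, n_cbp_cluster, n_pseudogenes)
  if (any(counts < 0)) stop("gene counts must be >= 0")
  if (sum(composition_bias) > 1 + 1e-9)
    stop("composition_bias fractions must sum to <= 1")
  if (!all(names(composition_bias) %in% .AA20))
    stop("composition_bias names must be amino-acid letters")
  structure(list(
    seed = as.integer(seed), n_sedc = as.integer(n_sedc),
    n_sftp = as.integer(n_sftp), n_cbp_cluster = as.integer(n_cbp_cluster),
    n_pseudogenes = as.integer(n_pseudogenes),
    composition_bias = composition_bias,
    intergenic_length_range = intergenic_length_range,
    tata_offset_range = tata_offset_range,
    noncoding_exon_range = noncoding_exon_range,
    intron_length_range = intron_length_range,
    utr5_range = utr5_range, utr3_range = utr3_range,
    cds_codon_range = cds_codon_range,
    repeat_gene = repeat_gene, fragmentation = fragmentation,
    read_length = as.integer(read_length),
    reads_per_tissue = reads_per_tissue,
    expression_profile = expression_profile,
    tata_ablation = tata_ablation,
    strand_mix = isTRUE(strand_mix),
    error_rate = error_rate), class = "synthetic_config")
}

.samp <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[2]), 1L)
}

.rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.aa_probs <- function(bias) {
  p <- stats::setNames(numeric(20), .AA20)
  if (length(bias)) p[names(bias)] <- bias
  rest <- setdiff(.AA20, names(bias))
  p[rest] <- (1 - sum(bias)) / length(rest)
  p
}

.sample_protein <- function(n, probs) {
  paste0(c("M", sample(.AA20, n - 1L, replace = TRUE, prob = probs)),
         collapse = "")
}

.encode_cds <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .codons_for_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste0(codons, collapse = ""), sample(.STOP_CODONS, 1L))
}

# one single-coding-exon gene cassette on its sense strand; coordinates are
# 0-based half-open relative to the cassette
.build_sedc_cassette <- function(cfg, protein) {
  pad5 <- .samp(c(40L, 80L)); pad3 <- .samp(c(20L, 40L))
  offset <- .samp(cfg$tata_offset_range)
  u1 <- .samp(cfg$noncoding_exon_range)
  li <- .samp(cfg$intron_length_range)
  utr5 <- .samp(cfg$utr5_range); utr3 <- .samp(cfg$utr3_range)
  cds <- .encode_cds(protein)
  tata_start <- pad5
  e1_start <- pad5 + offset
  e1_end <- e1_start + u1
  i_end <- e1_end + li
  cds_start <- i_end + utr5
  cds_end <- cds_start + nchar(cds)
  e2_end <- cds_end + utr3
  seq <- paste0(
    .rand_dna(pad5), "TATAAA", .rand_dna(offset - 6L), .rand_dna(u1),
    "GT", .rand_dna(li - 4L), "AG",
    .rand_dna(utr5), cds, .rand_dna(utr3), .rand_dna(pad3))
  list(seq = seq, length = e2_end + pad3,
       exons = rbind(c(e1_start, e1_end), c(i_end, e2_end)),
       coding = rbind(c(cds_start, cds_end)),
       tata = c(tata_start, tata_start + 6L),
       donor = e1_end, acceptor = i_end,
       protein = protein)
}

.build_sftp_cassette <- function(cfg, protein) {
  pad5 <- .samp(c(40L, 80L)); pad3 <- .samp(c(20L, 40L))
  offset <- .samp(cfg$tata_offset_range)
  u1 <- .samp(cfg$noncoding_exon_range)
  li1 <- .samp(cfg$intron_length_range)
  li2 <- .samp(cfg$intron_length_range)
  utr5 <- .samp(cfg$utr5_range); utr3 <- .samp(cfg$utr3_range)
  n <- nchar(protein)
  k1 <- n %/% 2L # phase-0 intron: split at a codon boundary
  aa <- strsplit(protein, "")[[1]]
  cds1 <- sub("...$", "", .encode_cds(paste0(aa[1:k1], collapse = "")))
  cds2_prot <- paste0(aa[(k1 + 1L):n], collapse = "")
  cds2 <- sub("^ATG", "", .encode_cds(paste0("M", cds2_prot)))
  tata_start <- pad5
  e1_start <- pad5 + offset; e1_end <- e1_start + u1
  i1_end <- e1_end + li1
  cds1_start <- i1_end + utr5; cds1_end <- cds1_start + nchar(cds1)
  i2_end <- cds1_end + li2
  cds2_start <- i2_end; cds2_end <- cds2_start + nchar(cds2)
  e3_end <- cds2_end + utr3
  seq <- paste0(
    .rand_dna(pad5), "TATAAA", .rand_dna(offset - 6L), .rand_dna(u1),
    "GT", .rand_dna(li1 - 4L), "AG",
    .rand_dna(utr5), cds1,
    "GT", .rand_dna(li2 - 4L), "AG",
    cds2, .rand_dna(utr3), .rand_dna(pad3))
  list(seq = seq, length = e3_end + pad3,
       exons = rbind(c(e1_start, e1_end), c(i1_end, cds1_end),
                     c(i2_end, e3_end)),
       coding = rbind(c(cds1_start, cds1_end), c(cds2_start, cds2_end)),
       tata = c(tata_start, tata_start + 6L),
       donor = e1_end, acceptor = i1_end,
       protein = protein)
}

.build_marker_cassette <- function(protein) {
  pad5 <- .samp(c(30L, 60L)); pad3 <- .samp(c(30L, 60L))
  cds <- .encode_cds(protein)
  seq <- paste0(.rand_dna(pad5), cds, .rand_dna(pad3))
  list(seq = seq, length = pad5 + nchar(cds) + pad3,
       exons = rbind(c(pad5, pad5 + nchar(cds))),
       coding = rbind(c(pad5, pad5 + nchar(cds))),
       tata = NULL, donor = NULL, acceptor = NULL,
       protein = protein)
}

# scramble the TATA box and any TATA-like motif upstream of the donor so
# promoter evidence is genuinely absent
.ablate_tata <- function(cas) {
  chars <- strsplit(cas$seq, "")[[1]]
  upstream_end <- cas$donor
  repeat {
    win <- paste0(chars[1:upstream_end], collapse = "")
    m <- regexpr("TATA[AT]A", win)
    if (m < 0) break
    chars[m:(m + 5L)] <- c("G", "C", "C", "G", "G", "C")
  }
  cas$seq <- paste0(chars, collapse = "")
  cas$tata <- NULL
  cas
}

# disrupt a coding sequence into a pseudogene: premature stops or a
# frameshift, then break any residual >= 40-codon ORF in the three sense
# frames so the cassette can never be called as an intact gene
.pseudogenize <- function(cas, type = c("stop", "frameshift")) {
  type <- match.arg(type)
  chars <- strsplit(cas$seq, "")[[1]]
  cs <- cas$coding[1, ]
  if (type == "stop") {
    n_codons <- (cs[2] - cs[1]) %/% 3L
    for (k in seq(12L, n_codons - 3L, by = 22L)) {
      at <- cs[1] + 3L * (k - 1L)
      chars[(at + 1L):(at + 3L)] <- c("T", "A", "A")
    }
  } else {
    at <- cs[1] + 3L * 9L # delete one nt in codon 10
    chars <- chars[-(at + 1L)]
    cas$length <- cas$length - 1L
    cas$exons[cas$exons > at] <- cas$exons[cas$exons > at] - 1L
    cs[2] <- cs[2] - 1L
  }
  cas$coding <- rbind(cs)
  # post-check: no ATG-initiated stop-free run >= 40 codons may survive in
  # any sense frame within the (former) coding span
  for (iter in 1:25) {
    seq <- paste0(chars, collapse = "")
    bad <- NULL
    for (f in 0:2) {
      prot <- translate(seq, f, "+")
      orfs <- .atg_runs(prot)
      if (nrow(orfs) == 0L) next
      orf_nt_start <- f + 3L * (orfs$atg - 1L)
      orf_nt_end <- f + 3L * orfs$end
      keep <- orfs$len >= 40L & orf_nt_end > cs[1] & orf_nt_start < cs[2]
      if (any(keep)) {
        i <- which(keep)[1]
        mid <- orfs$atg[i] + orfs$len[i] %/% 2L
        bad <- f + 3L * (mid - 1L)
        break
      }
    }
    if (is.null(bad)) break
    chars[(bad + 1L):(bad + 3L)] <- c("T", "G", "A")
  }
  cas$seq <- paste0(chars, collapse = "")
  cas$protein <- NULL
  cas
}

# ATG-initiated stop-free runs in a frame translation: data.frame of 1-based
# residue positions (atg), exclusive end, and length in codons
.atg_runs <- function(prot) {
  chars <- strsplit(prot, "")[[1]]
  stops <- c(0L, which(chars == "*"), length(chars) + 1L)
  out <- list()
  for (s in seq_len(length(stops) - 1L)) {
    a <- stops[s] + 1L; b <- stops[s + 1L] - 1L
    if (b < a) next
    ms <- which(chars[a:b] == "M")
    if (length(ms) == 0L) next
    atg <- a + ms[1] - 1L
    out[[length(out) + 1L]] <-
      data.frame(atg = atg, end = b + 1L, len = b + 1L - atg)
  }
  if (length(out) == 0L)
    return(data.frame(atg = integer(), end = integer(), len = integer()))
  do.call(rbind, out)
}

.canonical_unit <- function(pattern) {
  vapply(pattern, function(p) p[p != ""][1], character(1))
}

.realize_unit <- function(pattern) {
  paste0(vapply(pattern, function(p) p[sample.int(length(p), 1L)],
                character(1)), collapse = "")
}

#' Generate a synthetic EDC-like locus with ground truth
#'
#' Emits one scaffold (or several, under fragmentation) containing, in
#' order: a 5' S100A12 stand-in, the SFTP genes, the SEDC genes with any
#' pseudogenes interspersed, an optional EDCRP-like repeat gene, a tandem
#' CBP-like cluster, the 3' S100A11 stand-in, and an ALAS1-like
#' housekeeping gene outside the locus proper.
#'
#' @param config a [synthetic_config()].
#' @param species species label for the emitted scaffolds.
#' @return list with `scaffolds` (list of [scaffold_record()]) and `truth`,
#'   a list carrying `models` (named list of validated [gene_model()]s),
#'   `proteins` (named character: true translation of each intact gene),
#'   `features` (per-gene TATA/splice coordinates), `gene_order`, and
#'   `repeat_info` when a repeat gene was planted.
#' @export
generate_edc_locus <- function(config, species = "synthetic_sp") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  probs <- .aa_probs(cfg$composition_bias)
  uniform <- .aa_probs(c())

  units <- list() # cassette specs in locus order
  add <- function(name, category, cas, flip) {
    units[[length(units) + 1L]] <<- list(name = name, category = category,
                                         cas = cas, flip = flip)
  }
  flip_coin <- function() cfg$strand_mix && sample(c(TRUE, FALSE), 1L)

  add("S100A12", "marker",
      .build_marker_cassette(.sample_protein(100L, uniform)), FALSE)
  sftp_names <- c("CRNN", "SCFN", sprintf("SFTP%d", seq_len(max(0, cfg$n_sftp - 2L))))
  for (i in seq_len(cfg$n_sftp))
    add(sftp_names[i], "SFTP",
        .build_sftp_cassette(cfg, .sample_protein(
          .samp(cfg$cds_codon_range + 50L), uniform)), flip_coin())

  sedc <- lapply(seq_len(cfg$n_sedc), function(i) {
    cas <- .build_sedc_cassette(cfg, .sample_protein(.samp(cfg$cds_codon_range), probs))
    list(name = sprintf("EDC%d", i), category = "SEDC", cas = cas)
  })
  pseudo <- lapply(seq_len(cfg$n_pseudogenes), function(i) {
    base <- .build_sedc_cassette(cfg, .sample_protein(.samp(cfg$cds_codon_range), probs))
    type <- if (i %% 2L == 1L) "stop" else "frameshift"
    list(name = sprintf("EDCP%d", i), category = "pseudogene",
         cas = .pseudogenize(base, type))
  })
  block <- c(sedc, pseudo)
  if (length(block))
    block <- block[sample.int(length(block))] # intersperse pseudogenes
  for (u in block) {
    cas <- u$cas
    if (u$name %in% cfg$tata_ablation) cas <- .ablate_tata(cas)
    add(u$name, u$category, cas, flip_coin())
  }

  repeat_info <- NULL
  if (!is.null(cfg$repeat_gene)) {
    pat <- parse_motif_pattern(cfg$repeat_gene$unit)
    ncop <- cfg$repeat_gene$copies
    copies <- vapply(seq_len(ncop), function(i) .realize_unit(pat), character(1))
    nterm <- .sample_protein(25L, probs) # starts with M
    cterm <- paste0(sample(.AA20, 25L, replace = TRUE, prob = probs),
                    collapse = "")
    prot <- paste0(nterm, paste0(copies, collapse = ""), cterm)
    cas <- .build_sedc_cassette(cfg, prot)
    add("EDCRP", "SEDC", cas, FALSE)
    repeat_info <- list(gene = "EDCRP", unit = cfg$repeat_gene$unit,
                        copies = ncop, copy_seqs = copies,
                        nterm_len = nchar(nterm), cterm_len = nchar(cterm))
  }

  if (cfg$n_cbp_cluster > 0L) {
    anc <- .sample_protein(.samp(cfg$cds_codon_range), probs)
    for (i in seq_len(cfg$n_cbp_cluster)) {
      aa <- strsplit(anc, "")[[1]]
      nmut <- rbinom(1L, length(aa) - 1L, 0.12)
      if (nmut > 0L) {
        at <- sample(2:length(aa), nmut)
        aa[at] <- sample(.AA20, nmut, replace = TRUE, prob = probs)
      }
      add(sprintf("CBP%d", i), "CBP",
          .build_sedc_cassette(cfg, paste0(aa, collapse = "")), flip_coin())
    }
  }
  add("S100A11", "marker",
      .build_marker_cassette(.sample_protein(100L, uniform)), FALSE)
  add("ALAS1", "marker",
      .build_sedc_cassette(cfg, .sample_protein(120L, uniform)), FALSE)

  # assemble ----------------------------------------------------------------
  pieces <- character(0)
  pos <- 0L
  gaps <- numeric(0) # genomic midpoints of intergenic gaps, for fragmentation
  models <- list(); proteins <- character(0); features <- list()
  for (k in seq_along(units)) {
    u <- units[[k]]
    cas <- u$cas
    len <- nchar(cas$seq)
    seq <- cas$seq
    exons <- cas$exons; coding <- cas$coding
    tata <- cas$tata; donor <- cas$donor; acceptor <- cas$acceptor
    strand <- "+"
    if (u$flip) {
      seq <- reverse_complement(seq)
      strand <- "-"
      fl <- function(iv) {
        if (is.null(iv)) return(NULL)
        if (is.null(dim(iv))) return(sort(len - iv))
        out <- cbind(len - iv[, 2], len - iv[, 1])
        out[order(out[, 1]), , drop = FALSE]
      }
      exons <- fl(exons); coding <- fl(coding); tata <- fl(tata)
      if (!is.null(donor)) {
        d <- donor; a <- acceptor
        donor <- len - a; acceptor <- len - d # swap roles under RC
      }
    }
    pieces <- c(pieces, seq)
    off <- pos
    m <- gene_model(id = u$name, scaffold_id = "locus", strand = strand,
                    exons = exons + off, coding_span = coding + off,
                    category = u$category, name = u$name)
    models[[u$name]] <- m
    if (u$category != "pseudogene" && !is.null(cas$protein))
      proteins[u$name] <- cas$protein
    features[[u$name]] <- list(
      tata = if (is.null(tata)) NULL else tata + off,
      donor = if (is.null(donor)) NULL else donor + off,
      acceptor = if (is.null(acceptor)) NULL else acceptor + off,
      strand = strand)
    pos <- pos + len
    if (k < length(units)) {
      g <- .samp(cfg$intergenic_length_range)
      pieces <- c(pieces, .rand_dna(g))
      gaps <- c(gaps, pos + g %/% 2L)
      pos <- pos + g
    }
  }
  scaffold_seq <- paste0(pieces, collapse = "")

  truth <- list(models = models, proteins = proteins, features = features,
                gene_order = vapply(units, `[[`, character(1), "name"),
                repeat_info = repeat_info, config = cfg, species = species)

  out <- .apply_fragmentation(scaffold_seq, truth, cfg, gaps, species)
  for (m in out$truth$models) {
    sc <- Filter(function(s) s$id == m$scaffold_id, out$scaffolds)[[1]]
    validate_gene_model(m, sc)
  }
  out
}

# split the assembled locus into fragments; genes hit by an explicit cut are
# truncated to partial models
.apply_fragmentation <- function(seq, truth, cfg, gaps, species) {
  frag <- cfg$fragmentation
  if (is.null(frag)) {
    sc <- scaffold_record("locus", seq, species)
    return(list(scaffolds = list(sc), truth = truth))
  }
  cuts <- if (length(frag) == 1L && frag[1] < length(gaps) + 1L &&
              frag[1] == round(frag[1]) && frag[1] <= length(gaps))
    sort(sample(gaps, frag[1])) else sort(as.numeric(frag))
  bounds <- c(0, cuts, nchar(seq))
  scaffolds <- list()
  models <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    fid <- sprintf("locus_frag%d", i)
    scaffolds[[i]] <- scaffold_record(fid, substr(seq, s + 1L, e), species)
    for (m in truth$models) {
      span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
      cds_anchor <- if (m$strand == "+") m$coding_span[1, 1]
                    else m$coding_span[nrow(m$coding_span), 2] - 1
      if (cds_anchor < s || cds_anchor >= e) next
      m2 <- m
      m2$scaffold_id <- fid
      clip <- function(iv) {
        iv[, 1] <- pmax(iv[, 1], s); iv[, 2] <- pmin(iv[, 2], e)
        iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
        iv - s
      }
      m2$exons <- clip(m$exons); m2$coding_span <- clip(m$coding_span)
      if (span[1] < s || span[2] > e) {
        m2$completeness <- "partial"
        truth$proteins <- truth$proteins[names(truth$proteins) != m$id]
      }
      f <- truth$features[[m$id]]
      shift <- function(x) if (is.null(x)) NULL else {
        y <- x - s
        if (any(y < 0) || any(y > e - s)) NULL else y
      }
      truth$features[[m$id]] <- list(tata = shift(f$tata),
                                     donor = shift(f$donor),
                                     acceptor = shift(f$acceptor),
                                     strand = f$strand)
      models[[m$id]] <- m2
    }
  }
  truth$models <- models[intersect(truth$gene_order, names(models))]
  list(scaffolds = scaffolds, truth = truth)
}
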