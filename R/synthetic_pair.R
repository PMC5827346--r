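# Diverged ortholog pairs and tissue-labelled read sets for the synthetic
# locus. Divergence is simulated by per-site nucleotide substitution with a
# 2:1 transition bias; substitutions that would create a premature stop or
# destroy an essential signal (start/stop codon, splice dinucleotides, TATA
# box) are reverted, emulating purifying selection so that the diverged
# locus remains annotatable like its real counterparts.

.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

.propose_base <- function(base) {
  if (runif(1) < 2 / 3) .TRANSITION[[base]]
  else sample(.TRANSVERSIONS[[base]], 1L)
}

# mutate one codon site by site, reverting any change that creates a stop
.mutate_codon <- function(codon, d) {
  for (s in 1:3) {
    if (runif(1) >= d) next
    old <- codon[s]
    codon[s] <- .propose_base(old)
    if (paste0(codon, collapse = "") %in% .STOP_CODONS) codon[s] <- old
  }
  codon
}

#' Generate a pair of diverged orthologous loci
#'
#' Locus A is a [generate_edc_locus()] draw (with an EDCRP-like repeat gene
#' planted by default); locus B is derived from it by per-site substitution
#' at the stated rate, preserving gene order, with `repeat_expansion` extra
#' tandem units inserted into the repeat gene's coding sequence. The truth
#' ortholog map pairs genes positionally.
#'
#' @param config a [synthetic_config()].
#' @param divergence substitutions per site, in `[0, 0.5]`.
#' @param repeat_expansion extra repeat-unit copies carried by locus B's
#'   repeat gene.
#' @return list with `locus_a`, `locus_b` (each `list(scaffolds, truth)`),
#'   and `ortholog_map` (data.frame `gene_a`, `gene_b`).
#' @export
generate_ortholog_pair <- function(config, divergence, repeat_expansion = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  if (is.null(config$repeat_gene))
    config$repeat_gene <- list(unit = "CCDPCQ(K|-)(T|P)(V|-)", copies = 3L)
  if (!is.null(config$fragmentation))
    stop("ortholog pairs are generated without fragmentation")
  locus_a <- generate_edc_locus(config, species = "species_A")

  set.seed(config$seed + 2L)
  seq_b <- locus_a$scaffolds[[1]]$sequence
  chars <- strsplit(seq_b, "")[[1]]
  truth_a <- locus_a$truth

  protected <- rep(FALSE, length(chars))
  coding <- rep(FALSE, length(chars))
  for (g in names(truth_a$models)) {
    m <- truth_a$models[[g]]
    f <- truth_a$features[[g]]
    for (i in seq_len(nrow(m$coding_span)))
      coding[(m$coding_span[i, 1] + 1L):m$coding_span[i, 2]] <- TRUE
    if (!is.null(f$tata)) protected[(f$tata[1] + 1L):f$tata[2]] <- TRUE
    if (!is.null(f$donor)) {
      protected[(f$donor + 1L):(f$donor + 2L)] <- TRUE
      protected[(f$acceptor - 1L):f$acceptor] <- TRUE
    }
    # start and stop codons (transcript ends of the CDS)
    cs <- m$coding_span
    if (m$strand == "+") {
      protected[(cs[1, 1] + 1L):(cs[1, 1] + 3L)] <- TRUE
      protected[(cs[nrow(cs), 2] - 2L):cs[nrow(cs), 2]] <- TRUE
    } else {
      protected[(cs[nrow(cs), 2] - 2L):cs[nrow(cs), 2]] <- TRUE
      protected[(cs[1, 1] + 1L):(cs[1, 1] + 3L)] <- TRUE
    }
  }

  if (divergence > 0) {
    # non-coding positions mutate freely
    free <- which(!coding & !protected)
    mutate <- free[runif(length(free)) < divergence]
    for (i in mutate) chars[i] <- .propose_base(chars[i])
    # coding positions mutate codon-wise with stop avoidance
    for (g in names(truth_a$models)) {
      m <- truth_a$models[[g]]
      cds_pos <- unlist(lapply(seq_len(nrow(m$coding_span)), function(i)
        (m$coding_span[i, 1] + 1L):m$coding_span[i, 2]))
      if (m$strand == "-") cds_pos <- rev(cds_pos)
      n_cod <- length(cds_pos) %/% 3L
      for (k in seq_len(n_cod)) {
        idx <- cds_pos[(3L * k - 2L):(3L * k)]
        if (any(protected[abs(idx)])) next
        codon <- chars[idx]
        if (m$strand == "-") codon <- unname(.DNA_COMP[codon])
        new <- .mutate_codon(codon, divergence)
        if (m$strand == "-") new <- unname(.DNA_COMP[new])
        chars[idx] <- new
      }
    }
  }

  truth_b <- truth_a
  truth_b$species <- "species_B"
  for (g in names(truth_b$models)) truth_b$models[[g]]$scaffold_id <- "locus_B"

  # insert extra repeat units into the repeat gene of locus B
  if (repeat_expansion > 0L) {
    ri <- truth_a$repeat_info
    if (is.null(ri)) stop("no repeat gene planted")
    m <- truth_b$models[[ri$gene]]
    pat <- parse_motif_pattern(ri$unit)
    new_units <- vapply(seq_len(repeat_expansion), function(i)
      .realize_unit(pat), character(1))
    insert_aa <- ri$nterm_len +
      sum(nchar(ri$copy_seqs[seq_len(ri$copies %/% 2L)]))
    new_cds_part <- sub("...$", "", .encode_cds(paste0(
      "M", paste0(new_units, collapse = ""))))
    new_cds_part <- sub("^ATG", "", new_cds_part)
    ins_len <- nchar(new_cds_part)
    cs <- m$coding_span[1, ]
    at <- if (m$strand == "+") cs[1] + 3L * insert_aa
          else cs[2] - 3L * insert_aa
    ins_seq <- if (m$strand == "+") new_cds_part
               else reverse_complement(new_cds_part)
    seq_b2 <- paste0(chars, collapse = "")
    seq_b2 <- paste0(substr(seq_b2, 1, at), ins_seq,
                     substring(seq_b2, at + 1L))
    chars <- strsplit(seq_b2, "")[[1]]
    shift_iv <- function(iv) {
      iv[iv > at] <- iv[iv > at] + ins_len
      # intervals straddling the insertion grow
      iv
    }
    for (g in names(truth_b$models)) {
      mm <- truth_b$models[[g]]
      mm$exons <- shift_iv(mm$exons)
      mm$coding_span <- shift_iv(mm$coding_span)
      truth_b$models[[g]] <- mm
    }
    truth_b$features <- lapply(truth_b$features, function(f) {
      sh <- function(x) { if (is.null(x)) return(NULL)
        x[x > at] <- x[x > at] + ins_len; x }
      list(tata = sh(f$tata), donor = sh(f$donor),
           acceptor = sh(f$acceptor), strand = f$strand)
    })
    truth_b$repeat_info$copies <- ri$copies + repeat_expansion
    truth_b$repeat_info$copy_seqs <- append(ri$copy_seqs, new_units,
                                            after = ri$copies %/% 2L)
  }

  scaffold_b <- scaffold_record("locus_B", paste0(chars, collapse = ""),
                                "species_B")
  # recompute truth proteins of locus B from the mutated sequence
  for (g in names(truth_b$proteins))
    truth_b$proteins[g] <- gene_protein(truth_b$models[[g]], scaffold_b)
  locus_b <- list(scaffolds = list(scaffold_b), truth = truth_b)
  for (m in locus_b$truth$models) validate_gene_model(m, scaffold_b)

  list(locus_a = locus_a, locus_b = locus_b,
       ortholog_map = data.frame(gene_a = names(truth_a$models),
                                 gene_b = names(truth_b$models),
                                 stringsAsFactors = FALSE),
       divergence = divergence, repeat_expansion = repeat_expansion)
}

#' Generate tissue-labelled RNA-seq reads for a locus
#'
#' Reads are exact substrings of the spliced transcripts (error-free by
#' default), with per-tissue gene counts drawn from a multinomial under the
#' expression profile. The default profile makes all EDC genes
#' skin-specific while the ALAS1-like housekeeping stand-in and the marker
#' genes are expressed uniformly in every tissue, so intron-spanning reads
#' exist for genes with a 5' noncoding exon.
#'
#' @param locus result of [generate_edc_locus()] (`scaffolds` + `truth`),
#'   or the `locus_a`/`locus_b` element of [generate_ortholog_pair()].
#' @param config the [synthetic_config()] used to build the locus.
#' @return list with `reads` (list of [read_record()]) and `table`
#'   (data.frame `read_id`, `gene`, `tissue`, `start`: the ground truth).
#'   Genes whose transcript is shorter than the read length are skipped
#'   with a warning.
#' @export
generate_tissue_reads <- function(locus, config = locus$truth$config) {
  truth <- locus$truth
  set.seed(config$seed + 1L)
  scafs <- stats::setNames(locus$scaffolds,
                           vapply(locus$scaffolds, `[[`, character(1), "id"))
  tissues <- names(config$reads_per_tissue)
  profile <- config$expression_profile
  if (is.null(profile)) {
    skin <- if ("skin" %in% tissues) "skin" else tissues[1]
    profile <- lapply(truth$models, function(m) {
      if (m$category %in% c("SEDC", "SFTP", "CBP"))
        stats::setNames(as.numeric(tissues == skin), tissues)
      else if (m$id == "ALAS1" || m$category == "marker")
        stats::setNames(rep(1, length(tissues)), tissues)
    })
    profile <- Filter(Negate(is.null), profile)
  }
  if (!all(names(profile) %in% names(truth$models)))
    stop("expression profile references unknown genes: ",
         paste(setdiff(names(profile), names(truth$models)), collapse = ", "))
  rl <- config$read_length
  transcripts <- list()
  for (g in names(profile)) {
    m <- truth$models[[g]]
    if (m$category == "pseudogene") next
    tx <- gene_transcript(m, scafs[[m$scaffold_id]])
    if (nchar(tx) < rl) {
      warning("transcript of ", g, " shorter than the read length; skipped")
      next
    }
    transcripts[[g]] <- tx
  }
  reads <- list(); rows <- list()
  for (tissue in tissues) {
    w <- vapply(names(transcripts), function(g) {
      x <- profile[[g]][tissue]
      if (is.na(x)) 0 else as.numeric(x)
    }, numeric(1))
    total <- config$reads_per_tissue[[tissue]]
    if (sum(w) == 0 || total == 0) next
    counts <- as.integer(rmultinom(1L, total, w))
    for (gi in seq_along(transcripts)) {
      if (counts[gi] == 0L) next
      g <- names(transcripts)[gi]
      tx <- transcripts[[gi]]
      starts <- sample.int(nchar(tx) - rl + 1L, counts[gi], replace = TRUE) - 1L
      for (s in starts) {
        rseq <- substr(tx, s + 1L, s + rl)
        if (config$error_rate > 0) {
          rch <- strsplit(rseq, "")[[1]]
          hit <- which(runif(rl) < config$error_rate)
          for (i in hit) rch[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                                  rch[i]), 1L)
          rseq <- paste0(rch, collapse = "")
        }
        rid <- sprintf("read_%s_%05d", tissue, length(reads) + 1L)
        reads[[length(reads) + 1L]] <- read_record(rid, rseq, tissue)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = rid, gene = g, tissue = tissue, start = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = reads,
       table = if (length(rows)) do.call(rbind, rows)
               else data.frame(read_id = character(), gene = character(),
                               tissue = character(), start = integer()))
}
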