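# Locus annotation: delimit the EDC between its S100A marker genes, order
# fragmented scaffolds against a reference locus map, and predict SEDC/SFTP
# gene models de novo with pseudogene triage and RNA-seq validation.

#' Locus region constructor
#'
#' @param segments list of segments, each a list with `scaffold_id`,
#'   `interval` (0-based half-open) and `orientation` (+/-).
#' @param discontinuity logical vector, one flag per junction between
#'   consecutive segments (length = segments - 1).
#' @param notes optional character vector, one per segment (e.g.
#'   "unplaced", "contradictory_anchors").
#' @return object of class `locus_region`.
#' @export
locus_region <- function(segments, discontinuity = logical(0),
                         notes = rep("", length(segments))) {
  stopifnot(length(discontinuity) == max(0L, length(segments) - 1L))
  structure(list(segments = segments, discontinuity = discontinuity,
                 notes = notes), class = "locus_region")
}

#' @export
print.locus_region <- function(x, ...) {
  cat("<locus_region>", length(x$segments), "segment(s)\n")
  for (i in seq_along(x$segments)) {
    s <- x$segments[[i]]
    cat(sprintf("  %s:[%d,%d) %s %s\n", s$scaffold_id, s$interval[1],
                s$interval[2], s$orientation,
                if (nzchar(x$notes[i])) paste0("(", x$notes[i], ")") else ""))
    if (i < length(x$segments) && x$discontinuity[i]) cat("  ~ discontinuity\n")
  }
  invisible(x)
}

#' Delimit the EDC between two S100A marker genes
#'
#' Locates the best translated-search hit for each marker protein. If both
#' markers land on one scaffold the region between them (exclusive of the
#' marker coding spans) is returned; if they land on different scaffolds,
#' each scaffold contributes the region from its marker hit toward the
#' scaffold end on the side with more sequence, joined by a discontinuity
#' flag.
#'
#' @param assembly list of [scaffold_record()] objects.
#' @param marker_proteins list of exactly two [protein_record()] queries
#'   (5' and 3' marker, e.g. S100A12 and S100A11 stand-ins).
#' @param scheme a [default_score_scheme()].
#' @param min_score minimum marker hit score.
#' @return a [locus_region()].
#' @export
find_flanked_region <- function(assembly, marker_proteins,
                                scheme = default_score_scheme(),
                                min_score = 40L) {
  if (length(assembly) == 0L) stop("assembly is empty")
  if (length(marker_proteins) != 2L)
    stop("exactly two marker queries are required")
  best <- lapply(marker_proteins, function(q) {
    hits <- list()
    for (sc in assembly)
      hits <- c(hits, translated_search(q, sc, scheme, min_score,
                                        max_hits_per_frame = 2L))
    if (length(hits) == 0L)
      stop("marker '", if (inherits(q, "protein_record")) q$id else "?",
           "' has no hit >= min_score in the assembly")
    hits[[1]] # translated_search sorts by score
  })
  h1 <- best[[1]]; h2 <- best[[2]]
  if (h1$target_id == h2$target_id) {
    a <- h1$target_span; b <- h2$target_span
    if (a[1] < b[2] && b[1] < a[2])
      stop("marker hits overlap; cannot delimit a region")
    if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
    locus_region(list(list(scaffold_id = h1$target_id,
                           interval = c(a[2], b[1]), orientation = "+")))
  } else {
    seg <- lapply(best, function(h) {
      L <- nchar(Filter(function(s) s$id == h$target_id, assembly)[[1]]$sequence)
      iv <- if (L - h$target_span[2] >= h$target_span[1])
        c(h$target_span[2], L) else c(0, h$target_span[1])
      list(scaffold_id = h$target_id, interval = iv, orientation = "+")
    })
    locus_region(seg, discontinuity = TRUE)
  }
}

#' Order locus segments against a reference gene order
#'
#' Segments are ordered and oriented so that the families their hits belong
#' to appear in the reference order. A segment whose own hits imply mutually
#' reversed orders is flagged `contradictory_anchors` (placed by median
#' rank, not silently); segments without hits are appended and flagged
#' `unplaced`. All junctions are marked as discontinuities.
#'
#' @param region a [locus_region()] (or bare list of segments).
#' @param reference_gene_order character vector of family names in
#'   reference locus order.
#' @param hits list of `alignment_hit` objects whose `query_id` is a family
#'   name in `reference_gene_order` and whose `target_id` is a scaffold id.
#' @return a [locus_region()] with reordered segments.
#' @export
order_scaffolds <- function(region, reference_gene_order, hits) {
  segments <- if (inherits(region, "locus_region")) region$segments else region
  if (length(segments) <= 1L)
    return(locus_region(segments))
  info <- lapply(segments, function(s) {
    sh <- Filter(function(h) h$target_id == s$scaffold_id &&
                   h$target_span[2] > s$interval[1] &&
                   h$target_span[1] < s$interval[2], hits)
    if (length(sh) == 0L)
      return(list(anchor = NA_real_, flip = FALSE, note = "unplaced"))
    pos <- vapply(sh, function(h) h$target_span[1], numeric(1))
    fam <- vapply(sh, `[[`, character(1), "query_id")
    rank <- match(fam, reference_gene_order)
    if (anyNA(rank))
      stop("hit family not in reference order: ",
           paste(unique(fam[is.na(rank)]), collapse = ", "))
    rank <- rank[order(pos)]
    note <- ""
    flip <- FALSE
    if (length(rank) > 1L) {
      if (!is.unsorted(rank)) flip <- FALSE
      else if (!is.unsorted(rev(rank))) flip <- TRUE
      else note <- "contradictory_anchors"
    }
    list(anchor = stats::median(rank), flip = flip, note = note)
  })
  anchor <- vapply(info, `[[`, numeric(1), "anchor")
  ids <- vapply(segments, `[[`, character(1), "scaffold_id")
  placed <- which(!is.na(anchor))
  unplaced <- which(is.na(anchor))
  ord <- c(placed[order(anchor[placed], ids[placed])],
           unplaced[order(ids[unplaced])])
  segs <- lapply(ord, function(i) {
    s <- segments[[i]]
    if (info[[i]]$flip)
      s$orientation <- if (s$orientation == "+") "-" else "+"
    s
  })
  locus_region(segs,
               discontinuity = rep(TRUE, length(segs) - 1L),
               notes = vapply(ord, function(i) info[[i]]$note, character(1)))
}

#' Parameters for SEDC gene prediction
#'
#' @param min_codons minimum protein length (residues) for a de novo
#'   candidate open reading frame.
#' @param bias_residues residues counted toward the EDC composition score.
#' @param bias_threshold minimum fraction of `bias_residues` for a
#'   composition-only candidate.
#' @param promoter_window nt window upstream of the intron donor scanned
#'   for a TATA motif.
#' @param tata_motif regular expression for the TATA box (W = A/T).
#' @param utr_window maximum nt between the intron acceptor and the ATG.
#' @param min_intron,max_intron allowed intron lengths (nt).
#' @param tata_dist_range allowed nt distance from the TATA box to the
#'   intron donor (a core promoter plus one short noncoding exon).
#' @param coding_bias expected fraction of `bias_residues` in EDC coding
#'   sequence (parameterizes the start-choice changepoint score).
#' @param background_bias fraction of `bias_residues` expected in
#'   translated random sequence (20 of the 61 sense codons).
#' @param evidence_bonus log-likelihood bonus added to candidate starts
#'   with full promoter (TATA + splice) evidence.
#' @param min_overhang minimum nt on each side of the exon junction for a
#'   read to count as intron-spanning.
#' @param validation_flank nt of genomic context added around predicted
#'   exons when matching reads (the predicted transcript ends are
#'   approximate; the flank makes true reads exact substrings).
#' @return list of parameters.
#' @export
sedc_params <- function(min_codons = 50L,
                        bias_residues = c("G", "S", "P", "K", "C", "Q"),
                        bias_threshold = 0.5,
                        promoter_window = 250L,
                        tata_motif = "TATA[AT]A",
                        utr_window = 25L,
                        min_intron = 70L, max_intron = 250L,
                        tata_dist_range = c(45L, 135L),
                        coding_bias = 0.6, background_bias = 20 / 61,
                        evidence_bonus = 3,
                        min_overhang = 5L,
                        validation_flank = 250L) {
  list(min_codons = min_codons, bias_residues = bias_residues,
       bias_threshold = bias_threshold, promoter_window = promoter_window,
       tata_motif = tata_motif, utr_window = utr_window,
       min_intron = min_intron, max_intron = max_intron,
       tata_dist_range = tata_dist_range,
       coding_bias = coding_bias, background_bias = background_bias,
       evidence_bonus = evidence_bonus,
       min_overhang = min_overhang, validation_flank = validation_flank)
}

# stop-bounded runs of a frame translation with their ATG positions
.orf_runs <- function(prot) {
  chars <- strsplit(prot, "")[[1]]
  stops <- c(0L, which(chars == "*"), length(chars) + 1L)
  runs <- list()
  for (s in seq_len(length(stops) - 1L)) {
    a <- stops[s] + 1L; b <- stops[s + 1L] - 1L
    if (b < a) next
    has_stop <- stops[s + 1L] <= length(chars)
    atgs <- a - 1L + which(chars[a:b] == "M")
    runs[[length(runs) + 1L]] <- list(start = a, end = b + 1L,
                                      atgs = atgs, has_stop = has_stop)
  }
  runs
}

# promoter evidence for a candidate ATG at sense-space nt position atg_nt
# (0-based): an AG acceptor within utr_window, a GT donor giving an intron
# in [min_intron, max_intron], and a TATA motif within promoter_window
# upstream of the donor
.promoter_evidence <- function(chars, tatas, atg_nt, params) {
  for (acc_end in seq(atg_nt, max(2L, atg_nt - params$utr_window), by = -1L)) {
    if (acc_end < 2L) break
    if (chars[acc_end - 1L] != "A" || chars[acc_end] != "G") next
    lens <- params$min_intron:min(params$max_intron, acc_end)
    donors <- acc_end - lens
    donors <- donors[donors >= 0L]
    if (length(donors) == 0L) next
    ok <- chars[donors + 1L] == "G" & chars[donors + 2L] == "T"
    for (donor in donors[ok]) {
      # the TATA box sits a core promoter plus one short noncoding exon
      # upstream of the donor; restrict to that canonical distance band
      lo <- max(donor - params$tata_dist_range[2],
                donor - params$promoter_window)
      hi <- donor - params$tata_dist_range[1]
      hit <- tatas[tatas >= lo & tatas <= hi]
      if (length(hit))
        return(list(tata = hit[length(hit)], donor = donor, acc_end = acc_end))
    }
  }
  NULL
}

.intervals_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

#' Predict SEDC genes in a locus region
#'
#' Scans all six frames of every segment for open reading frames. An
#' ATG-initiated ORF of at least `min_codons` residues becomes a candidate
#' when it overlaps a homology hit or when its G+S+P+K+C+Q fraction reaches
#' `bias_threshold`. For each candidate the upstream sequence is scanned
#' for a TATA motif and a GT..AG intron whose acceptor lies within
#' `utr_window` of the ATG; the 5' noncoding exon is attached only when
#' both TATA and splice evidence exist. When several in-frame ATGs could
#' start the ORF, the most upstream ATG with full promoter evidence wins,
#' falling back to the most upstream ATG. Homology hits over runs without a
#' qualifying ATG yield stop-to-stop candidates (to catch partial genes at
#' scaffold edges). Overlapping candidates in different frames are both
#' kept and flagged, never merged.
#'
#' @param region a [locus_region()].
#' @param assembly list of [scaffold_record()] objects.
#' @param homology_hits optional list of `alignment_hit` objects (genomic
#'   coordinates, e.g. from [translated_search()] on the scaffolds).
#' @param params a [sedc_params()] list.
#' @return list of `gene_prediction` objects: each has `$model` (a
#'   single-coding-exon [gene_model()]) and `$evidence` (TATA position,
#'   splice sites, homology hit count, confidence tier, flags).
#' @export
predict_sedc_genes <- function(region, assembly, homology_hits = NULL,
                               params = sedc_params()) {
  scafs <- stats::setNames(assembly,
                           vapply(assembly, `[[`, character(1), "id"))
  preds <- list()
  counter <- 0L
  for (seg in region$segments) {
    sc <- scafs[[seg$scaffold_id]]
    if (is.null(sc)) stop("segment scaffold not in assembly: ", seg$scaffold_id)
    segseq <- .extract(sc$sequence, seg$interval)
    if (nchar(segseq) < 3L) next
    off <- seg$interval[1]
    Lseg <- nchar(segseq)
    for (strand in c("+", "-")) {
      sense <- if (strand == "+") segseq else reverse_complement(segseq)
      chars <- strsplit(sense, "")[[1]]
      tatas <- {
        m <- gregexpr(params$tata_motif, sense)[[1]]
        if (m[1] < 0) integer(0) else as.integer(m) - 1L
      }
      to_genomic <- function(iv) {
        if (strand == "+") iv + off else c(Lseg - iv[2], Lseg - iv[1]) + off
      }
      seg_hits <- Filter(function(h)
        identical(h$target_id, sc$id) && identical(h$strand, strand) &&
          .intervals_overlap(h$target_span, seg$interval), homology_hits)
      hit_spans_sense <- lapply(seg_hits, function(h) {
        iv <- h$target_span - off
        if (strand == "+") iv else c(Lseg - iv[2], Lseg - iv[1])
      })
      for (frame in 0:2) {
        if (nchar(sense) < frame + 3L) next
        prot <- translate(sense, frame, "+")
        pchars <- strsplit(prot, "")[[1]]
        for (run in .orf_runs(prot)) {
          run_nt <- c(frame + 3L * (run$start - 1L), frame + 3L * run$end)
          atgs <- run$atgs[run$end - run$atgs >= params$min_codons]
          overlaps_hit <- any(vapply(hit_spans_sense, function(iv)
            .intervals_overlap(iv, run_nt), logical(1)))
          if (length(atgs) == 0L) {
            # stop-to-stop homology-anchored candidate (partial/pseudogene)
            if (!overlaps_hit || run$end - run$start < params$min_codons) next
            cds_iv <- c(frame + 3L * (run$start - 1L),
                        frame + 3L * (run$end - 1L) +
                          if (run$has_stop) 3L else 0L)
            cds_iv[2] <- min(cds_iv[2], Lseg)
            counter <- counter + 1L
            giv <- to_genomic(cds_iv)
            model <- gene_model(sprintf("pred%03d", counter), sc$id, strand,
                                exons = rbind(giv), coding_span = rbind(giv),
                                category = "SEDC",
                                name = sprintf("pred%03d", counter))
            preds[[length(preds) + 1L]] <- structure(list(
              model = model,
              evidence = list(hits = length(seg_hits), tata_position = NULL,
                              splice_sites = NULL, read_support = NA_integer_,
                              intron_spanning_reads = NA_integer_,
                              confidence = "homology",
                              no_atg = TRUE, frame_overlap = FALSE)),
              class = "gene_prediction")
            next
          }
          # choose the start by a composition changepoint: residues after
          # the true start should look EDC-coding (bias fraction ~
          # coding_bias), residues before it background-like; candidate
          # starts with full promoter evidence get a bonus. Ties go to the
          # most upstream ATG.
          w_pos <- log(params$coding_bias / params$background_bias)
          w_neg <- log((1 - params$coding_bias) / (1 - params$background_bias))
          w <- ifelse(pchars %in% params$bias_residues, w_pos, w_neg)
          w[pchars == "M"] <- 0 # initiator/internal Met carries no signal
          suffix <- rev(cumsum(rev(w[seq_len(run$end - 1L)])))
          evs <- lapply(atgs, function(atg)
            .promoter_evidence(chars, tatas, frame + 3L * (atg - 1L), params))
          score <- suffix[atgs] +
            params$evidence_bonus * !vapply(evs, is.null, logical(1))
          best_i <- which.max(score)
          chosen <- atgs[best_i]
          ev <- evs[[best_i]]
          cand_prot <- paste0(pchars[chosen:(run$end - 1L)], collapse = "")
          bias_frac <- mean(strsplit(cand_prot, "")[[1]] %in% params$bias_residues)
          if (!overlaps_hit && bias_frac < params$bias_threshold) next
          atg_nt <- frame + 3L * (chosen - 1L)
          cds_end <- frame + 3L * (run$end - 1L) +
            if (run$has_stop) 3L else 0L
          cds_end <- min(cds_end, Lseg)
          cds_iv <- c(atg_nt, cds_end)
          counter <- counter + 1L
          id <- sprintf("pred%03d", counter)
          if (!is.null(ev)) {
            exon1 <- c(min(ev$tata + 6L + 24L, ev$donor - 1L), ev$donor)
            exons <- rbind(exon1, c(ev$acc_end, cds_iv[2]))
            gex <- t(apply(exons, 1, to_genomic))
            gex <- gex[order(gex[, 1]), , drop = FALSE]
            model <- gene_model(id, sc$id, strand, exons = gex,
                                coding_span = rbind(to_genomic(cds_iv)),
                                category = "SEDC", name = id)
            splice <- sort(to_genomic(c(ev$donor, ev$acc_end)))
            tata_pos <- to_genomic(c(ev$tata, ev$tata + 6L))[1]
          } else {
            giv <- to_genomic(cds_iv)
            model <- gene_model(id, sc$id, strand, exons = rbind(giv),
                                coding_span = rbind(giv),
                                category = "SEDC", name = id)
            splice <- NULL; tata_pos <- NULL
          }
          conf <- if (overlaps_hit) "homology" else "composition-only"
          preds[[length(preds) + 1L]] <- structure(list(
            model = model,
            evidence = list(hits = sum(vapply(hit_spans_sense, function(iv)
                              .intervals_overlap(iv, cds_iv), logical(1))),
                            tata_position = tata_pos, splice_sites = splice,
                            read_support = NA_integer_,
                            intron_spanning_reads = NA_integer_,
                            confidence = conf, no_atg = FALSE,
                            frame_overlap = FALSE)),
            class = "gene_prediction")
        }
      }
    }
  }
  .flag_frame_overlaps(preds)
}

.flag_frame_overlaps <- function(preds) {
  if (length(preds) < 2L) return(preds)
  spans <- lapply(preds, function(p)
    c(p$model$coding_span[1, 1], p$model$coding_span[nrow(p$model$coding_span), 2]))
  scaf <- vapply(preds, function(p) p$model$scaffold_id, character(1))
  for (i in seq_along(preds))
    for (j in seq_along(preds))
      if (i != j && scaf[i] == scaf[j] &&
          .intervals_overlap(spans[[i]], spans[[j]]))
        preds[[i]]$evidence$frame_overlap <- TRUE
  preds
}

#' @export
print.gene_prediction <- function(x, ...) {
  print(x$model)
  cat(sprintf("  evidence: %s%s%s hits=%s\n", x$evidence$confidence,
              if (!is.null(x$evidence$tata_position)) " +TATA" else "",
              if (!is.null(x$evidence$splice_sites)) " +splice" else "",
              x$evidence$hits))
  invisible(x)
}

#' Predict two-coding-exon SFTP genes
#'
#' Pairs of translated-search hits of an SFTP query in the same strand,
#' with complementary query spans and separated by at most `max_intron` nt,
#' are joined across a canonical GT..AG intron. Exon boundaries are refined
#' within a +/-9 nt window around the hit edges so that the joined coding
#' sequence is in frame, starts with ATG and ends at a stop; the boundary
#' pair whose joined translation best matches the query wins. A join whose
#' translation contains an internal stop is demoted to a pseudogene
#' candidate.
#'
#' @param region a [locus_region()].
#' @param assembly list of [scaffold_record()] objects.
#' @param sftp_queries list of [protein_record()] SFTP queries (e.g. CRNN,
#'   SCFN of a related species).
#' @param scheme a [default_score_scheme()].
#' @param params a [sedc_params()] list (`max_intron` bounds the joined
#'   intron).
#' @param min_score per-exon hit threshold.
#' @return list of `gene_prediction` objects with two-coding-exon models.
#' @export
predict_sftp_genes <- function(region, assembly, sftp_queries,
                               scheme = default_score_scheme(),
                               params = sedc_params(), min_score = 40L) {
  if (length(sftp_queries) == 0L) stop("at least one SFTP query is required")
  scafs <- stats::setNames(assembly,
                           vapply(assembly, `[[`, character(1), "id"))
  preds <- list()
  counter <- 0L
  for (seg in region$segments) {
    sc <- scafs[[seg$scaffold_id]]
    segseq <- .extract(sc$sequence, seg$interval)
    off <- seg$interval[1]
    Lseg <- nchar(segseq)
    for (q in sftp_queries) {
      qlen <- nchar(.as_protein_string(q))
      hits <- translated_search(q, segseq, scheme, min_score,
                                max_hits_per_frame = 4L)
      for (strand in c("+", "-")) {
        sh <- Filter(function(h) h$strand == strand, hits)
        if (length(sh) == 0L) next
        sense_span <- function(h) {
          if (strand == "+") h$target_span
          else c(Lseg - h$target_span[2], Lseg - h$target_span[1])
        }
        sense <- if (strand == "+") segseq else reverse_complement(segseq)
        ord <- order(vapply(sh, function(h) sense_span(h)[1], numeric(1)))
        sh <- sh[ord]
        to_genomic <- function(iv) {
          if (strand == "+") iv + off else c(Lseg - iv[2], Lseg - iv[1]) + off
        }
        # anchor the CDS start from the hit reaching the query N-terminus
        # and the CDS end from the hit reaching the C-terminus, then search
        # all codon-boundary GT donors with an in-range AG acceptor
        qs <- vapply(sh, function(h) h$query_span[1], numeric(1))
        qe <- vapply(sh, function(h) h$query_span[2], numeric(1))
        sc_ord <- vapply(sh, `[[`, numeric(1), "score")
        i_start <- order(qs, -sc_ord)[1]
        i_end <- order(-qe, -sc_ord)[1]
        if (qs[i_start] > 5 || qe[i_end] < qlen - 5) next
        s1 <- sense_span(sh[[i_start]]); s2 <- sense_span(sh[[i_end]])
        cds_start0 <- s1[1] - 3L * sh[[i_start]]$query_span[1]
        cds_end0 <- s2[2] + 3L * (qlen - sh[[i_end]]$query_span[2]) + 3L
        mdl <- .assemble_sftp(sense, cds_start0, cds_end0, q, qlen,
                              scheme, params)
        if (is.null(mdl)) next
        counter <- counter + 1L
        id <- sprintf("sftp%02d", counter)
        cs <- rbind(to_genomic(mdl$cds1), to_genomic(mdl$cds2))
        cs <- cs[order(cs[, 1]), , drop = FALSE]
        category <- if (mdl$pseudo) "pseudogene" else "SFTP"
        model <- gene_model(id, sc$id, strand, exons = cs,
                            coding_span = cs, category = category,
                            name = if (inherits(q, "protein_record"))
                              paste0(q$id, "_like") else id)
        preds[[length(preds) + 1L]] <- structure(list(
          model = model,
          evidence = list(hits = length(sh), tata_position = NULL,
                          splice_sites = sort(to_genomic(
                            c(mdl$cds1[2], mdl$cds2[1]))),
                          read_support = NA_integer_,
                          intron_spanning_reads = NA_integer_,
                          confidence = "homology",
                          no_atg = FALSE, frame_overlap = FALSE)),
          class = "gene_prediction")
      }
    }
  }
  # deduplicate by coding span (several query pairs may find the same gene)
  seen <- character(0)
  keep <- list()
  for (p in preds) {
    key <- paste(p$model$scaffold_id, p$model$strand,
                 paste(p$model$coding_span, collapse = ","))
    if (key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- p
  }
  keep
}

# assemble a two-coding-exon model between anchored CDS endpoints: search
# codon-boundary GT donors and in-range AG acceptors for the stop-free
# in-frame join that best matches the query; joins whose only canonical
# splice solutions contain internal stops are demoted to pseudogene
.assemble_sftp <- function(sense, cds_start0, cds_end0, q, qlen,
                           scheme, params) {
  chars <- strsplit(sense, "")[[1]]
  n <- length(chars)
  cds_start <- cds_start0
  if (cds_start < 0L || cds_start + 3L > n) return(NULL)
  if (paste0(chars[(cds_start + 1L):(cds_start + 3L)], collapse = "") != "ATG") {
    found <- FALSE
    for (dd in c(-3L, 3L, -6L, 6L, -9L, 9L)) {
      cs <- cds_start0 + dd
      if (cs >= 0L && cs + 3L <= n &&
          paste0(chars[(cs + 1L):(cs + 3L)], collapse = "") == "ATG") {
        cds_start <- cs; found <- TRUE; break
      }
    }
    if (!found) return(NULL)
  }
  best <- NULL; best_pseudo <- NULL
  ce_opts <- unique(pmin(cds_end0 + seq(-15L, 15L, by = 3L), n))
  d_opts <- seq(cds_start + 3L, min(n - 3L, max(ce_opts)), by = 3L)
  d_opts <- d_opts[chars[d_opts + 1L] == "G" & chars[d_opts + 2L] == "T"]
  for (d in d_opts) {
    accs <- d + params$min_intron:params$max_intron
    accs <- accs[accs <= n - 3L]
    accs <- accs[chars[accs - 1L] == "A" & chars[accs] == "G"]
    for (a in accs) {
      for (ce in ce_opts) {
        len1 <- d - cds_start; len2 <- ce - a
        if (len1 < 3L || len2 < 3L) next
        if ((len1 + len2) %% 3L != 0L) next
        cds <- paste0(c(chars[(cds_start + 1L):d], chars[(a + 1L):ce]),
                      collapse = "")
        prot <- translate(cds)
        if (!endsWith(prot, "*")) next
        body <- sub("\\*$", "", prot)
        if (!startsWith(body, "M")) next
        if (grepl("\\*", body)) {
          cand <- list(cds1 = c(cds_start, d), cds2 = c(a, ce),
                       score = -sum(strsplit(body, "")[[1]] == "*"),
                       pseudo = TRUE)
          if (is.null(best_pseudo) || cand$score > best_pseudo$score)
            best_pseudo <- cand
          next
        }
        score <- global_align(body, .as_protein_string(q), scheme)$score
        cand <- list(cds1 = c(cds_start, d), cds2 = c(a, ce),
                     score = score, pseudo = FALSE)
        if (is.null(best) || cand$score > best$score) best <- cand
      }
    }
  }
  if (!is.null(best)) best else best_pseudo
}

#' Classify a prediction as complete, partial or pseudogene
#'
#' complete: stop-free ATG-initiated CDS fully inside assembled (non-N)
#' sequence; partial: CDS truncated by a scaffold end or N run; pseudogene:
#' internal stop, missing start, or (when family members are supplied)
#' gross truncation relative to intact family members. Pseudogenes are
#' retained but flagged for exclusion from protein-level analyses.
#'
#' @param prediction a `gene_prediction` (or bare [gene_model()]).
#' @param assembly list of [scaffold_record()] objects.
#' @param family_members optional character vector of intact family-member
#'   protein sequences.
#' @return one of `"complete"`, `"partial"`, `"pseudogene"`.
#' @export
classify_gene_status <- function(prediction, assembly, family_members = NULL) {
  model <- if (inherits(prediction, "gene_prediction")) prediction$model
           else prediction
  sc <- Filter(function(s) s$id == model$scaffold_id, assembly)[[1]]
  L <- nchar(sc$sequence)
  span <- c(min(model$coding_span[, 1]), max(model$coding_span[, 2]))
  cds <- gene_cds(model, sc)
  at_edge <- span[1] <= 2L || span[2] >= L - 2L
  in_gap <- grepl("N{5,}", cds)
  prot <- translate(substr(cds, 1, nchar(cds) - nchar(cds) %% 3))
  body <- sub("\\*$", "", prot)
  if (grepl("\\*", body)) return("pseudogene")
  if (at_edge || in_gap) return("partial")
  if (!startsWith(body, "M")) return("pseudogene")
  if (!is.null(family_members) && length(family_members)) {
    if (nchar(body) < 0.5 * stats::median(nchar(family_members)))
      return("pseudogene")
  }
  "complete"
}

#' Validate a prediction with RNA-seq reads
#'
#' Counts reads matching the predicted transcript exactly (100% identity,
#' full read length) and the subset straddling the noncoding/coding exon
#' junction with at least `min_overhang` nt on each side. Because predicted
#' transcript ends are approximate, the spliced validation sequence is
#' extended by `validation_flank` nt of genomic context on both sides of
#' the exon chain.
#'
#' @param prediction a `gene_prediction`.
#' @param assembly list of [scaffold_record()] objects.
#' @param reads list of [read_record()] objects.
#' @param params a [sedc_params()] list.
#' @return the prediction with `evidence$read_support` and
#'   `evidence$intron_spanning_reads` filled in.
#' @export
validate_with_reads <- function(prediction, assembly, reads,
                                params = sedc_params()) {
  model <- prediction$model
  sc <- Filter(function(s) s$id == model$scaffold_id, assembly)[[1]]
  L <- nchar(sc$sequence)
  fl <- params$validation_flank
  span <- c(min(model$exons[, 1]), max(model$exons[, 2]))
  ext <- c(max(0L, span[1] - fl), min(L, span[2] + fl))
  # work on the transcript (sense) strand of the extended window
  useq <- .extract(sc$sequence, ext)
  if (model$strand == "-") useq <- reverse_complement(useq)
  n <- nchar(useq)
  to_sense <- function(x) {
    if (model$strand == "+") x - ext[1] else ext[2] - x
  }
  # coding start and model acceptor/donor in sense coordinates
  cs <- model$coding_span
  cds_start_s <- if (model$strand == "+") to_sense(cs[1, 1])
                 else to_sense(cs[nrow(cs), 2])
  has_intron <- nrow(model$exons) > 1L
  support <- 0L; spanning <- 0L
  uchars <- strsplit(useq, "")[[1]]
  # candidate junctions: acceptor AG ends within utr_window of the coding
  # start, donor GT at an allowed intron distance upstream; the model's own
  # splice sites are candidates by construction
  cand <- list()
  if (has_intron) {
    for (a in seq(cds_start_s, max(2L, cds_start_s - params$utr_window), by = -1L)) {
      if (a < 2L) break
      if (uchars[a - 1L] != "A" || uchars[a] != "G") next
      ds <- a - params$min_intron:params$max_intron
      ds <- ds[ds >= 1L]
      ds <- ds[uchars[ds + 1L] == "G" & uchars[ds + 2L] == "T"]
      for (d in ds) cand[[length(cand) + 1L]] <- c(d, a)
    }
  }
  spliced <- lapply(cand, function(j)
    paste0(substr(useq, 1L, j[1]), substring(useq, j[2] + 1L)))
  for (r in reads) {
    rs <- r$sequence
    if (regexpr(rs, useq, fixed = TRUE) > 0) {
      support <- support + 1L
      next
    }
    if (!has_intron) next
    for (k in seq_along(cand)) {
      at <- regexpr(rs, spliced[[k]], fixed = TRUE)
      if (at < 0) next
      a0 <- at - 1L; a1 <- a0 + nchar(rs)
      junction <- cand[[k]][1]
      support <- support + 1L
      if (junction - a0 >= params$min_overhang &&
          a1 - junction >= params$min_overhang)
        spanning <- spanning + 1L
      break
    }
  }
  prediction$evidence$read_support <- support
  prediction$evidence$intron_spanning_reads <- spanning
  prediction
}

#' Compare SEDC predictions with generator ground truth
#'
#' A truth gene is recovered when some prediction on the same scaffold and
#' strand overlaps its coding span; the coding span is exact when the
#' intervals match precisely. Predictions overlapping no truth gene span of
#' any category are false positives.
#'
#' @param predictions list of `gene_prediction` objects.
#' @param truth generator truth (`$models`).
#' @param categories truth categories counted as recoverable positives.
#' @return list with `recall`, `precision`, `exactness`, `n_truth`,
#'   `n_pred`, `false_positives`.
#' @export
evaluate_sedc_predictions <- function(predictions, truth,
                                      categories = c("SEDC", "CBP")) {
  tm <- Filter(function(m) m$category %in% categories, truth$models)
  pred_cs <- lapply(predictions, function(p) p$model$coding_span[1, ])
  pred_key <- lapply(predictions, function(p)
    list(sc = p$model$scaffold_id, strand = p$model$strand))
  recovered <- 0L; exact <- 0L
  matched_pred <- logical(length(predictions))
  for (m in tm) {
    cs <- m$coding_span[1, ]
    idx <- which(vapply(seq_along(predictions), function(i)
      pred_key[[i]]$sc == m$scaffold_id && pred_key[[i]]$strand == m$strand &&
        .intervals_overlap(pred_cs[[i]], cs), logical(1)))
    if (length(idx)) {
      recovered <- recovered + 1L
      matched_pred[idx] <- TRUE
      if (any(vapply(idx, function(i)
        all(pred_cs[[i]] == cs), logical(1)))) exact <- exact + 1L
    }
  }
  # predictions overlapping any truth feature (incl. pseudogenes, markers)
  # are not false positives; only hits in empty sequence are
  all_spans <- lapply(truth$models, function(m)
    list(sc = m$scaffold_id,
         iv = c(min(m$exons[, 1]), max(m$exons[, 2]))))
  fp <- 0L
  for (i in seq_along(predictions)) {
    if (matched_pred[i]) next
    over <- any(vapply(all_spans, function(s)
      s$sc == pred_key[[i]]$sc && .intervals_overlap(s$iv, pred_cs[[i]]),
      logical(1)))
    if (!over) fp <- fp + 1L
  }
  n_pred <- length(predictions)
  list(recall = if (length(tm)) recovered / length(tm) else NA_real_,
       precision = if (n_pred) 1 - fp / n_pred else NA_real_,
       exactness = if (recovered) exact / recovered else NA_real_,
       n_truth = length(tm), n_pred = n_pred, false_positives = fp)
}
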