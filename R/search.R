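# Translated homology search: a protein query against all six reading
# frames of a DNA target, with no low-complexity masking. This is the
# pipeline's stand-in for a tBLASTn search: exact dynamic programming in
# every frame rather than heuristic seeding -- the EDC spans only hundreds
# of kilobases, so correctness is prioritized over speed.

#' Search a protein query against the six frames of a DNA target
#'
#' Each frame translation is aligned with [local_align()]; hits scoring at
#' least `min_score` are reported. Within each frame, overlapping suboptimal
#' hits are found by iterated masking of the best hit's target span (so
#' multi-copy families yield one hit per copy), up to `max_hits_per_frame`.
#' Target spans are reported in nucleotide coordinates on the forward
#' strand, 0-based half-open.
#'
#' @param query protein string or [protein_record()].
#' @param target DNA string or [scaffold_record()]; length at least 3.
#' @param scheme a [default_score_scheme()].
#' @param min_score minimum raw alignment score for a reported hit
#'   (default 40); there is no E-value model.
#' @param max_hits_per_frame cap on iterated-masking rounds per frame.
#' @return list of `alignment_hit` objects sorted by decreasing score
#'   (ties: plus strand first, then frame, then target start).
#' @export
translated_search <- function(query, target, scheme = default_score_scheme(),
                              min_score = 40L, max_hits_per_frame = 10L) {
  if (min_score < 1L) stop("min_score must be at least 1")
  qs <- .as_protein_string(query)
  ts <- if (inherits(target, "scaffold_record")) target$sequence else .check_dna(target)
  if (nchar(ts) < 3L) stop("target shorter than one codon")
  qid <- if (inherits(query, "protein_record")) query$id else NA_character_
  tid <- if (inherits(target, "scaffold_record")) target$id else NA_character_
  L <- nchar(ts)
  hits <- list()
  for (strand in c("+", "-")) {
    for (frame in 0:2) {
      if (L < frame + 3L) next
      prot <- translate(ts, frame, strand)
      for (round in seq_len(max_hits_per_frame)) {
        h <- local_align(qs, prot, scheme)
        if (h$score < min_score) break
        res_span <- h$target_span
        h$query_id <- qid; h$target_id <- tid
        h$frame <- frame; h$strand <- strand
        h$target_span <- .frame_to_nt(res_span, frame, strand, L)
        hits[[length(hits) + 1L]] <- h
        # mask matched residues so the next round finds the next copy
        masked <- strsplit(prot, "")[[1]]
        masked[seq.int(res_span[1] + 1L, res_span[2])] <- "*"
        prot <- paste0(masked, collapse = "")
      }
    }
  }
  if (length(hits) == 0L) return(list())
  ord <- order(-vapply(hits, `[[`, numeric(1), "score"),
               vapply(hits, `[[`, character(1), "strand"),
               vapply(hits, `[[`, integer(1), "frame"),
               vapply(hits, function(h) h$target_span[1], numeric(1)))
  hits[ord]
}

# residue span [r1, r2) in frame/strand translation -> forward-strand nt span
.frame_to_nt <- function(res_span, frame, strand, L) {
  r1 <- res_span[1]; r2 <- res_span[2]
  if (strand == "+") c(frame + 3 * r1, frame + 3 * r2)
  else c(L - frame - 3 * r2, L - frame - 3 * r1)
}

#' Tabulate alignment hits
#'
#' @param hits list of `alignment_hit` objects.
#' @return data.frame with one row per hit.
#' @export
hits_table <- function(hits) {
  if (length(hits) == 0L)
    return(data.frame(query_id = character(), target_id = character(),
                      score = integer(), identity = numeric(),
                      frame = integer(), strand = character(),
                      q_start = numeric(), q_end = numeric(),
                      t_start = numeric(), t_end = numeric()))
  data.frame(
    query_id = vapply(hits, `[[`, character(1), "query_id"),
    target_id = vapply(hits, `[[`, character(1), "target_id"),
    score = vapply(hits, `[[`, numeric(1), "score"),
    identity = vapply(hits, `[[`, numeric(1), "identity"),
    frame = vapply(hits, `[[`, integer(1), "frame"),
    strand = vapply(hits, `[[`, character(1), "strand"),
    q_start = vapply(hits, function(h) h$query_span[1], numeric(1)),
    q_end = vapply(hits, function(h) h$query_span[2], numeric(1)),
    t_start = vapply(hits, function(h) h$target_span[1], numeric(1)),
    t_end = vapply(hits, function(h) h$target_span[2], numeric(1)),
    stringsAsFactors = FALSE)
}
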