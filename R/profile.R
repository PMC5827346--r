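# Amino-acid composition profiling of EDC proteins: percentage vectors,
# enrichment classes under the strict >20% rule, and terminal
# lysine/glutamine (transglutamination-substrate) motif scanning.

#' Amino-acid composition of a protein
#'
#' Exact per-residue percentages of total residues. `X` (unknown) residues
#' are excluded from the denominator and reported in `$n_excluded`.
#'
#' @param protein protein string or [protein_record()].
#' @param id optional protein id for the profile.
#' @return object of class `composition_profile`: list with `protein_id`,
#'   `percent` (named numeric over all 20 residues, zeros included, summing
#'   to 100), `length` (residues counted) and `n_excluded`.
#' @export
composition <- function(protein, id = NULL) {
  seq <- .as_protein_string(protein)
  if (is.null(id) && inherits(protein, "protein_record")) id <- protein$id
  if (nchar(seq) < 1L) stop("empty protein sequence")
  chars <- strsplit(toupper(seq), "")[[1]]
  excluded <- sum(chars == "X")
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) stop("protein consists only of X residues")
  bad <- setdiff(chars, .AA20)
  if (length(bad)) stop("invalid residues: ", paste(unique(bad), collapse = ", "))
  counts <- table(factor(chars, levels = .AA20))
  structure(list(protein_id = if (is.null(id)) NA_character_ else id,
                 percent = 100 * as.numeric(counts) / length(chars),
                 length = length(chars), n_excluded = excluded),
            class = "composition_profile") -> out
  names(out$percent) <- .AA20
  out
}

#' Count occurrences of one residue
#'
#' @param protein protein string or [protein_record()].
#' @param residue single amino-acid letter.
#' @return integer count.
#' @export
count_residue <- function(protein, residue) {
  stopifnot(residue %in% c(.AA20, "X"))
  seq <- .as_protein_string(protein)
  sum(strsplit(toupper(seq), "")[[1]] == residue)
}

#' Residues enriched above a percentage threshold
#'
#' Returns the residues whose composition percentage strictly exceeds the
#' threshold (the EDC convention is "exceeds 20%", so exactly 20% does not
#' qualify). By default only the EDC-characteristic residues G, S, P, K, C
#' and Q are considered.
#'
#' @param profile a [composition()] profile.
#' @param threshold percentage in (0, 100); default 20.
#' @param residues residues eligible for enrichment calls.
#' @param all consider all 20 residues instead.
#' @return character vector of enriched residues (possibly empty).
#' @export
enrichment_classes <- function(profile, threshold = 20,
                               residues = c("G", "S", "P", "K", "C", "Q"),
                               all = FALSE) {
  stopifnot(inherits(profile, "composition_profile"),
            threshold > 0, threshold < 100)
  if (all) residues <- .AA20
  p <- profile$percent[residues]
  names(p)[p > threshold]
}

#' Terminal lysine/glutamine motifs
#'
#' Within a window at each terminus, reports the subspan (length >=
#' `min_len`) with the highest K+Q density, provided that density reaches
#' `min_kq`. These spans are candidate transglutamination cross-linking
#' sites. Ties are resolved toward the longer, then the more terminal span.
#'
#' @param protein protein string or [protein_record()].
#' @param terminal_window window length at each terminus (default 20).
#' @param min_len minimum motif length (default 5).
#' @param min_kq minimum K+Q fraction within the motif (default 0.4).
#' @return list of motifs, each a list with `terminus` ("N" or "C"), `span`
#'   (0-based half-open, protein coordinates) and `kq_fraction`; empty list
#'   when no span qualifies.
#' @export
terminal_kq_motifs <- function(protein, terminal_window = 20L, min_len = 5L,
                               min_kq = 0.4) {
  seq <- .as_protein_string(protein)
  n <- nchar(seq)
  if (n < terminal_window)
    stop("protein shorter than the terminal window")
  chars <- strsplit(seq, "")[[1]]
  is_kq <- chars %in% c("K", "Q")
  best_in <- function(idx, from_end = FALSE) {
    best <- NULL
    w <- length(idx)
    for (len in seq.int(min_len, w)) {
      for (s in seq_len(w - len + 1L)) {
        span_idx <- idx[s:(s + len - 1L)]
        frac <- mean(is_kq[span_idx])
        if (frac < min_kq) next
        dist <- if (from_end) n - span_idx[len] else span_idx[1] - 1L
        cand <- list(span = c(span_idx[1] - 1L, span_idx[len]),
                     kq_fraction = frac, len = len, dist = dist)
        if (is.null(best) ||
            frac > best$kq_fraction ||
            (frac == best$kq_fraction && len > best$len) ||
            (frac == best$kq_fraction && len == best$len && dist < best$dist))
          best <- cand
      }
    }
    best
  }
  out <- list()
  b <- best_in(seq_len(terminal_window))
  if (!is.null(b))
    out[[length(out) + 1L]] <- list(terminus = "N", span = b$span,
                                    kq_fraction = b$kq_fraction)
  b <- best_in(seq.int(n - terminal_window + 1L, n), from_end = TRUE)
  if (!is.null(b))
    out[[length(out) + 1L]] <- list(terminus = "C", span = b$span,
                                    kq_fraction = b$kq_fraction)
  out
}

#' Composition matrix for a set of proteins
#'
#' @param proteins named character vector or list of [protein_record()]s.
#' @return data.frame: one row per protein, one column per residue
#'   (percentages), plus `length`.
#' @export
composition_matrix <- function(proteins) {
  if (is.list(proteins)) {
    ids <- vapply(proteins, `[[`, character(1), "id")
    seqs <- vapply(proteins, `[[`, character(1), "sequence")
  } else {
    ids <- names(proteins); seqs <- proteins
  }
  rows <- lapply(seq_along(seqs), function(i) {
    p <- composition(seqs[i], id = ids[i])
    cbind(data.frame(protein_id = ids[i]),
          as.data.frame(as.list(p$percent)),
          data.frame(length = p$length))
  })
  do.call(rbind, rows)
}
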