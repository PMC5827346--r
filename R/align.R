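# Protein alignment scoring. The default scheme is the standard BLOSUM62
# table with affine gaps (open 11, extend 1) -- the defaults behind routine
# translated searches -- with two local conventions: X scores 0 against
# everything (neutral placeholder for gap-translated codons), and the stop
# symbol * scores strongly negative so alignments never cross a stop.

.ALN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V","X","*")

#' Default protein scoring scheme
#'
#' BLOSUM62 with gap open 11 and gap extend 1 (a length-k gap costs
#' `open + k * extend`). X scores 0 against every residue; the translated
#' stop symbol `*` scores -16 against everything so local alignments stay
#' within open reading frames.
#'
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend per-residue gap extension penalty (positive).
#' @return object of class `score_scheme`: a list with the integer score
#'   `matrix` (rows/cols over the 20 residues, X and `*`) and the two gap
#'   penalties.
#' @export
default_score_scheme <- function(gap_open = 11L, gap_extend = 1L) {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  aa <- .ALN_ALPHABET
  m <- matrix(0L, length(aa), length(aa), dimnames = list(aa, aa))
  core <- setdiff(aa, c("X", "*"))
  m[core, core] <- b62[core, core]
  m["X", ] <- 0L; m[, "X"] <- 0L
  m["*", ] <- -16L; m[, "*"] <- -16L
  structure(list(matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "score_scheme")
}

.encode_protein <- function(x, what = "sequence") {
  ch <- strsplit(toupper(x), "")[[1]]
  idx <- match(ch, .ALN_ALPHABET) - 1L
  if (anyNA(idx))
    stop(what, " contains unknown residues: ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx
}

.as_protein_string <- function(x) {
  if (inherits(x, "protein_record")) x$sequence else x
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps (Gotoh). Ties are broken by earliest
#' target start, then earliest query start, then shortest alignment.
#'
#' @param query,target protein strings or [protein_record()] objects.
#' @param scheme a [default_score_scheme()].
#' @return an `alignment_hit`: list with `score`, 0-based half-open
#'   `query_span` and `target_span` (residue coordinates), `identity`
#'   (matches over aligned columns), `ops` (column string over D/I/J),
#'   and `frame`/`strand` set to `NA` (filled by [translated_search()]).
#' @export
local_align <- function(query, target, scheme = default_score_scheme()) {
  q <- .as_protein_string(query); t <- .as_protein_string(target)
  if (nchar(q) == 0L || nchar(t) == 0L) stop("empty sequence")
  r <- cpp_local_align(.encode_protein(q, "query"),
                       .encode_protein(t, "target"),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend)
  structure(list(
    query_id = if (inherits(query, "protein_record")) query$id else NA_character_,
    target_id = if (inherits(target, "protein_record")) target$id else NA_character_,
    score = r$score,
    query_span = c(r$q_start, r$q_end),
    target_span = c(r$t_start, r$t_end),
    identity = if (r$columns > 0L) r$matches / r$columns else 0,
    ops = r$ops, frame = NA_integer_, strand = NA_character_),
    class = "alignment_hit")
}

#' Optimal global alignment of two proteins
#'
#' Needleman-Wunsch with affine gaps; end gaps are penalized. Tie-breaking
#' is deterministic (diagonal preferred on traceback ties).
#'
#' @param a,b protein strings or [protein_record()] objects.
#' @param scheme a [default_score_scheme()].
#' @return list with `score`, `identity` (matches over aligned columns),
#'   gapped `aligned_a`/`aligned_b` strings and the column `ops` string.
#' @export
global_align <- function(a, b, scheme = default_score_scheme()) {
  sa <- .as_protein_string(a); sb <- .as_protein_string(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty sequence")
  r <- cpp_global_align(.encode_protein(sa, "a"), .encode_protein(sb, "b"),
                        scheme$matrix, scheme$gap_open, scheme$gap_extend)
  ops <- strsplit(r$ops, "")[[1]]
  ai <- bi <- 0L
  ca <- cb <- character(length(ops))
  chars_a <- strsplit(sa, "")[[1]]; chars_b <- strsplit(sb, "")[[1]]
  for (k in seq_along(ops)) {
    if (ops[k] == "D") { ai <- ai + 1L; bi <- bi + 1L
      ca[k] <- chars_a[ai]; cb[k] <- chars_b[bi] }
    else if (ops[k] == "I") { ai <- ai + 1L; ca[k] <- chars_a[ai]; cb[k] <- "-" }
    else { bi <- bi + 1L; ca[k] <- "-"; cb[k] <- chars_b[bi] }
  }
  list(score = r$score,
       identity = if (r$columns > 0L) r$matches / r$columns else 0,
       aligned_a = paste0(ca, collapse = ""),
       aligned_b = paste0(cb, collapse = ""),
       ops = r$ops)
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf(
    "<alignment_hit> %s vs %s score=%d id=%.3f q[%d,%d) t[%d,%d) frame=%s strand=%s\n",
    x$query_id, x$target_id, x$score, x$identity,
    x$query_span[1], x$query_span[2], x$target_span[1], x$target_span[2],
    x$frame, x$strand))
  invisible(x)
}
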