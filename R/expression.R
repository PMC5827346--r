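# Semiquantitative tissue-expression profiling by exact-match read
# counting: a read counts for a query protein when one of its six frame
# translations shares a 100%-identical substring of at least `min_match`
# residues with the query -- the translated-search analogue of counting
# reads with perfect hits to a protein query. Counts are normalized against
# a ubiquitously expressed housekeeping control (ALAS1 stand-in) rather
# than library size.

#' Default minimum match length for exact read counting
#'
#' The full translatable length guaranteed in every reading frame of an
#' L-nt read, `floor((L - 2) / 3)` residues, i.e. effectively full-read
#' identity at the protein level.
#'
#' @param read_length read length in nt.
#' @return integer residue count.
#' @export
default_min_match <- function(read_length) as.integer((read_length - 2) %/% 3)

#' Count reads matching a protein query at 100% identity
#'
#' @param query_protein protein string or [protein_record()].
#' @param reads list of [read_record()] objects (tissue-labelled).
#' @param min_match minimum run of identical residues; defaults to the
#'   full translatable read length.
#' @return named integer vector of counts per tissue (all tissues present
#'   in `reads`; zeros explicit).
#' @export
count_exact_matches <- function(query_protein, reads, min_match = NULL) {
  q <- .as_protein_string(query_protein)
  if (nchar(q) == 0L) stop("empty query")
  tissues <- unique(vapply(reads, `[[`, character(1), "tissue"))
  counts <- stats::setNames(integer(length(tissues)), tissues)
  if (length(reads) == 0L) return(counts)
  if (is.null(min_match))
    min_match <- default_min_match(nchar(reads[[1]]$sequence))
  frags <- .read_fragments(reads, min_match)
  for (i in seq_along(reads)) {
    if (.fragments_match(q, frags[[i]], min_match))
      counts[reads[[i]]$tissue] <- counts[reads[[i]]$tissue] + 1L
  }
  counts
}

# per read: the stop/X-free stretches (>= min_match residues) of all six
# frame translations; only these can carry a 100%-identical protein match
.read_fragments <- function(reads, min_match) {
  lapply(reads, function(r) {
    out <- character(0)
    if (nchar(r$sequence) < 3L) return(out)
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        if (nchar(r$sequence) < frame + 3L) next
        p <- translate(r$sequence, frame, strand)
        parts <- strsplit(p, "[*X]")[[1]]
        out <- c(out, parts[nchar(parts) >= min_match])
      }
    }
    out
  })
}

.fragments_match <- function(query, fragments, min_match) {
  for (part in fragments)
    if (.has_common_substring(part, query, min_match)) return(TRUE)
  FALSE
}

.has_common_substring <- function(p, query, min_match) {
  for (s in seq_len(nchar(p) - min_match + 1L))
    if (grepl(substr(p, s, s + min_match - 1L), query, fixed = TRUE))
      return(TRUE)
  FALSE
}

#' Expression table over genes and tissues
#'
#' @param queries named character vector (or list of [protein_record()]s)
#'   of query proteins, one per gene.
#' @param reads list of [read_record()] objects.
#' @param control_gene name of the housekeeping control among the queries.
#' @param min_match see [count_exact_matches()].
#' @return object of class `expression_table`: data.frame with columns
#'   `gene_id`, `tissue`, `read_count` (every pair present, zeros
#'   explicit), with the control gene and per-tissue totals as attributes.
#' @export
expression_table <- function(queries, reads, control_gene,
                             min_match = NULL) {
  if (is.list(queries)) {
    nm <- vapply(queries, `[[`, character(1), "id")
    queries <- stats::setNames(vapply(queries, `[[`, character(1),
                                      "sequence"), nm)
  }
  if (!control_gene %in% names(queries))
    stop("control gene ", control_gene, " not among the queries")
  if (is.null(min_match) && length(reads))
    min_match <- default_min_match(nchar(reads[[1]]$sequence))
  frags <- .read_fragments(reads, min_match)
  tissues <- unique(vapply(reads, `[[`, character(1), "tissue"))
  rows <- lapply(names(queries), function(g) {
    cts <- stats::setNames(integer(length(tissues)), tissues)
    for (i in seq_along(reads))
      if (.fragments_match(queries[[g]], frags[[i]], min_match))
        cts[reads[[i]]$tissue] <- cts[reads[[i]]$tissue] + 1L
    data.frame(gene_id = g, tissue = names(cts), read_count = as.integer(cts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, control_gene = control_gene,
            tissue_totals = tapply(out$read_count, out$tissue, sum),
            class = c("expression_table", "data.frame"))
}

#' Classify genes by tissue specificity
#'
#' Counts are normalized by the control gene's count in each tissue. A
#' gene is `tissue-specific:<tissue>` when at least `spec_fraction` of its
#' normalized signal falls in one tissue, `undetected` when its total raw
#' count is below `min_total`, and `broad` otherwise.
#'
#' @param table an [expression_table()].
#' @param spec_fraction specificity threshold on the normalized signal
#'   (default 0.9).
#' @param min_total minimum raw count for detection (default 5).
#' @return named character vector of labels, one per gene.
#' @export
tissue_specificity <- function(table, spec_fraction = 0.9, min_total = 5L) {
  control <- attr(table, "control_gene")
  ctrl <- table[table$gene_id == control, ]
  if (any(ctrl$read_count == 0L))
    stop("control gene ", control, " has zero counts in ",
         paste(ctrl$tissue[ctrl$read_count == 0L], collapse = ", "),
         "; normalization undefined")
  norm <- stats::setNames(ctrl$read_count, ctrl$tissue)
  genes <- unique(table$gene_id)
  out <- stats::setNames(character(length(genes)), genes)
  for (g in genes) {
    sub <- table[table$gene_id == g, ]
    if (sum(sub$read_count) < min_total) { out[g] <- "undetected"; next }
    x <- sub$read_count / norm[sub$tissue]
    frac <- x / sum(x)
    if (max(frac) >= spec_fraction)
      out[g] <- paste0("tissue-specific:", sub$tissue[which.max(frac)])
    else out[g] <- "broad"
  }
  out
}
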