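# Core record types. All are light S3 lists: a ScaffoldRecord holds one
# genome scaffold, a ProteinRecord one protein, a ReadRecord one RNA-seq
# read, and a gene model an annotated EDC gene. Intervals are 0-based
# half-open on the forward strand of the scaffold; exon rows are stored in
# ascending genomic order regardless of strand.

#' Scaffold record
#'
#' @param id scaffold identifier, unique within an assembly.
#' @param sequence non-empty DNA string over A, C, G, T, N; lowercase
#'   (soft-masked) input is uppercased on ingest.
#' @param species species label.
#' @return object of class `scaffold_record`.
#' @export
scaffold_record <- function(id, sequence, species = "unknown") {
  sequence <- .check_dna(sequence)
  if (nchar(sequence) == 0L) stop("scaffold sequence must be non-empty")
  structure(list(id = as.character(id), sequence = sequence,
                 species = as.character(species)),
            class = "scaffold_record")
}

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Protein record
#'
#' @param id protein identifier.
#' @param sequence protein string over the 20 amino-acid letters plus X; no
#'   internal stop symbol; length at least 1.
#' @param source_gene optional id of the gene model the protein derives from.
#' @param species species label.
#' @return object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, source_gene = NA_character_,
                           species = "unknown") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("protein sequence must be non-empty")
  if (grepl("\\*", sequence)) stop("protein sequence contains a stop symbol")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(.AA20, "X"))
  if (length(bad))
    stop("invalid amino-acid letters: ", paste(unique(bad), collapse = ", "))
  structure(list(id = as.character(id), sequence = sequence,
                 source_gene = source_gene, species = as.character(species)),
            class = "protein_record")
}

#' RNA-seq read record
#'
#' @param id read identifier.
#' @param sequence DNA string over A, C, G, T, N.
#' @param tissue tissue label the read was sequenced from.
#' @return object of class `read_record`.
#' @export
read_record <- function(id, sequence, tissue) {
  sequence <- .check_dna(sequence)
  structure(list(id = as.character(id), sequence = sequence,
                 tissue = as.character(tissue)),
            class = "read_record")
}

.GENE_CATEGORIES <- c("SEDC", "SFTP", "CBP", "pseudogene", "marker")

#' EDC gene model
#'
#' An annotated gene: exon coordinates, coding span(s), category and
#' completeness. SEDC models carry their whole coding region on one exon;
#' SFTP models carry coding sequence on exactly two exons.
#'
#' @param id gene identifier.
#' @param scaffold_id scaffold the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open, forward-strand coordinates), one row per exon, rows in
#'   ascending genomic order.
#' @param coding_span like `exons`: one row for SEDC/CBP/marker models, two
#'   for SFTP models. Must be contained in exons. Includes the stop codon.
#' @param category one of SEDC, SFTP, CBP, pseudogene, marker.
#' @param name nomenclature string (e.g. `EDCH5`).
#' @param completeness `"complete"` or `"partial"`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(id, scaffold_id, strand, exons, coding_span,
                       category, name = id, completeness = "complete") {
  exons <- .as_interval_matrix(exons)
  coding_span <- .as_interval_matrix(coding_span)
  structure(list(id = as.character(id), scaffold_id = as.character(scaffold_id),
                 strand = strand, exons = exons, coding_span = coding_span,
                 category = category, name = as.character(name),
                 completeness = completeness),
            class = "gene_model")
}

.as_interval_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 2L, byrow = TRUE)
  x <- matrix(as.numeric(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  x
}

#' Validate a gene model
#'
#' Checks the structural invariants: valid category and strand, exons
#' non-overlapping and sorted, coding span contained in exons, the
#' category-specific coding-exon counts (one for SEDC, two for SFTP), and --
#' when the scaffold is supplied -- that a complete non-pseudogene model
#' translates to a protein starting with M without internal stops. Models
#' whose coding span overlaps an assembly-gap run of Ns are flagged rather
#' than silently accepted.
#'
#' @param model a [gene_model()].
#' @param scaffold optional [scaffold_record()] carrying the model.
#' @return invisibly `TRUE`; throws an error describing the first violated
#'   invariant. A warning is raised for coding spans overlapping N runs.
#' @export
validate_gene_model <- function(model, scaffold = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$strand %in% c("+", "-"))
    stop(model$id, ": strand must be '+' or '-'")
  if (!model$category %in% .GENE_CATEGORIES)
    stop(model$id, ": unknown category ", model$category)
  if (!model$completeness %in% c("complete", "partial"))
    stop(model$id, ": unknown completeness ", model$completeness)
  ex <- model$exons
  if (nrow(ex) < 1L) stop(model$id, ": no exons")
  if (any(ex[, 2] <= ex[, 1])) stop(model$id, ": empty or reversed exon")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, 1], strictly = TRUE))
      stop(model$id, ": exons not sorted")
    if (any(ex[-1L, 1] < ex[-nrow(ex), 2]))
      stop(model$id, ": overlapping exons")
  }
  cs <- model$coding_span
  if (nrow(cs) < 1L) stop(model$id, ": no coding span")
  contained <- vapply(seq_len(nrow(cs)), function(i) {
    any(cs[i, 1] >= ex[, 1] & cs[i, 2] <= ex[, 2])
  }, logical(1))
  if (!all(contained))
    stop(model$id, ": coding span not contained in exons")
  if (model$category %in% c("SEDC", "CBP") && nrow(cs) != 1L)
    stop(model$id, ": ", model$category,
         " models must have exactly one coding exon")
  if (model$category == "SFTP" && nrow(cs) != 2L)
    stop(model$id, ": SFTP models must have coding sequence on exactly two exons")
  if (!is.null(scaffold)) {
    stopifnot(inherits(scaffold, "scaffold_record"))
    if (max(ex[, 2]) > nchar(scaffold$sequence))
      stop(model$id, ": exons exceed scaffold length")
    cds <- gene_cds(model, scaffold)
    if (grepl("N{5,}", cds))
      warning(model$id, ": coding span overlaps an assembly-gap N run")
    if (model$category != "pseudogene" && model$completeness == "complete") {
      prot <- translate(cds)
      body <- sub("\\*$", "", prot)
      if (!startsWith(body, "M"))
        stop(model$id, ": complete model does not begin with M")
      if (grepl("\\*", body))
        stop(model$id, ": complete model contains an internal stop")
    }
  }
  invisible(TRUE)
}

.extract <- function(sequence, iv) substr(sequence, iv[1] + 1L, iv[2])

#' Coding sequence of a gene model
#'
#' Concatenated coding intervals in transcript orientation (reverse
#' complemented for minus-strand models).
#'
#' @param model a [gene_model()].
#' @param scaffold the [scaffold_record()] carrying the model.
#' @return DNA string.
#' @export
gene_cds <- function(model, scaffold) {
  .splice(model$coding_span, model$strand, scaffold$sequence)
}

#' Spliced transcript of a gene model
#'
#' Concatenated exons in transcript orientation.
#'
#' @inheritParams gene_cds
#' @return DNA string.
#' @export
gene_transcript <- function(model, scaffold) {
  .splice(model$exons, model$strand, scaffold$sequence)
}

.splice <- function(iv, strand, sequence) {
  parts <- vapply(seq_len(nrow(iv)), function(i) .extract(sequence, iv[i, ]),
                  character(1))
  out <- paste0(parts, collapse = "")
  if (strand == "-") out <- reverse_complement(out)
  out
}

#' Conceptual translation of a gene model
#'
#' Translation of the coding sequence with the trailing stop removed.
#'
#' @inheritParams gene_cds
#' @return protein string (may contain `*` for pseudogene models).
#' @export
gene_protein <- function(model, scaffold) {
  sub("\\*$", "", translate(gene_cds(model, scaffold)))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s) %s:%s %d exon(s), CDS %s\n",
              x$id, x$category, x$completeness, x$scaffold_id, x$strand,
              nrow(x$exons),
              paste(sprintf("[%d,%d)", x$coding_span[, 1], x$coding_span[, 2]),
                    collapse = "+")))
  invisible(x)
}

#' @export
print.scaffold_record <- function(x, ...) {
  cat(sprintf("<scaffold_record> %s (%s), %d nt\n", x$id, x$species,
              nchar(x$sequence)))
  invisible(x)
}
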