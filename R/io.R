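# Readers and writers for FASTA, FASTQ and GFF3, thin wrappers around
# Biostrings and rtracklayer. Internal coordinates are 0-based half-open;
# emitted GFF3 is 1-based inclusive per the standard.

.scan_fasta_lines <- function(path) {
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA record at line ", first, " of ", path,
         ": expected '>'")
  invisible(lines)
}

#' Read a FASTA file
#'
#' @param path file path.
#' @param type `"dna"` for scaffolds or `"protein"`.
#' @param species species label attached to every record.
#' @return list of [scaffold_record()] or [protein_record()] objects.
#' @export
read_fasta <- function(path, type = c("dna", "protein"), species = "unknown") {
  type <- match.arg(type)
  .scan_fasta_lines(path)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  if (type == "dna")
    lapply(seq_along(ids), function(i)
      scaffold_record(ids[i], seqs[i], species))
  else
    lapply(seq_along(ids), function(i)
      protein_record(ids[i], seqs[i], species = species))
}

#' Write records to a FASTA file
#'
#' @param records list of [scaffold_record()] or [protein_record()] objects,
#'   or a named character vector of sequences.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- vapply(records, function(r) r$sequence, character(1))
    names(seqs) <- vapply(records, function(r) r$id, character(1))
  }
  if (anyDuplicated(names(seqs))) stop("duplicate record ids")
  is_dna <- !any(grepl("[^ACGTN]", seqs))
  set <- if (is_dna) Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file into read records
#'
#' @param path file path.
#' @param tissue tissue label attached to every read.
#' @return list of [read_record()] objects.
#' @export
read_fastq <- function(path, tissue = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): line count not a multiple of 4, near line ",
         (length(lines) %/% 4L) * 4L + 1L)
  bad <- which(!startsWith(lines[seq(1, length(lines), by = 4L)], "@"))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1] - 1L) * 4L + 1L,
         " of ", path, ": expected '@'")
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate read ids in ", path)
  seqs <- as.character(set)
  lapply(seq_along(ids), function(i) read_record(ids[i], seqs[i], tissue))
}

#' Write read records to a FASTQ file
#'
#' Qualities are constant (`I`), as the reads carry none.
#'
#' @param reads list of [read_record()] objects.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- vapply(reads, function(r) r$sequence, character(1))
  ids <- vapply(reads, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate read ids")
  set <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  invisible(path)
}

# gene models <-> GFF3 -------------------------------------------------------

.models_to_granges <- function(models) {
  rows <- list()
  for (m in models) {
    gid <- m$id
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = m$scaffold_id, start = span[1] + 1L, end = span[2],
      strand = m$strand, type = "gene", ID = gid, Parent = NA_character_,
      Name = m$name, category = m$category, completeness = m$completeness,
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(m$exons)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$scaffold_id, start = m$exons[i, 1] + 1L,
        end = m$exons[i, 2], strand = m$strand, type = "exon",
        ID = sprintf("%s.exon%d", gid, i), Parent = gid, Name = NA_character_,
        category = NA_character_, completeness = NA_character_,
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(m$coding_span)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$scaffold_id, start = m$coding_span[i, 1] + 1L,
        end = m$coding_span[i, 2], strand = m$strand, type = "CDS",
        ID = sprintf("%s.cds%d", gid, i), Parent = gid, Name = NA_character_,
        category = NA_character_, completeness = NA_character_,
        stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, phase = ifelse(df$type == "CDS", 0L, NA_integer_),
    ID = df$ID, Parent = df$Parent, Name = df$Name,
    category = df$category, completeness = df$completeness)
  gr
}

#' Write gene models to a GFF3 file
#'
#' Each model is emitted as a `gene` feature with `exon` and `CDS` children;
#' coordinates are converted from the internal 0-based half-open convention
#' to the 1-based inclusive GFF3 standard.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_gff3 <- function(models, path) {
  ids <- vapply(models, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene model ids")
  gr <- .models_to_granges(models)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Inverse of [write_gff3()]: reassembles `gene`/`exon`/`CDS` features into
#' [gene_model()] objects with 0-based half-open coordinates.
#'
#' @param path file path.
#' @return list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GFF3 at line ", i, " of ", path, ": expected 9 columns")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("malformed GFF3 at line ", i, " of ", path,
           ": end < start or non-numeric coordinates")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  starts <- GenomicRanges::start(gr) - 1L # back to 0-based half-open
  ends <- GenomicRanges::end(gr)
  genes <- which(type == "gene")
  if (anyDuplicated(id[genes])) stop("duplicate gene ids in ", path)
  lapply(genes, function(g) {
    gid <- id[g]
    kids <- which(parent == gid)
    ex <- kids[type[kids] == "exon"]
    cds <- kids[type[kids] == "CDS"]
    if (length(ex) == 0L) ex <- g # bare gene: exon = gene span
    ord <- order(starts[ex])
    exm <- cbind(start = starts[ex][ord], end = ends[ex][ord])
    ordc <- order(starts[cds])
    csm <- cbind(start = starts[cds][ordc], end = ends[cds][ordc])
    gene_model(id = gid, scaffold_id = as.character(GenomicRanges::seqnames(gr)[g]),
               strand = as.character(GenomicRanges::strand(gr)[g]),
               exons = exm, coding_span = csm,
               category = as.character(md$category[g]),
               name = as.character(md$Name[g]),
               completeness = as.character(md$completeness[g]))
  })
}
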