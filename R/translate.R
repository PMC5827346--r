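# Genetic-code translation over the standard nuclear code. Internally all
# coordinates are 0-based half-open; translation operates on plain character
# strings so the hot paths stay allocation-light.

.GENCODE <- local({
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
})

.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param dna character scalar over A, C, G, T, N (lowercase accepted and
#'   uppercased).
#' @return character scalar.
#' @export
reverse_complement <- function(dna) {
  dna <- .check_dna(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

.check_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (nchar(dna) > 0L && grepl("[^ACGTN]", dna))
    stop("sequence contains characters other than A, C, G, T, N")
  dna
}

#' Translate DNA in a given frame and strand
#'
#' Standard genetic code, codon by codon until fewer than three nucleotides
#' remain. Stop codons are rendered as `*`; codons containing `N` translate
#' to `X`. On the minus strand the reverse complement is translated.
#'
#' @param dna DNA string over A, C, G, T, N.
#' @param frame 0, 1 or 2: number of nucleotides skipped at the 5' end.
#' @param strand `"+"` or `"-"`.
#' @return protein string, possibly containing `*` and `X`.
#' @examples
#' translate("ATGAAA")       # "MK"
#' translate("TTTCAT", strand = "-")  # "MK"
#' @export
translate <- function(dna, frame = 0L, strand = "+") {
  dna <- .check_dna(dna)
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (nchar(dna) < frame + 3L)
    stop("sequence too short to translate in frame ", frame)
  if (strand == "-")
    dna <- reverse_complement(dna)
  dna <- substring(dna, frame + 1L)
  n_codons <- nchar(dna) %/% 3L
  if (n_codons == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(dna, starts, starts + 2L)
  aa <- .GENCODE[codons]
  aa[is.na(aa)] <- "X" # codons containing N
  paste0(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates all three frames of both strands. Frame `f` on either strand
#' yields `floor((L - f) / 3)` residues.
#'
#' @param dna DNA string, length at least 3.
#' @return data.frame with columns `frame` (0:2), `strand` (+/-) and
#'   `protein`.
#' @export
six_frame_translate <- function(dna) {
  dna <- .check_dna(dna)
  if (nchar(dna) < 3L)
    stop("sequence shorter than one codon")
  grid <- expand.grid(frame = 0:2, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  grid$protein <- mapply(function(f, s) translate(dna, f, s),
                         grid$frame, grid$strand)
  grid
}
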