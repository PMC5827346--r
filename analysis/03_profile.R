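#!/usr/bin/env Rscript
# Stage 3: amino-acid composition of the predicted EDC proteins, residues
# enriched above the strict 20% rule, and terminal lysine/glutamine
# (transglutamination) motifs.

library(edclocus)

prot <- read_fasta("results/annotation/predicted_proteins.fasta",
                   type = "protein")
outdir <- "results/profile"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cm <- composition_matrix(prot)
write.table(cm, file.path(outdir, "composition.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

enr <- lapply(prot, function(p) enrichment_classes(composition(p)))
enr_df <- data.frame(
  protein = vapply(prot, `[[`, "", "id"),
  enriched = vapply(enr, paste, "", collapse = ","))
write.table(enr_df, file.path(outdir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

motif_rows <- list()
for (p in prot) {
  if (nchar(p$sequence) < 20) next
  for (m in terminal_kq_motifs(p)) {
    motif_rows[[length(motif_rows) + 1L]] <- data.frame(
      protein = p$id, terminus = m$terminus,
      start = m$span[1], end = m$span[2],
      kq_fraction = m$kq_fraction)
  }
}
motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
  data.frame(protein = character(), terminus = character(),
             start = integer(), end = integer(), kq_fraction = numeric())
write.table(motifs, file.path(outdir, "terminal_motifs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_enriched <- sum(nzchar(enr_df$enriched))
message(n_enriched, " of ", nrow(enr_df),
        " predicted proteins exceed 20% in at least one of G,S,P,K,C,Q")
message(nrow(motifs), " terminal K/Q motifs found across ",
        length(unique(motifs$protein)), " proteins")
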