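#!/usr/bin/env Rscript
# Stage 5: semiquantitative tissue expression -- count reads matching each
# predicted protein at 100% identity per tissue, normalize by the ALAS1
# housekeeping control, and classify tissue specificity.

library(edclocus)

prot <- read_fasta("results/annotation/predicted_proteins.fasta",
                   type = "protein")
truth_prot <- read_fasta("results/data/truth_proteins_A.fasta",
                         type = "protein")
names(truth_prot) <- vapply(truth_prot, `[[`, "", "id")
reads <- do.call(c, lapply(c("skin", "heart", "liver"), function(t)
  read_fastq(sprintf("results/data/reads_%s.fastq", t), tissue = t)))
outdir <- "results/expression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

queries <- stats::setNames(vapply(prot, `[[`, "", "sequence"),
                           vapply(prot, `[[`, "", "id"))
queries[["ALAS1"]] <- truth_prot[["ALAS1"]]$sequence

et <- expression_table(queries, reads, control_gene = "ALAS1")
write.table(as.data.frame(et), file.path(outdir, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
lab <- tissue_specificity(et)
write.table(data.frame(gene = names(lab), label = unname(lab)),
            file.path(outdir, "specificity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("specificity labels: ",
        paste(names(table(lab)), table(lab), sep = "=", collapse = ", "))
off <- et[et$gene_id != "ALAS1" & et$tissue != "skin", ]
message("off-skin read count over all predicted EDC genes: ",
        sum(off$read_count), " (control ALAS1 is '",
        unname(lab["ALAS1"]), "')")
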