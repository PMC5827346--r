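#!/usr/bin/env Rscript
# Stage 2: annotate species A from files alone -- delimit the EDC between
# the S100A markers, predict SEDC genes de novo and SFTP genes by homology,
# triage gene status, and validate with the tissue reads. Scores the
# predictions against the simulated truth.

library(edclocus)

ddir <- "results/data"
outdir <- "results/annotation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

assembly <- read_fasta(file.path(ddir, "assembly_A.fasta"))
truth_models <- read_gff3(file.path(ddir, "truth_A.gff3"))
names(truth_models) <- vapply(truth_models, `[[`, "", "id")
truth_prot <- read_fasta(file.path(ddir, "truth_proteins_A.fasta"),
                         type = "protein")
names(truth_prot) <- vapply(truth_prot, `[[`, "", "id")
reads <- do.call(c, lapply(c("skin", "heart", "liver"), function(t)
  read_fastq(file.path(ddir, sprintf("reads_%s.fastq", t)), tissue = t)))

markers <- truth_prot[c("S100A12", "S100A11")]
region <- find_flanked_region(assembly, markers)
message("EDC delimited: ", region$segments[[1]]$scaffold_id, ":",
        region$segments[[1]]$interval[1], "-",
        region$segments[[1]]$interval[2])

preds <- predict_sedc_genes(region, assembly)
sftp <- predict_sftp_genes(region, assembly,
                           truth_prot[c("CRNN", "SCFN")])
preds <- c(preds, sftp)
status <- vapply(preds, classify_gene_status, "", assembly = assembly)
preds <- lapply(preds, validate_with_reads, assembly = assembly,
                reads = reads)

write_gff3(lapply(preds, `[[`, "model"),
           file.path(outdir, "predicted.gff3"))
ev <- data.frame(
  gene = vapply(preds, function(p) p$model$id, ""),
  category = vapply(preds, function(p) p$model$category, ""),
  status = status,
  confidence = vapply(preds, function(p) p$evidence$confidence, ""),
  read_support = vapply(preds, function(p)
    p$evidence$read_support, integer(1)),
  intron_spanning = vapply(preds, function(p)
    p$evidence$intron_spanning_reads, integer(1)))
write.table(ev, file.path(outdir, "evidence.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prot <- character(0)
for (p in preds) {
  if (p$model$category == "pseudogene") next
  sc <- Filter(function(s) s$id == p$model$scaffold_id, assembly)[[1]]
  tp <- gene_protein(p$model, sc)
  if (!grepl("\\*", tp)) prot[p$model$id] <- tp
}
write_fasta(prot, file.path(outdir, "predicted_proteins.fasta"))

truth <- list(models = truth_models)
sc_eval <- evaluate_sedc_predictions(
  Filter(function(p) p$model$category == "SEDC", preds), truth)
message(sprintf(
  "single-exon gene recovery: recall %.3f, precision %.3f, exact spans %.3f (n = %d truth genes)",
  sc_eval$recall, sc_eval$precision, sc_eval$exactness, sc_eval$n_truth))
message(sum(ev$intron_spanning > 0), " genes confirmed by intron-spanning reads")
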