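# End-to-end orchestration of the synthetic-data analysis:
# simulate -> annotate -> profile -> repeats -> express -> compare,
# driven by a single configuration, with a content-hash manifest so reruns
# are verifiably identical. Stages communicate only through declared files.

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed integer seed (mandatory: the simulate stage runs).
#' @param synthetic arguments passed to [synthetic_config()].
#' @param divergence ortholog-pair divergence for the compare stage.
#' @param repeat_expansion extra repeat units in the second species.
#' @param tree newick string for the two synthetic species.
#' @param log_level `"info"` or `"quiet"`.
#' @return named list, the pipeline configuration.
#' @export
pipeline_config <- function(outdir, seed, synthetic = list(),
                            divergence = 0.1, repeat_expansion = 10L,
                            tree = "(species_A:1,species_B:1);",
                            log_level = "info") {
  if (missing(seed)) stop("seed is mandatory when the simulate stage runs")
  list(outdir = outdir, seed = as.integer(seed), synthetic = synthetic,
       divergence = divergence, repeat_expansion = repeat_expansion,
       tree = tree, log_level = log_level)
}

.log <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[edclocus] ", ...)
}

#' Run the full synthetic-locus pipeline
#'
#' Runs the stages in dependency order and writes every artifact under
#' `config$outdir`: scaffold FASTA, truth and predicted GFF3, predicted
#' protein FASTA, per-tissue FASTQ, composition/repeat/expression/census/
#' event TSVs, and a manifest with MD5 content hashes. Rerunning with the
#' same configuration reproduces identical hashes. On stage failure the
#' partial outputs are moved to a `quarantine/` subdirectory and the
#' failing stage is named in the error.
#'
#' @param config a [pipeline_config()] list, or the path of a YAML file
#'   with the same fields.
#' @return invisibly the manifest data.frame (`path`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("seed is mandatory")
  if (is.null(config$outdir)) stop("outdir is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(outdir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "simulate"
  result <- tryCatch({
    cfg <- do.call(synthetic_config, c(list(seed = config$seed),
                                       config$synthetic))
    .log(config, "simulate: generating ortholog pair, seed ", config$seed)
    pair <- generate_ortholog_pair(cfg,
                                   divergence = config$divergence %||% 0.1,
                                   repeat_expansion =
                                     config$repeat_expansion %||% 10L)
    locus <- pair$locus_a
    truth <- locus$truth
    emit(function(o, p) write_fasta(o, p), locus$scaffolds, "assembly_A.fasta")
    emit(function(o, p) write_fasta(o, p), pair$locus_b$scaffolds,
         "assembly_B.fasta")
    emit(function(o, p) write_gff3(o, p), unname(truth$models),
         "truth_A.gff3")
    emit(function(o, p) write_fasta(o, p), truth$proteins,
         "truth_proteins_A.fasta")
    emit(function(o, p) write_fasta(o, p), pair$locus_b$truth$proteins,
         "truth_proteins_B.fasta")
    rd <- generate_tissue_reads(locus, cfg)
    for (tissue in unique(vapply(rd$reads, `[[`, character(1), "tissue"))) {
      sel <- Filter(function(r) r$tissue == tissue, rd$reads)
      emit(function(o, p) write_fastq(o, p), sel,
           sprintf("reads_%s.fastq", tissue))
    }
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE),
         rd$table, "truth_reads.tsv")

    stage <- "annotate"
    .log(config, "annotate: delimiting locus and predicting genes")
    markers <- list(
      protein_record("S100A12", truth$proteins[["S100A12"]]),
      protein_record("S100A11", truth$proteins[["S100A11"]]))
    region <- find_flanked_region(locus$scaffolds, markers)
    preds <- predict_sedc_genes(region, locus$scaffolds)
    sftp_q <- lapply(intersect(c("CRNN", "SCFN"), names(truth$proteins)),
                     function(g) protein_record(g, truth$proteins[[g]]))
    if (length(sftp_q))
      preds <- c(preds, predict_sftp_genes(region, locus$scaffolds, sftp_q))
    preds <- lapply(preds, function(p) {
      p$model$completeness <- if (classify_gene_status(p, locus$scaffolds) ==
                                  "partial") "partial" else "complete"
      p
    })
    preds <- lapply(preds, validate_with_reads, locus$scaffolds, rd$reads)
    emit(function(o, p) write_gff3(o, p), lapply(preds, `[[`, "model"),
         "predicted.gff3")
    pred_prot <- stats::setNames(
      vapply(preds, function(p) {
        sc <- Filter(function(s) s$id == p$model$scaffold_id,
                     locus$scaffolds)[[1]]
        gene_protein(p$model, sc)
      }, character(1)),
      vapply(preds, function(p) p$model$id, character(1)))
    pred_prot <- pred_prot[!grepl("\\*", pred_prot)]
    emit(function(o, p) write_fasta(o, p), pred_prot, "predicted_proteins.fasta")
    ev <- data.frame(
      gene = vapply(preds, function(p) p$model$id, character(1)),
      confidence = vapply(preds, function(p) p$evidence$confidence, character(1)),
      read_support = vapply(preds, function(p) p$evidence$read_support, integer(1)),
      intron_spanning = vapply(preds, function(p)
        p$evidence$intron_spanning_reads, integer(1)))
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE), ev, "evidence.tsv")

    stage <- "profile"
    .log(config, "profile: composition and terminal motifs")
    comp <- composition_matrix(truth$proteins)
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE), comp, "composition.tsv")

    stage <- "repeats"
    .log(config, "repeats: motif copy counting")
    rep_rows <- list()
    for (g in names(truth$proteins)) {
      ra <- count_motif_copies(truth$proteins[[g]],
                               truth$repeat_info$unit %||%
                                 "CCDPCQ(K|-)(T|P)(V|-)")
      if (!is.null(ra))
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          gene = g, copies = ra$copies, span_start = ra$span[1],
          span_end = ra$span[2])
    }
    rep_df <- if (length(rep_rows)) do.call(rbind, rep_rows)
              else data.frame(gene = character(), copies = integer(),
                              span_start = integer(), span_end = integer())
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE), rep_df, "repeats.tsv")

    stage <- "express"
    .log(config, "express: exact-match read counting")
    et <- expression_table(truth$proteins, rd$reads, control_gene = "ALAS1")
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE),
         as.data.frame(et), "expression.tsv")

    stage <- "compare"
    .log(config, "compare: orthology, census, gain/loss")
    pa <- truth$proteins; pb <- pair$locus_b$truth$proteins
    omap <- reciprocal_best_hits(pa, pb)
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE), omap, "orthologs.tsv")
    fam_of <- function(models) vapply(models, function(m)
      if (m$category %in% c("SEDC", "SFTP")) m$name else m$category,
      character(1))
    ann <- lapply(list(species_A = truth, species_B = pair$locus_b$truth),
                  function(tr) {
      keep <- names(tr$models)[vapply(tr$models, function(m)
        m$category != "marker", logical(1))]
      data.frame(gene = keep,
                 family = fam_of(tr$models[keep]),
                 status = vapply(tr$models[keep], function(m)
                   if (m$category == "pseudogene") "pseudogene"
                   else m$completeness, character(1)),
                 stringsAsFactors = FALSE)
    })
    census <- family_census(ann)
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE),
         as.data.frame(census), "census.tsv")
    tree <- ape::read.tree(text = config$tree %||%
                             "(species_A:1,species_B:1);")
    ev2 <- dollo_gain_loss(census, tree)
    emit(function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE), ev2, "events.tsv")

    stage <- "manifest"
    manifest <- data.frame(path = basename(written),
                           md5 = unname(tools::md5sum(written)),
                           stringsAsFactors = FALSE)
    write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest
  }, error = function(e) {
    qdir <- file.path(outdir, "quarantine")
    dir.create(qdir, showWarnings = FALSE)
    for (f in written) if (file.exists(f))
      file.rename(f, file.path(qdir, basename(f)))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
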