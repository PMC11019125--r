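## End-to-end orchestration: simulate -> process-atac -> process-meth ->
## associate -> annotate -> clocks x 3 data types -> evaluate, with every
## stage output written to disk under a common provenance header.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates (or reads) a dataset, builds the accessibility and methylation
#' feature matrices, fits per-feature age models, annotates and tests
#' chromatin-state enrichment, trains the three LOOCV elastic-net clocks
#' (atac, dnam, combined) with meta-features, and evaluates predictions,
#' breed-size strata, residual ages and cross-clock residual correlations.
#' Output files carry '#' headers naming the package version and the config
#' hash; stage timings and QC feature counts go to `run.log`. Two runs with
#' the same config and seed produce byte-identical numeric outputs.
#'
#' @param config a [SimConfig-class] describing the synthetic study.
#' @param outDir output directory.
#' @param seed integer seed for every downstream stochastic step (inner CV
#'   fold assignment); the generator itself is seeded by `config@seed`.
#' @param dataTypes which clocks to build.
#' @param scaling "global" (study order) or "fold" (leakage-free).
#' @param alpha,innerFolds,nLambda clock hyper-parameters.
#' @param qThreshold FDR cut-off for age-associated features.
#' @return invisible list with every stage result.
#' @export
runPipeline <- function(config = simConfig(), outDir, seed = config@seed,
                        dataTypes = c("atac", "dnam", "combined"),
                        scaling = c("global", "fold"), alpha = 0.5,
                        innerFolds = 10, nLambda = 100, qThreshold = 0.05) {
  scaling <- match.arg(scaling)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cfgHash <- configHash(list(
    config = .simConfigAsList(config), seed = seed, alpha = alpha,
    innerFolds = innerFolds, nLambda = nLambda, scaling = scaling,
    qThreshold = qThreshold, dataTypes = dataTypes))
  hdr <- sprintf("# config=%s", cfgHash)
  logPath <- file.path(outDir, "run.log")
  cat(sprintf("# epiAgeClock %s config=%s\n", pkgVersion(), cfgHash),
      file = logPath)
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = logPath, append = TRUE, sep = "")
  }
  qc <- function(msg) logf("%s", msg)

  logf("stage simulate: start (seed %d)", config@seed)
  sim <- simulateDataset(config)
  writeDataset(sim, file.path(outDir, "data"))
  ## resolved run configuration next to the outputs
  jsonlite::write_json(
    list(config = .simConfigAsList(config), seed = seed, alpha = alpha,
         innerFolds = innerFolds, nLambda = nLambda, scaling = scaling,
         qThreshold = qThreshold, dataTypes = dataTypes,
         version = pkgVersion(), configHash = cfgHash),
    file.path(outDir, "run_config.json"), auto_unbox = TRUE, digits = NA)

  logf("stage process-atac: start")
  atac <- processAtac(sim$atac$peaks, sim$atac$counts, log = qc)
  logf("stage process-meth: start")
  meth <- processMethylation(sim$meth$methylated, sim$meth$unmethylated,
                             sim$meth$sites$chrom, log = qc)

  logf("stage associate: start")
  assoc <- list(
    atac = fitFeatureAgeModels(atac$se, sim$metadata, qThreshold),
    dnam = fitFeatureAgeModels(meth$se, sim$metadata, qThreshold))
  for (dt in names(assoc))
    writeTsvWithHeader(assoc[[dt]],
                       file.path(outDir, sprintf("association_%s.tsv", dt)),
                       hdr)
  screen <- screenMetadataAge(sim$metadata)
  writeTsvWithHeader(screen, file.path(outDir, "metadata_screen.tsv"), hdr)

  logf("stage annotate: start")
  peakStates <- assignState(atac$peaks, sim$states)
  enrich <- tryCatch(
    stateEnrichment(assoc$atac$direction, peakStates),
    error = function(e) { logf("enrichment skipped: %s",
                               conditionMessage(e)); NULL })
  if (!is.null(enrich))
    writeTsvWithHeader(enrich, file.path(outDir, "state_enrichment.tsv"), hdr)

  logf("stage clock: start (%s scaling)", scaling)
  set.seed(seed)
  ages <- sim$metadata$age
  blocks <- list(atac = list(atac$se), dnam = list(meth$se),
                 combined = list(atac$se, meth$se))
  clocks <- list()
  for (dt in dataTypes) {
    logf("clock %s: start", dt)
    X <- buildDesign(blocks[[dt]], sim$metadata)
    clocks[[dt]] <- loocvClock(X, ages, alpha = alpha, k = innerFolds,
                               scaling = scaling, dataType = dt,
                               nLambda = nLambda)
    writeTsvWithHeader(clockPredictions(clocks[[dt]]),
                       file.path(outDir, sprintf("predictions_%s.tsv", dt)),
                       hdr)
  }

  logf("stage evaluate: start")
  evals <- resids <- list()
  for (dt in names(clocks)) {
    pr <- clockPredictions(clocks[[dt]])
    ev <- stratifiedEvaluation(pr$predicted_age, pr$age,
                               sim$metadata$weight_category)
    ev <- cbind(data_type = dt, ev)
    evals[[dt]] <- ev
    resids[[dt]] <- residualAge(pr$predicted_age, pr$age)
  }
  writeTsvWithHeader(do.call(rbind, evals),
                     file.path(outDir, "evaluation.tsv"), hdr)
  residDf <- data.frame(sample_id = sim$metadata$sample_id,
                        as.data.frame(resids))
  writeTsvWithHeader(residDf, file.path(outDir, "residual_age.tsv"), hdr)

  rvw <- lapply(resids, residualVsWeight,
                breedWeight = sim$metadata$breed_weight_kg)
  rvwDf <- data.frame(data_type = names(rvw),
                      slope = vapply(rvw, `[[`, 0, "slope"),
                      p = vapply(rvw, `[[`, 0, "p"),
                      r2 = vapply(rvw, `[[`, 0, "r2"))
  writeTsvWithHeader(rvwDf, file.path(outDir, "residual_vs_weight.tsv"), hdr)

  crossCor <- NULL
  if (length(resids) >= 2) {
    prs <- utils::combn(names(resids), 2, simplify = FALSE)
    crossCor <- do.call(rbind, lapply(prs, function(pq) {
      cc <- crossClockResidualCorrelation(resids[[pq[1]]], resids[[pq[2]]])
      data.frame(clock_a = pq[1], clock_b = pq[2], r = cc$r, p = cc$p)
    }))
    writeTsvWithHeader(crossCor,
                       file.path(outDir, "residual_correlations.tsv"), hdr)
  }

  selReport <- selectionFrequencyReport(clocks)
  writeTsvWithHeader(selReport$frequencies,
                     file.path(outDir, "selection_frequency.tsv"), hdr)

  overlap <- NULL
  if (all(c("atac", "dnam", "combined") %in% names(clocks))) {
    nearest <- nearestGene(atac$peaks, sim$genes)
    cpgGr <- GenomicRanges::GRanges(
      sub("^cpg_([^_]+)_\\d+$", "\\1", rownames(meth$se)),
      IRanges::IRanges(as.integer(sub("^cpg_.*_(\\d+)$", "\\1",
                                      rownames(meth$se))), width = 1))
    names(cpgGr) <- rownames(meth$se)
    nearestCpg <- nearestGene(cpgGr, sim$genes)
    geneMap <- stats::setNames(c(nearest$gene, nearestCpg$gene),
                               c(nearest$feature, nearestCpg$feature))
    overlap <- clockGeneOverlap(selReport$everSelected[
      c("atac", "dnam", "combined")], geneMap)
    writeLines(c(sprintf("# epiAgeClock %s", pkgVersion()), hdr,
                 sprintf("%s\t%d", names(overlap$venn), overlap$venn),
                 sprintf("intersection\t%s",
                         paste(overlap$intersectionGenes, collapse = ","))),
               file.path(outDir, "clock_gene_overlap.tsv"))
  }
  logf("stage evaluate: done")

  invisible(list(sim = sim, atac = atac, meth = meth, assoc = assoc,
                 screen = screen, peakStates = peakStates, enrich = enrich,
                 clocks = clocks, evaluation = do.call(rbind, evals),
                 residuals = resids, residualVsWeight = rvwDf,
                 crossCor = crossCor, selection = selReport,
                 overlap = overlap))
}

.simConfigAsList <- function(config) {
  sn <- methods::slotNames("SimConfig")
  stats::setNames(lapply(sn, function(s) methods::slot(config, s)), sn)
}
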