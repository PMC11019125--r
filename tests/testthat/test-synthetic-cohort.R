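test_that("config validation names the offending field", {
  expect_error(simConfig(nSamples = 0), "nSamples")
  expect_error(simConfig(fracAgeAssocMeth = 1.2), "fracAgeAssocMeth")
  expect_error(simConfig(ageRange = c(10, 2)), "ageRange")
})

test_that("cohort has the designed size and age range, deterministically", {
  cfg <- simConfig(nSamples = 71, seed = 1)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$metadata), 71)
  expect_true(all(a$metadata$age >= 1 & a$metadata$age <= 16))
  expect_true(all(a$metadata$age == round(a$metadata$age)))
  cells <- as.matrix(a$metadata[grep("^cell\\.", names(a$metadata))])
  expect_equal(ncol(cells), 31)
  expect_true(all(cells >= 0 & cells <= 100))
  ## weight category consistent with thresholds
  expect_identical(
    a$metadata$weight_category,
    as.character(cut(a$metadata$breed_weight_kg, c(-Inf, 10, 25, Inf),
                     labels = c("small", "medium", "large"), right = FALSE)))
  ## a different seed gives a different cohort
  expect_false(identical(simulateCohort(simConfig(seed = 2))$metadata,
                         a$metadata))
})

test_that("zero cell-type slope gives zero expected age correlation", {
  ## 200 replicate cohorts; mean correlation of the designated type with age
  ## must sit within 3 standard errors of 0
  cors <- vapply(seq_len(200), function(s) {
    m <- simulateCohort(simConfig(nSamples = 40, celltypeAgeSlope = 0,
                                  seed = 1000 + s))$metadata
    cor(m$cell.CD8, m$age)
  }, numeric(1))
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se + 1e-12)
})

test_that("designed cell-type slope is recovered by OLS at large n", {
  m <- simulateCohort(simConfig(nSamples = 5000, celltypeAgeSlope = 0.5,
                                seed = 7))$metadata
  fit <- olsFit(m$cell.CD8, cbind(1, age = m$age))
  expect_lt(abs(fit$coefficients["age"] - 0.5) / 0.5, 0.1)
  ## non-designated types stay flat
  fit0 <- olsFit(m$cell.type03, cbind(1, age = m$age))
  expect_gt(fit0$p["age"], 0.001)
})

test_that("exercise vigor declines stochastically with age", {
  m <- simulateCohort(simConfig(nSamples = 2000, seed = 5))$metadata
  lev <- c(minimal = 1, light = 2, moderate = 3, vigorous = 4)
  expect_lt(cor(lev[m$exercise], m$age), -0.2)
})

test_that("methylation generator honours the configured truth layout", {
  cfg <- simConfig(nSamples = 20, nCpgSites = 1000, fracAgeAssocMeth = 0.1,
                   nDecoyFeatures = 12, seed = 3)
  cohort <- simulateCohort(cfg)
  sim <- simulateMethylation(cohort, cfg)
  expect_equal(length(sim$truth$ageAssocIds), 100)      # exactly frac * n
  expect_equal(nrow(sim$methylated), 1012)              # sites + decoys
  expect_true(all(sim$truth$ageAssocIds %in% sim$sites$id))
  ## decoys carry no age effect and sit on decoy contigs
  decoyIds <- sim$sites$id[grepl("chrM|scaffold", sim$sites$chrom)]
  expect_equal(length(decoyIds), 12)
  expect_true(all(sim$truth$slopes[decoyIds] == 0))
  expect_true(all(sim$methylated >= 0 & sim$unmethylated >= 0))
  ## determinism
  expect_identical(simulateMethylation(cohort, cfg), sim)
})

test_that("atac generator produces merge-eligible summits, decoys and >=2-fold library spread", {
  cfg <- simConfig(nSamples = 20, nAtacPeaks = 500, nDecoyFeatures = 10,
                   seed = 4)
  cohort <- simulateCohort(cfg)
  sim <- simulateAtac(cohort, cfg)
  expect_equal(length(sim$peaks), 510)
  expect_equal(nrow(sim$counts), 510)
  ## engineered close pair: consecutive summits < 500 bp on one chromosome
  bychrom <- split(sim$peaks$summit,
                   as.character(GenomicRanges::seqnames(sim$peaks)))
  gaps <- unlist(lapply(bychrom, function(s) diff(sort(s))))
  expect_true(any(gaps < 500))
  expect_gte(max(sim$libFactors) / min(sim$libFactors), 2)
  ## low-coverage peaks exist (median <= 20) for the filter to remove
  med <- apply(sim$counts, 1, median)
  expect_true(any(med <= 20))
  ## summit inside [start, end)
  expect_true(all(sim$peaks$summit >= GenomicRanges::start(sim$peaks) - 1))
  expect_true(all(sim$peaks$summit < GenomicRanges::end(sim$peaks)))
})

test_that("annotation covers the genome with all 13 states, disjoint and sorted", {
  cfg <- simConfig(seed = 9, nAtacPeaks = 300)
  ann <- simulateAnnotation(cfg)
  expect_setequal(unique(ann$states$state), as.character(1:13))
  ## non-overlapping within chromosome
  byChr <- split(ann$states, as.character(GenomicRanges::seqnames(ann$states)))
  for (gr in byChr) {
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    o <- order(s)
    expect_true(all(s[o][-1] > e[o][-length(e)]))
  }
  expect_equal(length(ann$genes), cfg@nGenes)
  expect_false(anyDuplicated(ann$genes$gene_name) > 0)
  ## every canonical-peak midpoint falls in exactly one state interval
  cohort <- simulateCohort(cfg)
  atac <- simulateAtac(cohort, cfg)
  pk <- atac$peaks[!grepl("chrM|scaffold",
                          as.character(GenomicRanges::seqnames(atac$peaks)))]
  mids <- floor((GenomicRanges::start(pk) + GenomicRanges::end(pk)) / 2)
  midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(pk),
                                  IRanges::IRanges(mids, mids))
  cnt <- GenomicRanges::countOverlaps(midGr, ann$states)
  expect_true(all(cnt == 1))
})

test_that("dataset write/read round-trips (counts bitwise)", {
  cfg <- simConfig(nSamples = 6, nCpgSites = 40, nAtacPeaks = 30,
                   nDecoyFeatures = 4, seed = 12)
  sim <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  writeDataset(sim, dir)
  back <- readDataset(dir)
  expect_identical(back$atac$counts, sim$atac$counts)
  expect_identical(unname(back$meth$methylated),
                   unname(sim$meth$methylated))
  expect_identical(unname(back$meth$unmethylated),
                   unname(sim$meth$unmethylated))
  expect_equal(GenomicRanges::start(back$atac$peaks),
               GenomicRanges::start(sim$atac$peaks))
  expect_identical(back$atac$peaks$summit, sim$atac$peaks$summit)
  expect_identical(back$states$state, sim$states$state)
  expect_identical(back$genes$gene_name, sim$genes$gene_name)
  expect_equal(back$metadata$age, sim$metadata$age)
  ## manifest lists every ground-truth age-associated identifier
  expect_setequal(back$truth$meth_age_assoc_ids, sim$meth$truth$ageAssocIds)
  expect_setequal(back$truth$atac_age_assoc_ids, sim$atac$truth$ageAssocIds)
})

test_that("byte-identical outputs for identical configs", {
  cfg <- simConfig(nSamples = 5, nCpgSites = 20, nAtacPeaks = 15, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeDataset(simulateDataset(cfg), d1)
  writeDataset(simulateDataset(cfg), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
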