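## Synthetic study generator: a cohort of companion dogs with flow-cytometry
## cell proportions, RRBS-style CpG counts, ATAC-style peak counts, a toy
## chromatin-state segmentation and gene set, plus a ground-truth manifest.

## breed table: AKC-style mean adult weights (kg), spanning the size classes
.breedTable <- data.frame(
  breed = c("Chihuahua", "Dachshund", "Pomeranian", "Shih Tzu", "Pug",
            "Miniature Schnauzer", "Beagle", "Cocker Spaniel",
            "Border Collie", "Australian Shepherd", "Brittany", "Whippet",
            "Bulldog", "Boxer", "Labrador Retriever", "Golden Retriever",
            "German Shepherd", "Rottweiler", "Doberman Pinscher",
            "Bernese Mountain Dog", "Great Dane", "Mastiff"),
  weight_kg = c(2.5, 7.5, 2.5, 5.5, 8, 7.5, 10, 12,
                17, 25, 16, 12.5,
                23, 30, 31, 30, 34, 48, 38, 42, 62, 82),
  stringsAsFactors = FALSE
)

cellTypeNames <- function(n) {
  stopifnot(n >= 1)
  base <- c("cell.CD8", "cell.DN")  # CD62L+/CD44+ CD8 and double-negative T
  if (n <= 2) return(base[seq_len(n)])
  c(base, sprintf("cell.type%02d", seq_len(n - 2) + 2L))
}

weightCategory <- function(weight, thresholds) {
  cut(weight, breaks = c(-Inf, thresholds, Inf),
      labels = c("small", "medium", "large"), right = FALSE)
}

#' Simulate cohort metadata with known ground truth
#'
#' Draws a cohort of dogs with integer ages uniform over the configured
#' range, sex, breed (and hence breed mean weight and size category), an
#' exercise-vigor category that stochastically declines with age, and a
#' flow-cytometry panel of cell-type proportions (percent of parent gate,
#' each in 0--100). The configured number of designated cell types increases
#' linearly with age at `celltypeAgeSlope` percentage points per year; all
#' other types are independent of age.
#'
#' @param config a [SimConfig-class]. The generator seeds its own RNG from
#'   `config@seed`, so identical configs give identical cohorts.
#' @return list with `metadata` (data.frame, one row per sample) and `truth`
#'   (list with `cellSlopes`, the per-cell-type true slopes).
#' @examples
#' cohort <- simulateCohort(simConfig(nSamples = 20))
#' head(cohort$metadata[, 1:7])
#' @export
simulateCohort <- function(config = simConfig()) {
  validObject(config)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed))
  set.seed(config@seed)

  n <- config@nSamples
  ages <- sample(seq(config@ageRange[1], config@ageRange[2]), n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  bidx <- sample(nrow(.breedTable), n, replace = TRUE)
  breed <- .breedTable$breed[bidx]
  weight <- .breedTable$weight_kg[bidx]
  wcat <- weightCategory(weight, config@weightThresholds)

  ## exercise vigor: ordered latent score decreasing in age
  latent <- 3.5 - 0.18 * ages + stats::rlogis(n)
  exercise <- cut(latent, breaks = c(-Inf, 0.8, 1.8, 2.8, Inf),
                  labels = c("minimal", "light", "moderate", "vigorous"))

  ctn <- cellTypeNames(config@nCellTypes)
  slopes <- stats::setNames(rep(0, config@nCellTypes), ctn)
  if (config@nAgeAssocCellTypes > 0)
    slopes[seq_len(config@nAgeAssocCellTypes)] <- config@celltypeAgeSlope
  baselines <- stats::setNames(stats::runif(config@nCellTypes, 5, 60), ctn)
  ## keep age-associated types mid-range so 0-100 clamping stays negligible
  baselines[slopes != 0] <- stats::runif(sum(slopes != 0), 20, 40)
  cells <- sapply(ctn, function(ct) {
    v <- baselines[ct] + slopes[ct] * ages + stats::rnorm(n, 0, 5)
    pmin(pmax(v, 0), 100)
  })
  cells <- matrix(cells, nrow = n, dimnames = list(NULL, ctn))

  metadata <- data.frame(
    sample_id = sprintf("dog%03d", seq_len(n)),
    age = ages, sex = sex, breed = breed,
    breed_weight_kg = weight,
    weight_category = as.character(wcat),
    exercise = as.character(exercise),
    stringsAsFactors = FALSE
  )
  metadata <- cbind(metadata, as.data.frame(cells))
  list(metadata = metadata, truth = list(cellSlopes = slopes))
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreSeed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

## place k features on a toy genome; returns data.frame(chrom, pos) sorted
.placeSites <- function(k, config, decoys = 0L) {
  chroms <- sprintf("chr%d", seq_len(config@nChrom))
  chrom <- sort(sample(chroms, k, replace = TRUE))
  pos <- unlist(lapply(split(seq_along(chrom), chrom), function(ix) {
    sort(sample(seq(100L, config@chromLength - 100L), length(ix)))
  }), use.names = FALSE)
  df <- data.frame(chrom = sort(chrom), pos = pos, stringsAsFactors = FALSE)
  if (decoys > 0L) {
    dchrom <- rep(c("chrM", "scaffold_1", "scaffold_2"), length.out = decoys)
    dpos <- sample(seq(100L, 16000L), decoys)
    df <- rbind(df, data.frame(chrom = dchrom, pos = dpos))
  }
  df
}

#' Simulate RRBS-style CpG methylation counts
#'
#' Per site i and sample j, depth is negative-binomial with the configured
#' mean and a per-site dispersion drawn from a log-normal; the methylated
#' count is Binomial(depth, p_ij) with logit(p_ij) = baseline_i +
#' slope_i * age_j. Baselines are drawn so that most sites have a
#' population-median fraction inside 0.1--0.9, with a configured minority
#' constitutively hyper-/hypo-methylated, and decoy sites are placed on chrM
#' and scaffold contigs — both there to exercise the downstream filters.
#' Exactly `round(fracAgeAssocMeth * nCpgSites)` sites carry nonzero true
#' slopes (decoys never do).
#'
#' @param cohort output of [simulateCohort()].
#' @param config the same [SimConfig-class].
#' @return list with `sites` (data.frame chrom/pos), `methylated` and
#'   `unmethylated` (sites x samples integer matrices), and `truth`
#'   (list: `ageAssocIds`, `slopes`).
#' @export
simulateMethylation <- function(cohort, config = simConfig()) {
  validObject(config)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed))
  set.seed(config@seed + 1L)

  ages <- cohort$metadata$age
  n <- length(ages)
  k <- config@nCpgSites
  sites <- .placeSites(k, config, config@nDecoyFeatures)
  ids <- sprintf("cpg_%s_%d", sites$chrom, sites$pos)
  ktot <- nrow(sites)

  nAssoc <- round(config@fracAgeAssocMeth * k)
  assoc <- sample(k, nAssoc)          # decoys (rows > k) never age-associated
  slopes <- rep(0, ktot)
  slopes[assoc] <- stats::rnorm(nAssoc, 0, config@methAgeSlopeSd)

  baseline <- stats::rnorm(ktot, 0, 1.2)
  nExtreme <- round(config@fracExtremeMeth * ktot)
  if (nExtreme > 0) {
    ext <- sample(ktot, nExtreme)
    baseline[ext] <- sample(c(-5, 5), nExtreme, replace = TRUE)
    slopes[ext] <- 0
  }
  ## anchor the age effect at mid-cohort age so medians stay interpretable
  midAge <- mean(config@ageRange)
  b0 <- baseline - slopes * midAge

  size <- stats::rlnorm(ktot, config@nbSizeMeanLog, config@nbSizeSdLog)
  depth <- matrix(stats::rnbinom(ktot * n, mu = config@meanDepthMeth,
                                 size = rep(size, n)),
                  nrow = ktot)
  p <- stats::plogis(outer(b0, rep(1, n)) + outer(slopes, ages))
  meth <- matrix(stats::rbinom(ktot * n, size = as.vector(depth),
                               prob = as.vector(p)), nrow = ktot)
  unmeth <- depth - meth
  storage.mode(meth) <- storage.mode(unmeth) <- "integer"
  dimnames(meth) <- dimnames(unmeth) <-
    list(ids, cohort$metadata$sample_id)
  list(sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                          id = ids, stringsAsFactors = FALSE),
       methylated = meth, unmethylated = unmeth,
       truth = list(ageAssocIds = ids[assoc],
                    slopes = stats::setNames(slopes, ids)))
}

#' Simulate an ATAC-style consensus peak set and count matrix
#'
#' Peaks get 0-based half-open coordinates, a summit, and counts drawn
#' negative-binomially with log mean baseline_i + slope_i * age_j +
#' log(libsize_j). Library-size factors vary at least two-fold across
#' samples. The set deliberately contains low-coverage peaks (median count
#' at or below 20), chrM/scaffold decoys, and at least one pair of peaks
#' with summits closer than 500 bp, so that every downstream filter and the
#' summit-merging rule have something to act on.
#'
#' @inheritParams simulateMethylation
#' @return list with `peaks` (a `GRanges` with mcols name/summit), `counts`
#'   (peaks x samples integer matrix), `libFactors`, and `truth`.
#' @export
simulateAtac <- function(cohort, config = simConfig()) {
  validObject(config)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed))
  set.seed(config@seed + 2L)

  ages <- cohort$metadata$age
  n <- length(ages)
  k <- config@nAtacPeaks

  chroms <- sprintf("chr%d", seq_len(config@nChrom))
  chrom <- sort(sample(chroms, k, replace = TRUE))
  width <- sample(200:800, k, replace = TRUE)
  start <- unlist(lapply(split(seq_along(chrom), chrom), function(ix) {
    m <- length(ix)
    sort(sample(seq(1000L, config@chromLength - 2000L), m))
  }), use.names = FALSE)
  chrom <- sort(chrom)
  end <- start + width
  summit <- start + as.integer(floor(width / 2))
  ## guarantee one merge-eligible pair: summits 400 bp apart on chrom[1]
  if (k >= 2) {
    chrom[1:2] <- chrom[1]
    start[1] <- 1000L; end[1] <- 1600L; summit[1] <- 1300L
    start[2] <- 1400L; end[2] <- 2000L; summit[2] <- 1700L
  }
  decoys <- config@nDecoyFeatures
  if (decoys > 0L) {
    dchrom <- rep(c("chrM", "scaffold_1", "scaffold_2"), length.out = decoys)
    dstart <- as.integer(seq(1000L, by = 3000L, length.out = decoys))
    dwidth <- sample(200:800, decoys, replace = TRUE)
    chrom <- c(chrom, dchrom)
    start <- c(start, dstart)
    end <- c(end, dstart + dwidth)
    summit <- c(summit, dstart + as.integer(floor(dwidth / 2)))
  }
  ktot <- length(chrom)
  ids <- sprintf("peak_%05d", seq_len(ktot))

  nAssoc <- round(config@fracAgeAssocAtac * k)
  assoc <- sample(k, nAssoc)
  slopes <- rep(0, ktot)
  slopes[assoc] <- stats::rnorm(nAssoc, 0, config@atacAgeSlopeSd)

  baseline <- stats::rnorm(ktot, log(config@meanDepthAtac), 0.7)
  nLow <- max(1L, round(0.05 * k))
  low <- sample(k, nLow)
  baseline[low] <- log(8)
  slopes[low] <- 0
  midAge <- mean(config@ageRange)
  b0 <- baseline - slopes * midAge

  libFactors <- exp(stats::runif(n, log(0.6), log(1.8)))
  libFactors[1] <- 0.6
  if (n >= 2) libFactors[2] <- 1.3   # enforce >= 2-fold spread

  size <- stats::rlnorm(ktot, config@nbSizeMeanLog, config@nbSizeSdLog)
  mu <- exp(outer(b0, rep(1, n)) + outer(slopes, ages) +
              outer(rep(1, ktot), log(libFactors)))
  counts <- matrix(stats::rnbinom(ktot * n, mu = as.vector(mu),
                                  size = rep(size, n)), nrow = ktot)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, cohort$metadata$sample_id)

  peaks <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),  # 1-based GRanges
    name = ids, summit = summit)
  names(peaks) <- ids
  list(peaks = peaks, counts = counts, libFactors = libFactors,
       truth = list(ageAssocIds = ids[assoc],
                    slopes = stats::setNames(slopes, ids)))
}

#' Simulate a chromatin-state segmentation and gene annotation
#'
#' Tiles the toy genome with non-overlapping intervals labelled with the 13
#' chromatin states, guaranteeing that every state label occurs, and draws a
#' gene set with unique names, strand and coordinates.
#'
#' @param config a [SimConfig-class].
#' @return list with `states` and `genes`, both `GRanges` (states carry
#'   mcols `state` in "1".."13"; genes carry `gene_name`, `score`, strand).
#' @export
simulateAnnotation <- function(config = simConfig()) {
  validObject(config)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed))
  set.seed(config@seed + 3L)

  chroms <- sprintf("chr%d", seq_len(config@nChrom))
  stateList <- lapply(chroms, function(ch) {
    pos <- 0L
    starts <- integer(); ends <- integer()
    while (pos < config@chromLength) {
      len <- sample(2000:50000, 1)
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + len, config@chromLength))
      pos <- pos + len
    }
    data.frame(chrom = ch, start = starts, end = ends)
  })
  st <- do.call(rbind, stateList)
  lab <- sample(as.character(1:13), nrow(st), replace = TRUE)
  lab[1:13] <- as.character(1:13)    # every state present
  states <- GenomicRanges::GRanges(
    st$chrom, IRanges::IRanges(start = st$start + 1L, end = st$end),
    state = lab)

  gchrom <- sort(sample(chroms, config@nGenes, replace = TRUE))
  gstart <- unlist(lapply(split(seq_along(gchrom), gchrom), function(ix) {
    sort(sample(seq(1000L, config@chromLength - 30000L), length(ix)))
  }), use.names = FALSE)
  gchrom <- sort(gchrom)
  gwidth <- sample(2000:20000, config@nGenes, replace = TRUE)
  genes <- GenomicRanges::GRanges(
    gchrom, IRanges::IRanges(start = gstart + 1L, end = gstart + gwidth),
    strand = sample(c("+", "-"), config@nGenes, replace = TRUE),
    gene_name = sprintf("gene%04d", seq_len(config@nGenes)),
    score = 0L)
  names(genes) <- genes$gene_name
  list(states = states, genes = genes)
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulateCohort()], [simulateMethylation()],
#' [simulateAtac()] and [simulateAnnotation()] under one config.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `metadata`, `cellTruth`, `meth`, `atac`,
#'   `states`, `genes`, `config`.
#' @export
simulateDataset <- function(config = simConfig()) {
  cohort <- simulateCohort(config)
  meth <- simulateMethylation(cohort, config)
  atac <- simulateAtac(cohort, config)
  ann <- simulateAnnotation(config)
  list(metadata = cohort$metadata, cellTruth = cohort$truth,
       meth = meth, atac = atac,
       states = ann$states, genes = ann$genes, config = config)
}
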