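#' Simulation configuration for a synthetic dog cohort
#'
#' Holds every knob of the synthetic-data generator: cohort size and age
#' range, numbers of CpG sites / ATAC peaks and the fraction carrying a true
#' age effect, effect-size scales, sequencing-depth means, decoy-contig
#' counts, the flow-cytometry cell panel size and how many cell types drift
#' with age, and the seed.
#'
#' Effect-size units: methylation age slopes are on the logit scale per year
#' of age; accessibility slopes are on the natural-log scale per year; the
#' cell-type slope is in percentage points (of the parent flow gate) per
#' year.
#'
#' @slot nSamples integer, cohort size (default 71).
#' @slot ageRange numeric length-2, years (default c(1, 16)); ages are drawn
#'   uniformly on the integers of this range.
#' @slot nCpgSites,nAtacPeaks integer feature counts (before decoys).
#' @slot fracAgeAssocMeth,fracAgeAssocAtac proportion of features with a true
#'   age slope.
#' @slot methAgeSlopeSd,atacAgeSlopeSd SD of the true slopes (logit / log
#'   scale per year).
#' @slot meanDepthMeth,meanDepthAtac mean sequencing depth (reads).
#' @slot nDecoyFeatures number of mitochondrial/scaffold decoy features added
#'   to each data type.
#' @slot nCellTypes size of the flow panel (default 31).
#' @slot nAgeAssocCellTypes number of cell types whose proportion increases
#'   with age (default 2, emulating the CD62L+/CD44+ CD8 and DN T cells).
#' @slot celltypeAgeSlope percentage points per year for those types.
#' @slot fracExtremeMeth proportion of CpG sites made constitutively hyper- or
#'   hypo-methylated (to exercise the 0.1--0.9 median filter).
#' @slot nbSizeMeanLog,nbSizeSdLog log-normal parameters for the per-feature
#'   negative-binomial size (inverse dispersion).
#' @slot weightThresholds kg cut-offs between small/medium and medium/large
#'   breed-weight categories.
#' @slot nChrom,chromLength toy-genome geometry.
#' @slot nGenes number of annotated genes in the toy genome.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
  nSamples = "integer", ageRange = "numeric",
  nCpgSites = "integer", nAtacPeaks = "integer",
  fracAgeAssocMeth = "numeric", fracAgeAssocAtac = "numeric",
  methAgeSlopeSd = "numeric", atacAgeSlopeSd = "numeric",
  meanDepthMeth = "numeric", meanDepthAtac = "numeric",
  nDecoyFeatures = "integer", nCellTypes = "integer",
  nAgeAssocCellTypes = "integer", celltypeAgeSlope = "numeric",
  fracExtremeMeth = "numeric",
  nbSizeMeanLog = "numeric", nbSizeSdLog = "numeric",
  weightThresholds = "numeric",
  nChrom = "integer", chromLength = "integer", nGenes = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  chkCount <- function(slot) {
    v <- slot(object, slot)
    if (length(v) != 1L || is.na(v) || v <= 0L)
      sprintf("invalid config field '%s': must be a positive count", slot)
    else TRUE
  }
  chkProp <- function(slot) {
    v <- slot(object, slot)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      sprintf("invalid config field '%s': must be a proportion in [0, 1]", slot)
    else TRUE
  }
  msgs <- character()
  for (s in c("nSamples", "nCpgSites", "nAtacPeaks", "nCellTypes",
              "nChrom", "chromLength", "nGenes")) {
    r <- chkCount(s); if (!isTRUE(r)) msgs <- c(msgs, r)
  }
  for (s in c("fracAgeAssocMeth", "fracAgeAssocAtac", "fracExtremeMeth")) {
    r <- chkProp(s); if (!isTRUE(r)) msgs <- c(msgs, r)
  }
  if (length(object@ageRange) != 2L || object@ageRange[1] >= object@ageRange[2])
    msgs <- c(msgs, "invalid config field 'ageRange': need min < max")
  if (object@nDecoyFeatures < 0L)
    msgs <- c(msgs, "invalid config field 'nDecoyFeatures': must be >= 0")
  if (object@nAgeAssocCellTypes < 0L ||
      object@nAgeAssocCellTypes > object@nCellTypes)
    msgs <- c(msgs, "invalid config field 'nAgeAssocCellTypes': must be in [0, nCellTypes]")
  if (any(object@meanDepthMeth <= 0, object@meanDepthAtac <= 0))
    msgs <- c(msgs, "invalid config field 'meanDepthMeth'/'meanDepthAtac': must be > 0")
  if (length(object@weightThresholds) != 2L ||
      diff(object@weightThresholds) <= 0)
    msgs <- c(msgs, "invalid config field 'weightThresholds': need two increasing kg cut-offs")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults restate the study design being emulated: 71 dogs aged 1--16
#' years, a 31-type flow panel with 2 age-associated T-cell populations, and
#' 5\% of epigenetic features carrying strong age effects (logit slope SD
#' 0.15/yr for methylation, log slope SD 0.05/yr for accessibility).
#'
#' @param nSamples,ageRange,nCpgSites,nAtacPeaks,fracAgeAssocMeth,fracAgeAssocAtac,methAgeSlopeSd,atacAgeSlopeSd,meanDepthMeth,meanDepthAtac,nDecoyFeatures,nCellTypes,nAgeAssocCellTypes,celltypeAgeSlope,fracExtremeMeth,nbSizeMeanLog,nbSizeSdLog,weightThresholds,nChrom,chromLength,nGenes,seed see [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSamples = 20, nCpgSites = 100, nAtacPeaks = 100)
#' @export
simConfig <- function(nSamples = 71, ageRange = c(1, 16),
                      nCpgSites = 2000, nAtacPeaks = 2000,
                      fracAgeAssocMeth = 0.05, fracAgeAssocAtac = 0.05,
                      methAgeSlopeSd = 0.15, atacAgeSlopeSd = 0.05,
                      meanDepthMeth = 30, meanDepthAtac = 100,
                      nDecoyFeatures = 20, nCellTypes = 31,
                      nAgeAssocCellTypes = 2, celltypeAgeSlope = 0.8,
                      fracExtremeMeth = 0.05,
                      nbSizeMeanLog = log(10), nbSizeSdLog = 0.5,
                      weightThresholds = c(10, 25),
                      nChrom = 20, chromLength = 1e6, nGenes = 200,
                      seed = 1) {
  new("SimConfig",
      nSamples = as.integer(nSamples), ageRange = as.numeric(ageRange),
      nCpgSites = as.integer(nCpgSites), nAtacPeaks = as.integer(nAtacPeaks),
      fracAgeAssocMeth = fracAgeAssocMeth, fracAgeAssocAtac = fracAgeAssocAtac,
      methAgeSlopeSd = methAgeSlopeSd, atacAgeSlopeSd = atacAgeSlopeSd,
      meanDepthMeth = meanDepthMeth, meanDepthAtac = meanDepthAtac,
      nDecoyFeatures = as.integer(nDecoyFeatures),
      nCellTypes = as.integer(nCellTypes),
      nAgeAssocCellTypes = as.integer(nAgeAssocCellTypes),
      celltypeAgeSlope = celltypeAgeSlope,
      fracExtremeMeth = fracExtremeMeth,
      nbSizeMeanLog = nbSizeMeanLog, nbSizeSdLog = nbSizeSdLog,
      weightThresholds = as.numeric(weightThresholds),
      nChrom = as.integer(nChrom), chromLength = as.integer(chromLength),
      nGenes = as.integer(nGenes), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSamples, "samples, ages",
      object@ageRange[1], "-", object@ageRange[2], "yr;",
      object@nCpgSites, "CpG sites,", object@nAtacPeaks, "ATAC peaks,",
      object@nCellTypes, "cell types; seed", object@seed, "\n")
})

#' Elastic-net fit
#'
#' Solution of the penalized least-squares objective
#' (1/2N) sum_i (y_i - b0 - x_i' b)^2 +
#' lambda * ((1 - alpha) ||b||_2^2 / 2 + alpha ||b||_1),
#' as returned by [fitElasticNet()].
#'
#' @slot intercept numeric, years.
#' @slot beta named numeric coefficient vector.
#' @slot lambda,alpha penalty weight and mixing parameter as fitted.
#' @slot selected character, features with exactly nonzero coefficients.
#' @slot objective numeric, final objective value.
#' @slot nIter integer, coordinate-descent sweeps used.
#' @slot converged logical.
#' @export
setClass("ElasticNetFit", representation(
  intercept = "numeric", beta = "numeric", lambda = "numeric",
  alpha = "numeric", selected = "character", objective = "numeric",
  nIter = "integer", converged = "logical"
))

setValidity("ElasticNetFit", function(object) {
  if (!identical(object@selected, names(object@beta)[object@beta != 0]))
    return("'selected' must be exactly the support of beta")
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

setMethod("show", "ElasticNetFit", function(object) {
  cat(sprintf(
    "ElasticNetFit: alpha=%g lambda=%.4g, %d/%d nonzero, intercept=%.3f\n",
    object@alpha, object@lambda, length(object@selected),
    length(object@beta), object@intercept))
})

#' @rdname ElasticNetFit-class
#' @param object an `ElasticNetFit`.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname ElasticNetFit-class
#' @export
setMethod("selectedFeatures", "ElasticNetFit", function(object) object@selected)

#' Leave-one-out cross-validated clock result
#'
#' One held-out age prediction per sample, the per-fold fitted models, and
#' aggregate feature-selection frequencies, for one data type
#' (`"atac"`, `"dnam"` or `"combined"`).
#'
#' @slot predictions data.frame with columns sample_id, age, predicted_age,
#'   lambda, n_selected (one row per held-out sample).
#' @slot fits list of [ElasticNetFit-class], one per fold.
#' @slot selectionFreq named integer, number of folds (0..N) in which each
#'   feature had a nonzero coefficient.
#' @slot dataType character, one of atac/dnam/combined.
#' @slot scaling character, "global" (standardization before the loop, the
#'   emulated study's order) or "fold" (leakage-free training-fold scaling).
#' @export
setClass("LoocvClockResult", representation(
  predictions = "data.frame", fits = "list", selectionFreq = "integer",
  dataType = "character", scaling = "character"
))

setValidity("LoocvClockResult", function(object) {
  n <- nrow(object@predictions)
  if (length(object@fits) != n)
    return("need exactly one fitted model per held-out sample")
  if (!all(c("sample_id", "age", "predicted_age", "lambda", "n_selected") %in%
           names(object@predictions)))
    return("predictions is missing required columns")
  if (any(!is.finite(object@predictions$predicted_age)))
    return("predicted ages must be finite")
  if (any(object@selectionFreq < 0L) || any(object@selectionFreq > n))
    return("selection frequencies must lie in 0..N")
  TRUE
})

setMethod("show", "LoocvClockResult", function(object) {
  n <- nrow(object@predictions)
  cat(sprintf(
    "LoocvClockResult (%s, %s scaling): %d folds, median lambda %.4g, median %d features/model\n",
    object@dataType, object@scaling, n,
    stats::median(object@predictions$lambda),
    as.integer(stats::median(object@predictions$n_selected))))
})

#' @rdname LoocvClockResult-class
#' @param object a `LoocvClockResult`.
#' @export
setGeneric("clockPredictions", function(object) standardGeneric("clockPredictions"))

#' @rdname LoocvClockResult-class
#' @export
setMethod("clockPredictions", "LoocvClockResult", function(object) object@predictions)

#' @rdname LoocvClockResult-class
#' @export
setGeneric("selectionFrequency", function(object) standardGeneric("selectionFrequency"))

#' @rdname LoocvClockResult-class
#' @export
setMethod("selectionFrequency", "LoocvClockResult", function(object) object@selectionFreq)
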