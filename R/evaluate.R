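## Clock scoring: predicted-vs-observed regression R2, RMSE, breed-size
## strata, residual age (age acceleration) and its associations, and
## feature-selection frequency summaries.

#' Score predicted against observed ages
#'
#' R2 comes from the OLS regression of predicted on observed (so it is
#' invariant to affine transformation of the predictions); adjusted R2 uses
#' the single-predictor correction 1 - (1-R2)(n-1)/(n-2). RMSE is computed
#' on the raw prediction errors (not the regression residuals); the
#' regression-residual variant is also reported as `rmse_model`. The signed
#' Pearson correlation `r` is reported alongside: a leave-one-out null
#' model predicts mean(y[-i]), an exactly decreasing function of the
#' held-out age, so an unsigned R2 can look perfect on a clock with no
#' skill — `sign(r) * r2_adj` is the honest null-calibration measure.
#'
#' @param predicted,observed paired finite vectors, n >= 3.
#' @param stratum label stored in the output row.
#' @return one-row data.frame: stratum, n, r, r2, r2_adj, rmse, rmse_model.
#' @export
evaluatePredictions <- function(predicted, observed, stratum = "all") {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("inputs must be finite")
  if (stats::sd(observed) == 0) stop("observed ages are constant")
  n <- length(predicted)
  if (stats::sd(predicted) == 0) {
    warning("constant predictions; reporting r2 = 0")
    r2 <- 0
    rr <- 0
    resid <- predicted - mean(predicted)
  } else {
    f <- olsFit(predicted, cbind(1, observed))
    r2 <- f$r2
    rr <- stats::cor(predicted, observed)
    resid <- f$residuals
  }
  data.frame(stratum = stratum, n = n, r = rr, r2 = r2,
             r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
             rmse = sqrt(mean((predicted - observed)^2)),
             rmse_model = sqrt(mean(resid^2)),
             stringsAsFactors = FALSE)
}

#' Clock evaluation stratified by breed-size category
#'
#' [evaluatePredictions()] overall and within each weight category; strata
#' with fewer than 3 samples are skipped with a message.
#'
#' @param predicted,observed paired vectors.
#' @param weightCategory "small"/"medium"/"large" per sample.
#' @return data.frame, one row per stratum (plus "all").
#' @export
stratifiedEvaluation <- function(predicted, observed, weightCategory) {
  out <- evaluatePredictions(predicted, observed, "all")
  for (s in c("small", "medium", "large")) {
    ix <- which(weightCategory == s)
    if (length(ix) < 3L) {
      message(sprintf("stratifiedEvaluation: skipping '%s' (n = %d < 3)",
                      s, length(ix)))
      next
    }
    out <- rbind(out, evaluatePredictions(predicted[ix], observed[ix], s))
  }
  out
}

#' Residual age (age acceleration)
#'
#' Signed residuals of the OLS regression of predicted on observed age
#' ("predicted versus observed" orientation; swap the arguments for the
#' sensitivity-analysis orientation). Residuals sum to zero and are exactly
#' uncorrelated with observed age.
#'
#' @param predicted,observed paired vectors.
#' @return numeric residuals, years.
#' @export
residualAge <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (stats::sd(observed) == 0) stop("observed ages are constant")
  olsFit(predicted, cbind(1, observed))$residuals
}

#' Regress residual age on breed mean weight
#'
#' @param residuals residual ages from [residualAge()].
#' @param breedWeight breed mean weight (kg) per sample.
#' @return list: slope, p (two-sided), r2.
#' @export
residualVsWeight <- function(residuals, breedWeight) {
  f <- olsFit(residuals, cbind(1, weight = breedWeight))
  list(slope = unname(f$coefficients[2]), p = unname(f$p[2]), r2 = f$r2)
}

#' Correlation between residual-age measures of two clocks
#'
#' Pearson correlation with the two-sided p-value from the t transform.
#'
#' @param residualsA,residualsB residual ages on the same samples, same
#'   order.
#' @return list: r, p.
#' @export
crossClockResidualCorrelation <- function(residualsA, residualsB) {
  if (length(residualsA) != length(residualsB)) stop("length mismatch")
  ct <- stats::cor.test(residualsA, residualsB, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Feature-selection frequency report across clocks
#'
#' Tabulates, for every feature and every clock, the number of LOOCV folds
#' in which the feature received a nonzero coefficient; meta-features (cell
#' proportions, weight category) are reported separately; and the per-clock
#' union of ever-selected epigenetic features is returned (the input to
#' [clockGeneOverlap()]).
#'
#' @param results named list of [LoocvClockResult-class] (e.g. atac, dnam,
#'   combined).
#' @return list: `frequencies` (long data.frame clock/feature/count/isMeta),
#'   `metaTable` (meta-features only, wide by clock), `everSelected` (named
#'   list of epigenetic feature ids selected in >= 1 fold).
#' @export
selectionFrequencyReport <- function(results) {
  isMetaName <- function(x) grepl("^cell\\.|^weight_category$", x)
  freqs <- lapply(names(results), function(nm) {
    f <- selectionFrequency(results[[nm]])
    data.frame(clock = nm, feature = names(f), count = as.integer(f),
               isMeta = isMetaName(names(f)), stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, freqs)
  meta <- long[long$isMeta, ]
  metaTable <- if (nrow(meta)) {
    stats::reshape(meta[, c("clock", "feature", "count")],
                   direction = "wide", idvar = "feature",
                   timevar = "clock")
  } else data.frame()
  ever <- lapply(results, function(r) {
    f <- selectionFrequency(r)
    names(f)[f > 0 & !isMetaName(names(f))]
  })
  list(frequencies = long, metaTable = metaTable, everSelected = ever)
}
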