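## Methylation matrix construction: per-site fractions, depth and
## intermediate-methylation filters, contig removal, center/scale.
## Fractions (beta values) are used directly; no M-value transform and no
## log step, mirroring how the accessibility arm differs from this one.

#' Per-site methylation fractions
#'
#' fraction = methylated / (methylated + unmethylated); cells with zero
#' depth are NA (missing), never 0.
#'
#' @param methylated,unmethylated site-by-sample count matrices.
#' @return list with `fractions` and `depths` matrices.
#' @export
computeFractions <- function(methylated, unmethylated) {
  if (!identical(dim(methylated), dim(unmethylated)))
    stop("count matrices must have identical dimensions")
  if (any(methylated < 0) || any(unmethylated < 0))
    stop("counts must be non-negative")
  depth <- methylated + unmethylated
  frac <- ifelse(depth > 0, methylated / depth, NA_real_)
  dimnames(frac) <- dimnames(methylated)
  list(fractions = frac, depths = depth)
}

#' Filter CpG sites on depth, intermediate methylation, and contig
#'
#' Retains sites with across-sample mean depth >= `meanDepthMin` (inclusive),
#' across-sample median fraction inside [`medianLow`, `medianHigh`]
#' (inclusive bounds, median over non-missing cells), and a canonical
#' contig (no chrM/scaffold match). Remaining missing cells (depth 0) are
#' imputed with the site's across-sample mean fraction, since the
#' downstream penalized regression needs complete data. The three criteria
#' commute.
#'
#' @param fractions,depths aligned site-by-sample matrices from
#'   [computeFractions()].
#' @param chrom contig per site.
#' @param meanDepthMin,medianLow,medianHigh filter parameters.
#' @param decoyPattern regex for mitochondrial/scaffold contigs.
#' @return list with filtered, imputed `fractions`, the logical `keep`
#'   vector, and removal tallies.
#' @export
filterSites <- function(fractions, depths, chrom, meanDepthMin = 5,
                        medianLow = 0.1, medianHigh = 0.9,
                        decoyPattern = .defaultDecoyPattern) {
  if (!identical(dim(fractions), dim(depths)))
    stop("fractions and depths must be aligned")
  if (length(chrom) != nrow(fractions))
    stop("need one contig per site")
  meanDepth <- rowMeans(depths)
  medFrac <- apply(fractions, 1L, stats::median, na.rm = TRUE)
  okDepth <- meanDepth >= meanDepthMin
  okMedian <- !is.na(medFrac) & medFrac >= medianLow & medFrac <= medianHigh
  okContig <- !grepl(decoyPattern, chrom)
  keep <- okDepth & okMedian & okContig
  if (!any(keep))
    stop("no CpG sites survive filtering")
  out <- fractions[keep, , drop = FALSE]
  ## impute residual missing cells with the site mean fraction
  nMissing <- sum(is.na(out))
  if (nMissing > 0) {
    siteMean <- rowMeans(out, na.rm = TRUE)
    idx <- which(is.na(out), arr.ind = TRUE)
    out[idx] <- siteMean[idx[, 1L]]
  }
  list(fractions = out, keep = keep,
       nRemovedDepth = sum(!okDepth), nRemovedMedian = sum(!okMedian),
       nRemovedContig = sum(!okContig), nImputed = nMissing)
}

#' Center and scale filtered methylation fractions
#'
#' Per-site mean 0 and unit sample SD, on the fraction (beta) scale with no
#' log transform. Zero-variance sites are flagged as in the accessibility
#' arm.
#'
#' @param fractions filtered, complete site-by-sample matrix.
#' @return `SummarizedExperiment` with assay `"z"` and featureKind "dnam".
#' @export
centerScaleMeth <- function(fractions) {
  if (any(is.na(fractions)))
    stop("fractions must be complete (impute via filterSites first)")
  se <- logCenterScale(fractions, pseudocount = 0, logBase = NA,
                       featureKind = "dnam")
  S4Vectors::metadata(se)$provenance <- c(
    "methylation fractions (no transform)",
    "centered (mean 0)", "scaled (sample SD 1, n-1 denominator)")
  se
}

#' Full methylation processing chain
#'
#' fractions -> depth / intermediate-methylation / contig filters ->
#' imputation -> center/scale, with QC counts logged at each step.
#'
#' @param methylated,unmethylated site-by-sample count matrices.
#' @param chrom contig per site.
#' @param meanDepthMin,medianLow,medianHigh,decoyPattern stage parameters.
#' @param log message sink for QC tallies.
#' @return list with the `SummarizedExperiment` (`se`) and the `keep` mask.
#' @export
processMethylation <- function(methylated, unmethylated, chrom,
                               meanDepthMin = 5, medianLow = 0.1,
                               medianHigh = 0.9,
                               decoyPattern = .defaultDecoyPattern,
                               log = message) {
  log(sprintf("dnam: %d sites in", nrow(methylated)))
  fr <- computeFractions(methylated, unmethylated)
  fl <- filterSites(fr$fractions, fr$depths, chrom, meanDepthMin,
                    medianLow, medianHigh, decoyPattern)
  log(sprintf(
    "dnam: %d sites after filters (%d mean depth < %g, %d median outside [%g, %g], %d on decoy contigs; %d cells imputed)",
    nrow(fl$fractions), fl$nRemovedDepth, meanDepthMin, fl$nRemovedMedian,
    medianLow, medianHigh, fl$nRemovedContig, fl$nImputed))
  se <- centerScaleMeth(fl$fractions)
  list(se = se, keep = fl$keep)
}
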