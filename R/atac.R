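## Accessibility matrix construction: summit-distance peak merging,
## coverage/contig filters, RPKM normalization, log-center-scale.

## contigs treated as mitochondrial or unplaced scaffold
.defaultDecoyPattern <- "^(chrM|MT)$|scaffold|chrUn|random"

#' Merge peaks whose summits are closer than a distance cut-off
#'
#' Single-linkage chaining per chromosome: consecutive summits strictly
#' closer than `minSummitDist` join one cluster (so the relation is applied
#' transitively), the merged peak spans min(start)..max(end), the merged
#' summit is the midpoint of the merged interval, and count rows of merged
#' peaks are summed. Unsorted input is sorted internally; peaks on different
#' chromosomes never merge. The operation is idempotent.
#'
#' @param peaks `GRanges` with mcols `name` and absolute `summit`.
#' @param counts optional peak-by-sample matrix, rows aligned with `peaks`
#'   (matched by name when rownames are present).
#' @param minSummitDist bp; summits at exactly this distance do NOT merge.
#' @return list with `peaks` (merged `GRanges`, mcol `nMerged`) and `counts`
#'   (summed rows, or NULL).
#' @export
mergePeaks <- function(peaks, counts = NULL, minSummitDist = 500) {
  if (!is.null(counts)) {
    if (nrow(counts) != length(peaks))
      stop("counts rows must align with peaks")
    if (!is.null(rownames(counts)) && !is.null(peaks$name))
      counts <- counts[peaks$name, , drop = FALSE]
  }
  ord <- order(as.character(GenomicRanges::seqnames(peaks)), peaks$summit)
  peaks <- peaks[ord]
  if (!is.null(counts)) counts <- counts[ord, , drop = FALSE]

  chrom <- as.character(GenomicRanges::seqnames(peaks))
  summit <- peaks$summit
  n <- length(peaks)
  if (n == 0L) return(list(peaks = peaks, counts = counts))
  newClust <- c(TRUE, (chrom[-1] != chrom[-n]) |
                  (summit[-1] - summit[-n] >= minSummitDist))
  clust <- cumsum(newClust)

  starts <- tapply(GenomicRanges::start(peaks), clust, min)
  ends <- tapply(GenomicRanges::end(peaks), clust, max)
  chroms <- tapply(chrom, clust, `[`, 1L)
  sizes <- tabulate(clust)
  nm <- tapply(seq_len(n), clust, function(ix) {
    if (length(ix) == 1L) peaks$name[ix]
    else sprintf("merged_%s", paste(peaks$name[ix], collapse = "_"))
  })
  merged <- GenomicRanges::GRanges(
    as.character(chroms),
    IRanges::IRanges(start = as.integer(starts), end = as.integer(ends)),
    name = as.character(nm),
    ## midpoint summit on the 0-based scale used on disk
    summit = as.integer(floor(((starts - 1L) + ends) / 2)),
    nMerged = as.integer(sizes))
  names(merged) <- merged$name
  if (!is.null(counts)) {
    counts <- rowsum(counts, clust, reorder = TRUE)
    rownames(counts) <- merged$name
  }
  list(peaks = merged, counts = counts)
}

#' Filter peaks on median coverage and contig
#'
#' Retains peaks whose across-sample median raw count is strictly greater
#' than `medianMin` and whose contig is neither mitochondrial nor a
#' scaffold (name match against `decoyPattern`). Order is preserved. The
#' two criteria commute.
#'
#' @param peaks `GRanges` with mcol `name`.
#' @param counts peak-by-sample matrix aligned with `peaks`.
#' @param medianMin reads; the cut is strict (median exactly `medianMin`
#'   is removed).
#' @param decoyPattern regex applied to contig names.
#' @return list with filtered `peaks` and `counts`, plus `nRemovedMedian`,
#'   `nRemovedContig`.
#' @export
filterPeaks <- function(peaks, counts, medianMin = 20,
                        decoyPattern = .defaultDecoyPattern) {
  if (nrow(counts) != length(peaks)) stop("counts rows must align with peaks")
  med <- apply(counts, 1L, stats::median)
  okMedian <- med > medianMin
  okContig <- !grepl(decoyPattern,
                     as.character(GenomicRanges::seqnames(peaks)))
  keep <- okMedian & okContig
  if (!any(keep))
    warning("all peaks removed by filtering; downstream fits will refuse")
  list(peaks = peaks[keep], counts = counts[keep, , drop = FALSE],
       nRemovedMedian = sum(!okMedian), nRemovedContig = sum(!okContig))
}

#' RPKM normalization
#'
#' reads per kilobase per million: `count / (width/1000) / (libSize/1e6)`.
#'
#' @param counts peak-by-sample matrix.
#' @param widths bp per peak (> 0).
#' @param libSizes total reads per sample (> 0). Defaults to the column
#'   sums of `counts` (total in-peak reads; genome-wide mapped totals are
#'   not available post-quantification).
#' @return numeric matrix of RPKM values.
#' @export
rpkmNormalize <- function(counts, widths, libSizes = colSums(counts)) {
  if (length(widths) != nrow(counts))
    stop("widths must have one entry per peak")
  if (length(libSizes) != ncol(counts))
    stop("libSizes must have one entry per sample")
  if (any(widths <= 0)) {
    bad <- which(widths <= 0)[1]
    stop(sprintf("non-positive width for feature %s",
                 rownames(counts)[bad] %||% bad))
  }
  if (any(libSizes <= 0)) {
    bad <- which(libSizes <= 0)[1]
    stop(sprintf("non-positive library size for sample %s",
                 colnames(counts)[bad] %||% bad))
  }
  sweep(sweep(counts, 1L, widths / 1000, "/"), 2L, libSizes / 1e6, "/")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Log-transform, center and scale a feature matrix
#'
#' Values become `log2(value + pseudocount)`, then each feature is centered
#' to mean 0 and scaled to unit sample SD across samples. Zero-variance
#' features stay at all-zeros and are flagged. Returns a
#' `SummarizedExperiment` (features in rows) whose metadata records the
#' processing provenance.
#'
#' @param values non-negative feature-by-sample matrix (e.g. RPKM).
#' @param pseudocount added before the log (default 1).
#' @param logBase base of the log (default 2); `NA` skips the log step (used
#'   for methylation fractions).
#' @param featureKind "atac", "dnam" or "meta", stored in rowData.
#' @param rowRanges optional `GRanges` aligned with rows.
#' @return `SummarizedExperiment` with assay `"z"`.
#' @export
logCenterScale <- function(values, pseudocount = 1, logBase = 2,
                           featureKind = "atac", rowRanges = NULL) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  lv <- if (is.na(logBase)) values else log(values + pseudocount, logBase)
  st <- standardizeColumns(t(lv))
  z <- t(st$z)
  dimnames(z) <- dimnames(values)
  prov <- c(if (!is.na(logBase))
    sprintf("log%g(x + %g)", logBase, pseudocount),
    "centered (mean 0)", "scaled (sample SD 1, n-1 denominator)")
  rd <- S4Vectors::DataFrame(
    feature_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    featureKind = featureKind,
    zeroVariance = st$zeroVariance)
  if (is.null(rowRanges)) {
    SummarizedExperiment::SummarizedExperiment(
      assays = list(z = z), rowData = rd,
      metadata = list(provenance = prov))
  } else {
    S4Vectors::mcols(rowRanges) <- cbind(S4Vectors::mcols(rowRanges), rd)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(z = z), rowRanges = rowRanges,
      metadata = list(provenance = prov))
  }
}

#' Full accessibility processing chain
#'
#' merge summit-close peaks, apply median-coverage and contig filters,
#' RPKM-normalize, then log2/center/scale. Refuses to continue when
#' filtering empties the peak set.
#'
#' @param peaks,counts consensus peak `GRanges` and aligned count matrix.
#' @param minSummitDist,medianMin,decoyPattern,pseudocount stage parameters
#'   (see the individual functions).
#' @param log function used for progress/QC messages (feature counts before
#'   and after each filter).
#' @return list with the final `SummarizedExperiment` (`se`), the retained
#'   `peaks` and raw `counts`, and `libSizes`.
#' @export
processAtac <- function(peaks, counts, minSummitDist = 500, medianMin = 20,
                        decoyPattern = .defaultDecoyPattern,
                        pseudocount = 1, log = message) {
  log(sprintf("atac: %d peaks in", length(peaks)))
  m <- mergePeaks(peaks, counts, minSummitDist)
  log(sprintf("atac: %d peaks after summit merging (<%g bp)",
              length(m$peaks), minSummitDist))
  libSizes <- colSums(m$counts)  # library size before peak filtering
  f <- filterPeaks(m$peaks, m$counts, medianMin, decoyPattern)
  log(sprintf("atac: %d peaks after filters (%d below median %g, %d on decoy contigs)",
              length(f$peaks), f$nRemovedMedian, f$nRemovedContig, medianMin))
  if (length(f$peaks) == 0L)
    stop("no peaks survive filtering; refusing to continue")
  rpkm <- rpkmNormalize(f$counts, GenomicRanges::width(f$peaks), libSizes)
  se <- logCenterScale(rpkm, pseudocount, 2, "atac", rowRanges = f$peaks)
  S4Vectors::metadata(se)$provenance <- c(
    sprintf("merged peaks with summits < %g bp", minSummitDist),
    sprintf("median count > %g, decoy contigs removed", medianMin),
    "RPKM (width, in-peak library size)",
    S4Vectors::metadata(se)$provenance)
  list(se = se, peaks = f$peaks, counts = f$counts, libSizes = libSizes)
}
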