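## Readers and writers for every on-disk format the pipeline touches.
## Coordinate conventions: BED files are 0-based half-open on disk;
## bismark coverage files are 1-based. Everything is normalized to 1-based
## closed GRanges (the GenomicRanges convention) at read time.

.ioStop <- function(path, lineno, line, why) {
  stop(sprintf("%s:%d: %s [%s]", path, lineno, why, line), call. = FALSE)
}

#' Read / write sample metadata
#'
#' Tab-separated, one row per sample: sample_id, age, sex, breed,
#' breed_weight_kg, weight_category, exercise, then one column per cell
#' type (percent of parent gate). '#' lines are provenance headers.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readMetadata <- function(path) {
  df <- readTsvSkipHeader(path)
  need <- c("sample_id", "age", "sex", "breed", "breed_weight_kg",
            "weight_category", "exercise")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing metadata columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  cellCols <- grep("^cell\\.", names(df), value = TRUE)
  bad <- cellCols[vapply(df[cellCols], function(v)
    any(v < 0 | v > 100, na.rm = TRUE), logical(1))]
  if (length(bad))
    stop(sprintf("%s: cell proportions outside [0, 100] in: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  df
}

#' @rdname readMetadata
#' @param metadata data.frame as returned by [simulateCohort()].
#' @export
writeMetadata <- function(metadata, path) {
  writeTsvWithHeader(metadata, path)
}

#' Read / write bismark-style CpG coverage files
#'
#' Dialect: chrom, start (1-based), end, methylation_percent,
#' count_methylated, count_unmethylated; tab-separated, no header. Lines
#' with zero total depth are accepted (the fraction is undefined there and
#' treated as missing downstream).
#'
#' @param path coverage file for one sample.
#' @return data.frame with columns chrom, pos, methylated, unmethylated.
#' @export
readCoverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      methylated = integer(), unmethylated = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 6L)
      .ioStop(path, i, lines[i], "expected 6 tab-separated fields")
    m <- suppressWarnings(as.integer(parts[[i]][5]))
    u <- suppressWarnings(as.integer(parts[[i]][6]))
    if (is.na(m) || is.na(u) || m < 0 || u < 0)
      .ioStop(path, i, lines[i], "counts must be non-negative integers")
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    methylated = as.integer(vapply(parts, `[`, "", 5L)),
    unmethylated = as.integer(vapply(parts, `[`, "", 6L)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$pos)))
    .ioStop(path, which(is.na(df$pos))[1], lines[which(is.na(df$pos))[1]],
            "non-numeric position")
  df
}

#' @rdname readCoverage
#' @param chrom,pos,methylated,unmethylated per-site vectors for one sample.
#' @export
writeCoverage <- function(chrom, pos, methylated, unmethylated, path) {
  depth <- methylated + unmethylated
  pct <- ifelse(depth > 0, 100 * methylated / depth, 0)
  df <- data.frame(chrom, pos, pos, format(pct, digits = 10, trim = TRUE),
                   methylated, unmethylated)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a narrowPeak-like BED6+1 peak file
#'
#' Columns: chrom, start (0-based), end (half-open), name, score, strand,
#' summit_offset (relative to start). Returned as a `GRanges` (1-based)
#' with mcols `name` and absolute `summit`.
#'
#' @param path peak file.
#' @return `GRanges`.
#' @export
readPeaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(GenomicRanges::GRanges(name = character(), summit = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 7L)
      .ioStop(path, i, lines[i], "expected 7 tab-separated fields (BED6+1)")
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e)) .ioStop(path, i, lines[i], "non-numeric coordinates")
    if (s >= e) .ioStop(path, i, lines[i], "start must be < end")
    off <- suppressWarnings(as.integer(p[7]))
    if (is.na(off) || off < 0 || s + off >= e)
      .ioStop(path, i, lines[i], "summit offset outside [0, width)")
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- as.integer(vapply(parts, `[`, "", 2L))
  end <- as.integer(vapply(parts, `[`, "", 3L))
  nm <- vapply(parts, `[`, "", 4L)
  if (anyDuplicated(nm))
    stop(sprintf("%s: duplicate peak names", path), call. = FALSE)
  off <- as.integer(vapply(parts, `[`, "", 7L))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end),
                               name = nm, summit = start0 + off)
  names(gr) <- nm
  gr
}

#' @rdname readPeaks
#' @param peaks `GRanges` with mcols `name` and absolute `summit`.
#' @export
writePeaks <- function(peaks, path) {
  start0 <- GenomicRanges::start(peaks) - 1L
  df <- data.frame(
    as.character(GenomicRanges::seqnames(peaks)), start0,
    GenomicRanges::end(peaks), peaks$name, 0L, ".",
    peaks$summit - start0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a feature-by-sample count matrix
#'
#' TSV with the feature name in the first column and one column per sample.
#'
#' @param path file path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
readCountMatrix <- function(path) {
  df <- readTsvSkipHeader(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountMatrix
#' @param counts matrix with rownames.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  writeTsvWithHeader(df, path)
}

#' Read / write BED interval tracks (chromatin states, genes)
#'
#' `readStates()` expects 4 columns (chrom, start, end, state "1".."13");
#' `readGenes()` expects BED6 (chrom, start, end, name, score, strand).
#' On-disk coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return `GRanges`.
#' @export
readStates <- function(path) {
  gr <- .readBedN(path, 4L)
  states <- vapply(gr$fields, `[`, "", 4L)
  if (!all(states %in% as.character(1:13)))
    stop(sprintf("%s: chromatin state labels must be in 1..13", path),
         call. = FALSE)
  out <- gr$gr
  out$state <- states
  out$fields <- NULL
  out
}

#' @rdname readStates
#' @export
readGenes <- function(path) {
  gr <- .readBedN(path, 6L)
  out <- gr$gr
  nm <- vapply(gr$fields, `[`, "", 4L)
  if (anyDuplicated(nm))
    stop(sprintf("%s: duplicate gene names", path), call. = FALSE)
  out$gene_name <- nm
  out$score <- as.integer(vapply(gr$fields, `[`, "", 5L))
  GenomicRanges::strand(out) <- vapply(gr$fields, `[`, "", 6L)
  out$fields <- NULL
  names(out) <- nm
  out
}

.readBedN <- function(path, nfields) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    return(list(gr = gr, fields = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != nfields)
      .ioStop(path, i, lines[i],
              sprintf("expected %d tab-separated fields", nfields))
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e)) .ioStop(path, i, lines[i], "non-numeric coordinates")
    if (s >= e) .ioStop(path, i, lines[i], "start must be < end")
  }
  gr <- GenomicRanges::GRanges(
    vapply(parts, `[`, "", 1L),
    IRanges::IRanges(start = as.integer(vapply(parts, `[`, "", 2L)) + 1L,
                     end = as.integer(vapply(parts, `[`, "", 3L))))
  list(gr = gr, fields = parts)
}

#' @rdname readStates
#' @param states `GRanges` with mcols `state`.
#' @export
writeStates <- function(states, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(states)),
                   GenomicRanges::start(states) - 1L,
                   GenomicRanges::end(states), states$state)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname readStates
#' @param genes `GRanges` with mcols `gene_name`, `score` and strand.
#' @export
writeGenes <- function(genes, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(genes)),
                   GenomicRanges::start(genes) - 1L,
                   GenomicRanges::end(genes), genes$gene_name, genes$score,
                   as.character(GenomicRanges::strand(genes)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits metadata.tsv, one <sample_id>.cov per sample, peaks.bed,
#' atac_counts.tsv, states.bed, genes.bed and truth.json (the ground-truth
#' manifest naming every truly age-associated feature and its slope). All
#' files round-trip losslessly through the package readers; counts
#' round-trip bitwise.
#'
#' @param dataset output of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMetadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  covdir <- file.path(dir, "coverage")
  if (!dir.exists(covdir)) dir.create(covdir)
  for (j in seq_len(ncol(dataset$meth$methylated))) {
    sid <- colnames(dataset$meth$methylated)[j]
    writeCoverage(dataset$meth$sites$chrom, dataset$meth$sites$pos,
                  dataset$meth$methylated[, j], dataset$meth$unmethylated[, j],
                  file.path(covdir, paste0(sid, ".cov")))
  }
  writePeaks(dataset$atac$peaks, file.path(dir, "peaks.bed"))
  writeCountMatrix(dataset$atac$counts, file.path(dir, "atac_counts.tsv"))
  writeStates(dataset$states, file.path(dir, "states.bed"))
  writeGenes(dataset$genes, file.path(dir, "genes.bed"))
  truth <- list(
    meth_age_assoc_ids = dataset$meth$truth$ageAssocIds,
    meth_slopes = as.list(dataset$meth$truth$slopes[
      dataset$meth$truth$ageAssocIds]),
    atac_age_assoc_ids = dataset$atac$truth$ageAssocIds,
    atac_slopes = as.list(dataset$atac$truth$slopes[
      dataset$atac$truth$ageAssocIds]),
    cell_slopes = as.list(dataset$cellTruth$cellSlopes))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @return list shaped like the output of [simulateDataset()] (without the
#'   config), with the truth manifest under `truth`.
#' @export
readDataset <- function(dir) {
  metadata <- readMetadata(file.path(dir, "metadata.tsv"))
  covdir <- file.path(dir, "coverage")
  covs <- lapply(metadata$sample_id, function(sid)
    readCoverage(file.path(covdir, paste0(sid, ".cov"))))
  names(covs) <- metadata$sample_id
  ref <- covs[[1]]
  ids <- sprintf("cpg_%s_%d", ref$chrom, ref$pos)
  meth <- sapply(covs, `[[`, "methylated")
  unmeth <- sapply(covs, `[[`, "unmethylated")
  rownames(meth) <- rownames(unmeth) <- ids
  peaks <- readPeaks(file.path(dir, "peaks.bed"))
  counts <- readCountMatrix(file.path(dir, "atac_counts.tsv"))
  states <- readStates(file.path(dir, "states.bed"))
  genes <- readGenes(file.path(dir, "genes.bed"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(metadata = metadata,
       meth = list(sites = data.frame(chrom = ref$chrom, pos = ref$pos,
                                      id = ids, stringsAsFactors = FALSE),
                   methylated = meth, unmethylated = unmeth),
       atac = list(peaks = peaks, counts = counts),
       states = states, genes = genes, truth = truth)
}
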