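#' @useDynLib epiAgeClock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Column-wise centering and scaling
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n - 1 denominator). Zero-variance columns are left at zero
#' after centering and flagged rather than producing NaN.
#'
#' @param x numeric matrix (observations in rows).
#' @param center,scale logical; apply centering / scaling.
#' @return list with elements `z` (transformed matrix), `mean`, `sd`
#'   (per-column statistics used) and `zeroVariance` (logical vector).
#' @export
standardizeColumns <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  z <- sweep(x, 2L, mu, "-")
  sdev <- apply(z, 2L, stats::sd)
  zeroVar <- !is.na(sdev) & sdev < .Machine$double.eps^0.5
  if (scale) {
    sc <- ifelse(zeroVar | is.na(sdev), 1, sdev)
    z <- sweep(z, 2L, sc, "/")
  } else {
    sdev <- rep(1, ncol(x))
  }
  list(z = z, mean = mu, sd = sdev, zeroVariance = zeroVar)
}

#' Rounded percentage of a count
#'
#' Integer-rounded percentage `k` out of `n`, as used in cohort summary
#' reporting (e.g. 68 of 71 sterilized animals is 96\%).
#'
#' @param k,n non-negative counts, `n > 0`.
#' @return numeric percentage rounded to the nearest integer.
#' @export
roundedPercent <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  round(100 * k / n)
}

## md5 of the serialized object via a temp file (tools:: only needs a path)
configHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

pkgVersion <- function() {
  as.character(utils::packageVersion("epiAgeClock"))
}

## write a data.frame as TSV with '#' provenance header lines
writeTsvWithHeader <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# epiAgeClock %s", pkgVersion()), extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsvSkipHeader <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}
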