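## Per-feature age association: ordinary least squares with the covariate
## set age + breed weight + sex + exercise + the two age-associated T-cell
## proportions, BH adjustment, and direction classification.

#' Ordinary least squares fit
#'
#' QR-based least squares with t-distribution inference. Errors on rank
#' deficiency, naming the collinear columns.
#'
#' @param y response vector.
#' @param X design matrix (include an intercept column yourself if wanted).
#' @return list with `coefficients`, `se`, `t`, `p` (two-sided), `residuals`,
#'   `fitted`, `r2`, `adjR2`, `df` (residual degrees of freedom), `sigma`.
#' @examples
#' X <- cbind(1, rnorm(20))
#' y <- X %*% c(2, 3)
#' olsFit(y, X)$coefficients  # exactly c(2, 3)
#' @export
olsFit <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- nrow(X); pcol <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || anyNA(X)) stop("rows must be complete (no NA)")
  qrX <- qr(X)
  if (qrX$rank < pcol) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):pcol]] %||%
      qrX$pivot[(qrX$rank + 1):pcol]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  if (n <= qrX$rank) stop("need more observations than parameters")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - qrX$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  adjR2 <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / df else NA_real_
  list(coefficients = beta, se = se, t = tval, p = p,
       residuals = res, fitted = fitted, r2 = r2, adjR2 = adjR2,
       df = df, sigma = sqrt(sigma2))
}

## the covariate design shared by every per-feature model:
## intercept + age + breed weight + sex indicator + exercise dummies +
## cell.CD8 + cell.DN
.ageModelDesign <- function(meta) {
  need <- c("age", "breed_weight_kg", "sex", "exercise", "cell.CD8", "cell.DN")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("metadata is missing covariates: %s",
                 paste(miss, collapse = ", ")))
  if (anyNA(meta[need])) stop("metadata covariates contain missing values")
  ex <- factor(meta$exercise)
  exDummies <- if (nlevels(ex) > 1)
    stats::model.matrix(~ ex)[, -1, drop = FALSE] else NULL
  X <- cbind(`(Intercept)` = 1, age = meta$age,
             weight = meta$breed_weight_kg,
             sexM = as.numeric(meta$sex == "M"))
  if (!is.null(exDummies)) {
    colnames(exDummies) <- sub("^ex", "exercise", colnames(exDummies))
    X <- cbind(X, exDummies)
  }
  cbind(X, cell.CD8 = meta$cell.CD8, cell.DN = meta$cell.DN)
}

#' Per-feature age models
#'
#' Fits every feature as a function of age plus covariates (breed mean
#' weight, sex, exercise category, and the CD62L+/CD44+ CD8 and DN T-cell
#' proportions), collecting the age term's effect, standard error, t, p,
#' BH-adjusted q and direction. A single QR factorization of the shared
#' design is reused across features.
#'
#' @param features `SummarizedExperiment` (assay `"z"`) or feature-by-sample
#'   matrix.
#' @param meta metadata data.frame covering all samples (rows aligned with
#'   the sample columns of `features`).
#' @param qThreshold FDR cut-off handed to [classifyDirection()].
#' @param adjust "BH" (default) or "BY", see [bhAdjust()].
#' @return data.frame: feature_id, beta_age, se, t, p, q, direction.
#' @export
fitFeatureAgeModels <- function(features, meta, qThreshold = 0.05,
                                adjust = c("BH", "BY")) {
  adjust <- match.arg(adjust)
  mat <- if (methods::is(features, "SummarizedExperiment"))
    SummarizedExperiment::assay(features, "z") else as.matrix(features)
  if (ncol(mat) != nrow(meta))
    stop("metadata must cover all samples (one row per sample column)")
  X <- .ageModelDesign(meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate design is rank deficient")
  n <- nrow(X); df <- n - qrX$rank
  Y <- t(mat)                               # samples x features
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  ageIdx <- which(colnames(X) == "age")
  seAge <- sqrt(sigma2 * XtXinv[ageIdx, ageIdx])
  bAge <- beta[ageIdx, ]
  tval <- bAge / seAge
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    beta_age = as.numeric(bAge), se = as.numeric(seAge),
    t = as.numeric(tval), p = as.numeric(p), stringsAsFactors = FALSE)
  out$q <- bhAdjust(out$p, method = adjust)
  classifyDirection(out, qThreshold)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) adjustment
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} (m / j) p_(j), capped at 1,
#' mapped back to input order. The BY variant multiplies by sum(1/k).
#'
#' @param p p-values in [0, 1].
#' @param method "BH" (default) or "BY".
#' @return adjusted values, same order as `p`.
#' @export
bhAdjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p, decreasing = TRUE)          # largest first for cummin
  i <- m:1L                                 # ranks of the sorted sequence
  q <- pmin(1, cummin(cm * (m / i) * p[o]))
  q[order(o)]
}

#' Screen metadata variables for age association
#'
#' Numeric variables (cell-type proportions) are regressed on age by OLS
#' (slope, t, p); categorical variables are tested by one-way ANOVA of age
#' across levels (F, p). BH adjustment is applied across the whole screen.
#' Categories with fewer than 2 observed levels are skipped with a message.
#'
#' @param meta cohort metadata data.frame.
#' @param categorical which metadata columns to treat as categorical
#'   (default: sex, breed-independent survey fields present).
#' @param qThreshold FDR cut-off for the `significant` flag.
#' @return data.frame: variable, type, estimate (slope or NA), statistic,
#'   p, q, significant.
#' @export
screenMetadataAge <- function(meta, categorical = c("sex", "exercise",
                                                    "weight_category"),
                              qThreshold = 0.05) {
  cellCols <- grep("^cell\\.", names(meta), value = TRUE)
  rows <- list()
  for (v in cellCols) {
    f <- olsFit(meta[[v]], cbind(1, age = meta$age))
    rows[[v]] <- data.frame(variable = v, type = "numeric",
                            estimate = f$coefficients[2],
                            statistic = f$t[2], p = f$p[2])
  }
  for (v in intersect(categorical, names(meta))) {
    g <- factor(meta[[v]])
    if (nlevels(droplevels(g)) < 2L) {
      message(sprintf("screenMetadataAge: skipping '%s' (fewer than 2 levels)", v))
      next
    }
    a <- stats::anova(stats::lm(meta$age ~ g))
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            estimate = NA_real_,
                            statistic = a$`F value`[1], p = a$`Pr(>F)`[1])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bhAdjust(out$p)
  out$significant <- out$q < qThreshold
  out
}

#' Classify features as age-increasing, age-decreasing or ns
#'
#' increasing/decreasing requires BH q below the threshold; everything else
#' is "ns".
#'
#' @param results data.frame with columns `beta_age` and `q`.
#' @param qThreshold FDR cut-off (default 0.05).
#' @return `results` with a `direction` column.
#' @export
classifyDirection <- function(results, qThreshold = 0.05) {
  stopifnot(all(c("beta_age", "q") %in% names(results)))
  results$direction <- ifelse(
    results$q < qThreshold & results$beta_age > 0, "increasing",
    ifelse(results$q < qThreshold & results$beta_age < 0, "decreasing", "ns"))
  results
}
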