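## The elastic-net age clock: design construction with meta-features,
## the coordinate-descent solver front-end, the lambda path, inner K-fold
## cross-validation for lambda, and the outer manual leave-one-out loop.

#' Build the clock design matrix
#'
#' Column-concatenates the epigenetic feature block(s) (samples x features,
#' from the processed `SummarizedExperiment`s), all cell-type proportion
#' columns, and breed weight category coded ordinally (small=1, medium=2,
#' large=3) — the "meta features". All columns are standardized. Sex is
#' deliberately not a predictor. For the combined data type pass both
#' feature sets in `features`.
#'
#' @param features a `SummarizedExperiment` or list of them (ATAC and/or
#'   DNAm blocks, concatenated in order).
#' @param meta cohort metadata (rows aligned with samples).
#' @param metaFeatures logical; append cell proportions and weight category.
#' @param standardize logical; standardize all columns (default TRUE).
#' @return samples x predictors matrix with attribute `"blocks"` naming the
#'   column ranges per block.
#' @export
buildDesign <- function(features, meta, metaFeatures = TRUE,
                        standardize = TRUE) {
  if (methods::is(features, "SummarizedExperiment"))
    features <- list(features)
  blocks <- lapply(features, function(se)
    t(SummarizedExperiment::assay(se, "z")))
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L || ns[1] != nrow(meta))
    stop(sprintf(
      "sample mismatch between feature blocks (%s) and metadata (%d rows)",
      paste(ns, collapse = ", "), nrow(meta)))
  X <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature ids across blocks")
  blockInfo <- list(epigenetic = seq_len(ncol(X)))
  if (metaFeatures) {
    cellCols <- grep("^cell\\.", names(meta), value = TRUE)
    wc <- c(small = 1, medium = 2, large = 3)[meta$weight_category]
    if (anyNA(wc)) stop("unknown weight_category level")
    M <- cbind(as.matrix(meta[cellCols]), weight_category = unname(wc))
    blockInfo$meta <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
  }
  if (standardize) X <- standardizeColumns(X)$z
  rownames(X) <- meta$sample_id
  attr(X, "blocks") <- blockInfo
  X
}

#' Fit the elastic net by cyclic coordinate descent
#'
#' Minimizes (1/2N) RSS + lambda ((1-alpha)/2 ||b||_2^2 + alpha ||b||_1) by
#' soft-thresholded coordinate updates with residual tracking. X and y are
#' centered internally, so the intercept is mean(y) for centered
#' predictors. Convergence is declared when the largest coefficient change
#' in a sweep drops below `tol * sd(y)`.
#'
#' @param X samples x predictors matrix (standardized columns expected).
#' @param y response (ages, years).
#' @param alpha mixing parameter in [0, 1] (0.5 = equal ridge/lasso blend).
#' @param lambda penalty weight >= 0.
#' @param warmStart optional coefficient vector to start from.
#' @param tol relative convergence tolerance (default 1e-7).
#' @param maxit maximum number of coordinate sweeps.
#' @param trace logical; record the objective after every sweep (exposed as
#'   attribute `"objTrace"` for diagnostics).
#' @return an [ElasticNetFit-class].
#' @export
fitElasticNet <- function(X, y, alpha = 0.5, lambda, warmStart = NULL,
                          tol = 1e-7, maxit = 100000L, trace = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("dimension mismatch between X and y")
  if (nrow(X) < 3L) stop("need at least 3 samples")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  cx <- colMeans(X)
  Xc <- sweep(X, 2L, cx, "-")
  ym <- mean(y)
  sdy <- stats::sd(y)
  tolAbs <- tol * if (sdy > 0) sdy else 1
  b0 <- if (is.null(warmStart)) rep(0, ncol(X)) else as.numeric(warmStart)
  fit <- .enetFitCpp(Xc, y - ym, alpha, lambda, b0, tolAbs,
                     as.integer(maxit), trace)
  if (!fit$converged)
    stop(sprintf(
      "coordinate descent did not converge in %d sweeps (last objective %.6g)",
      maxit, fit$objective))
  beta <- stats::setNames(fit$beta,
                          colnames(X) %||% as.character(seq_len(ncol(X))))
  intercept <- ym - sum(cx * beta)
  out <- new("ElasticNetFit", intercept = intercept, beta = beta,
             lambda = lambda, alpha = alpha,
             selected = names(beta)[beta != 0],
             objective = fit$objective, nIter = as.integer(fit$nIter),
             converged = fit$converged)
  if (trace) attr(out, "objTrace") <- fit$objTrace
  out
}

#' Regularization path
#'
#' Log-spaced decreasing sequence from lambda_max (the smallest penalty
#' yielding the all-zero solution, `max_j |x_j'(y - ybar)| / (N alpha)`)
#' down to `epsRatio * lambda_max`. The default `epsRatio` follows the
#' reference-implementation convention: 1e-3 when N > p, else 1e-2. For
#' pure ridge (alpha = 0) lambda_max is undefined and the alpha = 0.001
#' value is used as a cap.
#'
#' @param X,y as in [fitElasticNet()].
#' @param alpha mixing parameter.
#' @param nLambda path length (default 100).
#' @param epsRatio ratio of smallest to largest lambda.
#' @return decreasing numeric vector of length `nLambda`.
#' @export
lambdaPath <- function(X, y, alpha = 0.5, nLambda = 100, epsRatio = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X)
  if (is.null(epsRatio)) epsRatio <- if (N > ncol(X)) 1e-3 else 1e-2
  Xc <- sweep(X, 2L, colMeans(X), "-")
  aEff <- max(alpha, 0.001)
  lmax <- max(abs(crossprod(Xc, y - mean(y)))) / (N * aEff)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * epsRatio), length.out = nLambda))
}

#' Select lambda by K-fold cross-validation
#'
#' Splits the samples into `k` folds (assignment drawn from the current
#' RNG stream, so seed the caller for reproducibility), fits the
#' warm-started path on each training fold, and averages held-out squared
#' error per lambda. The selected lambda minimizes mean CV MSE; ties go to
#' the larger (more penalized) lambda. The one-standard-error rule is
#' available via `rule = "1se"`.
#'
#' @param X,y as in [fitElasticNet()].
#' @param alpha mixing parameter.
#' @param k number of folds (k = N gives inner leave-one-out).
#' @param path lambda sequence (default [lambdaPath()]).
#' @param rule "min" (default) or "1se".
#' @param foldid optional integer fold assignment (overrides the draw).
#' @param tol,maxit solver controls.
#' @return list: `lambda` (selected), `path`, `cvm` (mean CV MSE per
#'   lambda), `cvsd` (SE of the fold means), `rule`.
#' @export
cvSelectLambda <- function(X, y, alpha = 0.5, k = 10, path = NULL,
                           rule = c("min", "1se"), foldid = NULL,
                           tol = 1e-6, maxit = 100000L) {
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X)
  if (k > N) stop("k must not exceed the number of samples")
  if (is.null(path)) path <- lambdaPath(X, y, alpha)
  if (is.null(foldid)) foldid <- sample(rep(seq_len(k), length.out = N))
  sdy <- stats::sd(y)
  tolAbs <- tol * if (sdy > 0) sdy else 1
  L <- length(path)
  errs <- matrix(NA_real_, nrow = k, ncol = L)
  for (f in seq_len(k)) {
    tr <- foldid != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    cx <- colMeans(Xtr); ym <- mean(ytr)
    pf <- .enetPathCpp(sweep(Xtr, 2L, cx, "-"), ytr - ym, alpha, path,
                       tolAbs, as.integer(maxit))
    Xte <- sweep(X[!tr, , drop = FALSE], 2L, cx, "-")
    pred <- ym + Xte %*% pf$beta                    # n_test x L
    errs[f, ] <- colMeans((pred - y[!tr])^2)
  }
  cvm <- colMeans(errs)
  cvsd <- apply(errs, 2L, stats::sd) / sqrt(k)
  iMin <- which.min(cvm)                 # first index = largest lambda on ties
  iSel <- if (rule == "1se") {
    thr <- cvm[iMin] + cvsd[iMin]
    which(cvm <= thr)[1]                 # largest lambda within one SE
  } else iMin
  list(lambda = path[iSel], path = path, cvm = cvm, cvsd = cvsd, rule = rule)
}

#' Leave-one-out cross-validated elastic-net clock
#'
#' The outer "manual" LOOCV loop: for each sample, inner K-fold
#' cross-validation selects lambda on the remaining N-1 samples, the final
#' model is refit there, and the held-out sample's age is predicted. With
#' `scaling = "global"` the design is used as passed (standardized once
#' before the loop, the order used by the emulated study); with
#' `scaling = "fold"` each training fold is restandardized and its
#' statistics applied to the held-out row (leakage-free).
#'
#' @param X design matrix from [buildDesign()].
#' @param y ages (years).
#' @param alpha mixing parameter (default 0.5, the equal ridge/lasso blend).
#' @param k inner folds (default 10).
#' @param scaling "global" or "fold".
#' @param dataType label stored in the result ("atac", "dnam", "combined").
#' @param nLambda,rule,tol,maxit passed to the inner machinery.
#' @param tolFinal tighter tolerance for the final per-fold fit (so every
#'   returned model passes the KKT certificate at 1e-6 * sd(y)).
#' @return a [LoocvClockResult-class]: exactly N folds, N held-out
#'   predictions, per-feature selection frequencies.
#' @export
loocvClock <- function(X, y, alpha = 0.5, k = 10,
                       scaling = c("global", "fold"),
                       dataType = "atac", nLambda = 100,
                       rule = c("min", "1se"), tol = 1e-6,
                       maxit = 100000L, tolFinal = 1e-9) {
  scaling <- match.arg(scaling)
  rule <- match.arg(rule)
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X)
  if (N < 4L) stop("need at least 4 samples for nested LOOCV")
  fits <- vector("list", N)
  pred <- lambdas <- numeric(N)
  nSel <- integer(N)
  freq <- stats::setNames(integer(ncol(X)), colnames(X))
  for (i in seq_len(N)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    xte <- X[i, , drop = FALSE]
    if (scaling == "fold") {
      st <- standardizeColumns(Xtr)
      Xtr <- st$z
      sc <- ifelse(st$zeroVariance, 1, st$sd)
      xte <- sweep(sweep(xte, 2L, st$mean, "-"), 2L, sc, "/")
      xte[, st$zeroVariance] <- 0
    }
    cv <- tryCatch(
      cvSelectLambda(Xtr, ytr, alpha, k, rule = rule, tol = tol,
                     maxit = maxit,
                     path = lambdaPath(Xtr, ytr, alpha, nLambda)),
      error = function(e) stop(sprintf("LOOCV fold %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    fit <- fitElasticNet(Xtr, ytr, alpha, cv$lambda, tol = tolFinal,
                         maxit = maxit)
    fits[[i]] <- fit
    pred[i] <- predictAge(fit, xte)
    lambdas[i] <- cv$lambda
    nSel[i] <- length(fit@selected)
    freq[fit@selected] <- freq[fit@selected] + 1L
  }
  new("LoocvClockResult",
      predictions = data.frame(
        sample_id = rownames(X) %||% as.character(seq_len(N)),
        age = y, predicted_age = pred, lambda = lambdas,
        n_selected = nSel, stringsAsFactors = FALSE),
      fits = fits, selectionFreq = freq, dataType = dataType,
      scaling = scaling)
}

#' Predict age from a fitted elastic net
#'
#' The linear predictor intercept + x' beta. `x` must be on the same
#' (standardized) scale as the training design.
#'
#' @param fit an [ElasticNetFit-class].
#' @param x predictor vector or matrix (rows = samples).
#' @return predicted age(s), years.
#' @export
predictAge <- function(fit, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(fit@beta))
    stop(sprintf("predictor length %d does not match model size %d",
                 ncol(x), length(fit@beta)))
  drop(fit@intercept + x %*% fit@beta)
}

#' Karush-Kuhn-Tucker certificate for an elastic-net fit
#'
#' Verifies the stationarity conditions at the returned solution: with
#' rho_j = (1/N) x_j' r (r the fitted residual, x_j the centered column),
#' nonzero coefficients must satisfy
#' |rho_j - lambda (1-alpha) beta_j - lambda alpha sign(beta_j)| below
#' tolerance, and zero coefficients |rho_j| <= lambda alpha + tolerance.
#' The tolerance is `tol * sd(y)`.
#'
#' @param fit an [ElasticNetFit-class].
#' @param X,y the training data the fit was produced from.
#' @param tol relative tolerance (default 1e-6).
#' @return list with `ok` (logical) and `maxViolation`.
#' @export
kktCheck <- function(fit, X, y, tol = 1e-6) {
  X <- as.matrix(X); y <- as.numeric(y)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  N <- nrow(X)
  r <- y - fit@intercept - drop(X %*% fit@beta)
  rho <- drop(crossprod(Xc, r)) / N
  la <- fit@lambda * fit@alpha
  lr <- fit@lambda * (1 - fit@alpha)
  nz <- fit@beta != 0
  violNz <- if (any(nz))
    abs(rho[nz] - lr * fit@beta[nz] - la * sign(fit@beta[nz])) else 0
  violZ <- if (any(!nz)) pmax(0, abs(rho[!nz]) - la) else 0
  mv <- max(violNz, violZ)
  tolAbs <- tol * max(stats::sd(y), .Machine$double.eps)
  list(ok = mv < tolAbs, maxViolation = mv)
}
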