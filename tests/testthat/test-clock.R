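test_that("design construction concatenates blocks and meta-features", {
  cfg <- simConfig(nSamples = 12, nCpgSites = 30, nAtacPeaks = 25,
                   nDecoyFeatures = 2, seed = 51)
  sim <- simulateDataset(cfg)
  atac <- processAtac(sim$atac$peaks, sim$atac$counts,
                      log = function(...) invisible())
  meth <- processMethylation(sim$meth$methylated, sim$meth$unmethylated,
                             sim$meth$sites$chrom,
                             log = function(...) invisible())
  X <- buildDesign(atac$se, sim$metadata)
  pAtac <- nrow(atac$se)
  expect_equal(ncol(X), pAtac + 31 + 1)      # features + cell panel + weight
  expect_equal(nrow(X), 12)
  ## combined design is the union of blocks plus meta, no duplicates
  Xc <- buildDesign(list(atac$se, meth$se), sim$metadata)
  expect_equal(ncol(Xc), pAtac + nrow(meth$se) + 32)
  expect_false(anyDuplicated(colnames(Xc)) > 0)
  ## standardization: mean 0, sd 1 for non-constant columns
  expect_true(all(abs(colMeans(X)) < 1e-10))
  sds <- apply(X, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-8))
  ## sample mismatch errors
  expect_error(buildDesign(atac$se, sim$metadata[-1, ]), "mismatch")
})

test_that("coordinate descent matches OLS, closed-form ridge and the null model", {
  d <- signalDesign(30, 6, seed = 13)
  ## lambda = 0 -> OLS
  f0 <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = 0, tol = 1e-12)
  ols <- olsFit(d$y, cbind(1, d$X))
  expect_lt(max(abs(f0@beta - ols$coefficients[-1])), 1e-8)
  expect_lt(abs(f0@intercept - ols$coefficients[1]), 1e-8)
  ## alpha = 0 -> ridge closed form under the 1/(2N) convention
  lam <- 0.7
  Xc <- scale(d$X, scale = FALSE); N <- nrow(d$X)
  ridge <- solve(crossprod(Xc) / N + lam * diag(ncol(d$X)),
                 crossprod(Xc, d$y - mean(d$y)) / N)
  fr <- fitElasticNet(d$X, d$y, alpha = 0, lambda = lam, tol = 1e-12)
  expect_lt(max(abs(fr@beta - drop(ridge))), 1e-8)
  ## lambda >= lambda_max -> exactly zero (KKT at the origin)
  lmax <- max(abs(crossprod(Xc, d$y - mean(d$y)))) / (N * 0.5)
  fz <- fitElasticNet(d$X, d$y, alpha = 0.5, lambda = lmax * (1 + 1e-12))
  expect_true(all(fz@beta == 0))
  expect_equal(fz@intercept, mean(d$y))
  expect_equal(length(fz@selected), 0)
})

test_that("every fit satisfies the KKT certificate and a monotone objective", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(20:60, 1); p <- sample(5:40, 1)
    X <- scale(matrix(rnorm(n * p), n))
    colnames(X) <- paste0("v", seq_len(p))
    y <- drop(X[, 1] + rnorm(n))
    lam <- runif(1, 0.01, 0.5)
    f <- fitElasticNet(X, y, alpha = 0.5, lambda = lam, tol = 1e-10,
                       trace = TRUE)
    k <- kktCheck(f, X, y)
    expect_true(k$ok, label = sprintf("instance %d violation %.2e", i,
                                      k$maxViolation))
    tr <- attr(f, "objTrace")
    expect_true(all(diff(tr) <= 1e-12))   # objective never increases
  }
})

test_that("solver agrees with glmnet along a warm-started path", {
  skip_if_not_installed("glmnet")
  set.seed(15)
  n <- 40; p <- 60
  X <- scale(matrix(rnorm(n * p), n)); colnames(X) <- paste0("v", 1:p)
  y <- drop(X[, 1:4] %*% c(2, -1, 1, 0.5) + rnorm(n))
  ## glmnet internally standardizes the response to unit 1/n-variance, so
  ## hand it a unit-variance response for an apples-to-apples lambda scale
  ys <- y / sqrt(mean((y - mean(y))^2))
  path <- lambdaPath(X, ys, 0.5, 30)
  g <- glmnet::glmnet(X, ys, alpha = 0.5, lambda = path,
                      standardize = FALSE, thresh = 1e-14)
  for (l in seq(1, 30, by = 4)) {
    f <- fitElasticNet(X, ys, alpha = 0.5, lambda = path[l], tol = 1e-12)
    denom <- max(abs(as.numeric(g$beta[, l])), 1)
    expect_lt(max(abs(f@beta - as.numeric(g$beta[, l]))) / denom, 1e-5)
  }
})

test_that("lambda path starts at the null model and decreases log-linearly", {
  d <- signalDesign(25, 10, seed = 16)
  path <- lambdaPath(d$X, d$y, alpha = 0.5, nLambda = 40)
  expect_equal(length(path), 40)
  expect_true(all(diff(path) < 0))
  ## lambda_max from the brute-force column scan
  Xc <- scale(d$X, scale = FALSE)
  lmaxOracle <- max(abs(crossprod(Xc, d$y - mean(d$y)))) / (25 * 0.5)
  expect_equal(path[1], lmaxOracle, tolerance = 1e-12)
  f <- fitElasticNet(d$X, d$y, 0.5, path[1])
  expect_equal(length(f@selected), 0)          # first lambda -> null model
  ## N <= p switches the default floor from 1e-3 to 1e-2
  pathWide <- lambdaPath(matrix(rnorm(25 * 30), 25), d$y, 0.5, 10)
  expect_equal(pathWide[10] / pathWide[1], 1e-2, tolerance = 1e-10)
  expect_equal(path[40] / path[1], 1e-3, tolerance = 1e-10)
})

test_that("cross-validation picks heavy penalty for noise, light for signal", {
  set.seed(17)
  ## pure noise: the CV-selected lambda should sit near the null end
  nHeavy <- 0
  for (r in 1:10) {
    X <- scale(matrix(rnorm(40 * 30), 40))
    y <- rnorm(40)
    cv <- cvSelectLambda(X, y, alpha = 0.5, k = 5)
    nHeavy <- nHeavy + (cv$lambda > median(cv$path))
  }
  expect_gte(nHeavy, 7)   # majority of replicates
  ## strong signal, N >> p: small lambda, CV MSE near the noise variance
  set.seed(18)
  X <- scale(matrix(rnorm(300 * 5), 300))
  y <- drop(X %*% c(3, 2, -2, 1, -1) + rnorm(300, 0, 0.5))
  cv <- cvSelectLambda(X, y, alpha = 0.5, k = 10)
  expect_lt(cv$lambda, median(cv$path))
  expect_lt(min(cv$cvm), 0.5^2 * 1.5)
  ## k = N reduces to inner LOOCV with a finite curve
  cvLoo <- cvSelectLambda(X[1:25, ], y[1:25], alpha = 0.5, k = 25)
  expect_true(all(is.finite(cvLoo$cvm)))
  expect_error(cvSelectLambda(X[1:5, ], y[1:5], k = 10), "exceed")
})

test_that("LOOCV clock returns one model per sample and finds planted signal", {
  set.seed(19)
  n <- 24; p <- 40
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("f%03d", 1:p)
  rownames(X) <- sprintf("s%03d", 1:n)
  y <- drop(4 * X[, 1] + rnorm(n, 0, 0.3)) + 8
  res <- loocvClock(X, y, k = 5, dataType = "dnam")
  expect_s4_class(res, "LoocvClockResult")
  expect_equal(nrow(clockPredictions(res)), n)   # exactly N folds
  expect_equal(length(res@fits), n)
  ## the truly predictive column is selected in every fold
  expect_equal(unname(selectionFrequency(res)["f001"]), n)
  ev <- evaluatePredictions(clockPredictions(res)$predicted_age, y)
  expect_gt(ev$r2, 0.95)
  ## selection frequencies bounded by N
  expect_true(all(selectionFrequency(res) <= n))
  ## KKT certificate on every per-fold model
  for (i in seq_len(n)) {
    k <- kktCheck(res@fits[[i]], X[-i, ], y[-i])
    expect_true(k$ok, label = sprintf("fold %d", i))
  }
})

test_that("fold-wise scaling gives no skill on permuted ages", {
  set.seed(20)
  n <- 20; p <- 30
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("f%03d", 1:p)
  y <- sample(1:16, n, replace = TRUE)
  res <- loocvClock(X, y, k = 5, scaling = "fold", nLambda = 40)
  ev <- evaluatePredictions(clockPredictions(res)$predicted_age, y)
  ## the leave-one-out null model predicts mean(y[-i]), which decreases in
  ## the held-out age, so skill must be judged on the SIGNED measure
  expect_lt(sign(ev$r) * ev$r2_adj, 0.05)
  expect_lte(ev$r, 0.3)
})

test_that("prediction is the plain linear predictor", {
  d <- signalDesign(30, 5, seed = 21)
  f <- fitElasticNet(d$X, d$y, 0.5, 0.05)
  x <- d$X[3, ]
  expect_equal(predictAge(f, x), f@intercept + sum(x * f@beta))
  ## x = 0 -> intercept
  expect_equal(predictAge(f, rep(0, 5)), f@intercept)
  ## null model predicts the training mean everywhere
  fz <- fitElasticNet(d$X, d$y, 0.5, lambdaPath(d$X, d$y, 0.5, 3)[1])
  expect_equal(predictAge(fz, x), mean(d$y))
  expect_error(predictAge(f, rep(0, 4)), "does not match")
})
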