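## shared fixtures and independent brute-force oracles

## minimal metadata with every Eq-style covariate, deterministic given seed
tinyMeta <- function(n = 24, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    age = sample(1:16, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    breed = "Beagle",
    breed_weight_kg = runif(n, 3, 60),
    weight_category = sample(c("small", "medium", "large"), n, replace = TRUE),
    exercise = sample(c("minimal", "light", "moderate", "vigorous"), n,
                      replace = TRUE),
    cell.CD8 = runif(n, 10, 40),
    cell.DN = runif(n, 5, 30),
    stringsAsFactors = FALSE)
}

## random peak set on a couple of chromosomes
randomPeaks <- function(n, seed = 1, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  chrom <- sort(sample(chroms, n, replace = TRUE))
  start <- unlist(lapply(split(seq_len(n), chrom), function(ix)
    sort(sample(1:200000, length(ix)))), use.names = FALSE)
  width <- sample(200:600, n, replace = TRUE)
  GenomicRanges::GRanges(
    sort(chrom), IRanges::IRanges(start = start, width = width),
    name = sprintf("p%04d", seq_len(n)),
    summit = start + sample(50:150, n, replace = TRUE))
}

## brute-force transitive closure of the "summits < minDist apart" relation
## (all-pairs union-find; the implementation under test uses sorted chaining)
bruteMergeClusters <- function(chrom, summit, minDist = 500) {
  n <- length(summit)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        abs(summit[i] - summit[j]) < minDist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## brute-force two-sided Fisher p via explicit probability enumeration
bruteFisherP <- function(a, b, cc, d) {
  K <- a + b; n2 <- cc + d; k <- a + cc
  if (K == 0 || n2 == 0 || k == 0 || k == K + n2) return(1)
  supp <- max(0, k - n2):min(k, K)
  lp <- lchoose(K, supp) + lchoose(n2, k - supp) - lchoose(K + n2, k)
  pr <- exp(lp)
  pobs <- exp(lchoose(K, a) + lchoose(n2, k - a) - lchoose(K + n2, k))
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

## brute-force BH step-up: q_(i) = min_{j >= i} (m/j) p_(j)
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  out <- numeric(m)
  out[o] <- q
  out
}

## standardized design with one truly predictive column
signalDesign <- function(n = 40, p = 10, seed = 1, noise = 0.5) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- sprintf("f%03d", seq_len(p))
  y <- drop(3 * X[, 1] + rnorm(n, 0, noise)) + 8
  list(X = X, y = y)
}
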