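mkStates <- function(chrom, starts, ends, labels) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         state = labels)
}

test_that("state assignment picks the maximal-overlap interval", {
  states <- mkStates("chr1", c(1, 1001, 2001), c(1000, 2000, 3000),
                     c("1", "2", "3"))
  ## fully contained
  f1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 300))
  expect_equal(assignState(f1, states), "1")
  ## 300 bp in state 2, 200 bp in state 3 -> state 2
  f2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1701, 2200))
  expect_equal(assignState(f2, states), "2")
  ## width-1 CpG position -> containing interval
  f3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1500))
  expect_equal(assignState(f3, states), "2")
  ## contig absent from the map -> unannotated
  f4 <- GenomicRanges::GRanges("chrX", IRanges::IRanges(100, 200))
  expect_equal(assignState(f4, states), "unannotated")
  ## midpoint mode
  expect_equal(assignState(f2, states, mode = "midpoint"), "2")
})

test_that("state assignment agrees with an exhaustive per-base overlap scan", {
  set.seed(8)
  breaks <- sort(sample(1:5000, 12))
  states <- mkStates("chr1", c(1, breaks + 1), c(breaks, 6000),
                     sample(as.character(1:13), 13, replace = TRUE))
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = sample(1:5500, 40),
                             width = sample(50:400, 40, replace = TRUE)))
  got <- assignState(feats, states)
  for (i in seq_along(feats)) {
    fb <- GenomicRanges::start(feats)[i]:GenomicRanges::end(feats)[i]
    ov <- vapply(seq_along(states), function(s)
      sum(fb >= GenomicRanges::start(states)[s] &
            fb <= GenomicRanges::end(states)[s]), integer(1))
    if (max(ov) == 0) expect_equal(got[i], "unannotated")
    else {
      best <- which(ov == max(ov))[1]   # earlier interval on ties
      expect_equal(got[i], states$state[best], label = paste("feature", i))
    }
  }
  ## partition property: exactly one label each
  expect_equal(length(got), length(feats))
  expect_true(all(got %in% c(as.character(1:13), "unannotated")))
})

test_that("Fisher two-sided p matches enumeration and fisher.test", {
  ## expected value frozen from the exhaustive enumeration over the 13
  ## tables with these margins (fisher.test agrees to 1e-7)
  f <- fisherExact2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
  expect_equal(f$p, 0.002759456, tolerance = 1e-5)
  expect_equal(f$p, bruteFisherP(1, 9, 11, 3), tolerance = 1e-10)
  ## symmetric table
  f2 <- fisherExact2x2(matrix(5, 2, 2))
  expect_equal(f2$p, 1)
  expect_equal(f2$oddsRatio, 1)
  ## fully concentrated table: enumeration gives 2/C(20,10)
  f3 <- fisherExact2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE))
  expect_equal(f3$p, 2 / choose(20, 10), tolerance = 1e-10)
  ## zero margin -> p 1, OR undefined
  f4 <- fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(f4$p, 1)
  expect_true(is.na(f4$oddsRatio))
  ## continuity-corrected OR only with a zero cell
  f5 <- fisherExact2x2(matrix(c(0, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(f5$oddsRatio, (0.5 * 5.5) / (5.5 * 5.5))
  ## random tables vs stats::fisher.test (independent reference)
  set.seed(9)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisherExact2x2(tab)$p,
                 fisher.test(tab)$p.value, tolerance = 1e-7,
                 label = paste(tab, collapse = ","))
  }
})

test_that("state enrichment recovers a designed direction bias", {
  set.seed(10)
  n <- 1000
  directions <- sample(c("increasing", "decreasing"), n, replace = TRUE)
  states <- sample(as.character(1:13), n, replace = TRUE)
  ## make state 1 five-fold more frequent among decreasing peaks
  dec <- directions == "decreasing"
  states[dec] <- sample(c("1", as.character(2:13)), sum(dec), replace = TRUE,
                        prob = c(5, rep(1, 12)))
  enr <- stateEnrichment(directions, states)
  s1 <- enr[enr$state == "1", ]
  expect_lt(s1$q, 0.05)
  expect_lt(s1$odds_ratio, 1)          # depleted among increasing
  ## margins: every per-state table sums to the same total
  tots <- rowSums(enr[, c("inState_inc", "inState_dec",
                          "other_inc", "other_dec")])
  expect_true(all(tots == tots[1]))
  ## refusal when one direction is absent
  expect_error(stateEnrichment(rep("increasing", 5), rep("1", 5)),
               "at least one")
})

test_that("nearest gene mapping matches a brute-force scan with tie rules", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5000, 9000, 9000), c(6000, 9500, 9500)),
    gene_name = c("B", "A", "C"), score = 0L)
  names(genes) <- genes$gene_name
  ## feature inside a gene -> distance 0
  f1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5100, 5200))
  names(f1) <- "f1"
  r1 <- nearestGene(f1, genes)
  expect_equal(r1$gene, "B"); expect_equal(r1$distance, 0)
  ## exact tie between the two genes at start 9000 -> lexicographic name
  f2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 8200))
  names(f2) <- "f2"
  r2 <- nearestGene(f2, genes)
  expect_equal(r2$gene, "A")   # ties at start 9000 broken lexicographically
  ## equidistant between B (end 6000) and the pair at 9000 -> smaller start
  f2b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7400, 7600))
  names(f2b) <- "f2b"
  expect_equal(nearestGene(f2b, genes)$gene, "B")
  ## random instance vs brute force
  set.seed(11)
  g <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 20, replace = TRUE),
    IRanges::IRanges(start = sample(1:100000, 20), width = 2000),
    gene_name = sprintf("g%02d", 1:20), score = 0L)
  names(g) <- g$gene_name
  feats <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 50, replace = TRUE),
    IRanges::IRanges(start = sample(1:100000, 50), width = 300))
  names(feats) <- sprintf("f%02d", 1:50)
  got <- nearestGene(feats, g)
  gap <- function(s1, e1, s2, e2) max(0, s2 - e1 - 1, s1 - e2 - 1)
  for (i in 1:50) {
    same <- as.character(GenomicRanges::seqnames(g)) ==
      as.character(GenomicRanges::seqnames(feats))[i]
    if (!any(same)) { expect_true(is.na(got$gene[i])); next }
    cand <- which(same)
    d <- vapply(cand, function(j)
      gap(GenomicRanges::start(feats)[i], GenomicRanges::end(feats)[i],
          GenomicRanges::start(g)[j], GenomicRanges::end(g)[j]), numeric(1))
    best <- cand[d == min(d)]
    best <- best[order(GenomicRanges::start(g)[best], g$gene_name[best])][1]
    expect_equal(got$gene[i], g$gene_name[best], label = paste("feature", i))
    expect_equal(got$distance[i], min(d), label = paste("distance", i))
  }
  expect_error(nearestGene(feats, g[0]), "empty gene set")
})

test_that("clock gene overlap reproduces direct set algebra", {
  geneMap <- setNames(paste0("g", c(1, 1, 2, 3, 4, 5)),
                      paste0("f", 1:6))
  sel <- list(atac = c("f1", "f3", "f4"),      # genes g1 g2 g3
              dnam = c("f2", "f3", "f5"),      # genes g1 g2 g4
              combined = c("f1", "f3", "f6"))  # genes g1 g2 g5
  ov <- clockGeneOverlap(sel, geneMap)
  expect_equal(unname(ov$venn["111"]), 2)      # g1, g2
  expect_equal(ov$intersectionGenes, c("g1", "g2"))
  expect_equal(unname(ov$venn["100"]), 1)      # g3
  expect_equal(sum(ov$venn), 5)
  ## identical selections -> everything in the triple intersection
  ov2 <- clockGeneOverlap(list(a = sel$atac, b = sel$atac, c = sel$atac),
                          geneMap)
  expect_equal(unname(ov2$venn["111"]), 3)
  expect_equal(sum(ov2$venn[names(ov2$venn) != "111"]), 0)
  ## disjoint gene sets -> empty intersection
  ov3 <- clockGeneOverlap(list(a = "f1", b = "f4", c = "f5"), geneMap)
  expect_equal(unname(ov3$venn["111"]), 0)
  expect_equal(length(ov3$intersectionGenes), 0)
})
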