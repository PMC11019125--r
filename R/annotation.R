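## Feature annotation: chromatin-state assignment by maximal base overlap,
## Fisher's exact enrichment of states among age-increasing vs -decreasing
## peaks, nearest-gene mapping, and cross-clock gene overlap.

#' Assign each feature its chromatin state
#'
#' Each feature gets the state whose interval overlaps it by the most
#' bases (ties broken toward the earlier interval); single-base features
#' get their containing interval. Features overlapping no state interval
#' are labelled `"unannotated"`. With `mode = "midpoint"`, the state
#' containing the feature midpoint is used instead.
#'
#' @param features `GRanges` (peaks, or width-1 CpG positions).
#' @param states `GRanges` with mcols `state`.
#' @param mode "maxOverlap" (default) or "midpoint".
#' @return character vector of state labels, one per feature.
#' @export
assignState <- function(features, states, mode = c("maxOverlap", "midpoint")) {
  mode <- match.arg(mode)
  if (any(GenomicRanges::start(states) > GenomicRanges::end(states)))
    stop("malformed state intervals")
  query <- features
  if (mode == "midpoint") {
    mid <- floor((GenomicRanges::start(features) +
                    GenomicRanges::end(features)) / 2)
    query <- GenomicRanges::GRanges(GenomicRanges::seqnames(features),
                                    IRanges::IRanges(mid, mid))
  }
  ## harmonize seqlevels so contigs absent from the map do not warn
  lv <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(states))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(states) <- lv
  hits <- GenomicRanges::findOverlaps(query, states, ignore.strand = TRUE)
  out <- rep("unannotated", length(features))
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(query)[qh], GenomicRanges::ranges(states)[sh]))
  ## per feature: maximal overlap, ties to the earlier (smaller index) state
  o <- order(qh, -ov, sh)
  first <- !duplicated(qh[o])
  out[qh[o][first]] <- states$state[sh[o][first]]
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by summing, over all tables with the observed margins, the
#' hypergeometric probabilities no greater than that of the observed table
#' (probability-ordering definition, with relative tolerance 1e-7 guarding
#' floating-point ties). The odds ratio is the sample OR (ad)/(bc), with a
#' 0.5 continuity correction applied only when a zero cell occurs. A zero
#' margin gives p = 1 and an undefined (NA) odds ratio.
#'
#' @param table 2x2 non-negative integer matrix (or vector a, b, c, d by
#'   row).
#' @return list with `oddsRatio` and `p`.
#' @examples
#' fisherExact2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of non-negative integers")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  K <- a + b       # row 1 margin
  nRow2 <- cc + d
  k <- a + cc      # column 1 margin
  n <- K + nRow2
  if (K == 0 || nRow2 == 0 || k == 0 || k == n)
    return(list(oddsRatio = NA_real_, p = 1))
  support <- max(0, k - nRow2):min(k, K)
  probs <- stats::dhyper(support, K, nRow2, k)
  pObs <- stats::dhyper(a, K, nRow2, k)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  or <- if (a == 0 || b == 0 || cc == 0 || d == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  list(oddsRatio = or, p = p)
}

#' Chromatin-state enrichment among age-increasing vs -decreasing peaks
#'
#' For each state s observed among the direction-classified peaks, builds
#' the 2x2 table (state = s vs != s) x (increasing vs decreasing), tests it
#' with [fisherExact2x2()], and BH-adjusts across states. The odds ratio is
#' oriented so that OR > 1 means the state is enriched among increasing
#' peaks. Only peaks labelled increasing or decreasing enter; states absent
#' from all of them are skipped with a message.
#'
#' @param directions character per peak ("increasing"/"decreasing"/"ns").
#' @param states state label per peak (same order).
#' @return data.frame: state, inState_inc, inState_dec, other_inc,
#'   other_dec, odds_ratio, p, q.
#' @export
stateEnrichment <- function(directions, states) {
  if (length(directions) != length(states))
    stop("directions and states must cover the same peaks")
  sel <- directions %in% c("increasing", "decreasing")
  directions <- directions[sel]; states <- states[sel]
  nInc <- sum(directions == "increasing")
  nDec <- sum(directions == "decreasing")
  if (nInc < 1L || nDec < 1L)
    stop("need at least one increasing and one decreasing peak")
  allStates <- as.character(sort(suppressWarnings(
    as.integer(unique(states[states != "unannotated"])))))
  allStates <- allStates[!is.na(allStates)]
  rows <- lapply(allStates, function(s) {
    aa <- sum(states == s & directions == "increasing")
    bb <- sum(states == s & directions == "decreasing")
    cNot <- nInc - aa; dNot <- nDec - bb
    ft <- fisherExact2x2(matrix(c(aa, bb, cNot, dNot), 2, byrow = TRUE))
    data.frame(state = s, inState_inc = aa, inState_dec = bb,
               other_inc = cNot, other_dec = dNot,
               odds_ratio = ft$oddsRatio, p = ft$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out
}

#' Map each feature to its nearest gene
#'
#' Distance is 0 when the feature overlaps the gene body, otherwise the gap
#' between the two intervals; strand is ignored. Ties are broken toward the
#' gene with the smaller start, then the lexicographically smaller name.
#' With `mode = "tss"`, distance is measured to the strand-aware
#' transcription start coordinate instead of the gene body.
#'
#' @param features `GRanges`.
#' @param genes `GRanges` with mcols `gene_name`.
#' @param mode "body" (default) or "tss".
#' @return data.frame: feature (names of `features`), gene, distance (bp;
#'   NA when no gene shares the contig).
#' @export
nearestGene <- function(features, genes, mode = c("body", "tss")) {
  mode <- match.arg(mode)
  if (length(genes) == 0L) stop("empty gene set")
  target <- genes
  if (mode == "tss") {
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                  GenomicRanges::end(genes), GenomicRanges::start(genes))
    target <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                     IRanges::IRanges(tss, tss),
                                     gene_name = genes$gene_name)
  }
  ## distances computed directly so ties on opposite sides are all seen
  ## (distanceToNearest(select = "all") can drop equal-distance candidates)
  fChr <- as.character(GenomicRanges::seqnames(features))
  gChr <- as.character(GenomicRanges::seqnames(target))
  fS <- GenomicRanges::start(features); fE <- GenomicRanges::end(features)
  gS <- GenomicRanges::start(target); gE <- GenomicRanges::end(target)
  gene <- rep(NA_character_, length(features))
  dd <- rep(NA_real_, length(features))
  for (ch in unique(fChr)) {
    gi <- which(gChr == ch)
    if (!length(gi)) next
    ## pre-sort candidate genes by the tie-break rule once per chromosome
    gi <- gi[order(gS[gi], target$gene_name[gi])]
    for (i in which(fChr == ch)) {
      d <- pmax(0, gS[gi] - fE[i] - 1L, fS[i] - gE[gi] - 1L)
      b <- which.min(d)             # first index = tie-break winner
      gene[i] <- target$gene_name[gi[b]]
      dd[i] <- d[b]
    }
  }
  data.frame(feature = names(features) %||%
               as.character(seq_along(features)),
             gene = gene, distance = dd, stringsAsFactors = FALSE)
}

#' Cross-clock nearest-gene overlap
#'
#' Maps each clock's ever-selected features to their unique nearest genes
#' and returns all seven Venn region counts plus the genes shared by all
#' three clocks.
#'
#' @param selected named list of three character vectors of feature ids
#'   (union of features selected in any LOOCV fold, per clock).
#' @param geneMap named character vector feature id -> nearest gene (e.g.
#'   from [nearestGene()]).
#' @return list with `geneSets`, `venn` (named counts for regions
#'   "100","010","001","110","101","011","111" in the order of
#'   `names(selected)`), and `intersectionGenes`.
#' @export
clockGeneOverlap <- function(selected, geneMap) {
  stopifnot(length(selected) == 3L)
  sets <- lapply(selected, function(ids) {
    g <- geneMap[intersect(ids, names(geneMap))]
    sort(unique(g[!is.na(g)]))
  })
  A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
  inA <- function(g) g %in% A; inB <- function(g) g %in% B
  inC <- function(g) g %in% C
  all <- sort(unique(c(A, B, C)))
  member <- cbind(inA(all), inB(all), inC(all))
  code <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  venn <- vapply(c("100", "010", "001", "110", "101", "011", "111"),
                 function(cd) sum(code == cd), integer(1))
  list(geneSets = sets, venn = venn,
       intersectionGenes = all[code == "111"])
}
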