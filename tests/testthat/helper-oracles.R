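# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately take a different computational route from the
# package functions they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

# --- chain oracle -----------------------------------------------------

# Expand a chain record into an explicit per-base source -> target lookup
# (0-based positions), by materializing every aligned block.
oracleChainExpand <- function(ch) {
  sPos <- tPos <- numeric(0)
  curS <- ch$sStart
  curT <- ch$tStart
  for (k in seq_len(nrow(ch$blocks))) {
    size <- ch$blocks[k, "size"]
    sPos <- c(sPos, seq(curS, length.out = size))
    tPos <- c(tPos, seq(curT, length.out = size))
    curS <- curS + size + ch$blocks[k, "sGap"]
    curT <- curT + size + ch$blocks[k, "tGap"]
  }
  if (ch$tStrand == "-") tPos <- ch$tSize - 1 - tPos
  list(sPos = sPos, tPos = tPos)
}

# Oracle lift of a 1-based closed interval through a ChainSet: pick the
# best-score (then lowest-id) chain overlapping the query, look every base
# up in the expanded map, apply the remap-ratio rule.
oracleLift <- function(chainSet, chrom, start1, end1, minRatio = 0.95) {
  cand <- Filter(function(ch) ch$sName == chrom &&
                   (start1 - 1) < ch$sEnd && end1 > ch$sStart,
                 chains(chainSet))
  if (length(cand) == 0L)
    return(list(status = "unmapped"))
  sc <- vapply(cand, `[[`, 0, "score")
  ids <- suppressWarnings(as.numeric(vapply(cand, `[[`, "", "id")))
  ord <- order(-sc, ids)
  ch <- cand[[ord[1L]]]
  map <- oracleChainExpand(ch)
  q <- (start1 - 1):(end1 - 1)
  hit <- match(q, map$sPos)
  ratio <- mean(!is.na(hit))
  if (ratio < minRatio || all(is.na(hit)))
    return(list(status = "unmapped", ratio = ratio))
  tp <- map$tPos[hit[!is.na(hit)]]
  list(status = "mapped", chrom = ch$tName,
       start = min(tp) + 1, end = max(tp) + 1, ratio = ratio,
       inverted = ch$tStrand == "-")
}

# Build a ChainSet directly from block specs (validity-checked).
makeChain <- function(sName, sStart, blocks, tName, tStart,
                      tStrand = "+", score = 100, id = "1",
                      sSize = NULL, tSize = NULL) {
  b <- do.call(rbind, blocks)
  colnames(b) <- c("size", "sGap", "tGap")
  sEnd <- sStart + sum(b[, "size"]) + sum(b[, "sGap"])
  tEnd <- tStart + sum(b[, "size"]) + sum(b[, "tGap"])
  if (is.null(sSize)) sSize <- sEnd + 100
  if (is.null(tSize)) tSize <- tEnd + 100
  new("ChainSet", chains = list(list(
    id = id, score = score,
    sName = sName, sSize = sSize, sStrand = "+",
    sStart = sStart, sEnd = sEnd,
    tName = tName, tSize = tSize, tStrand = tStrand,
    tStart = tStart, tEnd = tEnd, blocks = b)))
}

# A random small chain for property tests.
randomChain <- function(id = "1", score = NULL) {
  nb <- sample(1:4, 1L)
  blocks <- lapply(seq_len(nb), function(k) {
    c(sample(3:40, 1L),
      if (k < nb) sample(0:15, 1L) else 0L,
      if (k < nb) sample(0:15, 1L) else 0L)
  })
  makeChain("src", sample(0:30, 1L), blocks, "tgt", sample(0:30, 1L),
            tStrand = sample(c("+", "-"), 1L, prob = c(0.7, 0.3)),
            score = if (is.null(score)) sample(50:500, 1L) else score,
            id = id)
}

# --- misc oracles -----------------------------------------------------

# Independent greedy overlap removal: repeatedly take the best remaining
# site (score, then start, then width) and discard everything overlapping
# it. Same objective as removeOverlaps, different mechanics.
oracleGreedy <- function(sites) {
  kept <- sites[0, , drop = FALSE]
  pool <- as.data.frame(sites)
  while (nrow(pool) > 0L) {
    width <- pool$end - pool$start
    best <- which(pool$score == min(pool$score))
    best <- best[pool$start[best] == min(pool$start[best])]
    best <- best[which.min(width[best])]
    kept <- rbind(kept, pool[best, , drop = FALSE])
    ov <- pool$start <= pool$end[best] & pool$end >= pool$start[best]
    pool <- pool[!ov, , drop = FALSE]
  }
  kept[order(kept$start), , drop = FALSE]
}

# Brute-force membership pattern counts for compareSets.
oracleCompareSets <- function(sets) {
  univ <- unique(unlist(sets))
  pats <- vapply(univ, function(el)
    paste(vapply(sets, function(s) el %in% s, TRUE), collapse = "|"), "")
  table(pats)
}

# Exact Kruskal-Wallis permutation p-value by full enumeration of group
# assignments, recomputing H from ranks by the textbook formula.
oracleKwPerm <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  Hof <- function(lab) {
    lab <- factor(lab)
    N <- length(r)
    tieTab <- table(r)
    C <- 1 - sum(tieTab^3 - tieTab) / (N^3 - N)
    s <- tapply(r, lab, sum)
    ni <- tabulate(lab)
    (12 / (N * (N + 1)) * sum(s^2 / ni) - 3 * (N + 1)) / C
  }
  sizes <- as.integer(table(groups))
  assign <- function(remaining, sizes, g, lab) {
    if (length(sizes) == 1L) {
      lab[remaining] <- g
      return(list(lab))
    }
    out <- list()
    for (cc in utils::combn(remaining, sizes[1L], simplify = FALSE)) {
      lab2 <- lab
      lab2[cc] <- g
      out <- c(out, assign(setdiff(remaining, cc), sizes[-1L], g + 1L,
                           lab2))
    }
    out
  }
  labs <- assign(seq_len(n), sizes, 1L, integer(n))
  Hobs <- round(Hof(as.integer(groups)), 10)
  Hs <- vapply(labs, function(l) round(Hof(l), 10), 0)
  mean(Hs >= Hobs)
}

# --- fixture builders -------------------------------------------------

makeCallSet <- function(chrom, start, end, strand, counts, samples,
                        callerId = "x", circType = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  cnt <- if (is.matrix(counts)) counts else
    matrix(as.integer(counts), nrow = length(gr), byrow = TRUE)
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- list(NULL, samples)
  BsjCallSet(gr, cnt, callerId = callerId, circType = circType)
}

toyModels <- function() {
  genes <- GRanges("chr1", IRanges(c(1000, 6000), c(5000, 8000)),
                   strand = c("+", "-"))
  names(genes) <- c("G1", "G2")
  genes$gene_name <- c("GENE1", "GENE2")
  ex <- GRangesList(
    G1 = GRanges("chr1", IRanges(c(1000, 2000, 3000, 4000),
                                 c(1200, 2200, 3300, 4500)),
                 strand = "+"),
    G2 = GRanges("chr1", IRanges(c(6000, 7500), c(6400, 8000)),
                 strand = "-"))
  GeneModels(genes, ex)
}
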