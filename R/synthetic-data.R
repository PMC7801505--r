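# Seeded generators producing every input the pipeline consumes, with
# planted ground truth for each downstream stage. Every generator is a
# pure function of (seed, parameters): same seed, same output.

#' SyntheticTruth: planted ground truth for a simulated dataset
#'
#' @slot circs \code{GRanges} of true circRNAs on the source genome with
#'   metadata columns \code{circ_id}, \code{category} (planted
#'   conservation category), \code{hostGene} (\code{""} when intergenic),
#'   \code{boundaryClass}.
#' @slot spongeSites list of planted binding-site tables (per circRNA).
#' @slot deEffects numeric matrix, circRNA x group fold-changes
#'   (1 = null); all > 0.
#' @slot seed the generating seed.
#' @export
setClass("SyntheticTruth",
         slots = c(circs = "GRanges", spongeSites = "list",
                   deEffects = "matrix", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (!all(object@circs$category %in% .CONS_CATEGORIES))
    msg <- c(msg, "invalid planted conservation category")
  if (!all(object@circs$boundaryClass %in% .BOUNDARY_CLASSES))
    msg <- c(msg, "invalid planted boundary class")
  if (nrow(object@deEffects) != length(object@circs))
    msg <- c(msg, "deEffects must have one row per circRNA")
  if (any(object@deEffects <= 0))
    msg <- c(msg, "fold-changes must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@circs), "planted circRNA(s), seed",
      object@seed, "\n")
  print(table(object@circs$category))
})

#' Example sample designs
#'
#' The two study layouts the generators emulate: a 12-sample, 3-group
#' single-timepoint brain design (four animals per treatment: adjuvant,
#' vaccine, control) and a 13-sample two-timepoint PBMC design (three
#' animals per treatment sampled at start and end, one sample re-extracted
#' and doubling as a technical batch).
#'
#' @param tissue \code{"encephalon"} or \code{"pbmc"}.
#' @return a sample sheet data.frame (see \code{\link{readSampleSheet}}).
#' @export
exampleDesign <- function(tissue = c("encephalon", "pbmc")) {
  tissue <- match.arg(tissue)
  if (tissue == "encephalon") {
    data.frame(
      sample_id = c("114-E", "115-E", "116-E", "117-E",
                    "121-E", "122-E", "124-E", "126-E",
                    "131-E", "135-E", "136-E", "137-E"),
      group = rep(c("Adjuvant", "Vaccine", "Control"), each = 4L),
      timepoint = "Tf", batch = "")
  } else {
    data.frame(
      sample_id = c("121-A", "124-A", "125-A", "121-B", "124-B", "125-B",
                    "125-Bb", "111-A", "114-A", "116-A", "111-B", "114-B",
                    "116-B"),
      group = rep(c("Adjuvant", "Vaccine"), c(7L, 6L)),
      timepoint = c("T0", "T0", "T0", "Tf", "Tf", "Tf", "Tf",
                    "T0", "T0", "T0", "Tf", "Tf", "Tf"),
      batch = c("b1", "b1", "b1", "b1", "b1", "b1", "b2",
                "b1", "b1", "b1", "b1", "b1", "b1"))
  }
}

#' Generate a toy gene annotation
#'
#' Places non-overlapping genes on the declared chromosomes, each gene
#' receiving a set of non-overlapping exons sorted by start. Genes land
#' on chromosomes with probability proportional to chromosome length, so
#' longer chromosomes carry more genes, as real annotations do.
#'
#' @param seed integer seed.
#' @param nGenes number of genes (>= 1).
#' @param exonsPerGeneRange inclusive range of exon counts per gene.
#' @param chromLengths named vector of chromosome lengths.
#' @param exonLenRange,intronLenRange inclusive ranges of exon and intron
#'   lengths (nt).
#' @return A \linkS4class{GeneModels}.
#' @export
genAnnotation <- function(seed, nGenes = 40L,
                          exonsPerGeneRange = c(2L, 8L),
                          chromLengths = c(chr1 = 3e5, chr2 = 1.5e5),
                          exonLenRange = c(80L, 300L),
                          intronLenRange = c(200L, 1000L)) {
  stopifnot(nGenes >= 1L, length(chromLengths) >= 1L,
            !is.null(names(chromLengths)))
  .withSeed(seed, {
    occupied <- lapply(chromLengths, function(x) IRanges())
    geneList <- vector("list", nGenes)
    exonList <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
      nEx <- sample(seq.int(exonsPerGeneRange[1L], exonsPerGeneRange[2L]),
                    1L)
      exLens <- sample(seq.int(exonLenRange[1L], exonLenRange[2L]), nEx,
                       replace = TRUE)
      inLens <- if (nEx > 1L)
        sample(seq.int(intronLenRange[1L], intronLenRange[2L]), nEx - 1L,
               replace = TRUE) else integer()
      geneLen <- sum(exLens) + sum(inLens)
      placed <- FALSE
      for (try in seq_len(2000L)) {
        chrom <- sample(names(chromLengths), 1L,
                        prob = chromLengths / sum(chromLengths))
        if (chromLengths[[chrom]] < geneLen + 2L) next
        gStart <- sample.int(chromLengths[[chrom]] - geneLen, 1L)
        cand <- IRanges(gStart, gStart + geneLen - 1L)
        if (length(findOverlaps(cand, occupied[[chrom]])) > 0L) next
        occupied[[chrom]] <- c(occupied[[chrom]], cand)
        strd <- sample(c("+", "-"), 1L)
        exStarts <- gStart + cumsum(c(0L, exLens[-nEx] + inLens))
        exonList[[i]] <- GRanges(chrom,
                                 IRanges(exStarts, exStarts + exLens - 1L),
                                 strand = strd)
        geneList[[i]] <- GRanges(chrom, cand, strand = strd)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("sizing error: cannot place ", nGenes, " genes on the ",
             "declared chromosomes", call. = FALSE)
    }
    # single-chromosome pieces carry disjoint seqlevels; merging is intended
    genes <- suppressWarnings(do.call(c, geneList))
    names(genes) <- sprintf("G%04d", seq_len(nGenes))
    genes$gene_name <- names(genes)
    ord <- order(as.character(seqnames(genes)), start(genes))
    genes <- genes[ord]
    ex <- GRangesList(exonList[ord])
    names(ex) <- names(genes)
    GeneModels(genes, ex)
  })
}

#' Generate a synthetic liftover chain
#'
#' One chain of gapless aligned blocks separated by source/target gaps,
#' optionally inverted on the target side. Gap sizes are bounded so that
#' distances between nearby source positions survive lifting roughly
#' intact (the classifier fixtures rely on spacing).
#'
#' @param seed integer seed.
#' @param sourceName,targetName sequence names.
#' @param sourceLength declared source sequence length.
#' @param nBlocks number of aligned blocks.
#' @param blockLenRange inclusive range of block sizes.
#' @param gapRange inclusive range of gap sizes (applies to source and
#'   target gaps independently; a gap of 0 merges visually but is kept).
#' @param inversionProb probability that the chain maps to the minus
#'   strand of the target.
#' @param score chain score.
#' @param id chain id.
#' @return A \linkS4class{ChainSet} with one chain.
#' @export
genChain <- function(seed, sourceName = "chr1", targetName = "hchr1",
                     sourceLength = 3.2e5, nBlocks = 40L,
                     blockLenRange = c(2000L, 10000L),
                     gapRange = c(0L, 150L), inversionProb = 0,
                     score = 1000, id = "1") {
  .withSeed(seed, {
    sizes <- sample(seq.int(blockLenRange[1L], blockLenRange[2L]), nBlocks,
                    replace = TRUE)
    sGap <- c(sample(seq.int(gapRange[1L], gapRange[2L]), nBlocks - 1L,
                     replace = TRUE), 0L)
    tGap <- c(sample(seq.int(gapRange[1L], gapRange[2L]), nBlocks - 1L,
                     replace = TRUE), 0L)
    inverted <- runif(1L) < inversionProb
    sStart <- sample.int(100L, 1L)
    sEnd <- sStart + sum(sizes) + sum(sGap)
    tStart <- sample.int(100L, 1L)
    tEnd <- tStart + sum(sizes) + sum(tGap)
    ch <- list(id = id, score = score,
               sName = sourceName, sSize = max(sourceLength, sEnd + 10),
               sStrand = "+", sStart = sStart, sEnd = sEnd,
               tName = targetName, tSize = tEnd + sample.int(100L, 1L),
               tStrand = if (inverted) "-" else "+",
               tStart = tStart, tEnd = tEnd,
               blocks = cbind(size = sizes, sGap = sGap, tGap = tGap))
    new("ChainSet", chains = list(ch))
  })
}

# Lift a single 1-based source position through the chain set using the
# same chain-selection rule as liftInterval. Returns 1-based target
# position and chrom, or NULL when unmapped.
#' @noRd
.liftPos1 <- function(chainSet, chrom, pos1) {
  ch <- .selectChain(chains(chainSet), chrom, pos1 - 1L, pos1)
  if (is.null(ch)) return(NULL)
  t0 <- .mapPosThroughChain(ch, pos1 - 1L)
  if (is.na(t0)) return(NULL)
  list(chrom = ch$tName, pos = as.integer(t0) + 1L)
}

# Source-gap intervals (1-based closed) of every chain, per chain.
#' @noRd
.chainSourceGaps <- function(chainSet) {
  out <- list()
  for (ch in chains(chainSet)) {
    b <- ch$blocks
    curS <- ch$sStart
    for (k in seq_len(nrow(b))) {
      curS <- curS + b[k, "size"]
      g <- b[k, "sGap"]
      if (g > 0)
        out[[length(out) + 1L]] <- list(chrom = ch$sName,
                                        start = curS + 1L,
                                        end = curS + g)
      curS <- curS + g
    }
  }
  out
}

#' Generate planted ground truth
#'
#' Places \code{nCirc} true circRNAs on the source genome so that each
#' receives its requested conservation category when lifted through
#' \code{chainSet} and classified against the database built by
#' \code{\link{genCircDb}}. Ends of circRNAs destined for mapped
#' categories are placed inside aligned chain blocks (using exon
#' boundaries of the annotation where possible, so boundary classes
#' vary); a \code{not_aligned} circRNA gets one end inside a source gap.
#' All source and lifted end positions are kept at least
#' \code{minSpacing} apart so database records planted for one circRNA
#' cannot accidentally match another.
#'
#' @param seed integer seed.
#' @param models a \linkS4class{GeneModels} (may be empty).
#' @param chainSet a \linkS4class{ChainSet}.
#' @param nCirc number of true circRNAs.
#' @param categories requested conservation categories, recycled to
#'   \code{nCirc}; default mixes all six.
#' @param groups group names for the fold-change matrix.
#' @param deFold optional full fold-change matrix (circ x group), or
#'   NULL for an all-1 (null) matrix.
#' @param minSpacing minimum distance between any two planted end
#'   positions, in source and in target coordinates.
#' @param minWidth minimum circRNA width; the minimum lifted end-to-end
#'   distance is also enforced so category records stay unambiguous.
#' @return A \linkS4class{SyntheticTruth}.
#' @export
genTruth <- function(seed, models, chainSet, nCirc = 50L,
                     categories = NULL,
                     groups = c("Adjuvant", "Vaccine", "Control"),
                     deFold = NULL, minSpacing = 300L, minWidth = 400L) {
  if (is.null(categories))
    categories <- rep(c("homologous", "no_homologous",
                        "five_prime_utilized", "three_prime_utilized",
                        "both_sites_utilized", "not_aligned"),
                      length.out = nCirc)
  categories <- rep(categories, length.out = nCirc)
  bad <- setdiff(categories, .CONS_CATEGORIES)
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)

  chainChroms <- unique(vapply(chains(chainSet), `[[`, "", "sName"))
  gaps <- .chainSourceGaps(chainSet)
  if (any(categories == "not_aligned") && length(gaps) == 0L)
    stop("generation error: chain has no source gaps; cannot plant ",
         "a not_aligned circRNA", call. = FALSE)

  genes <- geneRanges(models)
  ex <- exonsByGene(models)
  genesOnChain <- which(as.character(seqnames(genes)) %in% chainChroms &
                          lengths(ex) >= 1L)

  .withSeed(seed, {
    usedSrc <- list()
    usedTgt <- list()
    spaced <- function(used, chrom, pos) {
      u <- used[[chrom]]
      is.null(u) || all(abs(u - pos) >= minSpacing)
    }
    note <- function(used, chrom, pos) {
      used[[chrom]] <- c(used[[chrom]], pos)
      used
    }
    circList <- vector("list", nCirc)
    for (i in seq_len(nCirc)) {
      cat_i <- categories[i]
      done <- FALSE
      for (try in seq_len(2000L)) {
        if (cat_i == "not_aligned") {
          g <- gaps[[sample.int(length(gaps), 1L)]]
          endPos <- if (g$end > g$start)
            sample(seq.int(g$start, g$end), 1L) else g$start
          startPos <- endPos - minWidth - sample.int(500L, 1L)
          chrom <- g$chrom
          if (startPos < 1L) next
          l1 <- .liftPos1(chainSet, chrom, startPos)
          if (!spaced(usedSrc, chrom, startPos) ||
              !spaced(usedSrc, chrom, endPos)) next
          if (!is.null(l1) && !spaced(usedTgt, l1$chrom, l1$pos)) next
          usedSrc <- note(note(usedSrc, chrom, startPos), chrom, endPos)
          if (!is.null(l1)) usedTgt <- note(usedTgt, l1$chrom, l1$pos)
          strd <- sample(c("+", "-"), 1L)
          circList[[i]] <- GRanges(chrom, IRanges(startPos, endPos),
                                   strand = strd)
          done <- TRUE
          break
        }
        useGene <- length(genesOnChain) > 0L && runif(1L) < 0.7
        if (useGene) {
          gi <- genesOnChain[sample.int(length(genesOnChain), 1L)]
          exg <- ex[[gi]]
          jk <- sort(sample.int(length(exg), min(2L, length(exg))))
          j <- jk[1L]; k <- jk[length(jk)]
          offS <- sample(c(0L, 0L, 5L), 1L)
          offE <- sample(c(0L, 0L, -5L), 1L)
          startPos <- start(exg)[j] + offS
          endPos <- end(exg)[k] + offE
          chrom <- as.character(seqnames(genes))[gi]
          strd <- as.character(strand(genes))[gi]
        } else {
          ch <- chains(chainSet)[[sample.int(length(chains(chainSet)), 1L)]]
          chrom <- ch$sName
          span <- ch$sEnd - ch$sStart
          startPos <- ch$sStart + sample.int(max(1L, span - minWidth -
                                                   2000L), 1L)
          endPos <- startPos + minWidth + sample.int(2000L, 1L)
          strd <- sample(c("+", "-"), 1L)
        }
        if (endPos - startPos + 1L < minWidth) next
        l5 <- .liftPos1(chainSet, chrom, startPos)
        l3 <- .liftPos1(chainSet, chrom, endPos)
        if (is.null(l5) || is.null(l3)) next
        if (l5$chrom == l3$chrom && abs(l5$pos - l3$pos) < 150L) next
        if (!spaced(usedSrc, chrom, startPos) ||
            !spaced(usedSrc, chrom, endPos)) next
        if (!spaced(usedTgt, l5$chrom, l5$pos) ||
            !spaced(usedTgt, l3$chrom, l3$pos)) next
        usedSrc <- note(note(usedSrc, chrom, startPos), chrom, endPos)
        usedTgt <- note(note(usedTgt, l5$chrom, l5$pos), l3$chrom, l3$pos)
        circList[[i]] <- GRanges(chrom, IRanges(startPos, endPos),
                                 strand = strd)
        done <- TRUE
        break
      }
      if (!done)
        stop("generation error: could not place circRNA ", i,
             " with category ", cat_i, call. = FALSE)
    }
    circs <- suppressWarnings(do.call(c, circList))
    circs$circ_id <- sprintf("tc%03d", seq_len(nCirc))
    circs$category <- categories

    # boundary class and host gene, computed directly from the models
    hostGene <- character(nCirc)
    bclass <- character(nCirc)
    for (i in seq_len(nCirc)) {
      ov <- which(as.character(seqnames(genes)) ==
                    as.character(seqnames(circs))[i] &
                    start(genes) <= end(circs)[i] &
                    end(genes) >= start(circs)[i])
      if (length(ov) == 0L) {
        hostGene[i] <- ""
        bclass[i] <- "intergenic"
      } else {
        hostGene[i] <- names(genes)[ov[1L]]
        exAll <- unlist(ex[ov], use.names = FALSE)
        sOK <- length(exAll) && any(start(exAll) == start(circs)[i])
        eOK <- length(exAll) && any(end(exAll) == end(circs)[i])
        bclass[i] <- if (sOK && eOK) "both_ends" else
          if (sOK || eOK) "one_end" else "neither"
      }
    }
    circs$hostGene <- hostGene
    circs$boundaryClass <- bclass

    de <- if (is.null(deFold))
      matrix(1, nCirc, length(groups),
             dimnames = list(circs$circ_id, groups))
    else deFold
    new("SyntheticTruth", circs = circs, spongeSites = list(),
        deEffects = de, seed = as.integer(seed))
  })
}

#' Generate a circRNA database realizing the planted categories
#'
#' Places target-genome database records so that lifting each truth
#' circRNA and running \code{\link{classifyConservation}} returns exactly
#' its planted category. Positive matches are planted at offsets drawn
#' from the inclusive tolerance window (\code{-tol..+tol}); negative
#' cases (\code{no_homologous}) get a record exactly \code{tol + 1} bases
#' off at both ends, probing the classifier's boundary. A mapped-category
#' circRNA whose end fails to lift (or a \code{not_aligned} one whose
#' ends all lift) is a generation error.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param chainSet the \linkS4class{ChainSet} the truth was built with.
#' @param toleranceNt the classifier tolerance the database is built for
#'   (default 2).
#' @return \code{GRanges} of database records with \code{circ_id} and
#'   \code{hostGene} columns (target genome).
#' @export
genCircDb <- function(truth, chainSet, toleranceNt = 2L) {
  circs <- truth@circs
  .withSeed(truth@seed + 1L, {
    recs <- list()
    addRec <- function(chrom, lo, hi) {
      recs[[length(recs) + 1L]] <<- GRanges(chrom, IRanges(min(lo, hi),
                                                           max(lo, hi)))
    }
    for (i in seq_along(circs)) {
      chrom <- as.character(seqnames(circs))[i]
      strd <- as.character(strand(circs))[i]
      eff <- if (strd == "-") "-" else "+"
      p5 <- if (eff == "+") start(circs)[i] else end(circs)[i]
      p3 <- if (eff == "+") end(circs)[i] else start(circs)[i]
      l5 <- .liftPos1(chainSet, chrom, p5)
      l3 <- .liftPos1(chainSet, chrom, p3)
      cat_i <- circs$category[i]
      if (cat_i == "not_aligned") {
        if (!is.null(l5) && !is.null(l3))
          stop("generation error: circRNA ", circs$circ_id[i],
               " planted not_aligned but both ends lift", call. = FALSE)
        next
      }
      if (is.null(l5) || is.null(l3))
        stop("generation error: circRNA ", circs$circ_id[i],
             " planted ", cat_i, " but an end does not lift",
             call. = FALSE)
      delta <- function() sample(seq.int(-toleranceNt, toleranceNt), 1L)
      far <- function() 60L + sample.int(20L, 1L)
      if (cat_i == "homologous") {
        addRec(l5$chrom, l5$pos + delta(), l3$pos + delta())
      } else if (cat_i == "five_prime_utilized") {
        off <- if (l5$pos < l3$pos) far() else -far()
        addRec(l5$chrom, l5$pos + delta(), l5$pos + off)
      } else if (cat_i == "three_prime_utilized") {
        off <- if (l3$pos < l5$pos) far() else -far()
        addRec(l3$chrom, l3$pos + delta(), l3$pos + off)
      } else if (cat_i == "both_sites_utilized") {
        off5 <- if (l5$pos < l3$pos) far() else -far()
        off3 <- if (l3$pos < l5$pos) far() else -far()
        addRec(l5$chrom, l5$pos + delta(), l5$pos + off5)
        addRec(l3$chrom, l3$pos + delta(), l3$pos + off3)
      } else if (cat_i == "no_homologous") {
        s <- sample(c(-1L, 1L), 1L)
        lo <- min(l5$pos, l3$pos)
        hi <- max(l5$pos, l3$pos)
        addRec(l5$chrom, lo - s * (toleranceNt + 1L),
               hi + s * (toleranceNt + 1L))
      }
    }
    if (length(recs) == 0L)
      return(GRanges())
    db <- suppressWarnings(do.call(c, recs))
    db$circ_id <- sprintf("DB%04d", seq_along(db))
    db$hostGene <- ""
    db
  })
}

#' Generate two caller tables from planted truth
#'
#' Each true circRNA appears in both callers' tables unless dropped
#' (per-caller Bernoulli dropout); counts are drawn independently per
#' caller and sample from a negative binomial with mean
#' \code{countMean * foldChange(group(sample))} and the given dispersion
#' (variance \code{mu + dispersion * mu^2}), the low-mean, high-variance
#' regime typical of backsplice counts. False positives are
#' caller-private junctions at positions distinct from every true
#' junction. \code{countFloor} raises all true-circ counts to a minimum,
#' for noiseless fixtures where every sample must pass the expression
#' threshold.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param design sample sheet data.frame.
#' @param fpRate length-2 vector: fraction of caller-private false
#'   junctions added to callers a and b (relative to the true count).
#' @param dropoutRate per-circ, per-caller probability of being missed.
#' @param countMean,countDispersion negative-binomial parameters
#'   (defaults 4 and 0.5).
#' @param countFloor minimum true-circ count (default 0 = no floor).
#' @param seed integer seed (defaults to the truth's seed + 2).
#' @return list with elements \code{a} and \code{b}, both
#'   \linkS4class{BsjCallSet}s.
#' @export
genCallerTables <- function(truth, design, fpRate = c(0.1, 0.1),
                            dropoutRate = 0, countMean = 4,
                            countDispersion = 0.5, countFloor = 0L,
                            seed = NULL) {
  if (is.null(seed)) seed <- truth@seed + 2L
  circs <- truth@circs
  n <- length(circs)
  samples <- design$sample_id
  grp <- design$group
  fc <- matrix(1, n, length(samples))
  if (ncol(truth@deEffects)) {
    m <- match(grp, colnames(truth@deEffects))
    known <- !is.na(m)
    fc[, known] <- truth@deEffects[, m[known], drop = FALSE]
  }
  size <- 1 / countDispersion
  trueKeys <- .junctionKey(circs)
  chromMax <- tapply(end(circs), as.character(seqnames(circs)), max)

  .withSeed(seed, {
    makeCaller <- function(callerId, fpFrac) {
      kept <- runif(n) >= dropoutRate
      cnt <- matrix(0L, sum(kept), length(samples))
      rows <- which(kept)
      for (r in seq_along(rows)) {
        mu <- countMean * fc[rows[r], ]
        cnt[r, ] <- pmax(rnbinom(length(samples), mu = mu, size = size),
                         countFloor)
      }
      gr <- circs[kept]
      circType <- ifelse(gr$boundaryClass == "both_ends", "exonic",
                         ifelse(gr$boundaryClass == "intergenic",
                                "intergenic", "unknown"))
      mcols(gr) <- NULL
      nFP <- round(fpFrac * n)
      if (nFP > 0L) {
        fpList <- list()
        existing <- trueKeys
        attempts <- 0L
        while (length(fpList) < nFP && attempts < nFP * 50L) {
          attempts <- attempts + 1L
          chrom <- sample(names(chromMax), 1L)
          s <- sample.int(as.integer(chromMax[[chrom]]) + 10000L, 1L)
          e <- s + 100L + sample.int(900L, 1L)
          strd <- sample(c("+", "-"), 1L)
          key <- paste(chrom, s, e, strd, sep = ":")
          if (key %in% existing) next
          existing <- c(existing, key)
          fpList[[length(fpList) + 1L]] <- GRanges(chrom, IRanges(s, e),
                                                   strand = strd)
        }
        fpGr <- suppressWarnings(do.call(c, fpList))
        fpCnt <- matrix(pmax(rnbinom(length(fpGr) * length(samples),
                                     mu = countMean, size = size), 0L),
                        length(fpGr), length(samples))
        gr <- suppressWarnings(c(gr, fpGr))
        cnt <- rbind(cnt, fpCnt)
        circType <- c(circType, rep("unknown", length(fpGr)))
      }
      colnames(cnt) <- samples
      BsjCallSet(gr, cnt, callerId = callerId, circType = circType)
    }
    list(a = makeCaller("callerA", fpRate[1L]),
         b = makeCaller("callerB", fpRate[2L]))
  })
}

#' Generate a sponge-screen fixture with planted binding sites
#'
#' Builds a background circRNA sequence by rejection sampling so that no
#' window anywhere reaches \code{minSeedPairs} seed-complementary pairs
#' to the miRNA (so the scanner finds nothing in pure background), then
#' implants exact reverse complements of the miRNA's first
#' \code{min(length, maxSiteLen)} bases at recorded, non-overlapping
#' positions.
#'
#' @param seed integer seed.
#' @param circLength background sequence length.
#' @param mirna named character (\code{c(name = "sequence")}) or a
#'   single-row data.frame from \code{\link{readMirnaRecords}}.
#' @param nPlantedSites number of sites to implant (0 = pure background);
#'   requires \code{nPlantedSites * (site + spacing) <= circLength}.
#' @param spacing minimum gap between consecutive planted sites.
#' @param seedSpan,minSeedPairs,maxSiteLen scanner parameters the
#'   background is cleaned against (keep in sync with the scan).
#' @return list with \code{sequence} (\code{RNAString}), \code{sites}
#'   (data.frame \code{start}, \code{end}, 1-based closed), and
#'   \code{mirna} (name).
#' @export
genSpongeFixture <- function(seed, circLength = 500L, mirna,
                             nPlantedSites = 5L, spacing = 30L,
                             seedSpan = c(1L, 8L), minSeedPairs = 6L,
                             maxSiteLen = 20L) {
  if (is.data.frame(mirna)) {
    mirName <- mirna$name[1L]
    mirSeq <- mirna$sequence[1L]
  } else {
    mirName <- if (!is.null(names(mirna))) names(mirna)[1L] else "miRNA"
    mirSeq <- unname(mirna[1L])
  }
  m <- .rnaCodes(mirSeq, "miRNA sequence")
  w <- min(length(m), maxSiteLen)
  if (nPlantedSites * (w + spacing) > circLength)
    stop("sizing error: planted sites do not fit the sequence",
         call. = FALSE)
  seedIdx <- seq.int(max(1L, seedSpan[1L]), min(seedSpan[2L], w))

  .withSeed(seed, {
    t <- sample.int(4L, circLength, replace = TRUE)
    badWindows <- function(t) {
      L <- length(t)
      if (L < w) return(integer())
      ends <- w:L
      sp <- integer(length(ends))
      for (i in seedIdx)
        sp <- sp + .IS_PAIR[m[i], t[ends - i + 1L]]
      ends[sp >= minSeedPairs]
    }
    for (iter in seq_len(500L)) {
      bw <- badWindows(t)
      if (length(bw) == 0L) break
      # resample the seed footprint of each offending window
      pos <- unique(unlist(lapply(bw, function(e) e - seedIdx + 1L)))
      t[pos] <- sample.int(4L, length(pos), replace = TRUE)
    }
    if (length(badWindows(t)) > 0L)
      stop("could not build a seed-free background", call. = FALSE)
    sites <- data.frame(start = integer(), end = integer())
    if (nPlantedSites > 0L) {
      siteCodes <- rev(5L - m[seq_len(w)])  # reverse complement (A<->U, C<->G)
      starts <- spacing + (seq_len(nPlantedSites) - 1L) * (w + spacing) -
        spacing + 1L
      for (s in starts) t[s:(s + w - 1L)] <- siteCodes
      sites <- data.frame(start = starts, end = starts + w - 1L)
    }
    list(sequence = RNAString(paste(.RNA_BASES[t], collapse = "")),
         sites = sites, mirna = mirName)
  })
}

#' Generate a group-labelled count matrix
#'
#' Negative-binomial counts for every planted circRNA in every sample,
#' with the mean scaled by the circRNA's fold-change in the sample's
#' group, plus per-sample mapped-read totals for SRPBM.
#'
#' @param design sample sheet data.frame.
#' @param truth a \linkS4class{SyntheticTruth}, a fold-change matrix
#'   (circ x group), or NULL for a null model of \code{nCirc} circRNAs.
#' @param librarySizes per-sample mapped-read totals; a single value is
#'   recycled.
#' @param nCirc number of circRNAs when \code{truth} is NULL.
#' @param countMean,countDispersion negative-binomial parameters.
#' @param seed integer seed.
#' @return list with \code{counts} (matrix) and \code{mappedTotals}
#'   (named vector).
#' @export
genCounts <- function(design, truth = NULL, librarySizes = 2e7,
                      nCirc = 100L, countMean = 4, countDispersion = 0.5,
                      seed = 1L) {
  samples <- design$sample_id
  fcMat <- if (is(truth, "SyntheticTruth")) truth@deEffects
    else if (is.matrix(truth)) truth
    else matrix(1, nCirc, length(unique(design$group)),
                dimnames = list(sprintf("circ%04d", seq_len(nCirc)),
                                unique(design$group)))
  n <- nrow(fcMat)
  ids <- rownames(fcMat)
  if (is.null(ids)) ids <- sprintf("circ%04d", seq_len(n))
  totals <- setNames(rep(librarySizes, length.out = length(samples)),
                     samples)
  m <- match(design$group, colnames(fcMat))
  .withSeed(seed, {
    cnt <- matrix(0L, n, length(samples), dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      fc <- if (is.na(m[j])) rep(1, n) else fcMat[, m[j]]
      cnt[, j] <- rnbinom(n, mu = countMean * fc,
                          size = 1 / countDispersion)
    }
    list(counts = cnt, mappedTotals = totals)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates annotation, chain, truth, caller tables, circRNA database,
#' a sponge fixture and a sample sheet under one seed and writes them to
#' \code{dir} as plain-text files (GTF, two caller tables, chain, circ
#' DB table, FASTA, sample sheet, truth tables).
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param nCirc number of planted circRNAs.
#' @return invisibly, a named list of the written file paths.
#' @export
writeFixtureBundle <- function(seed, dir, nCirc = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- genAnnotation(seed)
  chain <- genChain(seed + 1L)
  truth <- genTruth(seed + 2L, models, chain, nCirc = nCirc)
  design <- exampleDesign("encephalon")
  tables <- genCallerTables(truth, design, fpRate = c(0.1, 0.1))
  db <- genCircDb(truth, chain)
  mir <- c("miR-sim" = "UGGAAGACUAGUGAUUUUGUUGU")
  sponge <- genSpongeFixture(seed + 3L, circLength = 600L, mirna = mir,
                             nPlantedSites = 4L)
  paths <- list(
    gtf = file.path(dir, "annotation.gtf"),
    callerA = file.path(dir, "caller_a.tsv"),
    callerB = file.path(dir, "caller_b.tsv"),
    chain = file.path(dir, "lift.chain"),
    circDb = file.path(dir, "circ_db.tsv"),
    fasta = file.path(dir, "sponge_circ.fa"),
    design = file.path(dir, "samples.tsv"),
    truthCircs = file.path(dir, "truth_circs.tsv"),
    truthSites = file.path(dir, "truth_sponge_sites.tsv"))
  writeGtf(models, paths$gtf)
  writeCallerTable(tables$a, paths$callerA)
  writeCallerTable(tables$b, paths$callerB)
  writeChain(chain, paths$chain)
  writeCircDb(db, paths$circDb)
  seqs <- DNAStringSet(chartr("U", "T", as.character(sponge$sequence)))
  names(seqs) <- "sponge_circ"
  Biostrings::writeXStringSet(seqs, paths$fasta)
  writeTable(design, paths$design)
  tc <- truth@circs
  writeTable(data.frame(circ_id = tc$circ_id,
                        chrom = as.character(seqnames(tc)),
                        start = start(tc), end = end(tc),
                        strand = as.character(strand(tc)),
                        category = tc$category,
                        hostGene = tc$hostGene,
                        boundaryClass = tc$boundaryClass),
             paths$truthCircs)
  writeTable(sponge$sites, paths$truthSites)
  invisible(paths)
}
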