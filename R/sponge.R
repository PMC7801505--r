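# miRNA sponge screening: cluster intersection, orthology filtering,
# seed-anchored duplex scanning, overlap removal, per-base ratio, and
# duplex profiling.
#
# The duplex scorer is a deliberately simple integer model (it is not a
# thermodynamic free-energy model): Watson-Crick pair -2, G:U wobble -1,
# mismatch +1, per-gap +3. Scanning is gapless, so the gap penalty only
# matters for the documented score scale. Parameters mirror the common
# screen settings: seed span 1:8 with >= 6 complementary pairs, duplex
# length cap 20 nt, score cutoff -10.

.RNA_BASES <- c("A", "C", "G", "U")

# score[m, t]: miRNA base m against target base t
.PAIR_SCORE <- matrix(1L, 4L, 4L,
                      dimnames = list(.RNA_BASES, .RNA_BASES))
.PAIR_SCORE["A", "U"] <- .PAIR_SCORE["U", "A"] <- -2L
.PAIR_SCORE["G", "C"] <- .PAIR_SCORE["C", "G"] <- -2L
.PAIR_SCORE["G", "U"] <- .PAIR_SCORE["U", "G"] <- -1L

.IS_PAIR <- .PAIR_SCORE < 0L          # WC or wobble
.IS_CANONICAL <- .PAIR_SCORE == -2L   # WC only

#' @noRd
.rnaCodes <- function(seq, what = "sequence") {
  s <- toupper(as.character(seq))
  s <- chartr("T", "U", s)
  codes <- match(strsplit(s, "")[[1L]], .RNA_BASES)
  if (anyNA(codes))
    stop("alphabet violation in ", what, ": only A/C/G/U (or T) allowed",
         call. = FALSE)
  codes
}

#' Intersect lifted circRNAs with reported miRNA sponge clusters
#'
#' A (circRNA, cluster) pair is reported when the overlap covers at least
#' \code{minFrac} of the \emph{cluster} (the sponge candidate: the screen
#' asks whether the circRNA contains the reported cluster). Computing the
#' fraction relative to the circRNA instead is available via
#' \code{fracOf = "circ"}.
#'
#' @param liftedCircs \code{GRanges} of circRNA intervals on the target
#'   genome, with a \code{circ_id} column.
#' @param clusters \code{GRanges} of reported binding-site clusters with
#'   \code{mirna} (and optionally \code{reportedSiteCount}) columns.
#' @param minFrac minimum overlap fraction, inclusive (default 0.75).
#' @param fracOf denominator of the fraction: \code{"cluster"} (default)
#'   or \code{"circ"}.
#' @return \code{DataFrame} with \code{circ_id}, \code{mirna},
#'   \code{clusterIdx}, \code{overlapFraction}.
#' @export
intersectClusters <- function(liftedCircs, clusters, minFrac = 0.75,
                              fracOf = c("cluster", "circ")) {
  fracOf <- match.arg(fracOf)
  hits <- findOverlaps(liftedCircs, clusters, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(DataFrame(circ_id = character(), mirna = character(),
                     clusterIdx = integer(), overlapFraction = numeric()))
  ov <- width(pintersect(ranges(liftedCircs)[queryHits(hits)],
                         ranges(clusters)[subjectHits(hits)]))
  denom <- if (fracOf == "cluster") width(clusters)[subjectHits(hits)]
    else width(liftedCircs)[queryHits(hits)]
  frac <- ov / denom
  keep <- frac >= minFrac
  ids <- if (!is.null(liftedCircs$circ_id)) liftedCircs$circ_id else
    paste0("circ", seq_along(liftedCircs))
  mir <- if (!is.null(clusters$mirna)) clusters$mirna else
    paste0("cluster", seq_along(clusters))
  DataFrame(circ_id = ids[queryHits(hits)[keep]],
            mirna = mir[subjectHits(hits)[keep]],
            clusterIdx = subjectHits(hits)[keep],
            overlapFraction = frac[keep])
}

#' Read a BED-plus file of miRNA sponge clusters
#'
#' BED6 plus a seventh column with the reported binding-site count; the
#' BED name field is the sponged miRNA.
#'
#' @param path input path.
#' @return \code{GRanges} with \code{mirna} and \code{reportedSiteCount}.
#' @export
readClustersBed <- function(path) {
  gr <- readBed(path)
  gr$mirna <- gr$name
  gr$name <- NULL
  if (!is.null(gr$extra1)) {
    gr$reportedSiteCount <- as.integer(gr$extra1)
    gr$extra1 <- NULL
    if (any(gr$reportedSiteCount < 1L))
      stop("reported site counts must be >= 1", call. = FALSE)
  }
  gr
}

#' Read mature miRNA records with orthology evidence
#'
#' @param fastaPath FASTA of mature miRNA sequences (RNA alphabet; T is
#'   accepted and transcribed).
#' @param orthoPath tab-separated table with header \code{name},
#'   \code{orthology_confident} (TRUE/FALSE), and optional
#'   \code{hairpin_identity}, \code{hairpin_coverage} (fractions, may be
#'   empty) from a precomputed hairpin alignment screen.
#' @return data.frame with columns \code{name}, \code{sequence},
#'   \code{orthologyConfident}, \code{hairpinIdentity},
#'   \code{hairpinCoverage}.
#' @export
readMirnaRecords <- function(fastaPath, orthoPath) {
  seqs <- readFastaSeqs(fastaPath, type = "RNA")
  ortho <- read.delim(orthoPath, header = TRUE)
  if (!all(c("name", "orthology_confident") %in% names(ortho)))
    stop("orthology table requires columns name, orthology_confident",
         call. = FALSE)
  m <- match(names(seqs), ortho$name)
  if (anyNA(m))
    stop("orthology table is missing miRNA(s): ",
         paste(names(seqs)[is.na(m)], collapse = ", "), call. = FALSE)
  data.frame(name = names(seqs),
             sequence = as.character(seqs),
             orthologyConfident = as.logical(ortho$orthology_confident[m]),
             hairpinIdentity = if ("hairpin_identity" %in% names(ortho))
               as.numeric(ortho$hairpin_identity[m]) else NA_real_,
             hairpinCoverage = if ("hairpin_coverage" %in% names(ortho))
               as.numeric(ortho$hairpin_coverage[m]) else NA_real_)
}

#' Filter sponge pairs by miRNA orthology confidence
#'
#' A (circRNA, miRNA) pair survives when the miRNA has a high-confidence
#' orthologue in the study species, or when its precomputed hairpin
#' alignment reaches the identity and coverage thresholds (both
#' inclusive).
#'
#' @param pairs \code{DataFrame} from \code{\link{intersectClusters}}.
#' @param mirnas data.frame from \code{\link{readMirnaRecords}}.
#' @param minIdentity minimum hairpin identity (default 0.90).
#' @param minCoverage minimum hairpin coverage (default 0.95).
#' @return the surviving rows of \code{pairs}.
#' @export
filterOrthology <- function(pairs, mirnas, minIdentity = 0.90,
                            minCoverage = 0.95) {
  m <- match(pairs$mirna, mirnas$name)
  if (anyNA(m))
    stop("miRNA record(s) missing: ",
         paste(unique(pairs$mirna[is.na(m)]), collapse = ", "),
         call. = FALSE)
  conf <- mirnas$orthologyConfident[m]
  idy <- mirnas$hairpinIdentity[m]
  cov <- mirnas$hairpinCoverage[m]
  byAln <- !is.na(idy) & !is.na(cov) & idy >= minIdentity & cov >= minCoverage
  pairs[conf | byAln, , drop = FALSE]
}

#' Scan a circRNA sequence for miRNA binding sites
#'
#' Slides a gapless duplex of length \code{min(length(miRNA), maxSiteLen)}
#' along the target; miRNA position 1 (5' end) pairs with the 3'-most base
#' of the target window (antiparallel). A window is reported when at
#' least \code{minSeedPairs} of the miRNA seed positions
#' (\code{seedSpan[1]}..\code{seedSpan[2]}) form Watson-Crick or G:U
#' pairs, and the total duplex score (WC -2, G:U -1, mismatch +1) is at
#' most \code{scoreThreshold}. DNA input is transcribed.
#'
#' @param circSeq target sequence (character, \code{RNAString} or
#'   \code{DNAString}).
#' @param mirna miRNA: a single row of \code{\link{readMirnaRecords}}
#'   output, or a named character (\code{c(name = sequence)}), or a plain
#'   sequence string.
#' @param seedSpan integer length-2, seed positions on the miRNA
#'   (default \code{c(1, 8)}).
#' @param minSeedPairs minimum complementary pairs within the seed
#'   (default 6).
#' @param maxSiteLen maximum duplex length in target bases (default 20).
#' @param scoreThreshold keep sites scoring at or below this (default
#'   -10; relaxing it towards 0 can only add sites).
#' @param circId identifier stored in the result.
#' @return \code{DataFrame} of sites: \code{circ_id}, \code{start},
#'   \code{end} (1-based closed on the circRNA sequence), \code{mirna},
#'   \code{score}, \code{seedPairs}, \code{mismatches}; sorted by start.
#' @export
scanBindingSites <- function(circSeq, mirna, seedSpan = c(1L, 8L),
                             minSeedPairs = 6L, maxSiteLen = 20L,
                             scoreThreshold = -10, circId = "circ") {
  if (is.data.frame(mirna)) {
    stopifnot(nrow(mirna) == 1L)
    mirName <- mirna$name
    mirSeq <- mirna$sequence
  } else if (!is.null(names(mirna)) && nzchar(names(mirna)[1L])) {
    mirName <- names(mirna)[1L]
    mirSeq <- unname(mirna[1L])
  } else {
    mirName <- "miRNA"
    mirSeq <- as.character(mirna)
  }
  t <- .rnaCodes(circSeq, "target sequence")
  m <- .rnaCodes(mirSeq, "miRNA sequence")
  L <- length(t)
  w <- min(length(m), maxSiteLen)
  if (w < 1L || L < w)
    return(DataFrame(circ_id = character(), start = integer(),
                     end = integer(), mirna = character(),
                     score = integer(), seedPairs = integer(),
                     mismatches = integer()))
  ends <- w:L
  score <- integer(length(ends))
  seedPairs <- integer(length(ends))
  mism <- integer(length(ends))
  seedIdx <- seq.int(max(1L, seedSpan[1L]), min(seedSpan[2L], w))
  for (i in seq_len(w)) {
    tb <- t[ends - i + 1L]
    sc <- .PAIR_SCORE[m[i], tb]
    score <- score + sc
    pair <- .IS_PAIR[m[i], tb]
    if (i %in% seedIdx) seedPairs <- seedPairs + pair
    mism <- mism + !pair
  }
  keep <- unname(seedPairs >= minSeedPairs & score <= scoreThreshold)
  DataFrame(circ_id = rep(circId, sum(keep)),
            start = ends[keep] - w + 1L, end = ends[keep],
            mirna = rep(mirName, sum(keep)),
            score = unname(score[keep]),
            seedPairs = unname(seedPairs[keep]),
            mismatches = unname(mism[keep]))
}

#' Remove overlapping binding sites
#'
#' Greedy selection by ascending score (strongest, i.e. most negative,
#' first), ties broken by leftmost start then shortest site; a site is
#' kept only when it overlaps no already-kept site. Input must be sites
#' on a single circRNA.
#'
#' @param sites \code{DataFrame} or data.frame with \code{start},
#'   \code{end}, \code{score} columns (as from
#'   \code{\link{scanBindingSites}}).
#' @return the kept rows, sorted by start.
#' @export
removeOverlaps <- function(sites) {
  n <- nrow(sites)
  if (is.null(n) || n == 0L) return(sites)
  if (length(unique(sites$circ_id)) > 1L)
    stop("all sites must be on one circRNA", call. = FALSE)
  ord <- order(sites$score, sites$start, sites$end - sites$start)
  keptStart <- numeric(0)
  keptEnd <- numeric(0)
  keep <- logical(n)
  for (i in ord) {
    s <- sites$start[i]; e <- sites$end[i]
    if (!any(s <= keptEnd & e >= keptStart)) {
      keep[i] <- TRUE
      keptStart <- c(keptStart, s)
      keptEnd <- c(keptEnd, e)
    }
  }
  out <- sites[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Per-base binding-site ratio
#'
#' Number of (non-overlapping) binding sites divided by the length of the
#' harbouring sequence; the density statistic used to compare sponge
#' candidates of different lengths.
#'
#' @param sites sites table (after \code{\link{removeOverlaps}}).
#' @param circLength length of the circRNA sequence (> 0).
#' @return a single number.
#' @examples
#' perBaseRatio(data.frame(start = 1:3, end = 2:4, score = -20), 1000)
#' @export
perBaseRatio <- function(sites, circLength) {
  if (circLength <= 0) stop("circLength must be > 0", call. = FALSE)
  nrow(sites) / circLength
}

#' Profile a miRNA:site duplex
#'
#' Gapless end-to-end alignment of the miRNA against a binding-site
#' sequence (miRNA position 1 pairing the site's 3' end). Reports the
#' number of canonical (Watson-Crick) pairs inside the seed, the total
#' number of mismatches (positions that are neither WC nor G:U), and a
#' pairing string along the miRNA (5' to 3'): \code{|} WC, \code{:} G:U
#' wobble, \code{.} mismatch.
#'
#' @param mirnaSeq miRNA sequence.
#' @param siteSeq binding-site sequence (target strand, 5' to 3').
#' @param seedSpan seed positions on the miRNA (default \code{c(1, 8)}).
#' @return list with \code{seedCanonical}, \code{mismatches},
#'   \code{pairing}.
#' @export
duplexProfile <- function(mirnaSeq, siteSeq, seedSpan = c(1L, 8L)) {
  m <- .rnaCodes(mirnaSeq, "miRNA sequence")
  s <- .rnaCodes(siteSeq, "site sequence")
  w <- min(length(m), length(s))
  sym <- character(length(m))
  sym[] <- " "
  canonical <- logical(length(m))
  pairflag <- logical(length(m))
  for (i in seq_len(w)) {
    tb <- s[length(s) - i + 1L]
    canonical[i] <- .IS_CANONICAL[m[i], tb]
    pairflag[i] <- .IS_PAIR[m[i], tb]
    sym[i] <- if (canonical[i]) "|" else if (pairflag[i]) ":" else "."
  }
  seedIdx <- seq.int(max(1L, seedSpan[1L]), min(seedSpan[2L], w))
  list(seedCanonical = sum(canonical[seedIdx]),
       mismatches = sum(!pairflag[seq_len(w)]),
       pairing = paste(sym, collapse = ""))
}
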