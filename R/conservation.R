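# Chain-file liftover and cross-species backsplice conservation
# classification.

# Map a single 0-based source position through one chain by walking its
# blocks. Returns the 0-based target position on the + strand of the
# target sequence, or NA when the position falls in a gap.
#' @noRd
.mapPosThroughChain <- function(ch, pos0) {
  if (pos0 < ch$sStart || pos0 >= ch$sEnd) return(NA_real_)
  curS <- ch$sStart
  curT <- ch$tStart
  b <- ch$blocks
  for (k in seq_len(nrow(b))) {
    size <- b[k, "size"]
    if (pos0 < curS + size) {
      tpos <- curT + (pos0 - curS)
      if (ch$tStrand == "-") tpos <- ch$tSize - 1 - tpos
      return(tpos)
    }
    curS <- curS + size + b[k, "sGap"]
    curT <- curT + size + b[k, "tGap"]
    if (pos0 < curS) return(NA_real_)   # inside the source gap
  }
  NA_real_
}

# Pick the chain used for a query: best score among chains whose source
# side overlaps the query; ties broken deterministically by lowest chain
# id (numeric when possible, else lexicographic).
#' @noRd
.selectChain <- function(chainList, chrom, start0, end0) {
  cand <- Filter(function(ch)
    ch$sName == chrom && start0 < ch$sEnd && end0 > ch$sStart, chainList)
  if (length(cand) == 0L) return(NULL)
  scores <- vapply(cand, `[[`, 0, "score")
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    ids <- vapply(cand[best], `[[`, "", "id")
    idsNum <- suppressWarnings(as.numeric(ids))
    ord <- if (all(!is.na(idsNum))) order(idsNum) else order(ids)
    best <- best[ord[1L]]
  }
  cand[[best]]
}

#' Lift genomic intervals through a chain file
#'
#' Reimplements interval liftover over UCSC chains: each query base is
#' mapped through the aligned blocks of the best-scoring chain overlapping
#' the query (score ties broken by lowest chain id). A query is
#' \code{mapped} when the fraction of its bases that map is at least
#' \code{minRatio} and the mapped bases are colinear on a single target
#' chromosome and strand; otherwise it is \code{unmapped}. Under a chain
#' whose target strand is \code{-} the result is reported on the target's
#' plus strand with the strand flag flipped. Backsplice ends are lifted as
#' 1-base intervals, for which \code{minRatio} is all-or-none.
#'
#' @param chainSet a \linkS4class{ChainSet}.
#' @param query \code{GRanges} of source-genome intervals.
#' @param minRatio minimum fraction of remapped bases (default 0.95, the
#'   liftOver default).
#' @return \code{DataFrame} with columns \code{status} ("mapped" /
#'   "unmapped"), \code{targetChrom}, \code{targetStart}, \code{targetEnd}
#'   (1-based closed; NA when unmapped), \code{targetStrand}, and
#'   \code{remapRatio}.
#' @export
liftInterval <- function(chainSet, query, minRatio = 0.95) {
  stopifnot(is(chainSet, "ChainSet"), is(query, "GRanges"))
  chainList <- chains(chainSet)
  n <- length(query)
  status <- rep("unmapped", n)
  tChrom <- rep(NA_character_, n)
  tStart <- tEnd <- rep(NA_integer_, n)
  tStrand <- rep(NA_character_, n)
  ratio <- rep(0, n)
  for (i in seq_len(n)) {
    s0 <- start(query)[i] - 1L       # internal 1-based -> 0-based
    e0 <- end(query)[i]              # half-open end
    ch <- .selectChain(chainList, as.character(seqnames(query))[i], s0, e0)
    if (is.null(ch)) next
    pos <- s0:(e0 - 1L)
    mapped <- vapply(pos, function(p) .mapPosThroughChain(ch, p), 0)
    ok <- !is.na(mapped)
    ratio[i] <- sum(ok) / length(pos)
    if (ratio[i] < minRatio || !any(ok)) next
    m <- mapped[ok]
    # colinearity on the target: consecutive mapped bases must be strictly
    # monotone in the direction implied by the chain's target strand
    if (length(m) > 1L) {
      d <- diff(m)
      if (ch$tStrand == "-" && any(d >= 0)) next
      if (ch$tStrand != "-" && any(d <= 0)) next
    }
    status[i] <- "mapped"
    tChrom[i] <- ch$tName
    tStart[i] <- as.integer(min(m)) + 1L
    tEnd[i] <- as.integer(max(m)) + 1L
    qs <- as.character(strand(query))[i]
    tStrand[i] <- if (ch$tStrand == "-") {
      if (qs == "+") "-" else if (qs == "-") "+" else "*"
    } else qs
  }
  DataFrame(status = status, targetChrom = tChrom, targetStart = tStart,
            targetEnd = tEnd, targetStrand = tStrand, remapRatio = ratio)
}

#' Classify backsplice conservation against a circRNA database
#'
#' For each candidate the two backsplice ends (strand-resolved: 5' end =
#' start on +, end on -; unknown strand assumed + and flagged) are lifted
#' as 1-base intervals through the chain set, then compared to database
#' records on the target genome. A lifted end matches a database splice
#' site when both are on the same target chromosome and within
#' \code{toleranceNt} bases (inclusive on both sides, so the default 2
#' spans 5 positions). Categories:
#' \describe{
#'   \item{not_aligned}{either end failed to lift.}
#'   \item{homologous}{one database record matches both ends (its two ends
#'     pair with the circRNA's two lifted ends).}
#'   \item{both_sites_utilized}{both ends match, but only via different
#'     records.}
#'   \item{five_prime_utilized / three_prime_utilized}{exactly one end
#'     matches some record.}
#'   \item{no_homologous}{neither end matches.}
#' }
#' Matching compares target coordinates only (database strand annotations
#' are unreliable across resources); \code{strict = TRUE} additionally
#' requires strand agreement for records with known strand.
#'
#' @param circs candidate circRNAs on the source genome: a
#'   \linkS4class{CircCandidateSet}, or a \code{GRanges} with a
#'   \code{circ_id} metadata column (or names).
#' @param chainSet a \linkS4class{ChainSet} from source to target genome.
#' @param db \code{GRanges} of database circRNAs on the target genome with
#'   a \code{circ_id} column (see \code{\link{readCircDb}}).
#' @param toleranceNt match tolerance around each lifted site (default 2).
#' @param minRatio passed to \code{\link{liftInterval}}.
#' @param strict require strand agreement with stranded DB records.
#' @return \code{DataFrame}, one row per candidate: \code{circ_id},
#'   lifted 5'/3' status and positions, \code{category} (factor over the
#'   six categories), \code{matched_db_ids} (CharacterList), and
#'   \code{strandAssumed} (TRUE when an unknown-strand candidate was
#'   treated as plus-strand).
#' @export
classifyConservation <- function(circs, chainSet, db, toleranceNt = 2L,
                                 minRatio = 0.95, strict = FALSE) {
  if (is(circs, "CircCandidateSet")) circs <- rowRanges(circs)
  stopifnot(is(circs, "GRanges"))
  ids <- if (!is.null(circs$circ_id)) circs$circ_id else
    if (!is.null(names(circs))) names(circs) else
      paste0("circ", seq_along(circs))
  strd <- as.character(strand(circs))
  assumed <- strd == "*"
  eff <- ifelse(assumed, "+", strd)
  p5 <- ifelse(eff == "+", start(circs), end(circs))
  p3 <- ifelse(eff == "+", end(circs), start(circs))

  ends5 <- GRanges(seqnames(circs), IRanges(p5, p5), strand = strd)
  ends3 <- GRanges(seqnames(circs), IRanges(p3, p3), strand = strd)
  lift5 <- liftInterval(chainSet, ends5, minRatio = minRatio)
  lift3 <- liftInterval(chainSet, ends3, minRatio = minRatio)

  dbChrom <- as.character(seqnames(db))
  dbStart <- start(db)
  dbEnd <- end(db)
  dbStrand <- as.character(strand(db))
  dbIds <- if (!is.null(db$circ_id)) db$circ_id else
    paste0("DB", seq_along(db))

  n <- length(circs)
  category <- character(n)
  matched <- vector("list", n)
  for (i in seq_len(n)) {
    if (lift5$status[i] != "mapped" || lift3$status[i] != "mapped") {
      category[i] <- "not_aligned"
      matched[[i]] <- character()
      next
    }
    L5 <- lift5$targetStart[i]; c5 <- lift5$targetChrom[i]
    L3 <- lift3$targetStart[i]; c3 <- lift3$targetChrom[i]
    okStrand <- if (strict) {
      ls <- lift5$targetStrand[i]
      dbStrand == "*" | ls == "*" | dbStrand == ls
    } else rep(TRUE, length(db))
    m5s <- dbChrom == c5 & abs(L5 - dbStart) <= toleranceNt & okStrand
    m5e <- dbChrom == c5 & abs(L5 - dbEnd) <= toleranceNt & okStrand
    m3s <- dbChrom == c3 & abs(L3 - dbStart) <= toleranceNt & okStrand
    m3e <- dbChrom == c3 & abs(L3 - dbEnd) <= toleranceNt & okStrand
    homo <- (m5s & m3e) | (m5e & m3s)   # one record serving both ends
    m5 <- m5s | m5e
    m3 <- m3s | m3e
    category[i] <- if (any(homo)) "homologous"
      else if (any(m5) && any(m3)) "both_sites_utilized"
      else if (any(m5)) "five_prime_utilized"
      else if (any(m3)) "three_prime_utilized"
      else "no_homologous"
    matched[[i]] <- dbIds[m5 | m3]
  }
  DataFrame(circ_id = ids,
            status5 = lift5$status, lifted5Chrom = lift5$targetChrom,
            lifted5Pos = lift5$targetStart,
            status3 = lift3$status, lifted3Chrom = lift3$targetChrom,
            lifted3Pos = lift3$targetStart,
            category = factor(category, levels = .CONS_CATEGORIES),
            matched_db_ids = CharacterList(matched),
            strandAssumed = assumed)
}

#' Summarize conservation categories
#'
#' Per-category counts and percentages. The denominator is all detected
#' circRNAs, including those whose coordinates could not be lifted
#' (\code{not_aligned}).
#'
#' @param calls either the \code{DataFrame} returned by
#'   \code{\link{classifyConservation}} or a character/factor vector of
#'   categories.
#' @param digits decimal places for the percentages (default 2).
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{percentage}; rows in canonical category order.
#' @examples
#' summarizeCategories(rep(c("homologous", "not_aligned"), c(3, 1)))
#' @export
summarizeCategories <- function(calls, digits = 2L) {
  cats <- if (is.data.frame(calls) || is(calls, "DataFrame"))
    calls$category else calls
  if (length(cats) == 0L) stop("no calls to summarize", call. = FALSE)
  cats <- factor(as.character(cats), levels = .CONS_CATEGORIES)
  if (anyNA(cats)) stop("unknown conservation category", call. = FALSE)
  counts <- table(cats)
  data.frame(category = names(counts),
             count = as.integer(counts),
             percentage = round(100 * as.integer(counts) / length(cats),
                                digits),
             row.names = NULL)
}
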