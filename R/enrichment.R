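# Term enrichment of circRNA host genes against an expressed-gene
# background: one-sided Fisher's exact tests with term-size filters and
# Benjamini-Hochberg correction, reproducible offline from a GMT file.

#' Read a GMT-style term file
#'
#' One term per line: term ID, term name, then member gene IDs, all
#' tab-separated.
#'
#' @param path GMT path.
#' @return data.frame with \code{term_id}, \code{term_name}, and a
#'   \code{genes} list-column.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1L], ": need id, name, >=1 gene",
         call. = FALSE)
  data.frame(term_id = vapply(f, `[[`, "", 1L),
             term_name = vapply(f, `[[`, "", 2L),
             genes = I(lapply(f, function(x) unique(x[-c(1L, 2L)]))))
}

#' Term over-representation analysis
#'
#' For each term the member genes are first intersected with the
#' background; terms with fewer than \code{minTerm} or more than
#' \code{maxTerm} background genes are excluded before testing (small
#' terms cost power under multiple-testing correction, huge ones have
#' little interpretative value). Surviving terms get a one-sided Fisher's
#' exact test (over-representation of the query among term members,
#' relative to the background), then Benjamini-Hochberg correction across
#' the tested terms; a term is significant when its FDR is below
#' \code{alpha}.
#'
#' @param queryGenes character vector of query gene IDs (e.g. circRNA
#'   host genes); must be a subset of the background.
#' @param termSets \code{\link{readGmt}} output, or a named list of gene
#'   ID vectors.
#' @param backgroundGenes character vector of background gene IDs (e.g.
#'   all expressed genes).
#' @param minTerm,maxTerm inclusive term-size bounds after background
#'   intersection (defaults 5 and 400).
#' @param alpha FDR cut-off (default 0.05).
#' @return data.frame with one row per tested term: \code{term_id},
#'   \code{term_name}, \code{term_size}, \code{overlap},
#'   \code{query_size}, \code{background_size}, \code{p_value},
#'   \code{fdr}, \code{significant}; sorted by p-value.
#' @export
enrich <- function(queryGenes, termSets, backgroundGenes,
                   minTerm = 5L, maxTerm = 400L, alpha = 0.05) {
  backgroundGenes <- unique(backgroundGenes)
  if (length(backgroundGenes) == 0L)
    stop("background gene set is empty", call. = FALSE)
  queryGenes <- unique(queryGenes)
  out <- setdiff(queryGenes, backgroundGenes)
  if (length(out))
    stop("query gene(s) not in background: ",
         paste(head(out, 5L), collapse = ", "), call. = FALSE)
  if (!is.data.frame(termSets)) {
    if (is.null(names(termSets))) stop("termSets must be named",
                                       call. = FALSE)
    termSets <- data.frame(term_id = names(termSets),
                           term_name = names(termSets),
                           genes = I(unname(termSets)))
  }
  N <- length(backgroundGenes)
  q <- length(queryGenes)
  rows <- lapply(seq_len(nrow(termSets)), function(i) {
    tg <- intersect(termSets$genes[[i]], backgroundGenes)
    K <- length(tg)
    if (K < minTerm || K > maxTerm) return(NULL)
    k <- length(intersect(tg, queryGenes))
    tab <- matrix(c(k, q - k, K - k, N - q - K + k), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = termSets$term_id[i],
               term_name = termSets$term_name[i],
               term_size = K, overlap = k, query_size = q,
               background_size = N, p_value = p)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      term_size = integer(), overlap = integer(),
                      query_size = integer(), background_size = integer(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical()))
  res <- do.call(rbind, rows)
  res$fdr <- bhAdjust(res$p_value)
  res$significant <- res$fdr < alpha
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}
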