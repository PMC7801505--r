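# Readers and writers for every external format the pipeline touches.
# Every reader declares its source coordinate convention and normalizes to
# the single internal convention (GRanges, 1-based closed) on entry.

.DIALECT_DEFAULT_CONVENTION <- c(dcc = "one_closed",
                                 segemehl = "zero_half_open",
                                 generic = "zero_half_open")

#' Read a caller's backsplice junction table
#'
#' Parses the tab-separated BSJ table of one circRNA caller into a
#' \linkS4class{BsjCallSet}. Three dialects are supported:
#' \describe{
#'   \item{dcc}{header with columns \code{Chr}, \code{Start}, \code{End},
#'     optionally \code{Strand}, \code{Gene}, \code{Region}; every other
#'     column is a per-sample count. Coordinates default to 1-based closed,
#'     as DCC emits them.}
#'   \item{segemehl}{BED-like: \code{chrom}, \code{start}, \code{end},
#'     \code{name}, \code{score}, \code{strand}, then per-sample counts.
#'     An optional leading \code{#}-prefixed header names the samples;
#'     without one, samples are named \code{S1..Sn}. Coordinates default
#'     to 0-based half-open. The exact layout of segemehl's splice output
#'     varies by version, so this dialect is a documented best effort and
#'     the convention is configurable.}
#'   \item{generic}{header \code{chrom}, \code{start}, \code{end},
#'     \code{strand}, then per-sample counts; 0-based half-open default.}
#' }
#' Duplicate junction rows (same chrom/start/end/strand) are summed with a
#' warning; malformed coordinates or negative counts are errors naming the
#' offending line.
#'
#' @param path path to the tab-separated table.
#' @param dialect one of \code{"dcc"}, \code{"segemehl"}, \code{"generic"}.
#' @param convention source coordinate convention, \code{"one_closed"} or
#'   \code{"zero_half_open"}; default depends on the dialect (see above).
#' @param callerId caller name stored in the result; defaults to the
#'   dialect.
#' @return A \linkS4class{BsjCallSet}.
#' @export
readCallerTable <- function(path,
                            dialect = c("generic", "dcc", "segemehl"),
                            convention = NULL,
                            callerId = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(convention)) convention <- .DIALECT_DEFAULT_CONVENTION[[dialect]]
  convention <- match.arg(convention, c("zero_half_open", "one_closed"))
  if (is.null(callerId)) callerId <- dialect
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty caller table: ", path, call. = FALSE)

  if (dialect == "segemehl") {
    hasHeader <- startsWith(lines[1L], "#")
    if (hasHeader) {
      hdr <- strsplit(sub("^#\\s*", "", lines[1L]), "\t")[[1L]]
      lines <- lines[-1L]
      firstLine <- 2L
    } else {
      hdr <- NULL
      firstLine <- 1L
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 7L))
      stop("parse error at line ", which(ncols < 7L)[1L] + firstLine - 1L,
           ": segemehl dialect needs >= 7 columns", call. = FALSE)
    mat <- do.call(rbind, fields)
    chrom <- mat[, 1L]; startRaw <- mat[, 2L]; endRaw <- mat[, 3L]
    strandRaw <- mat[, 6L]
    countCols <- mat[, 7:ncol(mat), drop = FALSE]
    sampleIds <- if (!is.null(hdr) && length(hdr) == ncol(mat))
      hdr[7:length(hdr)] else paste0("S", seq_len(ncol(countCols)))
    circType <- NULL
    lineNo <- seq_along(lines) + firstLine - 1L
  } else {
    df <- read.delim(path, header = TRUE, colClasses = "character",
                     check.names = FALSE)
    nm <- names(df)
    if (dialect == "dcc") {
      req <- c("Chr", "Start", "End")
      if (!all(req %in% nm))
        stop("dcc dialect requires columns Chr, Start, End", call. = FALSE)
      known <- c("Chr", "Start", "End", "Strand", "Gene", "JunctionType",
                 "Region")
      chrom <- df$Chr; startRaw <- df$Start; endRaw <- df$End
      strandRaw <- if ("Strand" %in% nm) df$Strand else rep(".", nrow(df))
      circType <- if ("Region" %in% nm) df$Region else NULL
    } else {
      req <- c("chrom", "start", "end", "strand")
      if (!all(req %in% nm))
        stop("generic dialect requires columns chrom, start, end, strand",
             call. = FALSE)
      known <- req
      chrom <- df$chrom; startRaw <- df$start; endRaw <- df$end
      strandRaw <- df$strand
      circType <- NULL
    }
    sampleIds <- setdiff(nm, known)
    if (length(sampleIds) == 0L)
      stop("no sample count columns found in ", path, call. = FALSE)
    countCols <- as.matrix(df[, sampleIds, drop = FALSE])
    lineNo <- seq_len(nrow(df)) + 1L   # header is line 1
  }

  startNum <- suppressWarnings(as.numeric(startRaw))
  endNum <- suppressWarnings(as.numeric(endRaw))
  bad <- which(is.na(startNum) | is.na(endNum) | !nzchar(chrom))
  if (length(bad))
    stop("parse error at line ", lineNo[bad[1L]],
         ": malformed coordinates", call. = FALSE)
  cnt <- suppressWarnings(matrix(as.numeric(countCols), nrow = length(chrom)))
  badc <- which(apply(cnt, 1L, function(r) any(is.na(r))))
  if (length(badc))
    stop("parse error at line ", lineNo[badc[1L]],
         ": non-numeric count", call. = FALSE)
  neg <- which(apply(cnt, 1L, function(r) any(r < 0)))
  if (length(neg))
    stop("validation error at line ", lineNo[neg[1L]],
         ": negative count", call. = FALSE)

  coords <- .toInternal(startNum, endNum, convention)
  strandN <- .normStrand(strandRaw)
  gr <- GRanges(chrom, IRanges(coords$start, coords$end), strand = strandN)
  colnames(cnt) <- sampleIds

  key <- .junctionKey(gr)
  if (anyDuplicated(key)) {
    warning("caller table ", path, ": ", sum(duplicated(key)),
            " duplicate junction row(s) summed", call. = FALSE)
    keep <- !duplicated(key)
    idx <- match(key, key[keep])
    cnt <- rowsum(cnt, idx, reorder = FALSE)  # first-occurrence order
    gr <- gr[keep]
    if (!is.null(circType)) circType <- circType[keep]
    colnames(cnt) <- sampleIds
  }
  BsjCallSet(gr, cnt, callerId = callerId, circType = circType)
}

#' Write a BsjCallSet as a generic-dialect caller table
#'
#' @param x a \linkS4class{BsjCallSet}.
#' @param path output path.
#' @param convention coordinate convention of the written file.
#' @return \code{path}, invisibly.
#' @export
writeCallerTable <- function(x, path, convention = "zero_half_open") {
  convention <- match.arg(convention, c("zero_half_open", "one_closed"))
  gr <- rowRanges(x)
  st <- start(gr); en <- end(gr)
  if (convention == "zero_half_open") st <- st - 1L
  df <- data.frame(chrom = as.character(seqnames(gr)), start = st, end = en,
                   strand = as.character(strand(gr)),
                   as.data.frame(assay(x, "counts")),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF or GFF3
#'
#' Exon features are grouped under their gene; GTF uses the \code{gene_id}
#' attribute, GFF3 resolves \code{Parent} through transcript features to a
#' gene. Exons whose gene cannot be resolved are skipped with a warning.
#' 1-based closed GTF/GFF coordinates are kept as the internal convention.
#' An empty file yields an empty annotation.
#'
#' @param path path to a GTF or GFF3 file (format detected from the
#'   extension, \code{.gff}/\code{.gff3} vs anything else as GTF).
#' @return A \linkS4class{GeneModels}.
#' @export
readGeneAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!any(nzchar(lines) & !startsWith(lines, "#")))
    return(GeneModels())
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)

  type <- as.character(gr$type)
  exons <- gr[type == "exon"]
  if ("gene_id" %in% colnames(mcols(gr)) &&
      !all(is.na(exons$gene_id))) {
    exGene <- as.character(exons$gene_id)
  } else {
    # GFF3: exon Parent -> transcript ID -> transcript Parent -> gene ID
    par <- as.character(vapply(exons$Parent, function(p)
      if (length(p)) p[[1L]] else NA_character_, ""))
    ids <- as.character(gr$ID)
    parentOf <- setNames(as.character(vapply(gr$Parent, function(p)
      if (length(p)) p[[1L]] else NA_character_, "")), ids)
    typeOf <- setNames(type, ids)
    resolve <- function(id) {
      seen <- 0L
      while (!is.na(id) && seen < 5L) {
        if (!is.na(typeOf[id]) && typeOf[id] == "gene") return(id)
        id <- parentOf[id]
        seen <- seen + 1L
      }
      NA_character_
    }
    exGene <- vapply(par, resolve, "")
  }
  drop <- is.na(exGene) | !nzchar(exGene)
  if (any(drop)) {
    warning(sum(drop), " exon(s) without resolvable gene parent skipped",
            call. = FALSE)
    exons <- exons[!drop]
    exGene <- exGene[!drop]
  }
  mcols(exons) <- NULL
  exList <- split(exons, exGene)
  exList <- exList[order(names(exList))]
  exList <- GRangesList(lapply(exList, function(e) e[order(start(e))]))

  geneFeat <- gr[type == "gene"]
  if (length(geneFeat)) {
    gid <- if ("gene_id" %in% colnames(mcols(geneFeat)) &&
               !all(is.na(geneFeat$gene_id)))
      as.character(geneFeat$gene_id) else as.character(geneFeat$ID)
    gname <- if ("gene_name" %in% colnames(mcols(geneFeat)))
      as.character(geneFeat$gene_name) else gid
    genes <- granges(geneFeat)
    names(genes) <- gid
    genes$gene_name <- gname
    genes <- genes[order(names(genes))]
    # genes with no exon feature keep an empty exon list
    missing <- setdiff(names(genes), names(exList))
    if (length(missing)) {
      empty <- GRangesList(rep(list(GRanges()), length(missing)))
      names(empty) <- missing
      exList <- c(exList, empty)
    }
    exList <- exList[names(genes)]
  } else {
    # no explicit gene features: gene span = range of its exons
    genes <- unlist(range(exList), use.names = TRUE)
    genes$gene_name <- names(genes)
  }
  GeneModels(genes, exList)
}

#' Write gene models as GTF
#'
#' Deterministic writer (fixed field formatting) so that identical inputs
#' produce byte-identical files.
#'
#' @param models a \linkS4class{GeneModels}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(models, path) {
  g <- geneRanges(models)
  ex <- exonsByGene(models)
  out <- character()
  for (i in seq_along(g)) {
    gid <- names(g)[i]
    gname <- if (!is.null(g$gene_name)) g$gene_name[i] else gid
    strd <- as.character(strand(g))[i]
    if (strd == "*") strd <- "."
    attrsG <- sprintf('gene_id "%s"; gene_name "%s";', gid, gname)
    out <- c(out, paste(as.character(seqnames(g))[i], "circPipe", "gene",
                        start(g)[i], end(g)[i], ".", strd, ".", attrsG,
                        sep = "\t"))
    e <- ex[[i]]
    if (length(e)) {
      attrsE <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                        gid, gid, gname)
      out <- c(out, paste(as.character(seqnames(e)), "circPipe", "exon",
                          start(e), end(e), ".", strd, ".", attrsE,
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses all chains and validates the chain-format arithmetic: for every
#' chain, block sizes plus gaps must equal the declared source and target
#' spans; a violation is an error naming the chain id.
#'
#' @param path path to a chain file.
#' @return A \linkS4class{ChainSet}.
#' @export
readChain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  chainsList <- list()
  i <- 1L
  autoId <- 0L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1L]]
    if (f[1L] != "chain" || length(f) < 12L)
      stop("malformed chain header at line ", i, call. = FALSE)
    autoId <- autoId + 1L
    id <- if (length(f) >= 13L) f[13L] else as.character(autoId)
    blocks <- matrix(numeric(0), ncol = 3L,
                     dimnames = list(NULL, c("size", "sGap", "tGap")))
    i <- i + 1L
    repeat {
      if (i > n || !nzchar(lines[i]))
        stop("chain ", id, ": truncated block list", call. = FALSE)
      b <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1L]]))
      if (any(is.na(b)))
        stop("chain ", id, ": malformed block at line ", i, call. = FALSE)
      if (length(b) == 3L) {
        blocks <- rbind(blocks, b)
        i <- i + 1L
      } else if (length(b) == 1L) {
        blocks <- rbind(blocks, c(b, 0, 0))
        i <- i + 1L
        break
      } else stop("chain ", id, ": malformed block at line ", i,
                  call. = FALSE)
    }
    colnames(blocks) <- c("size", "sGap", "tGap")
    ch <- list(id = id, score = as.numeric(f[2L]),
               sName = f[3L], sSize = as.numeric(f[4L]), sStrand = f[5L],
               sStart = as.numeric(f[6L]), sEnd = as.numeric(f[7L]),
               tName = f[8L], tSize = as.numeric(f[9L]), tStrand = f[10L],
               tStart = as.numeric(f[11L]), tEnd = as.numeric(f[12L]),
               blocks = blocks)
    sSpan <- sum(blocks[, "size"]) + sum(blocks[, "sGap"])
    tSpan <- sum(blocks[, "size"]) + sum(blocks[, "tGap"])
    if (sSpan != ch$sEnd - ch$sStart || tSpan != ch$tEnd - ch$tStart)
      stop("validation error in chain ", id,
           ": block arithmetic does not match declared spans", call. = FALSE)
    chainsList[[length(chainsList) + 1L]] <- ch
  }
  new("ChainSet", chains = chainsList)
}

#' Write a ChainSet as a UCSC chain file
#'
#' @param x a \linkS4class{ChainSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChain <- function(x, path) {
  out <- character()
  for (ch in chains(x)) {
    out <- c(out, sprintf("chain %g %s %g %s %g %g %s %g %s %g %g %s",
                          ch$score, ch$sName, ch$sSize, ch$sStrand,
                          ch$sStart, ch$sEnd, ch$tName, ch$tSize,
                          ch$tStrand, ch$tStart, ch$tEnd, ch$id))
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1L)
      out <- c(out, sprintf("%g\t%g\t%g", b[-nb, "size"], b[-nb, "sGap"],
                            b[-nb, "tGap"]))
    out <- c(out, sprintf("%g", b[nb, "size"]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a circRNA database table
#'
#' Tab-separated with header \code{circ_id}, \code{chrom}, \code{start},
#' \code{end}, \code{strand}, \code{gene} (gene may be empty).
#'
#' @param path input path.
#' @param convention source coordinate convention (default 1-based closed,
#'   as database exports usually are).
#' @return \code{GRanges} with \code{circ_id} and \code{hostGene} columns.
#' @export
readCircDb <- function(path, convention = "one_closed") {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  req <- c("circ_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(df)))
    stop("circ DB requires columns circ_id, chrom, start, end, strand",
         call. = FALSE)
  coords <- .toInternal(as.numeric(df$start), as.numeric(df$end), convention)
  gr <- GRanges(df$chrom, IRanges(coords$start, coords$end),
                strand = .normStrand(df$strand))
  gr$circ_id <- df$circ_id
  gr$hostGene <- if ("gene" %in% names(df)) df$gene else ""
  gr
}

#' @rdname readCircDb
#' @param x \code{GRanges} with \code{circ_id} (and optionally
#'   \code{hostGene}) columns.
#' @export
writeCircDb <- function(x, path) {
  df <- data.frame(circ_id = x$circ_id,
                   chrom = as.character(seqnames(x)),
                   start = start(x), end = end(x),
                   strand = as.character(strand(x)),
                   gene = if (!is.null(x$hostGene)) x$hostGene else "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Sequences are keyed by the first whitespace-delimited header token.
#'
#' @param path FASTA path.
#' @param type \code{"DNA"} or \code{"RNA"}.
#' @return A \code{DNAStringSet} or \code{RNAStringSet}.
#' @export
readFastaSeqs <- function(path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  seqs <- if (type == "DNA") readDNAStringSet(path) else
    readRNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Read a sample sheet
#'
#' Tab-separated with header; requires \code{sample_id} and \code{group},
#' accepts \code{timepoint} and \code{batch} (filled with \code{""} when
#' absent). Sample IDs must be unique.
#'
#' @param path input path.
#' @return data.frame with columns sample_id, group, timepoint, batch.
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample sheet requires columns sample_id and group", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in sample sheet", call. = FALSE)
  if (is.null(df$timepoint)) df$timepoint <- ""
  if (is.null(df$batch)) df$batch <- ""
  df[, c("sample_id", "group", "timepoint", "batch")]
}

#' Write genomic intervals as BED6
#'
#' Output is 0-based half-open regardless of the internal convention;
#' unknown strand is written as \code{.}.
#'
#' @param x \code{GRanges}; names (or a \code{circ_id} column) become the
#'   BED name field.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
  nm <- if (!is.null(x$circ_id)) x$circ_id else
    if (!is.null(names(x))) names(x) else rep(".", length(x))
  strd <- as.character(strand(x))
  strd[strd == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = end(x),
                   name = nm, score = 0L, strand = strd)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' BED3-BED6; 0-based half-open input normalized to the internal
#' convention. Extra columns beyond the sixth are kept as
#' \code{extra1..extraN} metadata columns (used for BED-plus sponge
#' cluster files).
#'
#' @param path BED path.
#' @return \code{GRanges} with \code{name} (and any extra) columns.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) return(GRanges())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- min(lengths(f))
  if (nc < 3L) stop("BED needs >= 3 columns", call. = FALSE)
  mat <- t(vapply(f, function(x) x[seq_len(nc)], character(nc)))
  if (nc == 3L) mat <- cbind(mat)
  coords <- .toInternal(as.numeric(mat[, 2L]), as.numeric(mat[, 3L]),
                        "zero_half_open")
  strd <- if (nc >= 6L) .normStrand(mat[, 6L]) else "*"
  gr <- GRanges(mat[, 1L], IRanges(coords$start, coords$end), strand = strd)
  if (nc >= 4L) gr$name <- mat[, 4L]
  if (nc > 6L)
    for (j in 7:nc) mcols(gr)[[paste0("extra", j - 6L)]] <- mat[, j]
  gr
}

#' Write a data.frame as a TSV table
#'
#' @param x data.frame-like.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
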