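# Readers/writers: convention normalization, duplicate handling, and
# round trips for every format.

writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("caller table conventions normalize to one internal convention", {
  f <- writeLinesTmp(c("chrom\tstart\tend\tstrand\ts1\ts2\ts3",
                       "chr1\t100\t200\t+\t3\t0\t5"))
  oc <- readCallerTable(f, dialect = "generic", convention = "one_closed")
  zh <- readCallerTable(f, dialect = "generic",
                        convention = "zero_half_open")
  # 1-based closed input keeps its coordinates; 0-based half-open input
  # shifts the start up by one
  expect_equal(start(rowRanges(oc)), 100L)
  expect_equal(end(rowRanges(oc)), 200L)
  expect_equal(start(rowRanges(zh)), 101L)
  expect_equal(end(rowRanges(zh)), 200L)
  expect_equal(unname(assay(oc, "counts")[1, ]), c(3L, 0L, 5L))
  # and the two conventions describe the same 100-base interval
  expect_equal(width(rowRanges(zh)), 100L)
})

test_that("duplicate junction rows within one caller are summed", {
  f <- writeLinesTmp(c("chrom\tstart\tend\tstrand\ts1\ts2\ts3",
                       "chr1\t100\t200\t+\t1\t1\t0",
                       "chr1\t100\t200\t+\t2\t0\t0"))
  expect_warning(x <- readCallerTable(f, dialect = "generic"),
                 "duplicate")
  expect_equal(length(x), 1L)
  expect_equal(unname(assay(x, "counts")[1, ]), c(3L, 1L, 0L))
})

test_that("malformed rows and negative counts are rejected with line numbers", {
  f <- writeLinesTmp(c("chrom\tstart\tend\tstrand\ts1",
                       "chr1\t100\t200\t+\t3",
                       "chr1\tnope\t300\t+\t1"))
  expect_error(readCallerTable(f, dialect = "generic"), "line 3")
  f2 <- writeLinesTmp(c("chrom\tstart\tend\tstrand\ts1",
                        "chr1\t100\t200\t+\t-2"))
  expect_error(readCallerTable(f2, dialect = "generic"),
               "negative count")
})

test_that("dcc and segemehl dialects parse their layouts", {
  fd <- writeLinesTmp(c("Chr\tStart\tEnd\tStrand\tRegion\ts1\ts2",
                        "chr2\t500\t900\t-\texonic\t4\t7"))
  d <- readCallerTable(fd, dialect = "dcc")
  expect_equal(start(rowRanges(d)), 500L)   # 1-based in, kept
  expect_equal(rowData(d)$circType, "exonic")
  expect_equal(sampleOrder(d), c("s1", "s2"))

  fs <- writeLinesTmp(c("#chrom\tstart\tend\tname\tscore\tstrand\tsA\tsB",
                        "chr3\t10\t60\tbsj1\t0\t+\t2\t9"))
  s <- readCallerTable(fs, dialect = "segemehl")
  expect_equal(start(rowRanges(s)), 11L)    # 0-based in, shifted
  expect_equal(end(rowRanges(s)), 60L)
  expect_equal(sampleOrder(s), c("sA", "sB"))
})

test_that("strand dot is stored as unknown, never coerced to plus", {
  f <- writeLinesTmp(c("chrom\tstart\tend\tstrand\ts1",
                       "chr1\t5\t50\t.\t3"))
  x <- readCallerTable(f, dialect = "generic")
  expect_equal(as.character(strand(rowRanges(x))), "*")
})

test_that("caller table round trip is identity under either convention", {
  set.seed(41)
  for (conv in c("zero_half_open", "one_closed")) {
    gr <- GRanges("chr1", IRanges(sample(1e5, 20), width = sample(100:900, 20)),
                  strand = sample(c("+", "-", "*"), 20, replace = TRUE))
    x <- BsjCallSet(gr, matrix(rpois(40, 4), 20, 2,
                               dimnames = list(NULL, c("a", "b"))),
                    callerId = "rt")
    f <- tempfile()
    writeCallerTable(x, f, convention = conv)
    y <- readCallerTable(f, dialect = "generic", convention = conv)
    expect_equal(paste(seqnames(rowRanges(y)), start(rowRanges(y)),
                       end(rowRanges(y)), strand(rowRanges(y))),
                 paste(seqnames(gr), start(gr), end(gr), strand(gr)))
    expect_equal(assay(y, "counts"), assay(x, "counts"),
                 ignore_attr = TRUE)
  }
})

test_that("GTF round trip preserves genes and sorted exons", {
  models <- toyModels()
  f <- tempfile(fileext = ".gtf")
  writeGtf(models, f)
  back <- readGeneAnnotation(f)
  expect_equal(names(geneRanges(back)), c("G1", "G2"))
  expect_equal(start(exonsByGene(back)$G1), c(1000L, 2000L, 3000L, 4000L))
  expect_equal(end(exonsByGene(back)$G2), c(6400L, 8000L))
  expect_false(is.unsorted(start(exonsByGene(back)$G1)))
})

test_that("empty annotation file yields an empty annotation", {
  f <- tempfile(fileext = ".gtf")
  writeLines(character(), f)
  expect_equal(length(readGeneAnnotation(f)), 0L)
})

test_that("chain parsing validates block arithmetic", {
  f <- writeLinesTmp(c("chain 100 s1 1000 + 0 50 t1 1000 + 0 50 7", "50", ""))
  cs <- readChain(f)
  expect_equal(length(cs), 1L)
  ch <- chains(cs)[[1]]
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$id, "7")

  bad <- writeLinesTmp(c("chain 100 s1 1000 + 0 60 t1 1000 + 0 50 9",
                         "50", ""))
  expect_error(readChain(bad), "chain 9")
})

test_that("chain write/read round trip preserves every field", {
  cs <- genChain(7, nBlocks = 5L, inversionProb = 1)
  f <- tempfile(fileext = ".chain")
  writeChain(cs, f)
  back <- readChain(f)
  a <- chains(cs)[[1]]
  b <- chains(back)[[1]]
  for (fld in c("score", "sName", "sStart", "sEnd", "tName", "tStrand",
                "tStart", "tEnd"))
    expect_equal(b[[fld]], a[[fld]], info = fld)
  expect_equal(unname(b$blocks), unname(a$blocks))
})

test_that("FASTA records are keyed by the first header token", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">seq1 some description", "ACGU", ">seq2", "GGCC"), f)
  s <- readFastaSeqs(f, type = "RNA")
  expect_equal(names(s), c("seq1", "seq2"))
  expect_equal(as.character(s[["seq1"]]), "ACGU")
})

test_that("the twelve-sample brain design reads back as 3 groups of 4", {
  f <- tempfile()
  writeTable(exampleDesign("encephalon"), f)
  d <- readSampleSheet(f)
  expect_equal(nrow(d), 12L)
  expect_equal(sort(unique(d$group)), c("Adjuvant", "Control", "Vaccine"))
  expect_equal(unname(table(d$group)), rep(4L, 3L), ignore_attr = TRUE)
  expect_true(all(c("114-E", "115-E", "116-E", "117-E") %in% d$sample_id))
  dup <- d
  dup$sample_id[2] <- dup$sample_id[1]
  f2 <- tempfile()
  writeTable(dup, f2)
  expect_error(readSampleSheet(f2), "duplicate")
})

test_that("BED round trip is lossless for chrom/start/end/strand", {
  gr <- GRanges(c("chr1", "chr2"), IRanges(c(101, 5001), c(200, 6000)),
                strand = c("+", "*"))
  gr$circ_id <- c("c1", "c2")
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  # the file itself must be 0-based half-open
  raw <- read.delim(f, header = FALSE)
  expect_equal(raw$V2, c(100L, 5000L))
  expect_equal(raw$V3, c(200L, 6000L))
  back <- readBed(f)
  expect_equal(as.character(seqnames(back)), c("chr1", "chr2"))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(strand(back)), c("+", "*"))
})

test_that("circ DB table round trips", {
  db <- GRanges("hchr1", IRanges(c(10, 500), c(100, 900)), strand = "+")
  db$circ_id <- c("DB1", "DB2")
  db$hostGene <- c("HG1", "")
  f <- tempfile()
  writeCircDb(db, f)
  back <- readCircDb(f)
  expect_equal(start(back), start(db))
  expect_equal(back$circ_id, db$circ_id)
  expect_equal(back$hostGene[2], "")
})
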