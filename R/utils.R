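# Internal helpers shared across modules.

# The six backsplice conservation categories, in display order.
.CONS_CATEGORIES <- c("not_aligned", "no_homologous", "five_prime_utilized",
                      "three_prime_utilized", "both_sites_utilized",
                      "homologous")

.BOUNDARY_CLASSES <- c("both_ends", "one_end", "neither", "intergenic")

#' @noRd
.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single non-empty string", call. = FALSE)
  invisible(x)
}

# Convert declared source convention to internal 1-based closed coordinates.
# zero_half_open: start is 0-based inclusive, end exclusive -> (start+1, end).
# one_closed: already internal.
#' @noRd
.toInternal <- function(start, end, convention) {
  convention <- match.arg(convention, c("zero_half_open", "one_closed"))
  if (convention == "zero_half_open") start <- start + 1L
  if (any(start > end))
    stop("invalid interval: start > end after convention normalization",
         call. = FALSE)
  list(start = as.integer(start), end = as.integer(end))
}

# Normalize strand symbols; "." and "" and NA become "*" (unknown).
#' @noRd
.normStrand <- function(s) {
  s <- as.character(s)
  s[is.na(s) | s %in% c(".", "", "?")] <- "*"
  bad <- !s %in% c("+", "-", "*")
  if (any(bad))
    stop("invalid strand value(s): ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  s
}

# Two strands are compatible when equal or at least one is unknown.
#' @noRd
.strandCompatible <- function(a, b) a == b | a == "*" | b == "*"

#' @noRd
.junctionKey <- function(gr, with_strand = TRUE) {
  if (with_strand)
    paste(as.character(seqnames(gr)), start(gr), end(gr),
          as.character(strand(gr)), sep = ":")
  else
    paste(as.character(seqnames(gr)), start(gr), end(gr), sep = ":")
}

# Deterministic RNG scope: all generators run under withr::with_seed so the
# caller's RNG state is untouched and same seed => same output.
#' @noRd
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  withr::with_seed(as.integer(seed), code)
}
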