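#' Genomic interval algebra
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' `start` is the first base covered, `end` is one past the last. A 1 bp
#' locus therefore has `end == start + 1`. Every file reader converts into
#' this convention on ingest and every writer converts out of it, so no
#' other code needs to think about coordinate systems.
#'
#' @name intervals
NULL

#' Normalize chromosome names to the "chr"-prefixed form
#'
#' Arrowhead domain lists write chromosomes as bare numbers ("3") while BED
#' and Roadmap files write "chr3"; every reader funnels names through this
#' so downstream comparisons are exact string matches.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector with a "chr" prefix on every element.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' Construct a validated genomic interval table
#'
#' @param chrom chromosome names (normalized via [normalize_chrom()]).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param ... further equal-length columns carried along (ids, scores, ...).
#' @return a data.frame with columns `chrom`, `start`, `end` and any extras.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be numeric and non-missing")
  }
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be strictly greater than start")
  chrom <- normalize_chrom(chrom)
  if (any(chrom == "chr" | chrom == "")) stop("chromosome name must be non-empty")
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

#' Convert a 0-based half-open interval table to a GRanges object
#'
#' @param x data.frame with `chrom`, `start`, `end` columns.
#' @return a [GenomicRanges::GRanges] (1-based closed, as GRanges requires).
#' @keywords internal
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Pairwise interval overlap test
#'
#' Half-open semantics: intervals sharing only an endpoint (`a$end ==
#' b$start`) do not overlap. Intervals on different chromosomes never
#' overlap.
#'
#' @param a,b interval tables of equal length (or length 1, recycled).
#' @return logical vector.
#' @export
iv_overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Gap distance between two intervals
#'
#' Number of bases strictly between two intervals on the same chromosome;
#' 0 when they overlap or abut; `Inf` when the chromosomes differ.
#'
#' @param a,b interval tables of equal length (or length 1, recycled).
#' @return numeric vector (`Inf` marks cross-chromosome pairs).
#' @export
gap_distance <- function(a, b) {
  gap <- pmax(pmax(a$start, b$start) - pmin(a$end, b$end), 0)
  gap[a$chrom != b$chrom] <- Inf
  gap
}

#' All subjects overlapping a query interval
#'
#' @param query a single-row interval table.
#' @param subjects an interval table (unsorted, duplicates allowed).
#' @return the rows of `subjects` overlapping `query`, in input order.
#' @export
overlap_query <- function(query, subjects) {
  stopifnot(nrow(query) == 1L)
  if (nrow(subjects) == 0L) return(subjects)
  hits <- overlap_hits(query, subjects)
  subjects[sort(hits$subject), , drop = FALSE]
}

#' Overlap hit pairs between two interval tables
#'
#' Bulk many-to-many overlap join, backed by
#' [GenomicRanges::findOverlaps()] with `minoverlap = 1` so the half-open
#' abutment case is excluded.
#'
#' @param query,subject interval tables.
#' @param maxgap maximum gap (bp) still counted as a hit; the default `-1`
#'   requires a true overlap, `0` additionally admits abutting intervals.
#' @return data.frame with integer columns `query` and `subject` (row
#'   indices into the two inputs).
#' @export
overlap_hits <- function(query, subject, maxgap = -1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  h <- GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject),
                                   maxgap = maxgap)
  data.frame(query = S4Vectors::queryHits(h),
             subject = S4Vectors::subjectHits(h))
}

#' Order interval-table rows in genome order
#'
#' Chromosomes sort numerically where possible (chr2 before chr11), then
#' lexicographically (chrX, chrY after the autosomes), then by start.
#'
#' @param x interval table.
#' @return integer permutation of `seq_len(nrow(x))`.
#' @export
genome_order <- function(x) {
  tag <- sub("^chr", "", x$chrom)
  num <- suppressWarnings(as.numeric(tag))
  order(is.na(num), num, tag, x$start, x$end)
}
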