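# Genomic intervals are plain data.frames with columns chrom / start / end in
# 0-based half-open coordinates; conversion to and from 1-based formats (SAM,
# IRanges) happens only at the boundaries below.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param name optional character vector of feature names.
#' @return data.frame with columns chrom, start, end (and name if given).
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start < 0)) stopf("interval start < 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stopf("interval %d has start >= end (%s:%s-%s)", bad, chrom[bad],
          start[bad], end[bad])
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- as.character(name)
  out
}

# 0-based half-open -> IRanges (1-based closed).
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1, end = end)

#' Occupied reference interval of an aligned tag
#'
#' A tag's 5' position (`pos5`) is the 5'-most aligned base on its strand; the
#' occupied interval is `[pos5, pos5 + span)` on the plus strand and
#' `[pos5 - span + 1, pos5 + 1)` on the minus strand.
#'
#' @param pos5 integer vector of 0-based 5' positions.
#' @param strand character vector of "+" / "-".
#' @param span integer vector of reference spans (bp).
#' @return data.frame with columns start, end (0-based half-open).
#' @export
tag_interval <- function(pos5, strand, span) {
  start <- ifelse(strand == "+", pos5, pos5 - span + 1)
  end <- ifelse(strand == "+", pos5 + span, pos5 + 1)
  data.frame(start = as.numeric(start), end = as.numeric(end))
}

#' Extend an interval symmetrically, clipped to the chromosome
#'
#' @param start,end 0-based half-open interval bounds.
#' @param extension bp added on both sides.
#' @param chrom_len chromosome length for right clipping, or `NA` for none.
#' @return data.frame with extended start, end.
#' @export
extend_interval <- function(start, end, extension, chrom_len = NA) {
  s <- pmax(0, start - extension)
  e <- end + extension
  if (!all(is.na(chrom_len))) e <- pmin(e, ifelse(is.na(chrom_len), e, chrom_len))
  data.frame(start = s, end = e)
}

# Hits between two 0-based half-open interval tables restricted to matching
# chromosomes; returns a data.frame of row indices (query, subject).
interval_hits <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  res <- vector("list", 0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges0(a$start[ia], a$end[ia]),
                                  as_iranges0(b$start[ib], b$end[ib]))
    if (length(hits)) {
      res[[length(res) + 1]] <- data.frame(
        query = ia[S4Vectors::queryHits(hits)],
        subject = ib[S4Vectors::subjectHits(hits)])
    }
  }
  if (!length(res)) return(data.frame(query = integer(0), subject = integer(0)))
  do.call(rbind, res)
}

# Does each interval in `a` overlap (>= 1 bp) at least one interval in `b`?
overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0) return(out)
  hits <- interval_hits(a, b)
  out[unique(hits$query)] <- TRUE
  out
}
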