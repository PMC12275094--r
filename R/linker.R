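# Bridge-linker detection and trimming.
#
# The in situ ChIA-PET protocol joins two proximal DNA fragments with a
# biotinylated double-stranded bridge linker. In base-called reads the
# biotinylated dT of the forward strand reads as a plain T, giving a 19-nt
# forward sequence; the reverse strand is its own 19-nt oligo. A read that
# contains the linker is chimeric: the sequence 5' of the junction is the
# genomic tag, everything from the junction on is trimmed away.

#' The bridge linker used for proximity ligation
#'
#' @param max_mismatches mismatches tolerated in a full-length match.
#' @return list with `forward`, `reverse`, the four query sequences in match
#'   priority order (forward, reverse, forward_rc, reverse_rc) and
#'   `max_mismatches`.
#' @export
bridge_linker <- function(max_mismatches = 2L) {
  fwd <- "CGCGATATCTTATCTGACT"
  rev <- "GTCAGATAAGATATCGCGT"
  queries <- c(forward = fwd, reverse = rev,
               forward_rc = revcomp(fwd), reverse_rc = revcomp(rev))
  stopifnot(max_mismatches >= 0, max_mismatches < nchar(fwd) / 2)
  list(forward = fwd, reverse = rev, queries = queries,
       max_mismatches = as.integer(max_mismatches))
}

# Mismatch count of each query placement over a read, including placements
# that run off the read's 3' end (partial matches). neditStartingAt counts
# out-of-range positions as mismatches, so the in-overlap mismatch count at
# offset s (0-based) for overlap o is ned[s+1] - (m - o).
scan_linker_one <- function(read_dna, L, queries_dna, max_mismatches,
                            min_overlap) {
  best <- NULL
  for (qi in seq_along(queries_dna)) {
    q <- queries_dna[[qi]]
    m <- length(q)
    if (L < min_overlap) next
    ned <- Biostrings::neditStartingAt(q, read_dna, starting.at = seq_len(L),
                                       with.indels = FALSE)
    o <- pmin(m, L - seq_len(L) + 1L)     # overlap length at each start
    mism <- ned - (m - o)
    full <- o == m
    allowed <- ifelse(full, max_mismatches,
                      floor(max_mismatches * o / m))
    cand <- which(mism <= allowed & (full | o >= min_overlap))
    if (length(cand)) {
      i <- cand[order(mism[cand], cand)[1]]
      hit <- list(offset = i - 1L, orientation = qi,
                  mismatches = as.integer(mism[i]), match_len = as.integer(o[i]))
      if (is.null(best) ||
          hit$mismatches < best$mismatches ||
          (hit$mismatches == best$mismatches && hit$offset < best$offset)) {
        best <- hit
      }
    }
  }
  best
}

#' Scan a read for the bridge linker
#'
#' Searches the forward linker, the reverse linker, and both reverse
#' complements at every offset. Full internal matches tolerate up to
#' `max_mismatches`; a 3'-terminal partial match must cover at least
#' `min_overlap` bases of the query and tolerates
#' `floor(max_mismatches * overlap / linker_length)` mismatches. The hit with
#' the fewest mismatches wins; ties break to the smaller offset, then to query
#' priority (forward > reverse > forward_rc > reverse_rc).
#'
#' @param read_seq a single read sequence (character).
#' @param linker a [bridge_linker()] object.
#' @param max_mismatches mismatches for a full match; defaults to the linker's.
#' @param min_overlap minimum bases of a 3'-terminal partial match.
#' @return `NULL` when no hit, else a list with `offset` (0-based),
#'   `orientation`, `mismatches` and `match_len`.
#' @export
scan_linker <- function(read_seq, linker = bridge_linker(),
                        max_mismatches = linker$max_mismatches,
                        min_overlap = 10L) {
  stopifnot(length(read_seq) == 1, nzchar(read_seq))
  qd <- lapply(linker$queries, Biostrings::DNAString)
  hit <- scan_linker_one(Biostrings::DNAString(read_seq), nchar(read_seq), qd,
                         max_mismatches, min_overlap)
  if (is.null(hit)) return(NULL)
  hit$orientation <- names(linker$queries)[hit$orientation]
  hit
}

#' Split a mate pair at the bridge linker into genomic tags
#'
#' The tag for each mate is the sequence 5' of its first (best) linker hit;
#' a mate without a hit contributes its whole sequence, provided the other
#' mate has a hit. Pairs with a hit in neither mate are rejected
#' (`no_linker`); pairs where either tag is shorter than `min_tag_len` are
#' rejected (`short_tag`).
#'
#' @param seq1,seq2 mate sequences.
#' @param linker a [bridge_linker()] object.
#' @param max_mismatches,min_overlap see [scan_linker()].
#' @param min_tag_len minimum tag length after trimming.
#' @return list with `status` ("ok", "no_linker" or "short_tag"), `tag1`,
#'   `tag2` (lengths, for quality trimming) and the two hits.
#' @export
split_pair <- function(seq1, seq2, linker = bridge_linker(),
                       max_mismatches = linker$max_mismatches,
                       min_overlap = 10L, min_tag_len = 18L) {
  hit1 <- scan_linker(seq1, linker, max_mismatches, min_overlap)
  hit2 <- scan_linker(seq2, linker, max_mismatches, min_overlap)
  if (is.null(hit1) && is.null(hit2)) {
    return(list(status = "no_linker", tag1 = NULL, tag2 = NULL,
                hit1 = NULL, hit2 = NULL))
  }
  len1 <- if (is.null(hit1)) nchar(seq1) else hit1$offset
  len2 <- if (is.null(hit2)) nchar(seq2) else hit2$offset
  if (len1 < min_tag_len || len2 < min_tag_len) {
    return(list(status = "short_tag", tag1 = NULL, tag2 = NULL,
                hit1 = hit1, hit2 = hit2))
  }
  list(status = "ok",
       tag1 = substr(seq1, 1L, len1), tag2 = substr(seq2, 1L, len2),
       hit1 = hit1, hit2 = hit2)
}

#' Detect and trim the bridge linker across a whole library
#'
#' @param pairs data.frame from [read_fastq_pairs()].
#' @param params a [pipeline_params()] object.
#' @param linker a [bridge_linker()] object.
#' @return list with `tags` (data.frame read_id, tag1, qual1, tag2, qual2) and
#'   `counters` (named numeric: pairs_read, pairs_with_linker,
#'   rejected_no_linker, rejected_short_tag, plus orientation counts).
#' @export
split_pairs <- function(pairs, params = pipeline_params(),
                        linker = bridge_linker(params$max_mismatches)) {
  n <- nrow(pairs)
  qd <- lapply(linker$queries, Biostrings::DNAString)
  orient_counts <- stats::setNames(numeric(4), names(linker$queries))
  status <- character(n)
  tag1 <- character(n); tag2 <- character(n)
  q1 <- character(n); q2 <- character(n)
  if (n > 0) {
    reads1 <- Biostrings::DNAStringSet(pairs$seq1)
    reads2 <- Biostrings::DNAStringSet(pairs$seq2)
    for (i in seq_len(n)) {
      h1 <- scan_linker_one(reads1[[i]], nchar(pairs$seq1[i]), qd,
                            params$max_mismatches, params$min_overlap)
      h2 <- scan_linker_one(reads2[[i]], nchar(pairs$seq2[i]), qd,
                            params$max_mismatches, params$min_overlap)
      for (h in list(h1, h2)) {
        if (!is.null(h)) orient_counts[h$orientation] <-
            orient_counts[h$orientation] + 1
      }
      if (is.null(h1) && is.null(h2)) { status[i] <- "no_linker"; next }
      len1 <- if (is.null(h1)) nchar(pairs$seq1[i]) else h1$offset
      len2 <- if (is.null(h2)) nchar(pairs$seq2[i]) else h2$offset
      if (len1 < params$min_tag_len || len2 < params$min_tag_len) {
        status[i] <- "short_tag"; next
      }
      status[i] <- "ok"
      tag1[i] <- substr(pairs$seq1[i], 1L, len1)
      tag2[i] <- substr(pairs$seq2[i], 1L, len2)
      q1[i] <- substr(pairs$qual1[i], 1L, len1)
      q2[i] <- substr(pairs$qual2[i], 1L, len2)
    }
  }
  ok <- status == "ok"
  counters <- c(pairs_read = n,
                pairs_with_linker = sum(status != "no_linker"),
                kept = sum(ok),
                rejected_no_linker = sum(status == "no_linker"),
                rejected_short_tag = sum(status == "short_tag"),
                orient_counts)
  tags <- data.frame(read_id = pairs$id[ok], tag1 = tag1[ok], qual1 = q1[ok],
                     tag2 = tag2[ok], qual2 = q2[ok], stringsAsFactors = FALSE)
  list(tags = tags, counters = counters)
}

#' Tabulate linker-detection statistics
#'
#' @param counters named counter vector from [split_pairs()].
#' @return data.frame with metric / value rows, including the linker rate.
#' @export
linker_report <- function(counters) {
  n <- counters[["pairs_read"]]
  rate <- if (n > 0) counters[["pairs_with_linker"]] / n else 0
  data.frame(
    metric = c("pairs_read", "pairs_with_linker", "linker_rate", "kept",
               "rejected_no_linker", "rejected_short_tag",
               "hits_forward", "hits_reverse", "hits_forward_rc",
               "hits_reverse_rc"),
    value = c(n, counters[["pairs_with_linker"]], rate, counters[["kept"]],
              counters[["rejected_no_linker"]],
              counters[["rejected_short_tag"]],
              counters[["forward"]], counters[["reverse"]],
              counters[["forward_rc"]], counters[["reverse_rc"]]),
    stringsAsFactors = FALSE)
}
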