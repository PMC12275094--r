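# Readers and writers for the standard formats the pipeline touches.
# Coordinate convention: everything in memory is 0-based half-open; BED and
# BEDPE pass through unchanged, SAM positions are converted by -1 on input.

strip_mate_suffix <- function(id) {
  id <- sub("[ \t].*$", "", id)
  sub("/[12]$", "", id)
}

read_fastq_one <- function(path) {
  # An empty file is a valid empty stream; readDNAStringSet rejects it.
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Read paired FASTQ files as mate pairs
#'
#' Reads two synchronised FASTQ files (or one interleaved file when `fq2` is
#' `NULL`); gzip is handled transparently. Mate IDs are matched after
#' stripping `/1`, `/2` and whitespace-delimited tails.
#'
#' @param fq1 path to mate-1 FASTQ (or the interleaved file).
#' @param fq2 path to mate-2 FASTQ, or `NULL` for interleaved input.
#' @return data.frame with columns id, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pairs <- function(fq1, fq2 = NULL) {
  if (is.null(fq2)) {
    x <- read_fastq_one(fq1)
    if (nrow(x) %% 2 != 0) {
      stopf("interleaved FASTQ %s has an odd record count (%d)", fq1, nrow(x))
    }
    odd <- seq_len(nrow(x)) %% 2 == 1
    r1 <- x[odd, , drop = FALSE]
    r2 <- x[!odd, , drop = FALSE]
  } else {
    r1 <- read_fastq_one(fq1)
    r2 <- read_fastq_one(fq2)
    if (nrow(r1) != nrow(r2)) {
      stopf("mate files differ in record count (%d vs %d); first unpaired record is %d",
            nrow(r1), nrow(r2), min(nrow(r1), nrow(r2)) + 1L)
    }
  }
  id1 <- strip_mate_suffix(r1$id)
  id2 <- strip_mate_suffix(r2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stopf("mate IDs disagree at record %d: '%s' vs '%s'", bad[1],
          id1[bad[1]], id2[bad[1]])
  }
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Convert a FASTQ quality string to phred scores
#' @param qual quality string (Sanger +33 encoding).
#' @return integer vector of phred scores.
#' @export
qual_to_phred <- function(qual) as.integer(charToRaw(qual)) - 33L

#' Write mate pairs (or trimmed tag pairs) as two FASTQ files
#'
#' @param pairs data.frame with id, seq1, qual1, seq2, qual2.
#' @param prefix output prefix; writes `<prefix>_1.fq` and `<prefix>_2.fq`.
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fq")
  p2 <- paste0(prefix, "_2.fq")
  fmt <- function(id, seq, qual, mate) {
    if (length(id) == 0) return(character(0))
    as.vector(rbind(paste0("@", id, "/", mate), seq, "+", qual))
  }
  writeLines(fmt(pairs$id, pairs$seq1, pairs$qual1, 1L), p1)
  writeLines(fmt(pairs$id, pairs$seq2, pairs$qual2, 2L), p2)
  invisible(c(p1, p2))
}

#' Read a BED3+ file of genomic intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' `track`, `browser` and `#` lines are skipped. A name column is retained
#' when present.
#'
#' @param path BED file path.
#' @return data.frame with chrom, start, end and (if present) name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3) stopf("%s: line %d has fewer than 3 columns", path,
                          lineno[which.min(lengths(fields))])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stopf("%s: non-numeric coordinates at line %d", path, lineno[bad])
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stopf("%s: start >= end at line %d", path, lineno[bad])
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (any(lengths(fields) >= 4)) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "",
                       "")
  }
  out
}

#' Write intervals as BED
#' @param intervals data.frame with chrom, start, end and optional name.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(intervals)))
  df <- intervals[, cols, drop = FALSE]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50L)
  invisible(path)
}

#' Write PET clusters or loops as 10+ column BEDPE
#'
#' Emits chrom1, start1, end1, chrom2, start2, end2, name, score (the PET
#' count), strand1 = strand2 = ".", sorted by (chrom1, start1, start2). Any
#' extra columns named in `extra` are appended after column 10.
#'
#' @param clusters data.frame with chrom, start1, end1, start2, end2,
#'   pet_count and optionally name.
#' @param path output path.
#' @param extra character vector of additional column names to append.
#' @export
write_bedpe <- function(clusters, path, extra = character(0)) {
  if (nrow(clusters) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order_radix(clusters$chrom, clusters$start1, clusters$start2)
  cl <- clusters[ord, , drop = FALSE]
  nm <- if ("name" %in% names(cl)) cl$name else paste0("cluster_", seq_len(nrow(cl)))
  df <- data.frame(chrom1 = cl$chrom, start1 = cl$start1, end1 = cl$end1,
                   chrom2 = cl$chrom, start2 = cl$start2, end2 = cl$end2,
                   name = nm, score = cl$pet_count,
                   strand1 = ".", strand2 = ".", stringsAsFactors = FALSE)
  for (col in extra) df[[col]] <- cl[[col]]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50L)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#' @param path BEDPE path.
#' @param extra names for columns beyond the standard 10, if any.
#' @return data.frame with chrom, start1, end1, start2, end2, name, pet_count.
#' @export
read_bedpe <- function(path, extra = character(0)) {
  empty <- data.frame(chrom = character(0), start1 = numeric(0),
                      end1 = numeric(0), start2 = numeric(0),
                      end2 = numeric(0), name = character(0),
                      pet_count = numeric(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  out <- data.frame(chrom = df[[1]], start1 = df[[2]], end1 = df[[3]],
                    start2 = df[[5]], end2 = df[[6]], name = df[[7]],
                    pet_count = df[[8]], stringsAsFactors = FALSE)
  for (i in seq_along(extra)) out[[extra[i]]] <- df[[10 + i]]
  out
}

# Reference span on the genome implied by a CIGAR string.
cigar_ref_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read mate pairs of aligned tags from a SAM file
#'
#' Consumes the output of an external aligner (e.g. bwa-mem run on the trimmed
#' tags). Secondary and supplementary records are ignored; mates are paired by
#' read name (with `/1`, `/2` suffixes stripped), so name-sorted input is not
#' required. Only pairs where both mates are mapped with mapping quality
#' strictly greater than `min_mapq` are returned. `pos5` is the 5'-most
#' aligned base on the mate's strand, 0-based.
#'
#' @param path SAM (or BAM) file path.
#' @param min_mapq mapping-quality threshold; tags must exceed it. Default 30.
#' @return data.frame with read_id, chrom1, pos1, strand1, span1, mapq1,
#'   chrom2, pos2, strand2, span2, mapq2 (mate order as in the file), with
#'   attribute `counts` (orphans, low_mapq_pairs, unmapped_pairs).
#' @export
read_sam_pairs <- function(path, min_mapq = 30L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  flag <- res$flag
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  qname <- strip_mate_suffix(res$qname[primary])
  flag <- flag[primary]
  mapped <- bitwAnd(flag, 0x4) == 0
  strand <- ifelse(bitwAnd(flag, 0x10) == 0, "+", "-")
  span <- rep(NA_integer_, sum(primary))
  ok_cigar <- mapped & !is.na(res$cigar[primary])
  span[ok_cigar] <- cigar_ref_span(res$cigar[primary][ok_cigar])
  pos0 <- as.numeric(res$pos[primary]) - 1
  pos5 <- ifelse(strand == "+", pos0, pos0 + span - 1)
  tags <- data.frame(read_id = qname,
                     chrom = as.character(res$rname[primary]),
                     pos5 = pos5, strand = strand, span = span,
                     mapq = as.integer(res$mapq[primary]),
                     mapped = mapped, stringsAsFactors = FALSE)
  counts <- c(orphans = 0L, low_mapq_pairs = 0L, unmapped_pairs = 0L)
  spl <- split(seq_len(nrow(tags)), tags$read_id)
  n_pairs <- sum(lengths(spl) == 2)
  counts["orphans"] <- sum(lengths(spl) != 2)
  keep1 <- integer(0); keep2 <- integer(0)
  for (idx in spl[lengths(spl) == 2]) {
    if (!all(tags$mapped[idx])) {
      counts["unmapped_pairs"] <- counts["unmapped_pairs"] + 1L
    } else if (!all(tags$mapq[idx] > min_mapq)) {
      counts["low_mapq_pairs"] <- counts["low_mapq_pairs"] + 1L
    } else {
      keep1 <- c(keep1, idx[1]); keep2 <- c(keep2, idx[2])
    }
  }
  out <- data.frame(read_id = tags$read_id[keep1],
                    chrom1 = tags$chrom[keep1], pos1 = tags$pos5[keep1],
                    strand1 = tags$strand[keep1], span1 = tags$span[keep1],
                    mapq1 = tags$mapq[keep1],
                    chrom2 = tags$chrom[keep2], pos2 = tags$pos5[keep2],
                    strand2 = tags$strand[keep2], span2 = tags$span[keep2],
                    mapq2 = tags$mapq[keep2], stringsAsFactors = FALSE)
  ord <- order_radix(out$read_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}
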