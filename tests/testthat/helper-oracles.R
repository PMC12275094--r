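# Independent oracles and fixture builders. These share no interval or string
# machinery with the package: plain character comparison and O(n^2) loops.

# Exhaustive Hamming scan for the bridge linker over every offset and query,
# in plain R. Same decision rule as the contract: fewest mismatches, then
# smaller offset, then query priority.
oracle_scan_linker <- function(read, queries, max_mismatches, min_overlap) {
  L <- nchar(read)
  rchars <- strsplit(read, "", fixed = TRUE)[[1]]
  best <- NULL
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    m <- nchar(q)
    qchars <- strsplit(q, "", fixed = TRUE)[[1]]
    for (off in 0:(L - 1)) {
      o <- min(m, L - off)
      full <- o == m
      if (!full && o < min_overlap) next
      allowed <- if (full) max_mismatches else {
        floor(max_mismatches * o / m)
      }
      mism <- sum(rchars[(off + 1):(off + o)] != qchars[1:o])
      if (mism <= allowed) {
        if (is.null(best) || mism < best$mismatches ||
            (mism == best$mismatches && off < best$offset)) {
          best <- list(offset = off, orientation = names(queries)[qi],
                       mismatches = mism)
        }
      }
    }
  }
  best
}

# Random DNA of length n.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Substitute k random positions of a string.
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in sample(seq_along(chars), k)) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Brute-force both-anchor-overlap clustering: O(n^2) pairwise link tests and
# naive component merging by relabelling.
oracle_cluster <- function(pets, extension, tag_span) {
  n <- nrow(pets)
  if (n == 0) return(integer(0))
  occ <- function(pos, strand, span) {
    s <- ifelse(strand == "+", pos, pos - span + 1)
    cbind(s, ifelse(strand == "+", pos + span, pos + 1))
  }
  sp1 <- ifelse(is.na(pets$span1), tag_span, pets$span1)
  sp2 <- ifelse(is.na(pets$span2), tag_span, pets$span2)
  a1 <- occ(pets$pos1, pets$strand1, sp1)
  a2 <- occ(pets$pos2, pets$strand2, sp2)
  a1[, 1] <- pmax(0, a1[, 1] - extension); a1[, 2] <- a1[, 2] + extension
  a2[, 1] <- pmax(0, a2[, 1] - extension); a2[, 2] <- a2[, 2] + extension
  comp <- seq_len(n)
  overlap <- function(x, i, j) x[i, 1] < x[j, 2] && x[j, 1] < x[i, 2]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (overlap(a1, i, j) && overlap(a2, i, j)) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  comp
}

# Canonical signature of a clustering: sorted list of sorted member-id sets.
partition_signature <- function(groups) {
  sets <- lapply(groups, function(g) paste(sort(g), collapse = ","))
  paste(sort(unlist(sets)), collapse = ";")
}

# Random intra-chromosomal inter-ligation PET table on one chromosome.
rand_pets <- function(n, chrom = "chrT", max_pos = 200000, span = 50) {
  pos1 <- sort(sample.int(max_pos, n, replace = TRUE))
  gap <- sample(9000:50000, n, replace = TRUE)
  data.frame(read_id = paste0("p", seq_len(n)),
             chrom1 = chrom, pos1 = pos1, strand1 = "+", span1 = span,
             chrom2 = chrom, pos2 = pos1 + gap,
             strand2 = sample(c("+", "-"), n, replace = TRUE), span2 = span,
             stringsAsFactors = FALSE)
}

# Minimal PET constructor for classification and dedup tests.
make_pet <- function(chrom1, pos1, chrom2, pos2, strand1 = "+", strand2 = "-",
                     span = 50, id = "r") {
  pair_tags(data.frame(read_id = id, chrom1 = chrom1, pos1 = pos1,
                       strand1 = strand1, span1 = span, chrom2 = chrom2,
                       pos2 = pos2, strand2 = strand2, span2 = span,
                       stringsAsFactors = FALSE))
}

# Write a small SAM file; records is a character vector of body lines.
write_sam <- function(records, sq = "@SQ\tSN:chrT\tLN:100000") {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, records), path)
  path
}

sam_line <- function(qname, flag, rname, pos1, mapq, cigar, seq) {
  paste(qname, flag, rname, pos1, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# Tiny FASTQ writer for fixture files.
write_fastq_file <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             vapply(seqs, function(s) strrep("I", nchar(s)), ""))),
             path)
}
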