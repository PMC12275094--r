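# Built-in exact/unique tag matcher for synthetic genomes, PET pairing, and
# PCR-duplicate removal. Real libraries aligned with an external aligner enter
# through read_sam_pairs() instead.

#' Build a reference index for the built-in matcher
#'
#' @param genome a named [Biostrings::DNAStringSet] or a FASTA path.
#' @param k minimum tag length accepted by the matcher (shorter tags are
#'   counted `too_short`). Default 12.
#' @return list with `seqs`, `lengths` (named) and `k`.
#' @export
reference_index <- function(genome, k = 12L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  names(genome) <- sub("\\s.*$", "", names(genome))
  list(seqs = genome,
       lengths = stats::setNames(Biostrings::width(genome), names(genome)),
       k = as.integer(k))
}

#' Map a tag sequence by exact, genome-wide-unique match
#'
#' Searches both strands for exact occurrences of the tag. A tag matching
#' exactly one locus genome-wide is reported with mapping quality 60; tags
#' with zero or multiple occurrences are rejected.
#'
#' @param tag_seq tag sequence (character, length 1).
#' @param index a [reference_index()].
#' @return list(chrom, pos5, strand, span, mapq) or `NULL` with attribute-free
#'   rejection reason in field `reason` of the returned list
#'   (`too_short`, `unmapped`, `multimapped`).
#' @export
map_exact <- function(tag_seq, index) {
  if (nchar(tag_seq) < index$k) return(list(reason = "too_short"))
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") tag_seq else revcomp(tag_seq)
    m <- Biostrings::vmatchPattern(pat, index$seqs)
    for (ci in seq_along(m)) {
      r <- m[[ci]]
      if (length(r)) {
        for (j in seq_along(r)) {
          hits[[length(hits) + 1]] <- list(
            chrom = names(index$seqs)[ci],
            start0 = IRanges::start(r)[j] - 1L,
            end0 = IRanges::end(r)[j], strand = strand)
        }
        if (length(hits) > 1) return(list(reason = "multimapped"))
      }
    }
  }
  if (length(hits) == 0) return(list(reason = "unmapped"))
  if (length(hits) > 1) return(list(reason = "multimapped"))
  h <- hits[[1]]
  pos5 <- if (h$strand == "+") h$start0 else h$end0 - 1L
  list(chrom = h$chrom, pos5 = as.numeric(pos5), strand = h$strand,
       span = nchar(tag_seq), mapq = 60L, reason = "mapped")
}

#' Map trimmed tag pairs with the built-in matcher and form PETs
#'
#' Both tags of a pair must map uniquely; pairs with an unmapped, multimapped
#' or too-short tag are dropped and counted. Identical tag sequences are
#' mapped once and the result reused, so PCR-duplicate copies cost nothing.
#'
#' @param tags data.frame from [split_pairs()] (`read_id`, `tag1`, `tag2`).
#' @param index a [reference_index()].
#' @return list with `pets` (canonical PET data.frame: read_id, chrom1, pos1,
#'   strand1, span1, chrom2, pos2, strand2, span2) and `counters`.
#' @export
map_tags <- function(tags, index) {
  all_seqs <- unique(c(tags$tag1, tags$tag2))
  cache <- lapply(all_seqs, map_exact, index = index)
  names(cache) <- all_seqs
  reasons1 <- vapply(cache[tags$tag1], `[[`, "", "reason")
  reasons2 <- vapply(cache[tags$tag2], `[[`, "", "reason")
  ok <- reasons1 == "mapped" & reasons2 == "mapped"
  pair_reason <- ifelse(ok, "mapped",
                 ifelse(reasons1 == "too_short" | reasons2 == "too_short",
                        "too_short",
                 ifelse(reasons1 == "unmapped" | reasons2 == "unmapped",
                        "unmapped", "multimapped")))
  counters <- c(
    pairs_in = nrow(tags),
    mapped_pets = sum(ok),
    dropped_too_short = sum(pair_reason == "too_short"),
    dropped_unmapped = sum(pair_reason == "unmapped"),
    dropped_multimapped = sum(pair_reason == "multimapped")
  )
  get <- function(seqs, field) {
    vapply(cache[seqs], function(h) {
      v <- h[[field]]
      if (is.character(v)) v else as.numeric(v)
    }, if (field %in% c("chrom", "strand")) "" else numeric(1))
  }
  idx <- which(ok)
  if (length(idx)) {
    t1 <- tags$tag1[idx]; t2 <- tags$tag2[idx]
    raw <- data.frame(
      read_id = tags$read_id[idx],
      chrom1 = get(t1, "chrom"), pos1 = get(t1, "pos5"),
      strand1 = get(t1, "strand"), span1 = get(t1, "span"),
      chrom2 = get(t2, "chrom"), pos2 = get(t2, "pos5"),
      strand2 = get(t2, "strand"), span2 = get(t2, "span"),
      stringsAsFactors = FALSE)
    pets <- pair_tags(raw)
  } else {
    pets <- empty_pets()
  }
  list(pets = pets, counters = counters)
}

empty_pets <- function() {
  data.frame(read_id = character(0), chrom1 = character(0), pos1 = numeric(0),
             strand1 = character(0), span1 = numeric(0),
             chrom2 = character(0), pos2 = numeric(0), strand2 = character(0),
             span2 = numeric(0), stringsAsFactors = FALSE)
}

#' Canonically order the two tags of each PET
#'
#' Tags are swapped so that tag1 <= tag2 by (chromosome name, 5' position);
#' classification and duplicate signatures are therefore symmetric in the
#' original mate order.
#'
#' @param pets PET data.frame (mate order).
#' @return PET data.frame in canonical order.
#' @export
pair_tags <- function(pets) {
  if (nrow(pets) == 0) return(empty_pets())
  swap <- pets$chrom2 < pets$chrom1 |
    (pets$chrom2 == pets$chrom1 & pets$pos2 < pets$pos1)
  sw <- function(a, b) {
    tmp <- pets[[a]][swap]
    pets[[a]][swap] <<- pets[[b]][swap]
    pets[[b]][swap] <<- tmp
  }
  sw("chrom1", "chrom2"); sw("pos1", "pos2")
  sw("strand1", "strand2"); sw("span1", "span2")
  pets
}

#' Remove PCR duplicates at the PET level
#'
#' Two PETs are duplicates iff the (chromosome, 5' position, strand) triples
#' of both tags are all equal. The first-seen PET of each signature survives;
#' output is sorted by tag1 then tag2 coordinates.
#'
#' @param pets canonical PET data.frame.
#' @return list with `pets` (nonredundant, sorted) and `n_duplicates`.
#' @export
dedup_pets <- function(pets) {
  if (nrow(pets) == 0) return(list(pets = pets, n_duplicates = 0L))
  dt <- data.table::as.data.table(pets)
  sig <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  keep <- !duplicated(dt, by = sig)
  out <- dt[keep]
  data.table::setorderv(out, c("chrom1", "pos1", "strand1",
                               "chrom2", "pos2", "strand2", "read_id"))
  list(pets = as.data.frame(out), n_duplicates = as.integer(sum(!keep)))
}
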