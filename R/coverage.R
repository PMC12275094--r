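# RNAPII binding coverage and raw binned contact matrices.
#
# All uniquely mapped, nonredundant PETs — self-ligation, inter-ligation and
# trans alike — contribute both tags to the binding-coverage track. The
# contact matrix bins intra-chromosomal inter-ligation PETs (singletons
# included) by the two tags' 5' positions and stores raw counts; normalisation
# is left to external tools.

#' Per-bin tag coverage across the genome
#'
#' Each tag contributes its occupied reference interval; a bin's value is the
#' number of tag intervals overlapping it.
#'
#' @param pets deduplicated PETs of all categories.
#' @param chrom_lens named vector of chromosome lengths.
#' @param bin bin size in bp.
#' @param params a [pipeline_params()] object (for `tag_span_default`).
#' @return object of class `coverage_track`: list with `bin`, `chrom_lens`
#'   and `values` (named list of integer vectors of length
#'   `ceiling(len / bin)`).
#' @export
coverage_track <- function(pets, chrom_lens, bin = 100L,
                           params = pipeline_params()) {
  ti <- pet_tag_intervals(pets, params)
  tags <- data.frame(
    chrom = c(pets$chrom1, pets$chrom2),
    start = pmax(0, c(ti$a1$start, ti$a2$start)),
    end = c(ti$a1$end, ti$a2$end),
    stringsAsFactors = FALSE)
  values <- lapply(names(chrom_lens), function(ch) {
    len <- chrom_lens[[ch]]
    nb <- ceiling(len / bin)
    v <- integer(nb)
    # clip tag intervals to the chromosome; drop any falling entirely outside
    sel <- tags$chrom == ch & tags$start < len & tags$end > 0
    if (any(sel)) {
      bins <- IRanges::IRanges(start = (seq_len(nb) - 1) * bin + 1,
                               end = pmin(seq_len(nb) * bin, len))
      v <- IRanges::countOverlaps(
        bins, as_iranges0(pmax(tags$start[sel], 0), pmin(tags$end[sel], len)))
    }
    v
  })
  names(values) <- names(chrom_lens)
  structure(list(bin = as.integer(bin), chrom_lens = chrom_lens,
                 values = values), class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' Zero bins are suppressed; adjacent bins are not merged.
#'
#' @param track a [coverage_track()] object.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    nz <- which(v > 0)
    if (length(nz)) {
      start <- (nz - 1) * track$bin
      end <- pmin(nz * track$bin, track$chrom_lens[[ch]])
      writeLines(paste(ch, format(start, scientific = FALSE, trim = TRUE),
                       format(end, scientific = FALSE, trim = TRUE), v[nz],
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Raw binned contact matrix from inter-ligation PETs
#'
#' Each intra-chromosomal inter-ligation PET (singletons included) increments
#' the (bin(pos1), bin(pos2)) triplet of its chromosome; canonical tag order
#' guarantees bin1 <= bin2, so the matrix is symmetric by construction and the
#' total count equals the number of contributing PETs.
#'
#' @param inter_pets intra-chromosomal inter-ligation PET data.frame.
#' @param bin bin size in bp.
#' @return data.frame chrom, bin1, bin2, count with attribute `bin`.
#' @export
contact_matrix <- function(inter_pets, bin = 25000L) {
  if (nrow(inter_pets) == 0) {
    out <- data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), count = integer(0))
    attr(out, "bin") <- as.integer(bin)
    return(out)
  }
  stopifnot(all(inter_pets$chrom1 == inter_pets$chrom2))
  dt <- data.table::data.table(
    chrom = inter_pets$chrom1,
    bin1 = as.integer(inter_pets$pos1 %/% bin),
    bin2 = as.integer(inter_pets$pos2 %/% bin))
  out <- dt[, .(count = .N), by = .(chrom, bin1, bin2)]
  data.table::setorderv(out, c("chrom", "bin1", "bin2"))
  out <- as.data.frame(out)
  attr(out, "bin") <- as.integer(bin)
  out
}

#' Write a contact matrix as COO text
#'
#' One block per chromosome, each headed by `# chrom=<name> bin_size=<bp>`,
#' followed by tab-separated bin1, bin2, count triplets.
#'
#' @param cm a [contact_matrix()] result.
#' @param path output path.
#' @export
write_contacts <- function(cm, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  bin <- attr(cm, "bin")
  for (ch in unique(cm$chrom)) {
    writeLines(sprintf("# chrom=%s bin_size=%d", ch, bin), con)
    sub <- cm[cm$chrom == ch, , drop = FALSE]
    writeLines(paste(sub$bin1, sub$bin2, sub$count, sep = "\t"), con)
  }
  invisible(path)
}
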