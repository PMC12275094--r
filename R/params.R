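#' Pipeline parameters
#'
#' Bundles every tunable threshold of the ChIA-PET processing pipeline.
#' Defaults follow the published protocol for RNAPII in situ ChIA-PET:
#' paired-end tags (PETs) on the same chromosome with a 5'-to-5' span below
#' `self_ligation_span` are self-ligation products, anchors of inter-ligation
#' PETs are extended by `anchor_extension` bp before overlap clustering, and
#' loops must carry at least `min_pet_count` PETs, H3K27ac on both anchors,
#' and an anchor distance below `max_loop_span`.
#'
#' @param self_ligation_span bp; same-chromosome PETs with span strictly below
#'   this are self-ligation, others inter-ligation. Default 8000.
#' @param anchor_extension bp added to both sides of each tag interval before
#'   the both-anchor overlap test. Default 500.
#' @param min_pet_count minimum PETs per cluster for a loop. Clusters with
#'   fewer are removed. Default 4.
#' @param max_loop_span bp; loops must have anchor midpoint distance strictly
#'   below this. Default 1e6.
#' @param min_mapq tags are kept when mapping quality is strictly greater than
#'   this value. Default 30.
#' @param max_mismatches maximum mismatches for a full-length bridge-linker
#'   match. Default 2.
#' @param min_overlap minimum bases of a 3'-terminal partial linker match.
#'   Default 10.
#' @param min_tag_len minimum genomic tag length after linker trimming.
#'   Default 18.
#' @param coverage_bin bp bin for the binding-coverage track. Default 100.
#' @param contact_bin bp bin for the raw contact matrix. Default 25000.
#' @param promoter_window bp on each side of a TSS that counts as promoter.
#'   Default 2000.
#' @param tag_span_default bp assumed for a tag's occupied interval when the
#'   alignment span is unknown (e.g. PETs read from a minimal TSV). Default 50.
#' @return a list of class `chia_params`.
#' @export
pipeline_params <- function(self_ligation_span = 8000L,
                            anchor_extension = 500L,
                            min_pet_count = 4L,
                            max_loop_span = 1000000L,
                            min_mapq = 30L,
                            max_mismatches = 2L,
                            min_overlap = 10L,
                            min_tag_len = 18L,
                            coverage_bin = 100L,
                            contact_bin = 25000L,
                            promoter_window = 2000L,
                            tag_span_default = 50L) {
  p <- list(
    self_ligation_span = as.integer(self_ligation_span),
    anchor_extension = as.integer(anchor_extension),
    min_pet_count = as.integer(min_pet_count),
    max_loop_span = as.numeric(max_loop_span),
    min_mapq = as.integer(min_mapq),
    max_mismatches = as.integer(max_mismatches),
    min_overlap = as.integer(min_overlap),
    min_tag_len = as.integer(min_tag_len),
    coverage_bin = as.integer(coverage_bin),
    contact_bin = as.integer(contact_bin),
    promoter_window = as.integer(promoter_window),
    tag_span_default = as.integer(tag_span_default)
  )
  stopifnot(
    p$self_ligation_span > 0, p$anchor_extension >= 0, p$min_pet_count >= 1,
    p$max_loop_span > p$self_ligation_span, p$min_mapq >= 0,
    p$max_mismatches >= 0, p$min_overlap > 0, p$min_tag_len > 0,
    p$coverage_bin > 0, p$contact_bin > 0, p$promoter_window >= 0,
    p$tag_span_default > 0
  )
  class(p) <- "chia_params"
  p
}
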