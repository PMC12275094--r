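# PET ligation taxonomy.
#
# Nonredundant PETs fall into three classes by the genomic span between the
# two tags' 5' positions: same chromosome with span < 8 kb -> self-ligation
# (both ends of one fragment, the ChIP-fragment proxy); same chromosome with
# span >= 8 kb -> inter-ligation (ends of two fragments held in one chromatin
# complex, i.e. a contact); different chromosomes -> trans. The 8-kb boundary
# itself is inter-ligation: "fewer than 8 kb" defines self-ligation strictly
# and the complement inherits the boundary.

#' Classify PETs into self-ligation / inter-ligation / trans
#'
#' @param pets canonical, deduplicated PET data.frame.
#' @param params a [pipeline_params()] object; uses `self_ligation_span`.
#' @return the PET data.frame with `span` (NA for trans) and `category` added.
#' @export
classify_pets <- function(pets, params = pipeline_params()) {
  if (nrow(pets) == 0) {
    pets$span <- numeric(0); pets$category <- character(0)
    return(pets)
  }
  same <- pets$chrom1 == pets$chrom2
  span <- ifelse(same, abs(pets$pos2 - pets$pos1), NA_real_)
  pets$span <- span
  pets$category <- ifelse(!same, "trans",
                          ifelse(span < params$self_ligation_span,
                                 "self_ligation", "inter_ligation"))
  pets
}

#' Partition classified PETs and summarise counts
#'
#' @param pets output of [classify_pets()].
#' @param params a [pipeline_params()] object.
#' @return list with `self_ligation`, `inter_ligation`, `trans` (disjoint,
#'   exhaustive data.frames) and `summary` (category, n, fraction).
#' @export
partition_pets <- function(pets, params = pipeline_params()) {
  if (!"category" %in% names(pets)) pets <- classify_pets(pets, params)
  cats <- c("self_ligation", "inter_ligation", "trans")
  parts <- lapply(cats, function(k) pets[pets$category == k, , drop = FALSE])
  names(parts) <- cats
  n <- vapply(parts, nrow, integer(1))
  total <- nrow(pets)
  parts$summary <- data.frame(
    category = cats, n = as.integer(n),
    fraction = if (total > 0) as.numeric(n) / total else rep(0, 3),
    stringsAsFactors = FALSE)
  parts
}
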