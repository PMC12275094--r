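# PET clustering.
#
# Both ends of every intra-chromosomal inter-ligation PET are extended by
# `anchor_extension` bp (500 by default) along the reference; two PETs are
# linked when their extended tag-1 intervals overlap AND their extended tag-2
# intervals overlap, and clusters are the connected components of that link
# graph. Reported anchors are the min-start/max-end hulls of the members'
# UNEXTENDED occupied intervals: the extension is a merging device, not a
# coordinate change. Clusters of size one are singletons.

# Occupied (unextended) intervals of both tags of each PET.
pet_tag_intervals <- function(pets, params) {
  span1 <- ifelse(is.na(pets$span1), params$tag_span_default, pets$span1)
  span2 <- ifelse(is.na(pets$span2), params$tag_span_default, pets$span2)
  i1 <- tag_interval(pets$pos1, pets$strand1, span1)
  i2 <- tag_interval(pets$pos2, pets$strand2, span2)
  list(a1 = i1, a2 = i2)
}

# Minimal union-find over 1..n; returns the component root of every element.
# Clustering is order-independent because components are a transitive closure.
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (j in seq_along(from)) {
    ra <- find(from[j]); rb <- find(to[j])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster inter-ligation PETs on one chromosome
#'
#' @param pets canonical intra-chromosomal inter-ligation PETs (one
#'   chromosome; mixing chromosomes is an error).
#' @param params a [pipeline_params()] object; uses `anchor_extension` and
#'   `tag_span_default`.
#' @param chrom_len optional chromosome length for extension clipping.
#' @return data.frame of clusters: chrom, start1, end1, start2, end2,
#'   pet_count, is_singleton, member_ids (list column), ordered by
#'   (start1, start2).
#' @export
cluster_pets <- function(pets, params = pipeline_params(), chrom_len = NA) {
  if (nrow(pets) == 0) return(empty_clusters())
  if (length(unique(pets$chrom1)) > 1 || any(pets$chrom1 != pets$chrom2)) {
    stopf("cluster_pets() expects intra-chromosomal PETs from one chromosome")
  }
  ti <- pet_tag_intervals(pets, params)
  e1 <- extend_interval(ti$a1$start, ti$a1$end, params$anchor_extension, chrom_len)
  e2 <- extend_interval(ti$a2$start, ti$a2$end, params$anchor_extension, chrom_len)
  h1 <- IRanges::findOverlaps(as_iranges0(e1$start, e1$end))
  h2 <- IRanges::findOverlaps(as_iranges0(e2$start, e2$end))
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  both <- k1 %in% k2
  qi <- S4Vectors::queryHits(h1)[both]
  si <- S4Vectors::subjectHits(h1)[both]
  edge <- qi < si
  comp <- uf_components(nrow(pets), qi[edge], si[edge])
  groups <- split(seq_len(nrow(pets)), comp)
  rows <- lapply(groups, function(idx) {
    data.frame(chrom = pets$chrom1[idx[1]],
               start1 = min(ti$a1$start[idx]), end1 = max(ti$a1$end[idx]),
               start2 = min(ti$a2$start[idx]), end2 = max(ti$a2$end[idx]),
               pet_count = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_singleton <- out$pet_count == 1L
  members <- lapply(groups, function(idx) pets$read_id[idx])
  ord <- order_radix(out$start1, out$start2)
  out <- out[ord, , drop = FALSE]
  out$member_ids <- members[ord]
  rownames(out) <- NULL
  out
}

empty_clusters <- function() {
  out <- data.frame(chrom = character(0), start1 = numeric(0),
                    end1 = numeric(0), start2 = numeric(0), end2 = numeric(0),
                    pet_count = integer(0), is_singleton = logical(0),
                    stringsAsFactors = FALSE)
  out$member_ids <- list()
  out
}

#' Cluster inter-ligation PETs genome-wide
#'
#' Splits PETs by chromosome, clusters each, and returns the combined table
#' ordered by (chrom, start1, start2) with names `cluster_1`, `cluster_2`, ...
#'
#' @param pets canonical intra-chromosomal inter-ligation PETs.
#' @param params a [pipeline_params()] object.
#' @param chrom_lens optional named vector of chromosome lengths.
#' @return data.frame as in [cluster_pets()], plus a `name` column.
#' @export
cluster_genome <- function(pets, params = pipeline_params(), chrom_lens = NULL) {
  if (nrow(pets) == 0) {
    out <- empty_clusters(); out$name <- character(0); return(out)
  }
  parts <- split(pets, pets$chrom1)
  parts <- parts[order_radix(names(parts))]
  res <- lapply(names(parts), function(ch) {
    cl <- if (!is.null(chrom_lens) && ch %in% names(chrom_lens)) {
      chrom_lens[[ch]]
    } else NA
    cluster_pets(parts[[ch]], params, cl)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$name <- paste0("cluster_", seq_len(nrow(out)))
  out
}

#' Summarise a clustering result
#'
#' @param clusters data.frame from [cluster_pets()] / [cluster_genome()].
#' @return list with `histogram` (pet_count, n_clusters), `singleton_fraction`
#'   and `span_quantiles` (anchor midpoint distance at 0/25/50/75/100%).
#' @export
cluster_summary <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(list(histogram = data.frame(pet_count = integer(0),
                                       n_clusters = integer(0)),
                singleton_fraction = NA_real_,
                span_quantiles = stats::setNames(rep(NA_real_, 5),
                                                 c("0%", "25%", "50%", "75%", "100%"))))
  }
  tab <- table(clusters$pet_count)
  hist <- data.frame(pet_count = as.integer(names(tab)),
                     n_clusters = as.integer(tab))
  spans <- (clusters$start2 + clusters$end2) / 2 -
    (clusters$start1 + clusters$end1) / 2
  list(histogram = hist,
       singleton_fraction = mean(clusters$is_singleton),
       span_quantiles = stats::quantile(spans))
}
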