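# Loop calling: three filters over PET clusters, then promoter/enhancer
# annotation against a TSS set.
#
# Filters, in order: (1) clusters with PET counts less than four are removed;
# (2) H3K27ac must appear on both anchors (>= 1 bp overlap with a peak);
# (3) only clusters with anchor distance (midpoint to midpoint) below 1 Mb
# are retained. Survivors are RNAPII-mediated chromatin loops.

anchor_df <- function(clusters, which) {
  data.frame(chrom = clusters$chrom,
             start = clusters[[paste0("start", which)]],
             end = clusters[[paste0("end", which)]],
             stringsAsFactors = FALSE)
}

anchor_distance <- function(clusters) {
  (clusters$start2 + clusters$end2) / 2 - (clusters$start1 + clusters$end1) / 2
}

#' Filter PET clusters into loops
#'
#' @param clusters data.frame from [cluster_genome()].
#' @param peaks H3K27ac peak intervals (data.frame chrom/start/end).
#' @param params a [pipeline_params()] object; uses `min_pet_count` and
#'   `max_loop_span`.
#' @return list with `loops` (clusters passing all filters, with
#'   `anchor_distance` added) and `rejections` (filter, n_rejected; plus a
#'   kept row). A warning is raised when peaks cover chromosomes absent from
#'   the clusters.
#' @export
filter_loops <- function(clusters, peaks, params = pipeline_params()) {
  lost <- setdiff(unique(peaks$chrom), unique(clusters$chrom))
  if (length(lost) && nrow(clusters)) {
    warning(sprintf("peaks on %d chromosome(s) absent from clusters: %s",
                    length(lost), paste(lost, collapse = ",")))
  }
  n0 <- nrow(clusters)
  keep1 <- clusters$pet_count >= params$min_pet_count
  c1 <- clusters[keep1, , drop = FALSE]
  keep2 <- overlaps_any(anchor_df(c1, 1), peaks) &
    overlaps_any(anchor_df(c1, 2), peaks)
  c2 <- c1[keep2, , drop = FALSE]
  dist <- anchor_distance(c2)
  keep3 <- dist < params$max_loop_span
  loops <- c2[keep3, , drop = FALSE]
  loops$anchor_distance <- dist[keep3]
  rownames(loops) <- NULL
  rejections <- data.frame(
    filter = c("pet_count", "h3k27ac_anchors", "anchor_distance", "kept"),
    n = c(sum(!keep1), sum(!keep2), sum(!keep3), nrow(loops)),
    stringsAsFactors = FALSE)
  stopifnot(sum(rejections$n) == n0)
  list(loops = loops, rejections = rejections)
}

classify_anchor <- function(anchors, promoters, peaks) {
  cls <- rep("other", nrow(anchors))
  cls[overlaps_any(anchors, peaks)] <- "enhancer"
  cls[overlaps_any(anchors, promoters)] <- "promoter"
  cls
}

anchor_genes <- function(anchors, promoters) {
  hits <- interval_hits(anchors, promoters)
  genes <- rep("", nrow(anchors))
  if (nrow(hits)) {
    agg <- tapply(promoters$name[hits$subject], hits$query,
                  function(g) paste(sort(unique(g)), collapse = ","))
    genes[as.integer(names(agg))] <- as.character(agg)
  }
  genes
}

#' Annotate loop anchors as promoter / enhancer / other
#'
#' Promoter windows are TSS +/- `promoter_window` bp. An anchor overlapping a
#' promoter window is a promoter anchor (genes recorded); otherwise an anchor
#' overlapping an H3K27ac peak is an enhancer anchor; otherwise "other".
#'
#' @param loops loops data.frame from [filter_loops()].
#' @param tss TSS intervals with a `name` (gene) column; point TSS may be
#'   given as 1-bp intervals.
#' @param peaks H3K27ac peaks used for the enhancer class.
#' @param params a [pipeline_params()] object; uses `promoter_window`.
#' @return list with `loops` (anchor1_class, anchor2_class, loop_class,
#'   genes1, genes2 added) and `gene_degree` (gene, degree: the number of
#'   distinct distal anchors connected to that gene's promoter).
#' @export
annotate_loops <- function(loops, tss, peaks, params = pipeline_params()) {
  if (!"name" %in% names(tss)) stopf("TSS table must carry a gene name column")
  w <- params$promoter_window
  promoters <- genomic_intervals(tss$chrom, pmax(0, tss$start - w),
                                 tss$end + w, tss$name)
  a1 <- anchor_df(loops, 1); a2 <- anchor_df(loops, 2)
  loops$anchor1_class <- classify_anchor(a1, promoters, peaks)
  loops$anchor2_class <- classify_anchor(a2, promoters, peaks)
  loops$loop_class <- paste(loops$anchor1_class, loops$anchor2_class, sep = "-")
  loops$genes1 <- anchor_genes(a1, promoters)
  loops$genes2 <- anchor_genes(a2, promoters)

  # Loop degree per gene: distinct distal anchors reached from the promoter.
  deg <- list()
  add <- function(genes, distal) {
    for (i in which(nzchar(genes))) {
      for (g in strsplit(genes[i], ",", fixed = TRUE)[[1]]) {
        key <- paste(distal$chrom[i], distal$start[i], distal$end[i])
        deg[[g]] <<- unique(c(deg[[g]], key))
      }
    }
  }
  add(loops$genes1, a2)
  add(loops$genes2, a1)
  gene_degree <- data.frame(gene = names(deg),
                            degree = vapply(deg, length, integer(1)),
                            stringsAsFactors = FALSE)
  rownames(gene_degree) <- NULL
  list(loops = loops, gene_degree = gene_degree)
}

#' Compare loop sets between two conditions
#'
#' Loops are matched one-to-one (greedily, nearest first) when both anchors'
#' midpoints agree within `slack` bp on the same chromosome.
#'
#' @param loops_a,loops_b loop data.frames (chrom, start1, end1, start2, end2).
#' @param slack bp tolerance on each anchor midpoint.
#' @return list with counts `shared`, `a_only`, `b_only` and the match table.
#' @export
compare_conditions <- function(loops_a, loops_b, slack = 500) {
  m <- match_loops(loops_a, loops_b, slack)
  list(shared = nrow(m),
       a_only = nrow(loops_a) - nrow(m),
       b_only = nrow(loops_b) - nrow(m),
       matches = m)
}

# Greedy one-to-one matching of two loop tables by anchor midpoints.
match_loops <- function(a, b, slack) {
  empty <- data.frame(a = integer(0), b = integer(0), dist = numeric(0))
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  mid <- function(x, w) (x[[paste0("start", w)]] + x[[paste0("end", w)]]) / 2
  am1 <- mid(a, 1); am2 <- mid(a, 2)
  bm1 <- mid(b, 1); bm2 <- mid(b, 2)
  cand <- list()
  for (i in seq_len(nrow(a))) {
    ok <- b$chrom == a$chrom[i] &
      abs(bm1 - am1[i]) <= slack & abs(bm2 - am2[i]) <= slack
    if (any(ok)) {
      cand[[length(cand) + 1]] <- data.frame(
        a = i, b = which(ok),
        dist = pmax(abs(bm1[ok] - am1[i]), abs(bm2[ok] - am2[i])))
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order_radix(cand$dist, cand$a, cand$b), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    if (!used_a[cand$a[j]] && !used_b[cand$b[j]]) {
      keep[j] <- TRUE
      used_a[cand$a[j]] <- TRUE
      used_b[cand$b[j]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
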