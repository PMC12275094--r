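# Synthetic ChIA-PET library generator with ground truth.
#
# Emulates what the wet-lab protocol delivers to the sequencer: proximity
# ligation products in which two genomic fragments are joined by the
# biotinylated bridge linker, sequenced as paired-end reads. Each read pair
# is labelled at emission (loop, self-ligation, trans noise, intra noise,
# PCR duplicate), so every pipeline stage can be scored against truth.

#' Simulation configuration
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param gc GC fraction of the i.i.d. genome.
#' @param n_loops number of planted loops.
#' @param anchor_width width of each loop anchor (bp).
#' @param loop_span range (min, max) of planted anchor separations (bp).
#' @param pets_per_loop mean PETs per loop.
#' @param pets_dispersion 0 for exactly `pets_per_loop` PETs per loop,
#'   otherwise the negative-binomial dispersion (variance = mu + mu^2 * disp).
#' @param self_ligation_fraction fraction of read pairs that are
#'   self-ligation products (span < 8 kb).
#' @param trans_noise_fraction fraction of pairs joining two chromosomes.
#' @param intra_noise_fraction fraction of pairs joining two random loci on
#'   one chromosome.
#' @param duplicate_rate fraction of extra pairs that are exact PCR copies of
#'   already-emitted pairs.
#' @param read_length read length (bp), 2 x 150 by default.
#' @param tag_length range (min, max) of genomic tag lengths within a read;
#'   the bridge linker follows the tag, so tags near `read_length` produce
#'   one-sided or partial linker reads.
#' @param error_rate per-base substitution rate applied after read assembly.
#' @param peak_fraction fraction of loop anchors covered by an H3K27ac truth
#'   peak (anchor +/- 250 bp); uncovered anchors are planted negatives for
#'   the loop filters.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1000000L,
                       gc = 0.45,
                       n_loops = 10L,
                       anchor_width = 500L,
                       loop_span = c(20000L, 400000L),
                       pets_per_loop = 6,
                       pets_dispersion = 0,
                       self_ligation_fraction = 0.4,
                       trans_noise_fraction = 0.05,
                       intra_noise_fraction = 0.05,
                       duplicate_rate = 0.1,
                       read_length = 150L,
                       tag_length = c(40L, 90L),
                       error_rate = 0.001,
                       peak_fraction = 1.0) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_chroms >= 1, cfg$chrom_length >= 10000, cfg$gc > 0, cfg$gc < 1,
    cfg$n_loops >= 0, cfg$anchor_width >= 50,
    length(cfg$loop_span) == 2, cfg$loop_span[1] > 8000,
    cfg$loop_span[2] <= cfg$chrom_length / 2,
    cfg$pets_per_loop >= 1, cfg$pets_dispersion >= 0,
    cfg$self_ligation_fraction >= 0, cfg$trans_noise_fraction >= 0,
    cfg$intra_noise_fraction >= 0,
    cfg$self_ligation_fraction + cfg$trans_noise_fraction +
      cfg$intra_noise_fraction < 1,
    cfg$duplicate_rate >= 0, cfg$duplicate_rate <= 1,
    cfg$read_length >= 50, length(cfg$tag_length) == 2,
    cfg$tag_length[1] >= 18, cfg$tag_length[2] >= cfg$tag_length[1],
    cfg$error_rate >= 0, cfg$error_rate < 0.5,
    cfg$peak_fraction >= 0, cfg$peak_fraction <= 1,
    cfg$n_chroms >= 2 || cfg$trans_noise_fraction == 0
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an i.i.d. genome
#'
#' @param config a [sim_config()].
#' @return named [Biostrings::DNAStringSet] (`chrS1`, `chrS2`, ...),
#'   deterministic for a fixed seed.
#' @export
simulate_genome <- function(config) {
  with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(names(p), config$chrom_length, replace = TRUE, prob = p),
            collapse = "")
    }, "")
    g <- Biostrings::DNAStringSet(seqs)
    names(g) <- paste0("chrS", seq_len(config$n_chroms))
    g
  })
}

# Genomic content of a tag read from its 5' end, optionally extended beyond
# the tag into flanking sequence (the rest of the ligation fragment).
# For "+" the 5' end is at `start` (0-based) reading right; for "-" the 5'
# end is at `end - 1` reading left (reverse complement).
tag_content <- function(genome, chrom, start, end, strand, n) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (strand == "+") {
    s <- start; e <- min(start + n, len)
    as.character(Biostrings::subseq(genome[[chrom]], s + 1, e))
  } else {
    s <- max(0, end - n); e <- end
    revcomp(as.character(Biostrings::subseq(genome[[chrom]], s + 1, e)))
  }
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Place `n_loops` loops so that no two anchors (across loops) come within
# `min_sep` bp of each other; distinct loops occupy distinct loci, as anchors
# of real loops do, and clusters of different planted loops cannot merge.
place_loops <- function(config, min_sep) {
  w <- config$anchor_width
  margin <- 2L * config$read_length + 100L
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  loops <- vector("list", config$n_loops)
  for (i in seq_len(config$n_loops)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ch <- paste0("chrS", sample.int(config$n_chroms, 1))
      span <- round(stats::runif(1, config$loop_span[1], config$loop_span[2]))
      a1 <- round(stats::runif(1, margin,
                               config$chrom_length - margin - span - w))
      a2 <- a1 + span
      cand <- data.frame(chrom = ch, start = c(a1, a2) - min_sep,
                         end = c(a1, a2) + w + min_sep)
      if (!any(overlaps_any(cand, placed))) {
        placed <- rbind(placed,
                        data.frame(chrom = ch, start = c(a1, a2),
                                   end = c(a1, a2) + w))
        loops[[i]] <- data.frame(loop_id = paste0("loop_", i), chrom = ch,
                                 a1_start = a1, a1_end = a1 + w,
                                 a2_start = a2, a2_end = a2 + w,
                                 stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place loop %d without anchor collisions; genome too small", i)
  }
  do.call(rbind, loops)
}

#' Simulate a ChIA-PET library with ground truth
#'
#' For each planted loop, PETs take tag 1 from anchor 1 (plus strand) and
#' tag 2 from anchor 2 (minus strand); the emitted mate pair concatenates the
#' tag-proximal genomic sequence, the bridge linker (forward in mate 1,
#' reverse complement in mate 2) and carry-over sequence from the partner
#' fragment, truncated to the read length. Self-ligation pairs take both tags
#' from one fragment shorter than 8 kb; trans and intra noise and exact PCR
#' duplicates are added as configured; substitution errors are applied after
#' assembly (duplicates copy the post-error bytes).
#'
#' @param config a [sim_config()].
#' @param genome from [simulate_genome()]; regenerated when `NULL`.
#' @return list with `reads` (read_id, seq1, qual1, seq2, qual2), `truth`
#'   (list: `loops`, `peaks`, `reads`), `genome` and `chrom_lens`.
#' @export
simulate_library <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  linker <- bridge_linker()
  with_seed(config$seed + 1L, {
    ext_guard <- 2L * 500L + config$anchor_width
    loops <- place_loops(config, ext_guard)
    n_per_loop <- if (config$pets_dispersion == 0) {
      rep(round(config$pets_per_loop), config$n_loops)
    } else {
      pmax(1L, stats::rnbinom(config$n_loops, mu = config$pets_per_loop,
                              size = 1 / config$pets_dispersion))
    }
    loops$n_pets <- if (config$n_loops > 0) n_per_loop else integer(0)

    n_loop_pets <- sum(loops$n_pets)
    f_noise <- config$self_ligation_fraction + config$trans_noise_fraction +
      config$intra_noise_fraction
    total <- if (n_loop_pets > 0) round(n_loop_pets / (1 - f_noise)) else 0L
    n_self <- round(total * config$self_ligation_fraction)
    n_trans <- round(total * config$trans_noise_fraction)
    n_intra <- round(total * config$intra_noise_fraction)

    draw_len <- function(n) {
      if (config$tag_length[1] == config$tag_length[2]) {
        rep(config$tag_length[1], n)
      } else {
        sample(seq(config$tag_length[1], config$tag_length[2]), n,
               replace = TRUE)
      }
    }

    specs <- list()
    # loop PETs: tag1 in anchor1 (+), tag2 in anchor2 (-)
    for (i in seq_len(nrow(loops))) {
      k <- loops$n_pets[i]
      la <- draw_len(k); lb <- draw_len(k)
      s1 <- floor(stats::runif(k, loops$a1_start[i], loops$a1_end[i] - la + 1))
      s2 <- floor(stats::runif(k, loops$a2_start[i], loops$a2_end[i] - lb + 1))
      for (j in seq_len(k)) {
        specs[[length(specs) + 1]] <- list(
          label = loops$loop_id[i],
          chrom1 = loops$chrom[i], start1 = s1[j], end1 = s1[j] + la[j],
          strand1 = "+",
          chrom2 = loops$chrom[i], start2 = s2[j], end2 = s2[j] + lb[j],
          strand2 = "-")
      }
    }
    # self-ligation: both ends of one fragment < 8 kb
    margin <- 10000L
    for (j in seq_len(n_self)) {
      ch <- paste0("chrS", sample.int(config$n_chroms, 1))
      s <- round(stats::runif(1, 400, 7999))
      la <- draw_len(1); lb <- draw_len(1)
      p <- floor(stats::runif(1, margin, chrom_lens[[ch]] - margin - s))
      specs[[length(specs) + 1]] <- list(
        label = "self", chrom1 = ch, start1 = p, end1 = p + la, strand1 = "+",
        chrom2 = ch, start2 = p + s - lb, end2 = p + s, strand2 = "-")
    }
    # intra-chromosomal noise
    for (j in seq_len(n_intra)) {
      ch <- paste0("chrS", sample.int(config$n_chroms, 1))
      gap <- round(stats::runif(1, 500, chrom_lens[[ch]] / 3))
      la <- draw_len(1); lb <- draw_len(1)
      p <- floor(stats::runif(1, margin, chrom_lens[[ch]] - margin - gap))
      specs[[length(specs) + 1]] <- list(
        label = "intra_noise", chrom1 = ch, start1 = p, end1 = p + la,
        strand1 = "+",
        chrom2 = ch, start2 = p + gap - lb, end2 = p + gap, strand2 = "-")
    }
    # trans noise
    for (j in seq_len(n_trans)) {
      chs <- paste0("chrS", sample.int(config$n_chroms, 2))
      la <- draw_len(1); lb <- draw_len(1)
      p1 <- floor(stats::runif(1, margin, chrom_lens[[chs[1]]] - margin))
      p2 <- floor(stats::runif(1, margin, chrom_lens[[chs[2]]] - margin))
      specs[[length(specs) + 1]] <- list(
        label = "trans", chrom1 = chs[1], start1 = p1, end1 = p1 + la,
        strand1 = "+",
        chrom2 = chs[2], start2 = p2 - lb, end2 = p2, strand2 = "-")
    }

    # assemble reads
    rl <- config$read_length
    lf <- linker$forward
    n_spec <- length(specs)
    emit <- vector("list", n_spec)
    for (i in seq_len(n_spec)) {
      sp <- specs[[i]]
      la <- sp$end1 - sp$start1
      lb <- sp$end2 - sp$start2
      t1 <- tag_content(genome, sp$chrom1, sp$start1, sp$end1, sp$strand1, la)
      t2 <- tag_content(genome, sp$chrom2, sp$start2, sp$end2, sp$strand2, lb)
      need1 <- rl - la - nchar(lf)
      carry1 <- if (need1 > 0) {
        tag_content(genome, sp$chrom2, sp$start2, sp$end2, sp$strand2,
                    lb + need1)
      } else ""
      carry1 <- if (need1 > 0) substr(carry1, 1, need1) else ""
      read1 <- substr(paste0(t1, lf, carry1), 1, rl)
      need2 <- rl - lb - nchar(lf)
      carry2 <- if (need2 > 0) {
        # continue past the junction into fragment 1, read back from its 3' end
        flip <- if (sp$strand1 == "+") "-" else "+"
        tag_content(genome, sp$chrom1, sp$start1, sp$end1, flip, la + need2)
      } else ""
      carry2 <- if (need2 > 0) substr(carry2, 1, need2) else ""
      read2 <- substr(paste0(t2, revcomp(lf), carry2), 1, rl)
      read1 <- apply_errors(read1, config$error_rate)
      read2 <- apply_errors(read2, config$error_rate)
      pos5_1 <- if (sp$strand1 == "+") sp$start1 else sp$end1 - 1
      pos5_2 <- if (sp$strand2 == "+") sp$start2 else sp$end2 - 1
      emit[[i]] <- data.frame(
        read_id = sprintf("sim%06d", i), label = sp$label,
        seq1 = read1, seq2 = read2,
        chrom1 = sp$chrom1, pos1 = pos5_1, strand1 = sp$strand1, len1 = la,
        chrom2 = sp$chrom2, pos2 = pos5_2, strand2 = sp$strand2, len2 = lb,
        duplicate = FALSE, duplicate_of = "", stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, emit)

    # exact PCR duplicates of already-emitted pairs
    n_dup <- round(config$duplicate_rate * n_spec)
    if (n_dup > 0 && n_spec > 0) {
      src <- sample.int(n_spec, n_dup, replace = TRUE)
      dups <- reads[src, , drop = FALSE]
      dups$duplicate <- TRUE
      dups$duplicate_of <- reads$read_id[src]
      dups$read_id <- sprintf("sim%06d", n_spec + seq_len(n_dup))
      reads <- rbind(reads, dups)
    }
    rownames(reads) <- NULL

    # H3K27ac truth peaks: anchor +/- 250 bp for a subset of anchors
    anchors <- rbind(
      data.frame(chrom = loops$chrom, start = loops$a1_start,
                 end = loops$a1_end,
                 name = paste0(loops$loop_id, "_anchor1")),
      data.frame(chrom = loops$chrom, start = loops$a2_start,
                 end = loops$a2_end,
                 name = paste0(loops$loop_id, "_anchor2")))
    covered <- stats::runif(nrow(anchors)) <= config$peak_fraction
    peaks <- anchors[covered, , drop = FALSE]
    if (nrow(peaks)) {
      peaks$start <- pmax(0, peaks$start - 250)
      peaks$end <- peaks$end + 250
      peaks$name <- sub("anchor", "peak", peaks$name)
    }
    rownames(peaks) <- NULL

    qual <- strrep("I", rl)
    list(
      reads = data.frame(id = reads$read_id, seq1 = reads$seq1, qual1 = qual,
                         seq2 = reads$seq2, qual2 = qual,
                         stringsAsFactors = FALSE),
      truth = list(
        loops = loops,
        peaks = peaks,
        reads = reads[, c("read_id", "label", "chrom1", "pos1", "strand1",
                          "len1", "chrom2", "pos2", "strand2", "len2",
                          "duplicate", "duplicate_of")]),
      genome = genome,
      chrom_lens = chrom_lens)
  })
}

#' Write a simulated library to disk
#'
#' Writes `genome.fa`, `chrom.sizes`, `reads_1.fq`, `reads_2.fq`,
#' `truth_loops.bedpe`, `truth_peaks.bed` and `truth_reads.tsv`.
#'
#' @param sim result of [simulate_library()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeLines(paste(names(sim$chrom_lens), sim$chrom_lens, sep = "\t"),
             file.path(dir, "chrom.sizes"))
  write_fastq_pair(sim$reads, file.path(dir, "reads"))
  tl <- sim$truth$loops
  write_bedpe(data.frame(chrom = tl$chrom, start1 = tl$a1_start,
                         end1 = tl$a1_end, start2 = tl$a2_start,
                         end2 = tl$a2_end, pet_count = tl$n_pets,
                         name = tl$loop_id, stringsAsFactors = FALSE),
              file.path(dir, "truth_loops.bedpe"))
  write_bed(sim$truth$peaks, file.path(dir, "truth_peaks.bed"))
  data.table::fwrite(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t")
  invisible(dir)
}

#' Score called loops against simulator truth
#'
#' A truth loop is recovered when a called loop on the same chromosome has
#' both anchor midpoints within `slack` bp of the truth anchor midpoints;
#' matching is greedy one-to-one by distance. Precision on an empty called
#' set is defined as 1.0.
#'
#' @param called loops data.frame (chrom, start1, end1, start2, end2) or a
#'   BEDPE path.
#' @param truth_loops simulator truth loops (as in `sim$truth$loops`).
#' @param slack bp tolerance per anchor midpoint.
#' @return list with `precision`, `recall`, `f1`, `n_called`, `n_truth` and
#'   the match table.
#' @export
score_recovery <- function(called, truth_loops, slack = 500) {
  if (is.character(called)) called <- read_bedpe(called)
  truth <- data.frame(chrom = truth_loops$chrom,
                      start1 = truth_loops$a1_start, end1 = truth_loops$a1_end,
                      start2 = truth_loops$a2_start, end2 = truth_loops$a2_end,
                      stringsAsFactors = FALSE)
  m <- match_loops(called, truth, slack)
  n_called <- nrow(called); n_truth <- nrow(truth)
  precision <- if (n_called == 0) 1.0 else nrow(m) / n_called
  recall <- if (n_truth == 0) 1.0 else nrow(m) / n_truth
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_called = n_called, n_truth = n_truth, matches = m)
}
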