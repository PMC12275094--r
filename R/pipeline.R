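# End-to-end orchestration: linker -> align -> dedup -> classify -> cluster ->
# filter/annotate -> coverage/contacts, with a JSON run manifest.

manifest_entry <- function(stage, counts = list(), outputs = character(0),
                           params = list()) {
  hashes <- if (length(outputs)) {
    as.list(tools::md5sum(outputs[file.exists(outputs)]))
  } else list()
  list(stage = stage, counts = counts, params = params,
       outputs = as.list(outputs), output_md5 = hashes)
}

#' Run the full ChIA-PET pipeline
#'
#' Inputs are either a simulation (`sim` is a [sim_config()]) or real files
#' (`fq1`/`fq2` plus a reference FASTA for the built-in matcher, or `sam` for
#' externally aligned tags). H3K27ac peaks come from `peaks` (path or
#' data.frame); when `NULL` and a simulation is run, the simulator's truth
#' peaks are used. Reruns with an identical configuration are byte-identical.
#'
#' @param out_dir output directory; created if needed.
#' @param params a [pipeline_params()] object.
#' @param sim optional [sim_config()]; when given, the library is simulated.
#' @param fq1,fq2 FASTQ paths (ignored when `sim` is given).
#' @param ref reference FASTA path or named DNAStringSet for the built-in
#'   matcher (ignored when `sam` is given).
#' @param sam optional SAM/BAM of pre-aligned tags.
#' @param peaks H3K27ac peak BED path or data.frame.
#' @param tss optional TSS BED path or data.frame (with gene names) for loop
#'   annotation.
#' @return list with `manifest`, `loops`, `clusters`, `partition`, `recovery`
#'   (when simulated), and the paths of all written artifacts.
#' @export
run_all <- function(out_dir, params = pipeline_params(), sim = NULL,
                    fq1 = NULL, fq2 = NULL, ref = NULL, sam = NULL,
                    peaks = NULL, tss = NULL) {
  # fail fast on missing inputs before any stage runs
  for (p in list(fq1 = fq1, fq2 = fq2, sam = sam)) {
    if (is.character(p) && !file.exists(p)) stopf("input path not found: %s", p)
  }
  if (is.character(peaks) && !file.exists(peaks)) {
    stopf("peaks BED not found: %s", peaks)
  }
  if (is.character(tss) && !file.exists(tss)) stopf("TSS BED not found: %s", tss)
  if (is.null(sim) && is.null(peaks)) stopf("peaks are required when not simulating")
  if (is.null(sim) && is.null(fq1) && is.null(sam)) {
    stopf("either a simulation config, FASTQ input, or SAM input is required")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()

  sim_res <- NULL
  if (!is.null(sim)) {
    sim_res <- simulate_library(sim)
    sim_dir <- file.path(out_dir, "sim")
    write_simulation(sim_res, sim_dir)
    fq1 <- file.path(sim_dir, "reads_1.fq")
    fq2 <- file.path(sim_dir, "reads_2.fq")
    ref <- sim_res$genome
    if (is.null(peaks)) peaks <- sim_res$truth$peaks
    manifest$sim <- manifest_entry(
      "sim", counts = list(n_pairs = nrow(sim_res$reads),
                           n_truth_loops = nrow(sim_res$truth$loops)),
      outputs = file.path(sim_dir, c("genome.fa", "reads_1.fq", "reads_2.fq",
                                     "truth_loops.bedpe", "truth_peaks.bed",
                                     "truth_reads.tsv")),
      params = list(seed = sim$seed))
  }
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (is.character(tss)) tss <- read_bed(tss)

  if (!is.null(sam)) {
    pairs_raw <- read_sam_pairs(sam, params$min_mapq)
    pets_all <- pair_tags(pairs_raw)
    chrom_lens <- NULL
    counts_linker <- c(pairs_read = NA_real_)
    manifest$align <- manifest_entry(
      "align_sam",
      counts = c(list(mapped_pets = nrow(pets_all)),
                 as.list(attr(pairs_raw, "counts"))),
      params = list(min_mapq = params$min_mapq))
  } else {
    pairs <- read_fastq_pairs(fq1, fq2)
    lk <- split_pairs(pairs, params)
    report <- linker_report(lk$counters)
    linker_path <- file.path(out_dir, "linker_report.tsv")
    data.table::fwrite(report, linker_path, sep = "\t")
    tags_prefix <- file.path(out_dir, "tags")
    write_fastq_pair(data.frame(id = lk$tags$read_id, seq1 = lk$tags$tag1,
                                qual1 = lk$tags$qual1, seq2 = lk$tags$tag2,
                                qual2 = lk$tags$qual2,
                                stringsAsFactors = FALSE), tags_prefix)
    manifest$linker <- manifest_entry(
      "linker", counts = as.list(lk$counters),
      outputs = c(linker_path, paste0(tags_prefix, c("_1.fq", "_2.fq"))),
      params = list(max_mismatches = params$max_mismatches,
                    min_overlap = params$min_overlap,
                    min_tag_len = params$min_tag_len))

    index <- reference_index(ref)
    chrom_lens <- index$lengths
    mp <- map_tags(lk$tags, index)
    pets_all <- mp$pets
    manifest$align <- manifest_entry(
      "align_builtin", counts = as.list(mp$counters),
      params = list(k = index$k))
  }

  dd <- dedup_pets(pets_all)
  pets <- classify_pets(dd$pets, params)
  pets_path <- file.path(out_dir, "pets.tsv")
  data.table::fwrite(pets, pets_path, sep = "\t")
  manifest$dedup <- manifest_entry(
    "dedup",
    counts = list(pets_in = nrow(pets_all), nonredundant = nrow(pets),
                  duplicates_removed = dd$n_duplicates),
    outputs = pets_path)

  part <- partition_pets(pets, params)
  summary_path <- file.path(out_dir, "pet_summary.tsv")
  data.table::fwrite(part$summary, summary_path, sep = "\t")
  manifest$classify <- manifest_entry(
    "classify",
    counts = stats::setNames(as.list(part$summary$n), part$summary$category),
    outputs = summary_path,
    params = list(self_ligation_span = params$self_ligation_span))

  clusters <- cluster_genome(part$inter_ligation, params, chrom_lens)
  clusters_path <- file.path(out_dir, "clusters.bedpe")
  singletons_path <- file.path(out_dir, "singletons.bedpe")
  write_bedpe(clusters[!clusters$is_singleton, , drop = FALSE], clusters_path)
  write_bedpe(clusters[clusters$is_singleton, , drop = FALSE], singletons_path)
  manifest$cluster <- manifest_entry(
    "cluster",
    counts = list(n_clusters = sum(!clusters$is_singleton),
                  n_singletons = sum(clusters$is_singleton),
                  total_pets = sum(clusters$pet_count)),
    outputs = c(clusters_path, singletons_path),
    params = list(anchor_extension = params$anchor_extension))

  fl <- filter_loops(clusters, peaks, params)
  loops <- fl$loops
  gene_degree <- NULL
  extra_cols <- character(0)
  if (!is.null(tss)) {
    ann <- annotate_loops(loops, tss, peaks, params)
    loops <- ann$loops
    gene_degree <- ann$gene_degree
    extra_cols <- c("loop_class", "genes1", "genes2")
    data.table::fwrite(gene_degree, file.path(out_dir, "gene_degree.tsv"),
                       sep = "\t")
  }
  loops_path <- file.path(out_dir, "loops.bedpe")
  rej_path <- file.path(out_dir, "loop_rejections.tsv")
  write_bedpe(loops, loops_path, extra = extra_cols)
  data.table::fwrite(fl$rejections, rej_path, sep = "\t")
  manifest$loops <- manifest_entry(
    "loops",
    counts = stats::setNames(as.list(fl$rejections$n),
                             paste0(ifelse(fl$rejections$filter == "kept", "",
                                           "rejected_"),
                                    fl$rejections$filter)),
    outputs = c(loops_path, rej_path),
    params = list(min_pet_count = params$min_pet_count,
                  max_loop_span = params$max_loop_span))

  cov_path <- track_path <- contacts_path <- NULL
  if (!is.null(chrom_lens)) {
    track <- coverage_track(pets, chrom_lens, params$coverage_bin, params)
    cov_path <- file.path(out_dir, "coverage.bedgraph")
    write_bedgraph(track, cov_path)
  }
  cm <- contact_matrix(part$inter_ligation, params$contact_bin)
  contacts_path <- file.path(out_dir, "contacts.tsv")
  write_contacts(cm, contacts_path)
  manifest$coverage_contacts <- manifest_entry(
    "coverage_contacts",
    counts = list(contact_mass = sum(cm$count)),
    outputs = c(cov_path, contacts_path),
    params = list(coverage_bin = params$coverage_bin,
                  contact_bin = params$contact_bin))

  recovery <- NULL
  if (!is.null(sim_res)) {
    recovery <- score_recovery(loops, sim_res$truth$loops,
                               slack = params$anchor_extension)
    manifest$recovery <- manifest_entry(
      "recovery",
      counts = list(precision = recovery$precision, recall = recovery$recall,
                    n_called = recovery$n_called,
                    n_truth = recovery$n_truth))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(manifest = manifest, manifest_path = manifest_path, loops = loops,
       clusters = clusters, partition = part, pets = pets,
       gene_degree = gene_degree, recovery = recovery, sim = sim_res,
       paths = list(loops = loops_path, clusters = clusters_path,
                    singletons = singletons_path, pets = pets_path,
                    coverage = cov_path, contacts = contacts_path))
}

#' Independently validate an emitted loops file
#'
#' Re-checks every loop in a BEDPE file against the three loop filters with a
#' naive implementation that shares no code with the pipeline: PET count >=
#' `min_pet_count`, both anchors overlapping at least one H3K27ac peak by at
#' least 1 bp (plain arithmetic, no interval library), and anchor midpoint
#' distance strictly below `max_loop_span`.
#'
#' @param loops_bedpe path to a loops BEDPE file.
#' @param peaks H3K27ac peaks (path or data.frame).
#' @param params a [pipeline_params()] object.
#' @return list with `pass` (logical) and `violations` (record, name, filter).
#' @export
validate_outputs <- function(loops_bedpe, peaks, params = pipeline_params()) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  violations <- data.frame(record = integer(0), name = character(0),
                           filter = character(0), stringsAsFactors = FALSE)
  if (file.size(loops_bedpe) > 0) {
    df <- utils::read.table(loops_bedpe, sep = "\t", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df))) {
      chrom <- df[i, 1]
      s1 <- df[i, 2]; e1 <- df[i, 3]; s2 <- df[i, 5]; e2 <- df[i, 6]
      score <- df[i, 8]
      fails <- character(0)
      if (score < params$min_pet_count) fails <- c(fails, "pet_count")
      hit <- function(s, e) {
        any(peaks$chrom == chrom & peaks$start < e & s < peaks$end)
      }
      if (!hit(s1, e1) || !hit(s2, e2)) fails <- c(fails, "h3k27ac_anchors")
      if (((s2 + e2) / 2 - (s1 + e1) / 2) >= params$max_loop_span) {
        fails <- c(fails, "anchor_distance")
      }
      if (length(fails)) {
        violations <- rbind(violations, data.frame(
          record = i, name = as.character(df[i, 7]),
          filter = paste(fails, collapse = ","), stringsAsFactors = FALSE))
      }
    }
  }
  list(pass = nrow(violations) == 0, violations = violations)
}
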