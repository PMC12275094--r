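#!/usr/bin/env Rscript
# Cluster inter-ligation PETs by both-anchor overlap after 500-bp extension,
# apply the three loop filters (PET count >= 4, H3K27ac on both anchors,
# anchor distance < 1 Mb), and annotate anchors against a TSS set derived
# from the truth loops. Writes clusters, loops and rejection tables.

suppressMessages(library(chialoopr))

lib <- "results/library"
out <- "results/loops"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- pipeline_params()

pets <- utils::read.table("results/pets/pets.tsv", header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
inter <- pets[pets$category == "inter_ligation", ]
sizes <- utils::read.table(file.path(lib, "chrom.sizes"),
                           col.names = c("chrom", "len"))
chrom_lens <- stats::setNames(sizes$len, sizes$chrom)

clusters <- cluster_genome(inter, params, chrom_lens)
cs <- cluster_summary(clusters)
cat("clusters:", sum(!clusters$is_singleton),
    " singletons:", sum(clusters$is_singleton), "\n")
print(cs$histogram)
write_bedpe(clusters[!clusters$is_singleton, ],
            file.path(out, "clusters.bedpe"))
write_bedpe(clusters[clusters$is_singleton, ],
            file.path(out, "singletons.bedpe"))

peaks <- read_bed(file.path(lib, "truth_peaks.bed"))
fl <- filter_loops(clusters, peaks, params)
print(fl$rejections)
data.table::fwrite(fl$rejections, file.path(out, "loop_rejections.tsv"),
                   sep = "\t")

# a TSS at each truth anchor-1 midpoint stands in for a gene annotation
truth <- read_bedpe(file.path(lib, "truth_loops.bedpe"))
tss <- data.frame(chrom = truth$chrom,
                  start = floor((truth$start1 + truth$end1) / 2),
                  end = floor((truth$start1 + truth$end1) / 2) + 1,
                  name = paste0("gene_", seq_len(nrow(truth))))
ann <- annotate_loops(fl$loops, tss, peaks, params)
write_bedpe(ann$loops, file.path(out, "loops.bedpe"),
            extra = c("loop_class", "genes1", "genes2"))
data.table::fwrite(ann$gene_degree, file.path(out, "gene_degree.tsv"),
                   sep = "\t")
cat("loops called:", nrow(ann$loops), "\n")
print(table(ann$loops$loop_class))
cat("written to", out, "\n")
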