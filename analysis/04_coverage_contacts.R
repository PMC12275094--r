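#!/usr/bin/env Rscript
# Export the RNAPII binding-coverage track (all nonredundant PETs, both
# tags) and the raw binned contact matrix (intra-chromosomal inter-ligation
# PETs, singletons included).

suppressMessages(library(chialoopr))

out <- "results/tracks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- pipeline_params()

pets <- utils::read.table("results/pets/pets.tsv", header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
sizes <- utils::read.table("results/library/chrom.sizes",
                           col.names = c("chrom", "len"))
chrom_lens <- stats::setNames(sizes$len, sizes$chrom)

track <- coverage_track(pets, chrom_lens, params$coverage_bin, params)
write_bedgraph(track, file.path(out, "coverage.bedgraph"))
cat("coverage: ", sum(vapply(track$values, sum, numeric(1))),
    "bin-overlap counts from", 2 * nrow(pets), "tags\n")

inter <- pets[pets$category == "inter_ligation", ]
cm <- contact_matrix(inter, params$contact_bin)
write_contacts(cm, file.path(out, "contacts.tsv"))
cat("contact matrix: ", nrow(cm), "nonzero bins, total mass", sum(cm$count),
    "=", nrow(inter), "inter-ligation PETs\n")
stopifnot(sum(cm$count) == nrow(inter))
cat("written to", out, "\n")
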