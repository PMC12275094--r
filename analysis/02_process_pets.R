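#!/usr/bin/env Rscript
# Stage 1-3 of the pipeline on the simulated library: bridge-linker
# detection and trimming, unique exact mapping of the trimmed tags, PCR
# deduplication, and classification into self-/inter-ligation and trans
# PETs. Writes the nonredundant classified PET table and summary tables.

suppressMessages(library(chialoopr))

lib <- "results/library"
out <- "results/pets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
params <- pipeline_params()

pairs <- read_fastq_pairs(file.path(lib, "reads_1.fq"),
                          file.path(lib, "reads_2.fq"))
lk <- split_pairs(pairs, params)
report <- linker_report(lk$counters)
data.table::fwrite(report, file.path(out, "linker_report.tsv"), sep = "\t")
cat(sprintf("linker rate: %.3f (%d of %d pairs)\n",
            report$value[report$metric == "linker_rate"],
            lk$counters[["pairs_with_linker"]],
            lk$counters[["pairs_read"]]))

index <- reference_index(file.path(lib, "genome.fa"))
mp <- map_tags(lk$tags, index)
cat(sprintf("mapped PETs: %d of %d tag pairs (unmapped %d, multimapped %d)\n",
            mp$counters[["mapped_pets"]], mp$counters[["pairs_in"]],
            mp$counters[["dropped_unmapped"]],
            mp$counters[["dropped_multimapped"]]))

dd <- dedup_pets(mp$pets)
cat(sprintf("nonredundant PETs: %d (%d PCR duplicates removed)\n",
            nrow(dd$pets), dd$n_duplicates))

pets <- classify_pets(dd$pets, params)
part <- partition_pets(pets, params)
data.table::fwrite(pets, file.path(out, "pets.tsv"), sep = "\t")
data.table::fwrite(part$summary, file.path(out, "pet_summary.tsv"), sep = "\t")
print(part$summary)
cat("written to", out, "\n")
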