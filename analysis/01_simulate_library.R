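#!/usr/bin/env Rscript
# Simulate the reference ChIA-PET library used throughout the analysis:
# a 2 x 1-Mb genome with 10 planted loops (6 PETs each) plus realistic
# nuisance reads (40% self-ligation, 5% trans, 5% intra noise, 10% PCR
# duplicates, 0.1% base errors), and write reads + ground truth.

suppressMessages(library(chialoopr))

out_dir <- "results/library"
cfg <- sim_config(seed = 20260925L)
sim <- simulate_library(cfg)
write_simulation(sim, out_dir)

cat("chromosomes:", length(sim$genome), "x",
    unique(Biostrings::width(sim$genome)), "bp\n")
cat("read pairs emitted:", nrow(sim$reads), "\n")
print(table(sub("_[0-9]+$", "", sim$truth$reads$label)))
cat("PCR duplicate pairs:", sum(sim$truth$reads$duplicate), "\n")
cat("truth loops:", nrow(sim$truth$loops),
    " truth peaks:", nrow(sim$truth$peaks), "\n")
cat("written to", out_dir, "\n")
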