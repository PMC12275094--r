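# Small, fast simulation shared by several tests.
cfg_clean <- sim_config(seed = 19, n_loops = 4, pets_per_loop = 6,
                        self_ligation_fraction = 0, trans_noise_fraction = 0,
                        intra_noise_fraction = 0, duplicate_rate = 0,
                        error_rate = 0, chrom_length = 400000L,
                        loop_span = c(20000L, 150000L))

test_that("the simulator is deterministic under a fixed seed", {
  g1 <- simulate_genome(cfg_clean)
  g2 <- simulate_genome(cfg_clean)
  expect_identical(as.character(g1), as.character(g2))
  s1 <- simulate_library(cfg_clean, g1)
  s2 <- simulate_library(cfg_clean, g2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$loops, s2$truth$loops)
})

test_that("the genome has the requested shape and base composition", {
  cfg <- sim_config(seed = 2, n_chroms = 2, chrom_length = 100000L, gc = 0.5,
                    loop_span = c(10000L, 50000L), trans_noise_fraction = 0)
  g <- simulate_genome(cfg)
  expect_equal(length(g), 2)
  expect_equal(unname(Biostrings::width(g)), c(100000L, 100000L))
  freq <- Biostrings::alphabetFrequency(g[[1]])
  gc_obs <- sum(freq[c("C", "G")])
  # binomial 3-sigma bound around 0.5 * n
  expect_lt(abs(gc_obs - 50000), 3 * sqrt(100000 * 0.25))
})

test_that("planted PET counts and labels match the configuration", {
  sim <- simulate_library(cfg_clean)
  tr <- sim$truth$reads
  expect_equal(nrow(tr), 4 * 6)
  expect_equal(unname(table(tr$label)), rep(6L, 4), ignore_attr = TRUE)
  expect_false(any(tr$duplicate))
  expect_equal(anyDuplicated(paste(sim$reads$seq1, sim$reads$seq2)), 0)
  # truth peaks cover every anchor at peak_fraction 1
  expect_equal(nrow(sim$truth$peaks), 2 * nrow(sim$truth$loops))
})

test_that("every loop-read mate carries a linker hit at the planted junction", {
  sim <- simulate_library(cfg_clean)
  linker <- bridge_linker()
  tr <- sim$truth$reads
  for (i in seq_len(nrow(tr))) {
    h1 <- scan_linker(sim$reads$seq1[i], linker)
    # the best hit sits at the junction, or one base 5' of it when the
    # flanking genomic base extends a shifted query variant
    expect_true(!is.null(h1) && h1$offset %in% c(tr$len1[i] - 1, tr$len1[i]))
    h2 <- scan_linker(sim$reads$seq2[i], linker)
    expect_true(!is.null(h2) && h2$offset %in% c(tr$len2[i] - 1, tr$len2[i]))
  }
})

test_that("duplicates are exact byte copies of their source pairs", {
  cfg <- sim_config(seed = 23, n_loops = 3, chrom_length = 400000L,
                    loop_span = c(20000L, 150000L), duplicate_rate = 0.3,
                    trans_noise_fraction = 0.05, error_rate = 0.002)
  sim <- simulate_library(cfg)
  tr <- sim$truth$reads
  dups <- tr[tr$duplicate, ]
  expect_gt(nrow(dups), 0)
  for (i in seq_len(nrow(dups))) {
    src <- which(tr$read_id == dups$duplicate_of[i])
    expect_identical(sim$reads$seq1[src],
                     sim$reads$seq1[tr$read_id == dups$read_id[i]])
    expect_identical(sim$reads$seq2[src],
                     sim$reads$seq2[tr$read_id == dups$read_id[i]])
  }
})

test_that("written simulations round-trip through the package readers", {
  sim <- simulate_library(cfg_clean)
  dir <- tempfile("simout")
  write_simulation(sim, dir)
  pairs <- read_fastq_pairs(file.path(dir, "reads_1.fq"),
                            file.path(dir, "reads_2.fq"))
  expect_equal(nrow(pairs), nrow(sim$reads))
  expect_equal(pairs$seq1, sim$reads$seq1)
  peaks <- read_bed(file.path(dir, "truth_peaks.bed"))
  expect_equal(nrow(peaks), nrow(sim$truth$peaks))
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
})

test_that("recovery scoring implements greedy one-to-one midpoint matching", {
  truth <- data.frame(loop_id = paste0("loop_", 1:10), chrom = "chrS1",
                      a1_start = (1:10) * 20000, a1_end = (1:10) * 20000 + 500,
                      a2_start = (1:10) * 20000 + 50000,
                      a2_end = (1:10) * 20000 + 50500,
                      stringsAsFactors = FALSE)
  called <- data.frame(chrom = "chrS1",
                       start1 = truth$a1_start, end1 = truth$a1_end,
                       start2 = truth$a2_start, end2 = truth$a2_end,
                       stringsAsFactors = FALSE)
  r <- score_recovery(called, truth, slack = 0)
  expect_equal(r$precision, 1.0)
  expect_equal(r$recall, 1.0)

  r0 <- score_recovery(called[0, ], truth, slack = 0)
  expect_equal(r0$precision, 1.0)
  expect_equal(r0$recall, 0)

  # 8 recovered plus 2 spurious calls
  part <- called[1:8, ]
  spurious <- data.frame(chrom = "chrS1", start1 = c(500000, 600000),
                         end1 = c(500500, 600500), start2 = c(700000, 800000),
                         end2 = c(700500, 800500))
  r2 <- score_recovery(rbind(part, spurious), truth, slack = 100)
  expect_equal(r2$precision, 0.8)
  expect_equal(r2$recall, 0.8)
})
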