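linker <- bridge_linker()

test_that("the bridge linker is found where planted", {
  # flank that cannot extend any shifted query
  read <- paste0("TTTTT", linker$forward, strrep("G", 5))
  hit <- scan_linker(read, linker)
  expect_equal(hit$offset, 5)
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$mismatches, 0)

  sub <- mutate_seq(linker$forward, 1)
  hit2 <- scan_linker(paste0("TTTTT", sub, strrep("G", 5)), linker)
  expect_equal(hit2$mismatches, 1)
})

test_that("overlapping queries win ties by the smaller-offset rule", {
  # reverse_rc equals "A" + forward[1:18], so an A immediately 5' of a
  # forward junction produces an exact reverse_rc hit one base earlier.
  read <- paste0("AAAAA", linker$forward, strrep("G", 5))
  hit <- scan_linker(read, linker)
  expect_equal(hit$offset, 4)
  expect_equal(hit$orientation, "reverse_rc")
  expect_equal(hit$mismatches, 0)
})

test_that("reads without a close linker occurrence yield no hit", {
  set.seed(42)
  for (i in 1:20) {
    read <- rand_dna(150)
    oracle <- oracle_scan_linker(read, as.list(linker$queries), 2, 10)
    hit <- scan_linker(read, linker)
    if (is.null(oracle)) expect_null(hit) else expect_false(is.null(hit))
  }
})

test_that("scan agrees with the exhaustive Hamming oracle on planted reads", {
  set.seed(101)
  for (i in 1:200) {
    read <- rand_dna(150)
    if (i %% 2 == 0) {
      q <- sample(linker$queries, 1)
      planted <- mutate_seq(q, sample(0:2, 1))
      off <- sample(0:(150 - nchar(planted)), 1)
      substr(read, off + 1, off + nchar(planted)) <- planted
    }
    oracle <- oracle_scan_linker(read, as.list(linker$queries), 2, 10)
    hit <- scan_linker(read, linker)
    if (is.null(oracle)) {
      expect_null(hit)
    } else {
      expect_equal(hit$offset, oracle$offset)
      expect_equal(hit$orientation, oracle$orientation)
      expect_equal(hit$mismatches, oracle$mismatches)
    }
  }
})

test_that("raising max_mismatches never loses linker hits", {
  set.seed(7)
  reads <- c(replicate(40, rand_dna(150)),
             replicate(10, paste0(rand_dna(40), mutate_seq(linker$forward, 2),
                                  rand_dna(60))))
  n_hits <- vapply(0:4, function(mm) {
    sum(!vapply(reads, function(r) {
      is.null(scan_linker(r, linker, max_mismatches = mm))
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_hits) >= 0))
})

test_that("pairs are split at the first linker junction with tag-length checks", {
  # tags end in T so the flank cannot extend a shifted query variant
  tag40a <- paste0(rand_dna(39), "T"); tag40b <- paste0(rand_dna(39), "T")
  s1 <- paste0(tag40a, linker$forward, rand_dna(60))
  s2 <- paste0(tag40b, revcomp(linker$forward), rand_dna(60))
  sp <- split_pair(s1, s2)
  expect_equal(sp$status, "ok")
  expect_equal(sp$tag1, tag40a)
  expect_equal(sp$tag2, tag40b)

  # linker at offset 10 in mate1 only: 10 < 18 -> short_tag
  short <- split_pair(paste0(strrep("T", 10), linker$forward, rand_dna(50)),
                      rand_dna(100))
  expect_equal(short$status, "short_tag")

  none <- split_pair(rand_dna(100), rand_dna(100))
  expect_equal(none$status, "no_linker")
})

test_that("a one-sided linker pair keeps the whole linker-less mate", {
  tagA <- paste0(rand_dna(49), "T")
  whole <- rand_dna(120)
  sp <- split_pair(paste0(tagA, linker$forward, rand_dna(40)), whole)
  expect_equal(sp$status, "ok")
  expect_equal(sp$tag1, tagA)
  expect_equal(sp$tag2, whole)
})

test_that("library-level splitting counts rejection reasons and is deterministic", {
  set.seed(9)
  ok <- replicate(7, paste0(rand_dna(40), linker$forward, rand_dna(40)))
  no <- replicate(2, rand_dna(100))
  short <- paste0(strrep("T", 5), linker$forward, rand_dna(80))
  pairs <- data.frame(
    id = paste0("r", 1:10),
    seq1 = c(ok, no, short),
    qual1 = strrep("I", 100), seq2 = c(ok, no, short),
    qual2 = strrep("I", 100), stringsAsFactors = FALSE)
  res <- split_pairs(pairs)
  expect_equal(unname(res$counters["pairs_read"]), 10)
  expect_equal(unname(res$counters["kept"]), 7)
  expect_equal(unname(res$counters["rejected_no_linker"]), 2)
  expect_equal(unname(res$counters["rejected_short_tag"]), 1)
  expect_equal(nchar(res$tags$qual1), nchar(res$tags$tag1))

  res2 <- split_pairs(pairs)
  expect_identical(res$tags, res2$tags)

  rep <- linker_report(res$counters)
  expect_equal(rep$value[rep$metric == "linker_rate"], 0.8)

  zero <- linker_report(split_pairs(pairs[0, ])$counters)
  expect_true(all(zero$value == 0))
})
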