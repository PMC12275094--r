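params <- pipeline_params()

test_that("tag intervals extend symmetrically with clipping", {
  e <- extend_interval(1000, 1050, 500)
  expect_equal(c(e$start, e$end), c(500, 1550))
  e2 <- extend_interval(200, 260, 500)
  expect_equal(c(e2$start, e2$end), c(0, 760))
  e3 <- extend_interval(1000, 1050, 0)
  expect_equal(c(e3$start, e3$end), c(1000, 1050))
  e4 <- extend_interval(900, 950, 500, chrom_len = 1200)
  expect_equal(c(e4$start, e4$end), c(400, 1200))
})

# Two PETs with tag intervals [100,150)/[5000,5050) and [700,750)/[5600,5650).
two_pets <- data.frame(
  read_id = c("A", "B"),
  chrom1 = "chrT", pos1 = c(100, 700), strand1 = "+", span1 = 50,
  chrom2 = "chrT", pos2 = c(5000, 5600), strand2 = "+", span2 = 50,
  stringsAsFactors = FALSE)

test_that("PETs overlapping at both extended ends merge into one cluster", {
  cl <- cluster_pets(two_pets, params)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pet_count, 2)
  # anchors are hulls of the UNextended member intervals
  expect_equal(c(cl$start1, cl$end1), c(100, 750))
  expect_equal(c(cl$start2, cl$end2), c(5000, 5650))
  expect_false(cl$is_singleton)
  expect_setequal(cl$member_ids[[1]], c("A", "B"))
})

test_that("left anchors 3 kb apart do not merge under 500-bp extension", {
  apart <- two_pets
  apart$pos1 <- c(100, 3100)
  cl <- cluster_pets(apart, params)
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$is_singleton))
})

test_that("merging is transitive: chains collapse into one cluster", {
  # A-B overlap, B-C overlap, A-C do not overlap directly
  chain <- data.frame(
    read_id = c("A", "B", "C"),
    chrom1 = "chrT", pos1 = c(100, 1000, 1900), strand1 = "+", span1 = 50,
    chrom2 = "chrT", pos2 = c(50000, 50900, 51800), strand2 = "+", span2 = 50,
    stringsAsFactors = FALSE)
  ac_left_gap <- 1900 - (100 + 50)   # 1750 > 2*500 + 50: A,C unlinked
  expect_true(ac_left_gap > 2 * params$anchor_extension + 50)
  cl <- cluster_pets(chain, params)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pet_count, 3)
})

test_that("clustering matches the brute-force both-anchor-overlap oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    pets <- rand_pets(n)
    cl <- cluster_pets(pets, params)
    comp <- oracle_cluster(pets, params$anchor_extension,
                           params$tag_span_default)
    oracle_groups <- split(pets$read_id, comp)
    expect_equal(partition_signature(cl$member_ids),
                 partition_signature(oracle_groups))
    expect_equal(sort(table(comp), decreasing = TRUE),
                 sort(table(rep(seq_len(nrow(cl)), cl$pet_count)),
                      decreasing = TRUE), ignore_attr = TRUE)
  }
})

test_that("pet counts are conserved and output is order-invariant", {
  set.seed(123)
  pets <- rand_pets(80)
  cl <- cluster_pets(pets, params)
  expect_equal(sum(cl$pet_count), nrow(pets))
  perm <- pets[sample(nrow(pets)), ]
  cl2 <- cluster_pets(perm, params)
  expect_equal(partition_signature(cl$member_ids),
               partition_signature(cl2$member_ids))
  expect_equal(cl[, c("start1", "end1", "start2", "end2", "pet_count")],
               cl2[, c("start1", "end1", "start2", "end2", "pet_count")])
})

test_that("increasing the extension never increases the number of clusters", {
  set.seed(55)
  pets <- rand_pets(60)
  n_clusters <- vapply(c(0L, 100L, 500L, 2000L, 5000L), function(ext) {
    nrow(cluster_pets(pets, pipeline_params(anchor_extension = ext)))
  }, numeric(1))
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("mixed chromosomes are rejected but cluster_genome splits them", {
  mixed <- rbind(two_pets,
                 within(two_pets, {chrom1 <- "chrU"; chrom2 <- "chrU"
                                   read_id <- c("C", "D")}))
  expect_error(cluster_pets(mixed, params), "one chromosome")
  cl <- cluster_genome(mixed, params)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$chrom, c("chrT", "chrU"))
  expect_equal(cl$name, c("cluster_1", "cluster_2"))
})

test_that("cluster summaries report the pet-count histogram", {
  set.seed(8)
  pets <- rbind(
    do.call(rbind, lapply(1:5, function(i) {
      p <- rand_pets(1); p$read_id <- paste0("s", i)
      p$pos1 <- i * 20000; p$pos2 <- i * 20000 + 300000 + i * 10000; p
    })),
    data.frame(read_id = paste0("c", 1:4), chrom1 = "chrT",
               pos1 = c(500, 520, 540, 560), strand1 = "+", span1 = 50,
               chrom2 = "chrT", pos2 = c(9500, 9520, 9540, 9560),
               strand2 = "+", span2 = 50, stringsAsFactors = FALSE))
  cs <- cluster_summary(cluster_pets(pets, params))
  expect_equal(cs$histogram,
               data.frame(pet_count = c(1L, 4L), n_clusters = c(5L, 1L)))
  expect_equal(cs$singleton_fraction, 5 / 6)

  empty <- cluster_summary(cluster_pets(two_pets[0, ], params))
  expect_equal(nrow(empty$histogram), 0)
})
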