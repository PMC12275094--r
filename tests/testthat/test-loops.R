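params <- pipeline_params()

make_clusters <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[["chrom"]] %||% "chr1",
               start1 = r[["start1"]], end1 = r[["end1"]],
               start2 = r[["start2"]], end2 = r[["end2"]],
               pet_count = r[["pet_count"]], stringsAsFactors = FALSE)
  }))
  df$is_singleton <- df$pet_count == 1
  df$name <- paste0("cluster_", seq_len(nrow(df)))
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

peaks_all <- data.frame(chrom = "chr1",
                        start = c(50, 4900, 899000),
                        end = c(400, 5400, 900500),
                        stringsAsFactors = FALSE)

test_that("the three loop filters reject and keep clusters as specified", {
  clusters <- make_clusters(
    list(start1 = 100, end1 = 300, start2 = 5000, end2 = 5300, pet_count = 3),
    list(start1 = 100, end1 = 300, start2 = 899100, end2 = 899500,
         pet_count = 4),
    list(start1 = 100, end1 = 300, start2 = 20000, end2 = 20400,
         pet_count = 8))
  out <- filter_loops(clusters, peaks_all, params)
  # count 3 -> filter 1; anchor2 at 20 kb has no peak -> filter 2;
  # count 4 with both peaks and midpoint distance ~899 kb < 1 Mb -> kept
  expect_equal(out$rejections$n[out$rejections$filter == "pet_count"], 1)
  expect_equal(out$rejections$n[out$rejections$filter == "h3k27ac_anchors"], 1)
  expect_equal(out$rejections$n[out$rejections$filter == "kept"], 1)
  expect_equal(out$loops$pet_count, 4)
  expect_lt(out$loops$anchor_distance, params$max_loop_span)
})

test_that("anchor distance uses midpoints against the 1-Mb bound", {
  near <- make_clusters(list(start1 = 0, end1 = 200, start2 = 999000,
                             end2 = 999800, pet_count = 5))
  peaks <- data.frame(chrom = "chr1", start = c(0, 999000),
                      end = c(200, 999800))
  # midpoints 100 and 999400 -> distance 999300 < 1e6: kept
  expect_equal(nrow(filter_loops(near, peaks, params)$loops), 1)
  far <- make_clusters(list(start1 = 0, end1 = 200, start2 = 1000000,
                            end2 = 1000800, pet_count = 5))
  peaks2 <- data.frame(chrom = "chr1", start = c(0, 1000000),
                       end = c(200, 1000800))
  # midpoints 100 and 1000400 -> distance 1000300 >= 1e6: rejected
  expect_equal(nrow(filter_loops(far, peaks2, params)$loops), 0)
})

test_that("rejections plus kept equal the input and filters commute in outcome", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 30
    clusters <- data.frame(
      chrom = "chr1",
      start1 = s1 <- sample.int(500000, n), end1 = s1 + 300,
      start2 = s2 <- s1 + sample(5000:1500000, n), end2 = s2 + 300,
      pet_count = sample(1:8, n, replace = TRUE), stringsAsFactors = FALSE)
    clusters$name <- paste0("c", 1:n)
    peaks <- data.frame(chrom = "chr1",
                        start = ps <- sample.int(2000000, 40),
                        end = ps + 400)
    out <- filter_loops(clusters, peaks, params)
    expect_equal(sum(out$rejections$n), n)
    # order-free evaluation of the same three predicates
    m_count <- clusters$pet_count >= params$min_pet_count
    hit <- function(s, e) vapply(seq_along(s), function(i) {
      any(peaks$start < e[i] & s[i] < peaks$end)
    }, logical(1))
    m_peak <- hit(clusters$start1, clusters$end1) &
      hit(clusters$start2, clusters$end2)
    m_dist <- (clusters$start2 + clusters$end2) / 2 -
      (clusters$start1 + clusters$end1) / 2 < params$max_loop_span
    expect_setequal(out$loops$name, clusters$name[m_count & m_peak & m_dist])
  }
})

test_that("peaks on chromosomes without clusters only warn", {
  clusters <- make_clusters(list(start1 = 100, end1 = 300, start2 = 20000,
                                 end2 = 20300, pet_count = 5))
  peaks <- rbind(peaks_all[0, ],
                 data.frame(chrom = c("chr1", "chr9"),
                            start = c(100, 5), end = c(20300, 50)))
  expect_warning(filter_loops(clusters, peaks, params), "chr9")
})

test_that("anchors are classed promoter/enhancer/other with gene lists", {
  # one promoter hub connected to three distal enhancers, plus an
  # enhancer-enhancer loop and an unannotated anchor
  loops <- make_clusters(
    list(start1 = 10000, end1 = 10400, start2 = 50000, end2 = 50400,
         pet_count = 5),
    list(start1 = 10000, end1 = 10400, start2 = 80000, end2 = 80400,
         pet_count = 5),
    list(start1 = 10000, end1 = 10400, start2 = 120000, end2 = 120400,
         pet_count = 5),
    list(start1 = 50000, end1 = 50400, start2 = 80000, end2 = 80400,
         pet_count = 4),
    list(start1 = 200000, end1 = 200400, start2 = 300000, end2 = 300400,
         pet_count = 4))
  loops$anchor_distance <- 1
  peaks <- data.frame(chrom = "chr1",
                      start = c(9900, 49900, 79900, 119900, 299900),
                      end = c(10500, 50500, 80500, 120500, 300500))
  tss <- data.frame(chrom = "chr1", start = 10200, end = 10201,
                    name = "geneX", stringsAsFactors = FALSE)
  ann <- annotate_loops(loops, tss, peaks, params)
  expect_equal(ann$loops$anchor1_class,
               c("promoter", "promoter", "promoter", "enhancer", "other"))
  expect_equal(ann$loops$anchor2_class,
               c("enhancer", "enhancer", "enhancer", "enhancer", "enhancer"))
  expect_equal(ann$loops$loop_class[1], "promoter-enhancer")
  expect_equal(ann$loops$genes1[1:3], rep("geneX", 3))
  # the geneX promoter reaches three distinct distal anchors
  expect_equal(ann$gene_degree$degree[ann$gene_degree$gene == "geneX"], 3L)

  expect_error(annotate_loops(loops, tss[, 1:3], peaks, params), "name")
})

test_that("condition comparison matches loops within anchor slack", {
  a <- make_clusters(
    list(start1 = 1000, end1 = 1400, start2 = 50000, end2 = 50400,
         pet_count = 5),
    list(start1 = 90000, end1 = 90400, start2 = 220000, end2 = 220400,
         pet_count = 6))
  expect_equal(compare_conditions(a, a, slack = 0)$shared, 2)

  b <- a; b$chrom <- "chr2"
  expect_equal(compare_conditions(a, b, slack = 1000)$shared, 0)

  shifted <- a
  shifted$start1 <- a$start1 + 400; shifted$end1 <- a$end1 + 400
  shifted$start2 <- a$start2 + 400; shifted$end2 <- a$end2 + 400
  cmp <- compare_conditions(a, shifted, slack = 500)
  expect_equal(cmp$shared, 2)
  expect_equal(cmp$a_only, 0)
  expect_equal(compare_conditions(a, shifted, slack = 100)$shared, 0)
})
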