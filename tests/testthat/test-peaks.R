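test_that("interval merging covers unions, including abutting intervals", {
  pk <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(1000, 1500),
                       peak_id = c("a", "b"))
  m <- merge_intervals(pk)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 1500))
  expect_equal(m$constituents[[1]], c("a", "b"))

  ab <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                       peak_id = c("a", "b"))
  m2 <- merge_intervals(ab)
  expect_equal(nrow(m2), 1)
  expect_equal(bf_union_length(ab$start, ab$end), sum(m2$end - m2$start))

  disj <- tibble::tibble(chrom = "chr1", start = c(500, 0), end = c(600, 100),
                         peak_id = c("b", "a"))
  m3 <- merge_intervals(disj)
  expect_equal(m3$start, c(0, 500)) # order normalized
})

test_that("merge agrees with brute force and is idempotent on random fixtures", {
  withr::with_seed(101, {
    for (i in 1:200) {
      pk <- random_peaks(sample(2:15, 1))
      m <- merge_intervals(pk)
      bf <- bf_merge(pk$start, pk$end)
      expect_equal(m$start, bf$start)
      expect_equal(m$end, bf$end)
      expect_equal(sum(m$end - m$start), bf_union_length(pk$start, pk$end))
      m2 <- merge_intervals(dplyr::select(m, -"n_constituents", -"constituents"))
      expect_equal(m2$start, m$start)
      expect_equal(m2$end, m$end)
    }
  })
})

test_that("summit extension clamps, merges and validates", {
  genome <- genome_spec(c(chr1 = 1e5))
  pk <- tibble::tibble(chrom = "chr1", start = c(4900, 400, 6300),
                       end = c(5100, 600, 6700),
                       peak_id = c("a", "b", "c"),
                       summit = c(5000, 500, 6500))
  ext <- extend_summits(pk, genome)
  expect_equal(ext$start, c(0, 4000))
  expect_equal(ext$end, c(1500, 7500)) # summits 5000/6500 merge after +/-1 kb
  pk$summit[1] <- NA
  expect_error(extend_summits(pk, genome), "summit")
})

test_that("blacklist subtraction removes any-overlap peaks, half-open", {
  bl <- tibble::tibble(chrom = "chr1", start = 150, end = 160, peak_id = "bl")
  pk <- tibble::tibble(chrom = "chr1", start = c(100, 200), end = c(200, 300),
                       peak_id = c("a", "b"))
  out <- subtract_blacklist(pk, bl)
  expect_equal(out$peak_id, "b")
  # end == blacklist start: no overlap under half-open coordinates
  bl2 <- tibble::tibble(chrom = "chr1", start = 200, end = 300, peak_id = "bl")
  expect_equal(subtract_blacklist(pk[1, ], bl2)$peak_id, "a")
  expect_identical(subtract_blacklist(pk, pk[0, ]), pk)
  expect_lte(nrow(subtract_blacklist(pk, bl)), nrow(pk))
})

test_that("nearest-TSS annotation matches a brute-force scan with tie rule", {
  genes <- tibble::tibble(gene_id = c("gB", "gA", "gC"),
                          chrom = "chr1", tss = c(10000, 12500, 50000),
                          strand = c("+", "+", "-"))
  pk <- tibble::tibble(chrom = "chr1", start = c(10400, 49000), end = c(10600, 51000),
                       peak_id = c("p1", "p2"))
  ann <- annotate_nearest_tss(pk, genes)
  expect_equal(ann$gene_id, c("gB", "gC"))
  expect_equal(ann$distance, c(500, 0))
  expect_equal(ann$promoter_flag, c(TRUE, TRUE))
  # distal peak, strand-aware sign: center 40000 nearest gC (TSS 50000, minus
  # strand) -> downstream of the TSS means centre below it
  pk2 <- tibble::tibble(chrom = "chr1", start = 39900, end = 40100, peak_id = "p3")
  ann2 <- annotate_nearest_tss(pk2, genes)
  expect_equal(ann2$gene_id, "gC")
  expect_equal(ann2$distance, 10000) # (40000 - 50000) * -1
  expect_false(ann2$promoter_flag)
  # equidistant: smaller gene_id wins
  mid <- tibble::tibble(chrom = "chr1", start = 11150, end = 11350, peak_id = "pm")
  expect_equal(annotate_nearest_tss(mid, genes)$gene_id, "gA")

  withr::with_seed(77, {
    g <- tibble::tibble(gene_id = sprintf("g%03d", 1:30), chrom = "chr1",
                        tss = sample.int(5e4, 30), strand = "+")
    p <- random_peaks(40, max_pos = 5e4)
    ann3 <- annotate_nearest_tss(p, g)
    for (i in seq_len(nrow(p))) {
      ctr <- (p$start[i] + p$end[i]) / 2
      j <- bf_nearest(ctr, g$tss, g$gene_id)
      expect_equal(ann3$gene_id[i], g$gene_id[j])
      expect_equal(abs(ann3$distance[i]), abs(ctr - g$tss[j]))
    }
  })
})

test_that("center-window pairing is one-to-one, greedy and boundary-inclusive", {
  mk <- function(centers, prefix) {
    tibble::tibble(chrom = "chr1", start = centers - 50, end = centers + 50,
                   peak_id = paste0(prefix, seq_along(centers)))
  }
  expect_equal(nrow(pair_by_center_window(mk(1000, "a"), mk(1000, "b"))), 1)
  expect_equal(nrow(pair_by_center_window(mk(1000, "a"), mk(1501, "b"))), 0)
  expect_equal(nrow(pair_by_center_window(mk(1000, "a"), mk(1500, "b"))), 1)
  # two candidates: nearer b wins
  p <- pair_by_center_window(mk(1000, "a"), mk(c(1400, 1100), "b"))
  expect_equal(p$b_id, "b2")
  # one-to-one: two a's, one b -> nearest a gets it
  p2 <- pair_by_center_window(mk(c(1000, 1200), "a"), mk(1150, "b"))
  expect_equal(nrow(p2), 1)
  expect_equal(p2$a_id, "a2")
})

test_that("BED and narrowPeak round-trips are byte-stable", {
  pk <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0L, 250L),
                       end = c(100L, 900L), peak_id = c("p1", "p2"),
                       score = c(5, 7), strand = c("+", "."),
                       signalValue = c(1.5, 2), pValue = c(-1, -1),
                       qValue = c(-1, -1), summit = c(50, 600))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_narrowpeak(pk, f1)
  rt <- read_narrowpeak(f1)
  expect_equal(rt$start, pk$start)
  expect_equal(rt$summit, pk$summit)
  write_narrowpeak(rt, f2)
  expect_identical(readLines(f1), readLines(f2))

  b1 <- withr::local_tempfile(); b2 <- withr::local_tempfile()
  write_bed(pk, b1)
  write_bed(read_bed(b1), b2)
  expect_identical(readLines(b1), readLines(b2))
})
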