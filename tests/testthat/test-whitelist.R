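pb_df <- function(barcode, min_q = 30L, umi = "ACGTACGTACGT") {
  n <- length(barcode)
  S4Vectors::DataFrame(read_id = sprintf("r%d", seq_len(n)),
                       barcode = barcode,
                       barcode_qual = rep(strrep("I", 16), n),
                       min_q = rep(as.integer(min_q), length.out = n),
                       umi = rep(umi, length.out = n),
                       strand = rep("forward", n))
}

test_that("minQ filtering keeps records at or above the threshold", {
  pbs <- pb_df(c("A", "B", "C"), min_q = c(30L, 14L, 15L))
  expect_equal(filterHighQuality(pbs)$barcode, c("A", "C"))
  # threshold 0 is the identity filter
  expect_equal(nrow(filterHighQuality(pbs, 0L)), 3L)
})

test_that("known-barcode filtering drops non-members and passes through on NULL", {
  pbs <- pb_df(c("AAAA", "CCCC", "AAAA"))
  expect_equal(filterKnownBarcodes(pbs, c("AAAA", "GGGG"))$barcode,
               c("AAAA", "AAAA"))
  expect_identical(filterKnownBarcodes(pbs, NULL), pbs)
  expect_warning(out <- filterKnownBarcodes(pbs, character()), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("barcode counting is exact and conserves record totals", {
  tab <- countBarcodes(pb_df(c("X", "X", "Y")))
  expect_equal(counts(tab), c(X = 2L, Y = 1L))
  expect_equal(tab@total, 3L)

  empty <- countBarcodes(pb_df(character()))
  expect_equal(length(empty), 0L)
  expect_equal(empty@total, 0L)

  singles <- countBarcodes(pb_df(c("A", "B", "C", "D", "E")))
  expect_true(all(counts(singles) == 1L))
  expect_equal(sum(counts(singles)), singles@total)
})

test_that("count tables rank descending with lexicographic tie-breaking", {
  tab <- BarcodeCountTable(c("TTTT", "AAAA", "CCCC", "GGGG"),
                           c(5L, 5L, 9L, 5L))
  expect_equal(barcodes(tab), c("CCCC", "AAAA", "GGGG", "TTTT"))
})

test_that("the quantile threshold implements T = 0.05 * count at rank ceil(0.95N)", {
  set.seed(31)
  tab <- BarcodeCountTable(
    c(sprintf("CELL%04d", 1:1000), sprintf("NOIS%04d", 1:5000)),
    c(rep(100L, 1000), sample(1:4, 5000, replace = TRUE)))
  expect_equal(quantileThreshold(tab, 500), 5.0)       # r=475, c=100
  expect_equal(quantileThreshold(tab, 1000), 5.0)      # r=950 still in cells

  # all counts equal k: T = 0.05k and every barcode passes
  flat <- BarcodeCountTable(sprintf("BC%03d", 1:200), rep(7L, 200))
  expect_equal(quantileThreshold(flat, 100), 0.35)
  expect_equal(length(buildWhitelist(flat, 100)), 200L)

  # rank clamps to the table size with a warning
  small <- BarcodeCountTable(sprintf("BC%02d", 1:10), c(10:1))
  expect_warning(t10 <- quantileThreshold(small, 500), "clamp")
  expect_equal(t10, 0.05 * 1)

  expect_error(quantileThreshold(countBarcodes(pb_df(character()))), "empty")
  expect_error(quantileThreshold(small, 0), "expected_cells")
})

test_that("whitelists use strict count > T and respect the mode", {
  set.seed(32)
  tab <- BarcodeCountTable(
    c(sprintf("CELL%04d", 1:1000), sprintf("NOIS%04d", 1:5000)),
    c(rep(100L, 1000), sample(1:4, 5000, replace = TRUE)))
  wl <- buildWhitelist(tab, 500)
  expect_equal(threshold(wl), 5.0)
  expect_equal(sort(barcodes(wl)), sprintf("CELL%04d", 1:1000))

  hs <- buildWhitelist(tab, 500, mode = "high_sensitivity")
  expect_equal(threshold(hs), 0.5)
  expect_equal(length(hs), 6000L)  # every count >= 1 passes

  tiny <- BarcodeCountTable("AAAACCCCGGGGTTTT", 10L)
  wl1 <- buildWhitelist(tiny, 1)
  expect_equal(threshold(wl1), 0.5)
  expect_equal(barcodes(wl1), "AAAACCCCGGGGTTTT")
})

test_that("high-sensitivity whitelists always contain the default whitelist", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    tab <- BarcodeCountTable(
      vapply(seq_len(n), function(i) rand_dna(16), ""),
      sample(1:500, n, replace = TRUE))
    N <- sample(c(5, 50, 500), 1)
    dflt <- suppressWarnings(buildWhitelist(tab, N))
    hs <- suppressWarnings(buildWhitelist(tab, N, mode = "high_sensitivity"))
    expect_true(all(barcodes(dflt) %in% barcodes(hs)))
    # lowering the threshold never shrinks the whitelist
    expect_true(all(tab@barcode[tab@count > threshold(dflt)] %in%
                      tab@barcode[tab@count > threshold(dflt) / 2]))
  }
})

test_that("whitelist size is stable in N when counts separate cleanly", {
  # a bimodal table: the 0.05c threshold lands in the count gap for any N
  # whose rank stays within (or clamps to) the well-supported block
  tab <- BarcodeCountTable(sprintf("CELL%04d", 1:1000), rep(100L, 1000))
  sizes <- vapply(c(100, 250, 500, 1000, 1500), function(N)
    length(suppressWarnings(buildWhitelist(tab, N))), numeric(1))
  expect_true(all(sizes == 1000))
})

test_that("end-to-end recovery at realistic depth and error is clean", {
  # 100 cells at 60x, 5% error, no ambient background; membership filtering
  # against the simulated barcode universe as in the standard workflow
  sim <- simulateDataset(simConfig(n_cells = 100, reads_per_cell = 60,
                                   n_background = 0, seed = 60))
  pbs <- extractPutativeBarcodes(sim$reads)
  tab <- countBarcodes(filterHighQuality(filterKnownBarcodes(pbs,
                                                             sim$universe)))
  wl <- buildWhitelist(tab, 100)
  truth <- sim$truth_whitelist
  # nothing but true cells is ever called
  expect_equal(mean(barcodes(wl) %in% truth), 1)
  # every cell observed in the high-quality stream is called; a cell can
  # only be missed if its barcode context mimics the adaptor so well that
  # the exactly-one-adaptor rule discards its reads systematically
  expect_setequal(barcodes(wl), barcodes(tab))
  expect_gte(mean(truth %in% barcodes(wl)), 0.99)
})

test_that("edit distance matches a full DP oracle", {
  expect_equal(editDistance("AAAA", "AAAA"), 0L)
  expect_equal(editDistance("AAAA", "AATA"), 1L)
  expect_equal(editDistance("kitten", "sitting"), 3L)
  expect_equal(lev_dp("kitten", "sitting"), 3L)
  set.seed(34)
  for (i in 1:200) {
    a <- rand_dna(sample(0:20, 1))
    b <- rand_dna(sample(0:20, 1))
    expect_equal(editDistance(a, b), lev_dp(a, b))
  }
})

test_that("background barcodes sit strictly beyond the edit-distance ring", {
  set.seed(35)
  tab <- BarcodeCountTable(
    vapply(1:300, function(i) rand_dna(16), ""),
    sample(1:50, 300, replace = TRUE))
  wl <- buildWhitelist(tab, 20)
  bg <- backgroundBarcodes(tab, wl, n = 60, seed = 99)
  expect_equal(length(bg), 60L)
  expect_false(anyDuplicated(bg) > 0)
  # postcondition replay with the independent DP oracle
  for (b in bg[1:15]) {
    dmin <- min(vapply(barcodes(wl), function(w) lev_dp(b, w), numeric(1)))
    expect_gt(dmin, 4)
  }
  expect_true(all(minEditDistance(bg, barcodes(wl)) > 4))

  # determinism under a fixed seed
  expect_identical(bg, backgroundBarcodes(tab, wl, n = 60, seed = 99))

  # empty whitelist: the constraint is vacuous
  none <- new("BarcodeWhitelist", barcodes = character(), threshold = 1,
              expected_cells = 1L, mode = "default")
  expect_equal(length(backgroundBarcodes(tab, none, n = 25, seed = 1)), 25L)
  expect_error(backgroundBarcodes(tab, wl, n = 0), "positive")
})

test_that("knee data lists every entry with its rank", {
  tab <- BarcodeCountTable(c("AA", "CC", "GG"), c(3L, 9L, 1L))
  kd <- kneeData(tab)
  expect_equal(kd$rank, 1:3)
  expect_equal(kd$barcode, c("CC", "AA", "GG"))
  expect_equal(kd$count, c(9L, 3L, 1L))
})

test_that("whitelist files are one barcode per line with optional suffix", {
  wl <- new("BarcodeWhitelist", barcodes = c("AAAA", "CCCC"), threshold = 1,
            expected_cells = 2L, mode = "default")
  f <- withr::local_tempfile()
  writeWhitelist(wl, f)
  expect_equal(readLines(f), c("AAAA", "CCCC"))
  writeWhitelist(wl, f, cellranger_suffix = TRUE)
  expect_equal(readLines(f), c("AAAA-1", "CCCC-1"))
})
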