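test_that("an exact adaptor copy is found once, at its end position", {
  read <- paste0(strrep("A", 50), "CTTCCGATCT", strrep("G", 40))
  hits <- findAdaptorHits(read)[[1]]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits[1, "end_pos"], c(end_pos = 60L))
  expect_equal(hits[1, "edit_dist"], c(edit_dist = 0L))
})

test_that("a mutated adaptor copy is found at its true edit distance", {
  read <- paste0(strrep("A", 50), "CTTCCGATAT", strrep("G", 40))
  hits <- findAdaptorHits(read)[[1]]
  expect_equal(nrow(hits), 1L)
  expect_equal(unname(hits[1, "edit_dist"]), 1L)
  # agrees with the exhaustive substring oracle
  expect_equal(unname(hits[1, "edit_dist"]),
               semiglobal_min_oracle(substr(read, 1, 200), "CTTCCGATCT", 2))
})

test_that("a homopolymer read has no adaptor hit", {
  expect_equal(nrow(findAdaptorHits(strrep("A", 300))[[1]]), 0L)
  expect_gt(semiglobal_min_oracle(strrep("A", 200), "CTTCCGATCT", 2), 2)
})

test_that("N in the read never matches the adaptor", {
  mk <- function(core) paste0(strrep("G", 30), core, strrep("G", 30))
  expect_equal(nrow(findAdaptorHits(mk("CTTCCGATCT"))[[1]]), 1L)
  two_n <- findAdaptorHits(mk("CTNCCGATNT"))[[1]]
  expect_equal(unname(two_n[1, "edit_dist"]), 2L)
  expect_equal(nrow(findAdaptorHits(mk("CTNCNGATNT"))[[1]]), 0L)
})

test_that("search is confined to the leading window", {
  read <- paste0(strrep("G", 250), "CTTCCGATCT", strrep("G", 40))
  expect_equal(nrow(findAdaptorHits(read)[[1]]), 0L)
  expect_equal(nrow(findAdaptorHits(read, search_window = 300L)[[1]]), 1L)
})

test_that("distant adaptor copies stay distinct, nearby ones collapse", {
  read <- paste0(strrep("G", 20), "CTTCCGATCT", strrep("G", 30),
                 "CTTCCGATCT", strrep("G", 30))
  hits <- findAdaptorHits(read)[[1]]
  expect_equal(nrow(hits), 2L)
  expect_equal(unname(hits[, "end_pos"]), c(30L, 70L))
})

test_that("adaptor scan agrees with the exhaustive DP oracle on random reads", {
  set.seed(21)
  adaptor <- "CTTCCGATCT"
  for (i in 1:200) {
    len <- sample(0:300, 1)
    read <- rand_dna(len, alphabet = c("A", "C", "G", "T", "N"))
    # plant a mutated copy in half the cases to exercise the hit path
    if (len >= 60 && i %% 2 == 0) {
      copy <- adaptor
      k <- sample(0:2, 1)
      if (k > 0) {
        at <- sample(10, k)
        substring(copy, at, at) <- strsplit(rand_dna(k), "")[[1]]
      }
      at <- sample(len - 40, 1)
      read <- paste0(substr(read, 1, at), copy,
                     substr(read, at + 11, len))
    }
    window <- substr(read, 1, 200)
    hits <- findAdaptorHits(read)[[1]]
    oracle <- semiglobal_min_oracle(window, adaptor, 2)
    if (oracle <= 2) {
      expect_gt(nrow(hits), 0)
      expect_equal(min(hits[, "edit_dist"]), oracle)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
})

test_that("polyT confirmation respects the downstream window", {
  ep <- 60L
  mk <- function(at, run = "TTTT", len = 160L) {
    s <- strrep("G", len)
    substring(s, ep + at + 1L, ep + at + nchar(run)) <- run
    s
  }
  expect_true(confirmPolyT(mk(30), ep))    # inside [20, 50)
  expect_false(confirmPolyT(mk(10), ep))   # upstream of the window
  expect_false(confirmPolyT(mk(55), ep))   # downstream of the window
  expect_true(confirmPolyT(mk(20), ep))    # first admissible offset
  expect_false(confirmPolyT(mk(47), ep))   # run would poke past the window
  expect_true(confirmPolyT(mk(46), ep))    # last fully-contained start
  # read truncated before a full run can fit
  short <- paste0(strrep("G", ep + 20L), "TT")
  expect_false(confirmPolyT(short, ep))
})

test_that("a clean read yields its putative barcode, qualities and UMI", {
  bc <- "AAACCCAAGAAACACT"
  r <- make_read(bc)
  reads <- reads_df(r)
  # give the barcode bases a distinctive quality profile
  q <- phredToInt(reads$qual[1])
  q[(r$bc_at + 1):(r$bc_at + 16)] <- c(25L, 31:45)
  reads$qual[1] <- intToPhred(q)
  pbs <- extractPutativeBarcodes(reads)
  expect_equal(nrow(pbs), 1L)
  expect_equal(pbs$barcode, bc)
  expect_equal(pbs$umi, "ACGTACGTACGT")
  expect_equal(pbs$strand, "forward")
  expect_equal(phredToInt(pbs$barcode_qual), c(25L, 31:45))
  expect_equal(pbs$min_q, 25L)
})

test_that("reads failing the exactly-one-valid-adaptor rule are rejected", {
  bc <- "AAACCCAAGAAACACT"
  good <- make_read(bc)
  # valid adaptor+polyT structure on both strands
  both <- list(seq = paste0(good$seq, revComp(good$seq)), qual = NULL)
  both$qual <- strrep("I", nchar(both$seq))
  # adaptor but no polyT anywhere downstream
  nopt <- make_read(bc, polyt = strrep("G", 15))
  pbs <- extractPutativeBarcodes(reads_df(good, both, nopt))
  expect_equal(pbs$read_id, "r1")
  tally <- S4Vectors::metadata(pbs)$tally
  expect_equal(unname(tally["multiple_adaptors"]), 1L)
  expect_equal(unname(tally["no_polyt"]), 1L)
  expect_equal(unname(tally["putative"]), 1L)
  rejects <- S4Vectors::metadata(pbs)$rejects
  expect_equal(rejects$reason[rejects$read_id == "r2"], "multiple_adaptors")
  expect_equal(rejects$reason[rejects$read_id == "r3"], "no_polyt")
})

test_that("a validated adaptor with <16 bases left gives no barcode", {
  # the default polyT geometry guarantees >=24 bases after a valid adaptor,
  # so exercise the guard with a tighter custom polyT window
  params <- locatorParams(polyt_start = 2L, polyt_end = 12L)
  short <- list(seq = paste0(strrep("G", 20), "CTTCCGATCT", "AATTTT"),
                qual = strrep("I", 36))
  pbs <- extractPutativeBarcodes(reads_df(short), params)
  expect_equal(nrow(pbs), 0L)
  tally <- S4Vectors::metadata(pbs)$tally
  expect_equal(unname(tally["too_short"]), 1L)
  expect_equal(S4Vectors::metadata(pbs)$rejects$reason, "too_short")
})

test_that("extraction is symmetric under reverse complementation", {
  set.seed(23)
  for (i in 1:20) {
    bc <- rand_dna(16)
    r <- make_read(bc, umi = rand_dna(12))
    reads <- reads_df(r)
    reads$qual[1] <- intToPhred(sample(10:40, nchar(r$seq), replace = TRUE))
    fwd <- extractPutativeBarcodes(reads)
    rcr <- reads
    rcr$seq[1] <- revComp(reads$seq[1])
    rcr$qual[1] <- intToPhred(rev(phredToInt(reads$qual[1])))
    rev_ <- extractPutativeBarcodes(rcr)
    expect_equal(nrow(fwd), nrow(rev_))
    if (nrow(fwd) == 1L && nrow(rev_) == 1L) {
      expect_equal(rev_$barcode, fwd$barcode)
      expect_equal(rev_$umi, fwd$umi)
      expect_equal(rev_$barcode_qual, fwd$barcode_qual)
      expect_equal(rev_$strand, "reverse")
      expect_equal(fwd$strand, "forward")
    }
  }
})
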