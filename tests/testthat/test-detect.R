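test_that("flank extension does plain clamped arithmetic and offsets map back", {
  set.seed(11)
  genome <- c(chr1 = rand_seq(1000))
  p <- detect_params()
  fl <- extend_flanks(genome, "chr1", 100L, 200L, p)
  expect_equal(fl$left_offset, 70L)
  expect_equal(nchar(fl$left), 60L)
  expect_equal(fl$right_offset, 170L)
  expect_equal(nchar(fl$right), 60L)
  # offsets recover the reference base at any flank position
  for (k in c(0L, 13L, 59L)) {
    expect_equal(substr(fl$left, k + 1L, k + 1L),
                 substr(genome[["chr1"]], fl$left_offset + k + 1L,
                        fl$left_offset + k + 1L))
  }
  # clamped at the chromosome start
  fl2 <- extend_flanks(genome, "chr1", 5L, 200L, p)
  expect_equal(fl2$left_offset, 0L)
  expect_equal(nchar(fl2$left), 35L)
  expect_error(extend_flanks(genome, "chrX", 0L, 10L, p), "unknown chromosome")
})

test_that("a planted unique duplication is found exactly; short or absent ones are not", {
  p <- detect_params()
  pad_l <- strrep("CT", 11)            # CT pad and GA pad share no >=7-mer
  pad_r <- strrep("GA", 11)
  hit <- find_tsd(paste0(pad_l, "GATTACAG"), paste0("GATTACAG", pad_r), p)
  expect_equal(hit$length, 8L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$score, 8L)
  expect_equal(hit$seq_left, "GATTACAG")
  expect_equal(hit$seq_right, "GATTACAG")
  expect_equal(hit$left_start, 22L)
  expect_equal(hit$right_start, 0L)
  # no common >=7-mer at all
  expect_null(find_tsd(paste0(pad_l, pad_l), paste0(pad_r, pad_r), p))
  # an exact 6-mer duplication is below the length floor
  expect_null(find_tsd(paste0(pad_l, "GATTAC"), paste0("GATTAC", pad_r), p))
})

test_that("find_tsd equals the brute-force substring-pair oracle", {
  set.seed(101)
  p <- detect_params()
  for (i in 1:150) {
    n <- sample(10:60, 1)
    m <- sample(10:60, 1)
    left <- rand_seq(n)
    right <- rand_seq(m)
    # half the cases get a planted duplication so hits are common
    if (i %% 2 == 0) {
      t <- rand_seq(sample(7:12, 1))
      a <- sample.int(max(n - nchar(t), 1), 1)
      b <- sample.int(max(m - nchar(t), 1), 1)
      substr(left, a, a + nchar(t) - 1L) <- t
      substr(right, b, b + nchar(t) - 1L) <- t
    }
    anchored <- i %% 3 == 0
    le <- if (anchored) sample.int(n, 1) else NULL
    re <- if (anchored) sample.int(m, 1) - 1L else NULL
    got <- find_tsd(left, right, p, left_edge = le, right_edge = re)
    want <- oracle_find_tsd(left, right, p, left_edge = le, right_edge = re)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[c("left_start", "left_end", "right_start", "right_end",
                         "length", "matches", "mismatches", "score")],
                   want[c("left_start", "left_end", "right_start", "right_end",
                          "length", "matches", "mismatches", "score")],
                   info = paste("case", i))
    }
  }
})

test_that("poly(A) runs are found with interruption and anchoring rules", {
  p <- detect_params()
  hit <- find_polya(paste0(strrep("G", 10), "AAAAAAAA"), p)
  expect_equal(hit[c("length", "a_count", "interruptions", "score")],
               list(length = 8L, a_count = 8L, interruptions = 0L, score = 8L))
  # four As are below the floor
  expect_null(find_polya(paste0(strrep("G", 10), "AAAA"), p))
  # one internal interruption is tolerated and scored
  hit2 <- find_polya(paste0(strrep("C", 5), "AAAAGAAA"), p)
  expect_equal(hit2[c("length", "a_count", "interruptions", "score")],
               list(length = 8L, a_count = 7L, interruptions = 1L, score = 6L))
  expect_equal(hit2$seq, "AAAAGAAA")
  # the run may sit up to polya_max_gap bases before the TSD edge ...
  hit3 <- find_polya(paste0(strrep("C", 5), "AAAAAAA", "GGG"), p)
  expect_equal(hit3$length, 7L)
  # ... but no further
  expect_null(find_polya(paste0(strrep("C", 5), "AAAAAAA", "GGGGGG"), p))
  # terminal positions must be A: a trailing G cannot anchor a run end
  expect_null(find_polya("GGGGGAGAGAG", p))
})

test_that("candidate scoring is additive, unit-per-base and monotone", {
  tsd <- list(matches = 7L, mismatches = 0L, indels = 0L)
  pa <- list(a_count = 5L, interruptions = 0L)
  sc <- score_candidate(tsd, pa)
  expect_equal(sc$total_score, 12)        # minimal passing candidate
  sc2 <- score_candidate(list(matches = 15L, mismatches = 0L, indels = 0L),
                         list(a_count = 10L, interruptions = 0L))
  expect_equal(sc2$total_score, 25)       # inside the typical 20-30 envelope
  # one more A never decreases the total
  sc3 <- score_candidate(tsd, list(a_count = 6L, interruptions = 0L))
  expect_gte(sc3$total_score, sc$total_score)
  # mismatches and interruptions never increase it
  sc4 <- score_candidate(list(matches = 6L, mismatches = 1L, indels = 0L), pa)
  expect_lte(sc4$total_score, sc$total_score)
})

test_that("a gap-enclosed fill with planted TSD pair and tail is called exactly", {
  set.seed(21)
  fx <- plant_one(tsd = "GATTACAG", polya_len = 9L, strand = "+")
  cand <- detect_candidates(fx$net, fx$genome, prefix = "hsa")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$id, "hsa-retrotransposon-1")
  expect_equal(cand$strand, "+")
  expect_equal(cand$tsdLen, 8L)
  expect_equal(cand$tsdSeqLeft, "GATTACAG")
  expect_equal(cand$tsdSeqRight, "GATTACAG")
  expect_equal(cand$tsdMismatches, 0L)
  expect_equal(cand$polyALen, 9L)
  expect_equal(cand$start, fx$at + 8L)
  expect_equal(cand$end, fx$at + fx$block_len - 8L)
  expect_equal(cand$totalScore, 17)
  expect_true(cand$passedFilters)
  expect_equal(cand$sourceStart, 5000L)
  # determinism: identical inputs give identical tables
  expect_identical(as.data.frame(detect_candidates(fx$net, fx$genome,
                                                   prefix = "hsa")),
                   as.data.frame(cand))
})

test_that("a minus-strand insertion is called with identical scores", {
  set.seed(22)
  fx <- plant_one(tsd = "GATTACAG", polya_len = 9L, strand = "-")
  cand <- detect_candidates(fx$net, fx$genome)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$strand, "-")
  expect_equal(cand$tsdLen, 8L)
  expect_equal(cand$polyALen, 9L)
  expect_equal(cand$totalScore, 17)
  expect_equal(cand$start, fx$at + 8L)
  expect_equal(cand$end, fx$at + fx$block_len - 8L)
  # the reference carries the tail as poly(T) 5'-ward: check it is there
  tail_ref <- substr(fx$genome[["chrT"]], fx$at + 8L + 1L, fx$at + 8L + 9L)
  expect_equal(tail_ref, strrep("T", 9L))
})

test_that("detection commutes with reverse complement of the reference", {
  set.seed(23)
  for (strand in c("+", "-")) {
    fx <- plant_one(strand = strand)
    L <- nchar(fx$genome[["chrT"]])
    flipped_genome <- c(chrT = revcomp(fx$genome[["chrT"]]))
    flipped <- detect_candidates(flip_net(fx$net), flipped_genome)
    orig <- detect_candidates(fx$net, fx$genome)
    expect_equal(nrow(flipped), nrow(orig))
    expect_equal(flipped$start, L - orig$end)
    expect_equal(flipped$end, L - orig$start)
    expect_equal(flipped$strand, ifelse(orig$strand == "+", "-", "+"))
    expect_equal(flipped$totalScore, orig$totalScore)
    expect_equal(flipped$tsdLen, orig$tsdLen)
    expect_equal(flipped$polyALen, orig$polyALen)
  }
})

test_that("gaps without fills, empty nets and missing chromosomes behave", {
  set.seed(24)
  genome <- c(chrT = rand_seq(2000))
  net <- parse_net(c("net chrT 2000",
                     " fill 0 2000 chrQ + 0 1900",
                     "  gap 500 100 chrQ + 500 0"))
  expect_equal(nrow(detect_candidates(net, genome)), 0L)
  expect_equal(nrow(detect_candidates(net_file(), genome)), 0L)
  expect_error(detect_candidates(net, c(chrZ = rand_seq(100))),
               "missing reference chromosome")
})

test_that("filtering retains exactly the candidates above every floor", {
  grid <- expand.grid(tsdLen = 5:10, polyALen = 3:8)
  cand <- data.frame(id = paste0("c", seq_len(nrow(grid))), chrom = "chr1",
                     start = 0L, end = 10L, strand = "+",
                     tsdLen = grid$tsdLen, polyALen = grid$polyALen,
                     tsdScore = grid$tsdLen, polyAScore = grid$polyALen,
                     totalScore = grid$tsdLen + grid$polyALen,
                     passedFilters = NA)
  kept <- filter_candidates(cand, detect_params())
  expect_true(all(kept$tsdLen >= 7))
  expect_true(all(kept$polyALen >= 5))
  expect_true(all(kept$totalScore >= 12))
  expect_equal(nrow(kept), sum(grid$tsdLen >= 7 & grid$polyALen >= 5))
  # empty input passes through
  expect_equal(nrow(filter_candidates(cand[0, ], detect_params())), 0L)
})
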