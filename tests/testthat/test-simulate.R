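test_that("random genomes are reproducible with near-uniform composition", {
  cfg <- sim_config(genome_length = 1e6, n_true = 0, n_control = 0, seed = 5)
  g1 <- random_genome(cfg)
  g2 <- random_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(names(g1), "chrSim")
  counts <- table(strsplit(g1[[1]], "")[[1]])
  # each base frequency within 3 sigma of 0.25 (binomial bound)
  sigma <- sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(counts / 1e6 - 0.25) < 3 * sigma))
  expect_error(sim_config(genome_length = 0), "genome_length")
})

test_that("planted insertion blocks reconstruct from their truth records", {
  set.seed(31)
  cfg <- sim_config(genome_length = 3e5, n_true = 6, n_control = 4)
  pre <- random_genome(cfg)
  planted <- plant_insertions(pre, cfg)
  tr <- planted$truths
  expect_equal(nrow(tr), 10L)
  expect_setequal(tr$isControl, c(TRUE, FALSE))
  for (i in seq_len(nrow(tr))) {
    got <- substr(planted$post[[1]], tr$postStart[i] + 1L, tr$postEnd[i])
    want <- if (tr$isControl[i]) {
      if (tr$strand[i] == "+") cfg$element else revcomp(cfg$element)
    } else {
      body <- paste0(cfg$element, strrep("A", tr$polyALen[i]))
      if (tr$strand[i] == "-") body <- revcomp(body)
      paste0(tr$tsdSeq[i], body, tr$tsdSeq[i])
    }
    expect_identical(got, want)
  }
  # insertions stay spaced and inside the chromosome
  expect_true(all(diff(sort(tr$prePosition)) >= cfg$min_spacing))
})

test_that("length is conserved and the pre genome is recoverable by excision", {
  set.seed(32)
  cfg <- sim_config(genome_length = 2e5, n_true = 5, n_control = 5,
                    motif_mode = "off")
  pre <- random_genome(cfg)
  planted <- plant_insertions(pre, cfg)
  tr <- planted$truths[order(planted$truths$postStart), ]
  expect_equal(nchar(planted$post[[1]]),
               nchar(pre[[1]]) + sum(tr$postEnd - tr$postStart))
  # excise the truth intervals and recover the input sequence exactly
  keep_s <- c(0L, tr$postEnd)
  keep_e <- c(tr$postStart, nchar(planted$post[[1]]))
  pieces <- substring(planted$post[[1]], keep_s + 1L, keep_e)
  expect_identical(paste(pieces, collapse = ""), pre[[1]])
})

test_that("zero insertions leave the genome untouched", {
  cfg <- sim_config(genome_length = 1e5, n_true = 0, n_control = 0, seed = 3)
  pre <- random_genome(cfg)
  planted <- plant_insertions(pre, cfg)
  expect_identical(planted$post, pre)
  expect_equal(nrow(planted$truths), 0L)
})

test_that("emulated nets have the canonical topology and round-trip", {
  cfg <- sim_config(genome_length = 3e5, n_true = 8, n_control = 4,
                    boundary_jitter = 0, seed = 33)
  sim <- simulate_retro(cfg)
  net <- sim$net
  top <- net$nets[[1]]$fills[[1]]
  expect_equal(top$level, 1L)
  expect_equal(length(top$children), nrow(sim$truths))
  tr <- sim$truths[order(sim$truths$postStart), ]
  for (i in seq_along(top$children)) {
    gap <- top$children[[i]]
    expect_equal(gap$kind, "gap")
    expect_equal(gap$ref_start, tr$postStart[i])
    expect_equal(gap$ref_start + gap$ref_size, tr$postEnd[i])
    expect_length(gap$children, 1L)
    fill <- gap$children[[1]]
    expect_equal(fill$kind, "fill")
    expect_equal(fill$level, 2L)
    # with no jitter the fill covers exactly the element body
    fs <- fill$ref_start
    fe <- fs + fill$ref_size
    if (tr$isControl[i]) {
      expect_equal(c(fs, fe), c(tr$postStart[i], tr$postEnd[i]))
    } else if (tr$strand[i] == "+") {
      expect_equal(fs, tr$postStart[i] + tr$tsdLen[i])
      expect_equal(fe, tr$postEnd[i] - tr$tsdLen[i] - tr$polyALen[i])
    } else {
      expect_equal(fs, tr$postStart[i] + tr$tsdLen[i] + tr$polyALen[i])
      expect_equal(fe, tr$postEnd[i] - tr$tsdLen[i])
    }
    expect_equal(fill$q_start, sim$parent_locus$start)
  }
  # serialised emulator output survives a parse/write cycle byte-for-byte
  lines <- write_net(net)
  expect_identical(parse_net(lines), net)
  expect_identical(write_net(parse_net(lines)), lines)
})

test_that("jittered fill edges stay clamped inside their gaps", {
  cfg <- sim_config(genome_length = 3e5, n_true = 10, n_control = 5,
                    boundary_jitter = 10, seed = 34)
  sim <- simulate_retro(cfg)
  for (gap in sim$net$nets[[1]]$fills[[1]]$children) {
    fill <- gap$children[[1]]
    expect_gte(fill$ref_start, gap$ref_start)
    expect_lte(fill$ref_start + fill$ref_size, gap$ref_start + gap$ref_size)
    expect_gt(fill$ref_size, 0L)
  }
})

test_that("the full simulation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 2e5, n_true = 4, n_control = 4, seed = 35)
  s1 <- simulate_retro(cfg)
  s2 <- simulate_retro(cfg)
  expect_identical(s1$post, s2$post)
  expect_identical(s1$truths, s2$truths)
  expect_identical(write_net(s1$net), write_net(s2$net))
})

test_that("perfect separation yields sensitivity, specificity and AUC of 1", {
  truths <- data.frame(id = c("t1", "t2", "c1", "c2"), chrom = "chrSim",
                       prePosition = c(100L, 5000L, 9000L, 12000L),
                       postStart = c(100L, 5000L, 9000L, 12000L),
                       postEnd = c(1100L, 6000L, 10000L, 13000L),
                       strand = "+", tsdSeq = "", tsdLen = 8L, polyALen = 9L,
                       isControl = c(FALSE, FALSE, TRUE, TRUE))
  cand <- data.frame(id = c("x1", "x2"), chrom = "chrSim",
                     start = c(110L, 5010L), end = c(1090L, 5990L),
                     strand = "+", tsdLen = 8L, polyALen = 9L,
                     totalScore = c(17, 20), passedFilters = TRUE)
  ev <- evaluate_candidates(cand, truths)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$tp, 2L)
  expect_equal(ev$fn, 0L)
  # ROC coordinates are monotone non-decreasing
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
  # truth tables without positives are refused
  expect_error(evaluate_candidates(cand, truths[truths$isControl, ]),
               "no positive instances")
})

test_that("trapezoidal AUC equals the rank statistic, including ties and misses", {
  set.seed(41)
  for (i in 1:50) {
    nt <- sample(5:60, 1)
    nc <- sample(5:60, 1)
    st <- sample(c(sample(5:30, nt, replace = TRUE), -Inf), nt)
    sc <- sample(c(sample(0:25, nc, replace = TRUE), -Inf), nc)
    roc <- roc_points(st, sc)
    expect_lt(abs(auc_trapezoid(roc$fpr, roc$tpr) - oracle_auc_rank(st, sc)),
              1e-9)
  }
})

test_that("AUC agrees with pROC on finite scores", {
  skip_if_not_installed("pROC")
  set.seed(42)
  st <- rnorm(40, mean = 2)
  sc <- rnorm(40)
  roc <- roc_points(st, sc)
  got <- auc_trapezoid(roc$fpr, roc$tpr)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 40)), predictor = c(st, sc),
    quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("label-free scores give a chance-level AUC", {
  set.seed(43)
  scores <- sample(10:40, 200, replace = TRUE)
  roc <- roc_points(scores[1:100], scores[101:200])
  a <- auc_trapezoid(roc$fpr, roc$tpr)
  expect_gt(a, 0.35)
  expect_lt(a, 0.65)
})
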