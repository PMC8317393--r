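make_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("homolog search finds verbatim and reverse-complement embeds", {
  q <- make_seq(300, 1)
  flank1 <- make_seq(500, 2)
  flank2 <- make_seq(400, 3)
  scaf <- c(s1 = paste0(flank1, q, flank2))
  h <- find_homologs(scaf, c(g = q))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 500)
  expect_equal(h$end, 800)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1.0)

  scaf_rc <- c(s1 = paste0(flank1, revcomp(q), flank2))
  h2 <- find_homologs(scaf_rc, c(g = q))
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 500)
  expect_equal(h2$end, 800)
  expect_equal(h2$identity, 1.0)
})

test_that("chain identity rejects a 10%-mismatched query at 0.95", {
  set.seed(4)
  q <- make_seq(300, 5)
  qc <- strsplit(q, "")[[1]]
  mut <- qc
  for (p in sample(10:290, 30))     # 10% scattered mismatches
    mut[p] <- sample(setdiff(c("A", "C", "G", "T"), qc[p]), 1)
  scaf <- c(s1 = paste0(make_seq(400, 6), paste(mut, collapse = ""),
                        make_seq(300, 7)))
  expect_equal(nrow(find_homologs(scaf, c(g = q), min_identity = 0.95)), 0)
  h <- find_homologs(scaf, c(g = q), min_identity = 0.85)
  expect_equal(nrow(h), 1)
  expect_lt(h$identity, 0.95)
})

test_that("homolog search agrees with brute-force window alignment", {
  set.seed(8)
  for (noise in c(0, 0.02, 0.05)) {
    q <- make_seq(240, 100 + noise * 100)
    qc <- strsplit(q, "")[[1]]
    emb <- qc
    nmut <- round(noise * length(qc))
    if (nmut > 0) {
      pos <- sample(seq_along(qc), nmut)
      for (p in pos) emb[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              qc[p]), 1)
    }
    scaf <- c(s1 = paste0(make_seq(600, 9), paste(emb, collapse = ""),
                          make_seq(350, 10)))
    bf <- bf_best_window(scaf[[1]], q)
    h <- find_homologs(scaf, c(g = q), min_identity = 0.8)
    expect_equal(nrow(h), 1)
    expect_equal(h$start - (h$q_start - 1), bf$start)  # same diagonal
    expect_equal(h$identity, bf$identity, tolerance = 0.02)
  }
})

test_that("k-mer depth matches hand-countable cases", {
  expect_equal(kmer_depth(character(0), region = make_seq(100, 11), k = 21),
               0)
  # exact 1x tiling with read length = k gives depth 1
  reg <- make_seq(200, 12)
  reads <- substring(reg, 1:(200 - 21 + 1), 21:200)
  expect_equal(kmer_depth(reads, reg, k = 21), 1)
  expect_error(kmer_depth(reads, "ACGT", k = 21), "shorter than k")
})

test_that("k-mer depth of a simulated region is Poisson-consistent", {
  reg <- make_seq(5000, 13)
  reads <- simulate_reads(c(r = reg), c(r = 30), read_length = 100,
                          seed = 14)
  d <- kmer_depth(reads, reg, k = 31)
  # interior k-mer coverage expectation: 30 * (L - k + 1) / L
  # read placements are correlated over ~read_length, so the effective
  # sample size is ~ region/read_length; allow 3 sigma on that scale
  expected <- 30 * (100 - 31 + 1) / 100
  expect_equal(d, expected, tolerance = 3 * sqrt(expected / 50) / expected)
  # invariant to read order and duplicate relabeling
  shuf <- sample(unname(reads))
  expect_equal(kmer_depth(shuf, reg, k = 31), d)
})

test_that("state classification applies the depth bands", {
  th <- depth_thresholds()
  t_call <- classify_state("rps1", 12, 100, 10, TRUE, TRUE, th)
  expect_equal(t_call$call, "T")   # ratio 1.2 nuclear band, 0.12 < 0.25
  m_call <- classify_state("nad1", 95, 100, 10, TRUE, TRUE, th)
  expect_equal(m_call$call, "M")   # ratio 0.95 in mito band
  l_call <- classify_state("rps2", NA, 100, 10, FALSE, FALSE, th)
  expect_equal(l_call$call, "L")
  u_call <- classify_state("rps3", 40, 100, 10, TRUE, TRUE, th)
  expect_equal(u_call$call, "U")   # between bands: explicit unknown
  expect_error(classify_state("x", 10, 0, 10, TRUE, TRUE, th), "> 0")
})

test_that("classification recovers the planted truth on noiseless data", {
  run <- small_pipeline_run()
  sim <- simulate_dataset(run$config)
  states <- run$result$states
  expect_identical(states[rownames(sim$states), colnames(sim$states)],
                   sim$states)
  expect_equal(sum(states == "U"), 0)
})
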