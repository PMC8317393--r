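rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("contiguous cDNA maps as a single exon with no introns", {
  cdna <- rand_seq(300, 1)
  scaf <- c(s1 = paste0(rand_seq(200, 2), cdna, rand_seq(150, 3)))
  em <- map_exons(cdna, scaf, gene_id = "g")
  expect_equal(nrow(em$exons), 1)
  expect_equal(em$placed_fraction, 1)
  expect_false(em$structural_failure)
  expect_equal(nrow(infer_introns(em)), 0)
  expect_identical(spliced_genomic_cds(em, scaf), cdna)
})

test_that("an insertion splits the cDNA into two colinear exons (cis)", {
  cdna <- rand_seq(600, 4)
  left <- substr(cdna, 1, 300)
  right <- substr(cdna, 301, 600)
  intron <- rand_seq(500, 5)
  # force the intron's first base to differ from the next exon base
  if (substr(intron, 1, 1) == substr(right, 1, 1))
    intron <- paste0(ifelse(substr(right, 1, 1) == "A", "C", "A"),
                     substr(intron, 2, 500))
  scaf <- c(s1 = paste0(rand_seq(100, 6), left, intron, right,
                        rand_seq(100, 7)))
  em <- map_exons(cdna, scaf, gene_id = "nad2")
  expect_equal(nrow(em$exons), 2)
  intr <- infer_introns(em)
  expect_equal(intr$mode, "cis")
  expect_equal(intr$insertion_point, 300)
  expect_equal(intr$phase, 0)
  expect_equal(intr$length, 500)
  expect_equal(intr$name, "nad2i300")
  expect_identical(spliced_genomic_cds(em, scaf), cdna)
})

test_that("exons on different scaffolds give a trans intron", {
  cdna <- rand_seq(542 + 200, 8)
  left <- substr(cdna, 1, 542)
  right <- substr(cdna, 543, nchar(cdna))
  scaf <- c(s1 = paste0(rand_seq(120, 9), left,
                        # guard: next base differs from right's first base
                        ifelse(substr(right, 1, 1) == "A", "C", "A"),
                        rand_seq(119, 10)),
            s2 = paste0(rand_seq(80, 11), right, rand_seq(90, 12)))
  em <- map_exons(cdna, scaf, gene_id = "nad2")
  expect_equal(nrow(em$exons), 2)
  expect_setequal(em$exons$scaffold_id, c("s1", "s2"))
  intr <- infer_introns(em)
  expect_equal(intr$mode, "trans")
  expect_true(is.na(intr$length))
  # the printed naming convention: insertion point 542 is phase 2
  expect_equal(intr$insertion_point, 542)
  expect_equal(intr$phase, 2)
  expect_equal(intr$name, "nad2i542")
})

test_that("minus-strand exons are mapped and spliced correctly", {
  cdna <- rand_seq(400, 13)
  scaf <- c(s1 = paste0(rand_seq(150, 14), revcomp(cdna),
                        rand_seq(130, 15)))
  em <- map_exons(cdna, scaf, gene_id = "g")
  expect_equal(nrow(em$exons), 1)
  expect_equal(em$exons$strand, "-")
  expect_identical(spliced_genomic_cds(em, scaf), cdna)
})

test_that("isolated mismatches (editing sites) do not break exons", {
  cdna <- rand_seq(300, 16)
  genomic <- cdna
  substr(genomic, 100, 100) <- ifelse(substr(cdna, 100, 100) == "C",
                                      "G", "C")
  scaf <- c(s1 = paste0(rand_seq(90, 17), genomic, rand_seq(95, 18)))
  em <- map_exons(cdna, scaf, gene_id = "g")
  expect_equal(nrow(em$exons), 1)
  expect_equal(em$placed_fraction, 1)
  gen <- spliced_genomic_cds(em, scaf)
  expect_identical(gen, genomic)
  expect_false(identical(gen, cdna))
})

test_that("unplaceable cDNA raises the structural-failure flag", {
  cdna <- rand_seq(300, 19)
  scaf <- c(s1 = paste0(rand_seq(90, 20), substr(cdna, 1, 100),
                        rand_seq(400, 21)))
  em <- map_exons(cdna, scaf, gene_id = "g")
  expect_true(em$structural_failure)
  expect_lt(em$placed_fraction, 0.9)
  expect_warning(intr <- infer_introns(em), "structural")
  expect_equal(nrow(intr), 0)
})

test_that("presequence detection measures the 5' extension and frame", {
  core <- rand_seq(360, 22)
  same <- detect_presequence(core, core, gene_id = "g")
  expect_equal(same$extension_length_nt, 0)
  expect_true(same$in_frame)

  ext90 <- detect_presequence(paste0(rand_seq(90, 23), core), core)
  expect_equal(ext90$extension_length_nt, 90)
  expect_true(ext90$in_frame)

  ext91 <- detect_presequence(paste0(rand_seq(91, 24), core), core)
  expect_equal(ext91$extension_length_nt, 91)
  expect_false(ext91$in_frame)

  expect_error(detect_presequence(rand_seq(300, 25), rand_seq(300, 26)),
               "refused")
})

test_that("simulation: inferred intron tables equal the planted spec", {
  run <- small_pipeline_run()
  planted <- truth_introns(run$result$truth)
  called <- run$result$introns
  expect_identical(
    intron_key(planted),
    intron_key(called[, c("species", "gene_id", "insertion_point",
                          "phase", "mode")]))
  # concatenation invariant held for every unflagged gene (the genomic
  # spliced CDS equals the cDNA length; editing accounts for mismatches)
  sim <- simulate_dataset(run$config)
  tr <- run$result$truth
  m_rows <- tr[tr$state == "M", ]
  sc <- split(sim$scaffolds, sub("[|].*$", "", names(sim$scaffolds)))
  for (i in utils::head(seq_len(nrow(m_rows)), 5)) {
    id <- paste0(m_rows$species[i], "|", m_rows$gene_id[i])
    em <- map_exons(sim$cdna[[id]], sc[[m_rows$species[i]]],
                    gene_id = m_rows$gene_id[i])
    gen <- spliced_genomic_cds(em, sc[[m_rows$species[i]]])
    expect_equal(nchar(gen), nchar(sim$cdna[[id]]))
    # genomic and cDNA agree everywhere except planted editing sites
    d <- which(strsplit(gen, "")[[1]] != strsplit(sim$cdna[[id]],
                                                  "")[[1]])
    planted_pos <- if (nzchar(m_rows$edit_pos[i]))
      as.integer(strsplit(m_rows$edit_pos[i], ",")[[1]]) else integer(0)
    expect_identical(d, sort(planted_pos))
  }
})

test_that("simulated presequence extensions are recovered", {
  run <- small_pipeline_run()
  tr <- run$result$truth
  ps <- run$result$presequences
  tg <- tr[tr$state == "T", ]
  for (i in seq_len(nrow(tg))) {
    row <- ps[ps$species == tg$species[i] & ps$gene_id == tg$gene_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$extension_length_nt, tg$presequence_nt[i])
  }
})
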