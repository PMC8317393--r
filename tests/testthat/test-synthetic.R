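test_that("config validation enforces the depth contrast and probabilities", {
  expect_error(sim_config(depth_mito = 10, depth_nuc = 10), "depth_mito")
  expect_error(sim_config(p_transfer = 1.2), "0, 1")
  expect_error(sim_config(p_transfer = 0.9, p_loss_M = 0.3), "exceed 1")
  cfg <- sim_config(seed = 1, n_genes = 12)
  expect_s3_class(cfg, "sim_config")
  expect_length(cfg$panel_genes, 12)
})

test_that("evolve_states honors degenerate probabilities", {
  cfg0 <- sim_config(seed = 5, n_genes = 8, p_transfer = 0,
                     p_loss_M = 0, p_loss_T = 0)
  evo <- evolve_states(cfg0)
  expect_true(all(evo$states == "M"))
  expect_equal(nrow(evo$events), 0)

  # certain loss on the root's child branches wipes every non-control gene
  cfg1 <- sim_config(seed = 5, n_genes = 8, p_transfer = 0, p_loss_M = 1,
                     p_loss_T = 0)
  evo1 <- evolve_states(cfg1)
  ctrl <- cfg1$control_mito
  expect_true(all(evo1$states[, setdiff(colnames(evo1$states), ctrl)] ==
                    "L"))
  expect_true(all(evo1$states[, ctrl] == "M"))
})

test_that("evolve_states replays exactly from the seeded stream", {
  cfg <- sim_config(seed = 31, n_genes = 10, p_transfer = 0.3,
                    p_loss_M = 0.1, p_loss_T = 0.1)
  evo <- evolve_states(cfg)
  # independent replay: same draw order (cladewise branches x panel genes,
  # one uniform per pair), same transition rules
  set.seed(cfg$seed)
  tree <- cfg$tree
  ntip <- ape::Ntip(tree)
  node_names <- c(tree$tip.label, tree$node.label)
  pre <- stats::reorder(tree, "cladewise")$edge
  st <- matrix(NA_character_, ntip + tree$Nnode, cfg$n_genes,
               dimnames = list(node_names, cfg$panel_genes))
  st[ntip + 1, ] <- "M"
  n_events <- 0
  for (r in seq_len(nrow(pre))) {
    s <- st[pre[r, 1], ]
    for (j in seq_along(cfg$panel_genes)) {
      u <- runif(1)
      exempt <- cfg$panel_genes[j] == cfg$control_mito
      if (!exempt && s[j] == "M" && u < cfg$p_transfer[j]) {
        s[j] <- "T"; n_events <- n_events + 1
      } else if (!exempt && s[j] == "M" &&
                 u < cfg$p_transfer[j] + cfg$p_loss_M[j]) {
        s[j] <- "L"; n_events <- n_events + 1
      } else if (!exempt && s[j] == "T" && u < cfg$p_loss_T[j]) {
        s[j] <- "L"; n_events <- n_events + 1
      }
    }
    st[pre[r, 2], ] <- s
  }
  expect_equal(nrow(evo$events), n_events)
  expect_identical(evo$states, st[seq_len(ntip), ])
  # and bit-reproducible
  expect_identical(evolve_states(cfg)$states, evo$states)
})

test_that("no lineage regains a lost or transferred copy (irreversibility)", {
  for (seed in c(2, 3, 4)) {
    cfg <- sim_config(seed = seed, n_genes = 15, p_transfer = 0.25,
                      p_loss_M = 0.2, p_loss_T = 0.3)
    evo <- evolve_states(cfg)
    ns <- evo$node_states
    tree <- cfg$tree
    rank <- c(M = 1, T = 2, L = 3)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      expect_true(all(rank[ns[ch, ]] >= rank[ns[p, ]]))
    }
  }
})

test_that("realized sequences carry the planted signatures", {
  cfg <- sim_config(seed = 13, n_genes = 10, p_transfer = 0.15,
                    editing_site_rate = 4)
  evo <- evolve_states(cfg)
  real <- realize_sequences(evo$states, cfg)
  tm <- real$templates
  # editing sites: genomic C, cDNA T on the template
  for (g in cfg$panel_genes) {
    for (p in tm[[g]]$edit_pos) {
      expect_equal(substr(tm[[g]]$cds_dna, p, p), "C")
      expect_equal(substr(tm[[g]]$cds_cdna, p, p), "T")
    }
  }
  # a transferred gene's nuclear copy contains the hardened (cDNA) form,
  # and its cDNA record equals the genomic copy (no editing)
  tg <- real$truth[real$truth$state == "T", ]
  if (nrow(tg)) {
    i <- 1
    id <- paste0(tg$species[i], "|", tg$gene_id[i])
    nuc <- real$scaffolds[[paste0(tg$species[i], "|nuc_1")]]
    expect_true(grepl(real$cdna[[id]], nuc, fixed = TRUE))
    expect_true(grepl(tm[[tg$gene_id[i]]]$cds_cdna, real$cdna[[id]],
                      fixed = TRUE))
  }
  # lost genes appear nowhere
  lg <- real$truth[real$truth$state == "L", ]
  if (nrow(lg)) {
    i <- 1
    body <- tm[[lg$gene_id[i]]]$cds_dna
    sp_scafs <- real$scaffolds[startsWith(names(real$scaffolds),
                                          paste0(lg$species[i], "|"))]
    expect_false(any(vapply(sp_scafs, grepl, TRUE, pattern = body,
                            fixed = TRUE)))
    expect_false(paste0(lg$species[i], "|", lg$gene_id[i]) %in%
                   names(real$cdna))
  }
})

test_that("trans introns split a gene across two scaffolds", {
  spec <- list(nad1 = data.frame(position = 150L, mode = "trans"))
  cfg <- sim_config(seed = 17, n_genes = 20, p_transfer = 0, p_loss_M = 0,
                    intron_rate = 0, intron_spec = spec)
  evo <- evolve_states(cfg)
  real <- realize_sequences(evo$states, cfg)
  tm <- real$templates$nad1
  sp <- rownames(evo$states)[1]
  part1 <- substr(tm$cds_dna, 1, 150)
  part2 <- substr(tm$cds_dna, 151, nchar(tm$cds_dna))
  on1 <- vapply(real$scaffolds, function(s)
    grepl(part1, s, fixed = TRUE) || grepl(revcomp(part1), s, fixed = TRUE),
    TRUE)
  on2 <- vapply(real$scaffolds, function(s)
    grepl(part2, s, fixed = TRUE) || grepl(revcomp(part2), s, fixed = TRUE),
    TRUE)
  sp_scaf <- grepl(paste0(sp, "|"), names(real$scaffolds), fixed = TRUE)
  expect_true(any(on1 & sp_scaf))
  expect_true(any(on2 & sp_scaf))
  # the two halves live on different scaffolds
  expect_false(any(on1 & on2 & sp_scaf))
})

test_that("read simulation hits Poisson-consistent depth and determinism", {
  set.seed(1)
  scaf <- c(s1 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                       collapse = ""))
  reads <- simulate_reads(scaf, c(s1 = 50), read_length = 100, seed = 9)
  expect_equal(length(reads), 5000, tolerance = 3 * sqrt(5000) / 5000)
  # realized mean depth near 50x
  depth <- length(reads) * 100 / 10000
  expect_equal(depth, 50, tolerance = 3 * sqrt(5000) / 5000 * 50)
  # determinism
  reads2 <- simulate_reads(scaf, c(s1 = 50), read_length = 100, seed = 9)
  expect_identical(reads, reads2)
  # depth 0 and short scaffolds
  expect_length(simulate_reads(scaf, c(s1 = 0), 100, seed = 1), 0)
  short <- c(tiny = "ACGTACGT")
  expect_warning(r <- simulate_reads(short, c(tiny = 10), 100, seed = 1),
                 "shorter")
  expect_length(r, 0)
})

test_that("simulate_dataset is bit-reproducible for a fixed seed", {
  cfg <- sim_config(seed = 21, n_genes = 8)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$states, b$states)
  expect_identical(a$scaffolds, b$scaffolds)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})
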