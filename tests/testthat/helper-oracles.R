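# Independent brute-force oracles used to verify the package's
# implementations, plus shared simulation fixtures.

# ---- Nei-Gojobori oracle: direct enumeration, no tabulation -------------

.bf_gc <- Biostrings::GENETIC_CODE

bf_codon_sites <- function(codon) {
  # fraction of single-base changes that are synonymous, per codon
  aa <- .bf_gc[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (.bf_gc[[alt]] == aa) syn <- syn + 1
    }
  }
  syn / 3
}

bf_paths <- function(from, to) {
  # all orderings of the differing positions, recursively
  diff <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(diff)) return(list())
  rec <- function(cur, remaining) {
    if (!length(remaining)) return(list(list()))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      step <- list(c(from = cur, to = nxt))
      for (tail in rec(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <- c(step, tail)
    }
    out
  }
  rec(from, diff)
}

bf_nei_gojobori <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- (sum(vapply(ca, bf_codon_sites, 1)) +
          sum(vapply(cb, bf_codon_sites, 1))) / 2
  N <- 3 * length(ca) - S
  Sd <- Nd <- 0
  for (i in which(ca != cb)) {
    paths <- bf_paths(ca[i], cb[i])
    ok <- Filter(function(p) !any(vapply(p, function(s)
      .bf_gc[[s[["to"]]]] == "*", TRUE)), paths)
    if (!length(ok)) ok <- paths
    sd <- vapply(ok, function(p) sum(vapply(p, function(s)
      .bf_gc[[s[["from"]]]] == .bf_gc[[s[["to"]]]], TRUE)), 1)
    nd <- vapply(ok, function(p) sum(vapply(p, function(s)
      .bf_gc[[s[["from"]]]] != .bf_gc[[s[["to"]]]], TRUE)), 1)
    Sd <- Sd + mean(sd)
    Nd <- Nd + mean(nd)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

random_codons <- function(n) {
  ok <- setdiff(names(.bf_gc), c("TAA", "TAG", "TGA"))
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

# ---- exhaustive minimum-cost labeling oracle ----------------------------

bf_sankoff_cost <- function(tree, tip_states, cost) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- c("M", "T", "L")
  tips <- match(tip_states[tree$tip.label], states)
  labelings <- as.matrix(expand.grid(rep(list(1:3), nnode)))
  best <- Inf
  for (r in seq_len(nrow(labelings))) {
    lab <- c(tips, labelings[r, ])
    cc <- sum(cost[cbind(lab[tree$edge[, 1]], lab[tree$edge[, 2]])])
    if (cc < best) best <- cc
  }
  best
}

# ---- brute-force ungapped window identity -------------------------------

bf_best_window <- function(scaffold, query) {
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(scaffold, "")[[1]]
  n <- length(sc) - length(qc) + 1
  best <- list(identity = -1, start = NA)
  for (off in seq_len(n)) {
    id <- mean(qc == sc[off:(off + length(qc) - 1)])
    if (id > best$identity) best <- list(identity = id, start = off - 1L)
  }
  best
}

# ---- truth-table parsing helpers ---------------------------------------

truth_editing_sites <- function(truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    if (truth$state[i] != "M" || truth$edit_pos[i] == "") return(NULL)
    data.frame(species = truth$species[i], gene_id = truth$gene_id[i],
               cds_position = as.integer(
                 strsplit(truth$edit_pos[i], ",")[[1]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

truth_introns <- function(truth) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    if (truth$state[i] != "M" || truth$introns[i] == "") return(NULL)
    f <- strsplit(strsplit(truth$introns[i], ";")[[1]], ":")
    data.frame(species = truth$species[i], gene_id = truth$gene_id[i],
               insertion_point = as.integer(vapply(f, `[`, "", 1)),
               phase = as.integer(vapply(f, `[`, "", 2)),
               mode = vapply(f, `[`, "", 3), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

edit_key <- function(d) sort(paste(d$species, d$gene_id, d$cds_position))
intron_key <- function(d)
  sort(paste(d$species, d$gene_id, d$insertion_point, d$phase, d$mode))

# ---- shared simulation fixtures (memoised across test files) ------------

.fixture_env <- new.env(parent = emptyenv())

small_pipeline_run <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(seed = 7, n_genes = 10, p_transfer = 0.08,
                      depth_mito = 80, depth_nuc = 10,
                      tree = ape::read.tree(text = "((a,b),(c,d));"))
    out <- file.path(tempdir(), "mt-small-pipe")
    res <- suppressMessages(run_pipeline(cfg, out_dir = out, force = TRUE))
    .fixture_env$small <- list(config = cfg, result = res, out_dir = out)
  }
  .fixture_env$small
}

full_pipeline_run <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- sim_config(seed = 42)  # 8-leaf tree, 40 genes, 100x/10x depth
    out <- file.path(tempdir(), "mt-full-pipe")
    res <- suppressMessages(run_pipeline(cfg, out_dir = out, force = TRUE))
    .fixture_env$full <- list(config = cfg, result = res, out_dir = out)
  }
  .fixture_env$full
}
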