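# Synthetic-evolution generator: plants transfer/loss events on a species
# tree, realises mitochondrial and nuclear sequences carrying editing
# sites, cis/trans introns and presequence extensions, and samples shotgun
# reads at an organellar and a nuclear depth tier.
#
# All randomness flows from the single config seed: evolve_states() seeds
# with `seed`, build_gene_templates() with `seed + 1`, realize_sequences()
# with `seed + 2`, simulate_reads() with `seed + 3`, so each stage is
# independently reproducible and a full simulate_dataset() run is
# bit-reproducible.

.default_sim_tree <- function()
  name_internal_nodes(ape::read.tree(
    text = "(((sp1,sp2),(sp3,sp4)),((sp5,sp6),(sp7,sp8)));"))

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: an ancestral
#' mitochondrial gene panel evolving on a species tree with irreversible
#' transfer (M->T) and loss (M->L, T->L) events; mitochondrial copies
#' carrying C-to-U editing sites and cis/trans introns; transferred nuclear
#' copies that are retroprocessed (editing sites hardened to genomic T,
#' mitochondrial introns absent, optional N-terminal presequence
#' extension); and reads sampled at a high mitochondrial and a low nuclear
#' depth tier.
#'
#' @param seed Integer seed; the single source for all stochastic draws.
#' @param tree Rooted [ape::phylo] species tree (default: balanced 8-leaf).
#' @param n_genes Panel size; gene ids are taken from [mito_gene_panel()].
#' @param gene_length_codons Range (codons) for template CDS lengths.
#' @param p_transfer,p_loss_M,p_loss_T Per-branch per-gene event
#'   probabilities (scalars or per-gene vectors recycled over the panel);
#'   transitions are restricted to M->T, M->L, T->L.
#' @param editing_site_rate Mean C-to-U editing sites per 100 codons.
#' @param intron_rate Mean introns per gene (Poisson, capped at 2).
#' @param p_trans_intron Probability that a planted intron is
#'   trans-spliced.
#' @param intron_length Range (nt) for cis intron lengths.
#' @param presequence_prob Probability that a transferred gene gains an
#'   N-terminal presequence extension.
#' @param presequence_length Range (nt) of the extension.
#' @param depth_mito,depth_nuc Mean coverage of the mitochondrial and
#'   nuclear scaffold tiers; `depth_mito > depth_nuc` enforces the
#'   organelle copy-number excess.
#' @param read_length Read length (bp).
#' @param substitution_rate_mito,substitution_rate_nuc_transferred
#'   Per-site per-branch substitution probabilities (0 = noiseless).
#' @param read_error_rate Per-base uniform read error probability
#'   (0 = error-free).
#' @param spacer_length Range (nt) of intergenic spacers on scaffolds.
#' @param control_mito Panel gene exempt from events, used as the
#'   organellar depth control (a nad2/nad5 analog); default `nad5` when in
#'   the panel, else the first panel gene.
#' @param control_nuc Id of the single-copy nuclear control gene placed on
#'   every nuclear scaffold (a LEAFY analog).
#' @param intron_spec Optional named list, gene id -> data frame with
#'   columns `position` (1-based nt offset in the CDS), `mode`
#'   (`cis`/`trans`) and optionally `length`; overrides random intron
#'   placement for those genes.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       tree = NULL,
                       n_genes = 40L,
                       gene_length_codons = c(90L, 180L),
                       p_transfer = 0.04,
                       p_loss_M = 0.02,
                       p_loss_T = 0.02,
                       editing_site_rate = 3,
                       intron_rate = 0.7,
                       p_trans_intron = 0.2,
                       intron_length = c(200L, 500L),
                       presequence_prob = 0.5,
                       presequence_length = c(60L, 150L),
                       depth_mito = 100,
                       depth_nuc = 10,
                       read_length = 100L,
                       substitution_rate_mito = 0,
                       substitution_rate_nuc_transferred = 0,
                       read_error_rate = 0,
                       spacer_length = c(150L, 300L),
                       control_mito = NULL,
                       control_nuc = "LEAFY",
                       intron_spec = NULL) {
  if (is.null(tree)) tree <- .default_sim_tree()
  tree <- name_internal_nodes(tree)
  panel <- utils::head(mito_gene_panel()$gene_id, n_genes)
  if (length(panel) < n_genes)
    stop("n_genes exceeds the ", nrow(mito_gene_panel()), "-gene panel")
  if (is.null(control_mito))
    control_mito <- if ("nad5" %in% panel) "nad5" else panel[1L]
  if (!control_mito %in% panel)
    stop("control_mito ('", control_mito, "') must be a panel gene")
  if (control_nuc %in% panel)
    stop("control_nuc must not collide with a panel gene id")
  probs <- list(p_transfer = p_transfer, p_loss_M = p_loss_M,
                p_loss_T = p_loss_T)
  for (nm in names(probs))
    if (any(probs[[nm]] < 0 | probs[[nm]] > 1))
      stop(nm, " must be in [0, 1]")
  pt <- rep_len(p_transfer, length(panel))
  plm <- rep_len(p_loss_M, length(panel))
  if (any(pt + plm > 1))
    stop("p_transfer + p_loss_M must not exceed 1 for any gene")
  if (depth_mito <= depth_nuc)
    stop("depth_mito must exceed depth_nuc (organelle copy-number excess)")
  if (read_length < 31L) stop("read_length must be at least 31")
  cfg <- list(seed = as.integer(seed), tree = tree, panel_genes = panel,
              n_genes = length(panel),
              gene_length_codons = gene_length_codons,
              p_transfer = pt, p_loss_M = plm,
              p_loss_T = rep_len(p_loss_T, length(panel)),
              editing_site_rate = editing_site_rate,
              intron_rate = intron_rate,
              p_trans_intron = p_trans_intron,
              intron_length = intron_length,
              presequence_prob = presequence_prob,
              presequence_length = presequence_length,
              depth_mito = depth_mito, depth_nuc = depth_nuc,
              read_length = as.integer(read_length),
              substitution_rate_mito = substitution_rate_mito,
              substitution_rate_nuc_transferred =
                substitution_rate_nuc_transferred,
              read_error_rate = read_error_rate,
              spacer_length = spacer_length,
              control_mito = control_mito, control_nuc = control_nuc,
              intron_spec = intron_spec)
  class(cfg) <- "sim_config"
  cfg
}

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

.random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(.NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

.random_seq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

.is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

# Plant editing sites on a template CDS: genomic base C, cDNA base T.
# Positions avoid the start/stop codons, sit >= 12 nt from the CDS ends,
# are >= 18 nt apart (identifiability margins for exact downstream
# recovery), and keep both codon variants stop-free.
.plant_editing <- function(dna, rate_per_100_codons) {
  n <- nchar(dna)
  ncod <- n %/% 3L
  n_sites <- stats::rpois(1L, rate_per_100_codons * ncod / 100)
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < n_sites && tries < n_sites * 30L + 30L) {
    tries <- tries + 1L
    p <- sample(13:(n - 12L), 1L)
    if (length(pos) && min(abs(pos - p)) < 18L) next
    cand <- dna
    substr(cand, p, p) <- "C"
    cstart <- 3L * ((p - 1L) %/% 3L) + 1L
    cod_dna <- substr(cand, cstart, cstart + 2L)
    cod_cdna <- cod_dna
    substr(cod_cdna, p - cstart + 1L, p - cstart + 1L) <- "T"
    if (.is_stop(cod_dna) || .is_stop(cod_cdna)) next
    dna <- cand
    pos <- c(pos, p)
  }
  pos <- sort(pos)
  cdna <- dna
  for (p in pos) substr(cdna, p, p) <- "T"
  list(dna = dna, cdna = cdna, edit_pos = pos)
}

# Plant introns on a template: positions >= 30 nt from either CDS end,
# >= 60 nt apart and >= 12 nt from any editing site.  The first intron
# base is forced to differ from the cDNA base following the insertion
# point so planted boundaries are recoverable exactly by left-greedy exon
# chaining.
.plant_introns <- function(gene_id, cdna, cfg, edit_pos = integer(0)) {
  len <- nchar(cdna)
  spec <- cfg$intron_spec[[gene_id]]
  if (is.null(spec)) {
    k <- min(stats::rpois(1L, cfg$intron_rate), 2L)
    if (k == 0L || len < 120L)
      return(data.frame(position = integer(0), phase = integer(0),
                        mode = character(0), length = integer(0),
                        stringsAsFactors = FALSE))
    ok <- function(p) (k < 2L || all(diff(p) >= 60L)) &&
      (!length(edit_pos) || min(abs(outer(p, edit_pos, "-"))) >= 12L)
    pos <- sort(sample(30:(len - 30L), k))
    tries <- 0L
    while (!ok(pos) && tries < 50L) {
      pos <- sort(sample(30:(len - 30L), k))
      tries <- tries + 1L
    }
    if (!ok(pos))
      return(data.frame(position = integer(0), phase = integer(0),
                        mode = character(0), length = integer(0),
                        stringsAsFactors = FALSE))
    mode <- ifelse(stats::runif(k) < cfg$p_trans_intron, "trans", "cis")
    ilen <- ifelse(mode == "cis",
                   sample(cfg$intron_length[1L]:cfg$intron_length[2L], k,
                          replace = TRUE), NA_integer_)
    spec <- data.frame(position = pos, mode = mode, length = ilen,
                       stringsAsFactors = FALSE)
  } else {
    if (any(spec$position >= len))
      stop("intron position beyond CDS length for gene ", gene_id)
    if (is.null(spec$length))
      spec$length <- ifelse(spec$mode == "cis",
                            sample(cfg$intron_length[1L]:cfg$intron_length[2L],
                                   nrow(spec), replace = TRUE), NA_integer_)
    spec <- spec[order(spec$position), , drop = FALSE]
  }
  spec$phase <- spec$position %% 3L
  seqs <- character(nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (spec$mode[i] == "cis") {
      s <- .random_seq(spec$length[i])
      nxt <- substr(cdna, spec$position[i] + 1L, spec$position[i] + 1L)
      if (substr(s, 1L, 1L) == nxt) {
        alt <- setdiff(c("A", "C", "G", "T"), nxt)
        substr(s, 1L, 1L) <- sample(alt, 1L)
      }
      seqs[i] <- s
    } else seqs[i] <- NA_character_
  }
  spec$seq <- seqs
  spec[, c("position", "phase", "mode", "length", "seq")]
}

#' Build the per-gene sequence templates for a simulation
#'
#' Draws each panel gene's ancestral CDS, its C-to-U editing sites and its
#' intron complement, plus the single-copy nuclear control gene.  Called
#' internally by [simulate_dataset()]; exposed for tests.
#'
#' @param config A [sim_config()].
#' @param reseed Reseed the RNG from the config seed (set `FALSE` when the
#'   caller manages the stream).
#' @return Named list of templates: `cds_dna`, `cds_cdna`, `edit_pos`,
#'   `introns` per gene.
#' @export
build_gene_templates <- function(config, reseed = TRUE) {
  if (reseed) set.seed(config$seed + 1L)
  genes <- c(config$panel_genes, config$control_nuc)
  templ <- vector("list", length(genes))
  names(templ) <- genes
  for (g in genes) {
    ncod <- sample(config$gene_length_codons[1L]:config$gene_length_codons[2L],
                   1L)
    cds <- .random_cds(ncod)
    if (g == config$control_nuc) {
      templ[[g]] <- list(gene_id = g, cds_dna = cds, cds_cdna = cds,
                         edit_pos = integer(0),
                         introns = data.frame(position = integer(0),
                                              phase = integer(0),
                                              mode = character(0),
                                              length = integer(0),
                                              seq = character(0),
                                              stringsAsFactors = FALSE))
      next
    }
    ed <- .plant_editing(cds, config$editing_site_rate)
    intr <- .plant_introns(g, ed$cdna, config, edit_pos = ed$edit_pos)
    templ[[g]] <- list(gene_id = g, cds_dna = ed$dna, cds_cdna = ed$cdna,
                       edit_pos = ed$edit_pos, introns = intr)
  }
  templ
}

#' Evolve gene states on the species tree
#'
#' Samples transfer and loss events independently per branch and per gene
#' with the configured probabilities, restricted to the irreversible
#' transitions M->T, M->L and T->L.  The mitochondrial control gene is
#' exempt.  One uniform draw is consumed per (branch, gene) pair in
#' cladewise branch order and panel gene order regardless of state, so a
#' seeded run can be replayed exactly.
#'
#' @param config A [sim_config()].
#' @param reseed Reseed the RNG from the config seed.
#' @return List: `states` (tip state matrix, values in M/T/L), `events`
#'   (data frame `branch`, `gene_id`, `event`), `node_states` (all-node
#'   matrix).
#' @export
evolve_states <- function(config, reseed = TRUE) {
  if (reseed) set.seed(config$seed)
  tree <- config$tree
  genes <- config$panel_genes
  pt <- config$p_transfer
  plm <- config$p_loss_M
  plt <- config$p_loss_T
  exempt <- genes == config$control_mito
  pt[exempt] <- 0; plm[exempt] <- 0; plt[exempt] <- 0
  ntip <- ape::Ntip(tree)
  node_names <- c(tree$tip.label, tree$node.label)
  pre <- stats::reorder(tree, "cladewise")$edge
  st <- matrix(NA_character_, ntip + tree$Nnode, length(genes),
               dimnames = list(node_names, genes))
  st[ntip + 1L, ] <- "M"
  ev <- list()
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1L]; ch <- pre[r, 2L]
    s <- st[p, ]
    for (j in seq_along(genes)) {
      u <- stats::runif(1L)
      if (s[j] == "M") {
        if (u < pt[j]) {
          s[j] <- "T"
          ev[[length(ev) + 1L]] <- data.frame(
            branch = node_names[ch], gene_id = genes[j],
            event = "transfer", stringsAsFactors = FALSE)
        } else if (u < pt[j] + plm[j]) {
          s[j] <- "L"
          ev[[length(ev) + 1L]] <- data.frame(
            branch = node_names[ch], gene_id = genes[j],
            event = "loss", stringsAsFactors = FALSE)
        }
      } else if (s[j] == "T" && u < plt[j]) {
        s[j] <- "L"
        ev[[length(ev) + 1L]] <- data.frame(
          branch = node_names[ch], gene_id = genes[j],
          event = "loss", stringsAsFactors = FALSE)
      }
    }
    st[ch, ] <- s
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(0), gene_id = character(0),
               event = character(0), stringsAsFactors = FALSE)
  list(states = st[seq_len(ntip), , drop = FALSE], events = events,
       node_states = st)
}

# genomic gene fragments for a state-M gene: cis introns inserted, the gene
# split at trans introns (fragments later placed on different scaffolds).
# Each fragment carries `cds_end`, the CDS offset its exon content ends at.
.mito_fragments <- function(template) {
  cds <- template$cds_dna
  intr <- template$introns
  frags <- list()
  cur <- ""
  last <- 0L
  cuts <- c(intr$position, nchar(cds))
  for (i in seq_along(cuts)) {
    seg <- substr(cds, last + 1L, cuts[i])
    cur <- paste0(cur, seg)
    if (i <= nrow(intr)) {
      if (intr$mode[i] == "cis") {
        cur <- paste0(cur, intr$seq[i])
      } else {
        frags[[length(frags) + 1L]] <- list(seq = cur, cds_end = cuts[i])
        cur <- ""
      }
    }
    last <- cuts[i]
  }
  frags[[length(frags) + 1L]] <- list(seq = cur, cds_end = nchar(cds))
  frags
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# a single base different from `avoid` (guards trans-fragment boundaries
# against chance extension into flanking spacer)
.guard_base <- function(avoid) {
  sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
}

.apply_substitutions <- function(seqs, rate_per_site) {
  if (rate_per_site <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    b <- .chars(seqs[[i]])
    hit <- which(stats::runif(length(b)) < rate_per_site)
    for (p in hit) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    seqs[[i]] <- paste(b, collapse = "")
  }
  seqs
}

#' Realise genomic scaffolds and cDNA sequences from evolved states
#'
#' State-M genes are placed on mitochondrial scaffolds with cis introns
#' inserted and trans introns realised by splitting the gene across two
#' scaffolds; editing sites are genomic C with cDNA T.  State-T genes are
#' placed on the nuclear scaffold retroprocessed: editing sites hardened to
#' genomic T, mitochondrial introns absent, an optional random in-frame-or-
#' not presequence extension prepended (present in both the nuclear copy
#' and its cDNA).  Lost genes are absent from both compartments.  The
#' single-copy nuclear control gene is placed on every species' nuclear
#' scaffold.
#'
#' @param states Tip state matrix from [evolve_states()].
#' @param config A [sim_config()].
#' @param templates Gene templates from [build_gene_templates()]; built
#'   (with the config seed) when `NULL`.
#' @param reseed Reseed the RNG from the config seed.
#' @return List: `scaffolds` (named vector, ids `species|mt_1`,
#'   `species|mt_2`, `species|nuc_1`), `cdna` (named vector, ids
#'   `species|gene`), `truth` (per species x gene data frame with planted
#'   state, editing sites, introns, presequence length and transfer
#'   branch), `templates`.
#' @export
realize_sequences <- function(states, config, templates = NULL,
                              reseed = TRUE) {
  if (is.null(templates)) templates <- build_gene_templates(config,
                                                            reseed = reseed)
  if (reseed) set.seed(config$seed + 2L)
  genes <- config$panel_genes
  species <- rownames(states)
  # branch of the transfer event for each tip x gene (from replaying states)
  scaffolds <- character(0)
  cdna <- character(0)
  truth <- list()
  spacer <- function() .random_seq(sample(
    config$spacer_length[1L]:config$spacer_length[2L], 1L))
  n_branch <- function(sp) {
    # number of branches from root to this tip (for substitution scaling)
    tr <- config$tree
    nd <- match(sp, tr$tip.label)
    k <- 0L
    while (nd != ape::Ntip(tr) + 1L) {
      nd <- tr$edge[tr$edge[, 2L] == nd, 1L]
      k <- k + 1L
    }
    k
  }
  for (sp in species) {
    mt <- list(`1` = character(0), `2` = character(0))
    nuc <- character(0)
    depth_path <- n_branch(sp)
    for (g in genes) {
      st <- states[sp, g]
      tm <- templates[[g]]
      n_edit <- length(tm$edit_pos)
      n_intr <- nrow(tm$introns)
      row <- data.frame(
        species = sp, gene_id = g, state = st,
        edit_pos = paste(tm$edit_pos, collapse = ","),
        n_edit_sites = n_edit,
        introns = paste(sprintf("%d:%d:%s", tm$introns$position,
                                tm$introns$phase, tm$introns$mode),
                        collapse = ";"),
        n_introns = n_intr,
        presequence_nt = 0L, stringsAsFactors = FALSE)
      if (st == "M") {
        frags <- .mito_fragments(tm)
        seqs <- unlist(.apply_substitutions(
          lapply(frags, `[[`, "seq"),
          config$substitution_rate_mito * depth_path))
        for (i in seq_along(seqs)) {
          f <- seqs[i]
          ce <- frags[[i]]$cds_end
          # base of the cDNA right after this fragment's exon content;
          # guard the flank so exon extension stops exactly at the cut
          cn <- if (ce < nchar(tm$cds_cdna))
            substr(tm$cds_cdna, ce + 1L, ce + 1L) else NA_character_
          flip <- stats::runif(1L) < 0.25
          k <- as.character((i - 1L) %% 2L + 1L)
          if (flip) {
            pieces <- c(if (!is.na(cn)) .guard_base(.COMPLEMENT[[cn]]),
                        revcomp(f))
          } else {
            pieces <- c(f, if (!is.na(cn)) .guard_base(cn))
          }
          mt[[k]] <- c(mt[[k]], spacer(), pieces)
        }
        cdna[paste0(sp, "|", g)] <- tm$cds_cdna
      } else if (st == "T") {
        body <- tm$cds_cdna    # retroprocessed: edits hardened, introns gone
        body <- .apply_substitutions(
          list(body), config$substitution_rate_nuc_transferred *
            depth_path)[[1L]]
        if (stats::runif(1L) < config$presequence_prob) {
          plen <- sample(config$presequence_length[1L]:
                           config$presequence_length[2L], 1L)
          body <- paste0(.random_seq(plen), body)
          row$presequence_nt <- plen
        }
        nuc <- c(nuc, spacer(), body)
        cdna[paste0(sp, "|", g)] <- body
        row$edit_pos <- ""
        row$n_edit_sites <- 0L
        row$introns <- ""
        row$n_introns <- 0L
      } else {
        row$edit_pos <- ""
        row$n_edit_sites <- 0L
        row$introns <- ""
        row$n_introns <- 0L
      }
      truth[[length(truth) + 1L]] <- row
    }
    ctrl <- templates[[config$control_nuc]]
    nuc <- c(nuc, spacer(), ctrl$cds_dna, spacer())
    cdna[paste0(sp, "|", config$control_nuc)] <- ctrl$cds_cdna
    for (k in c("1", "2")) {
      if (length(mt[[k]]))
        scaffolds[paste0(sp, "|mt_", k)] <-
          paste(c(mt[[k]], spacer()), collapse = "")
    }
    scaffolds[paste0(sp, "|nuc_1")] <- paste(nuc, collapse = "")
  }
  truth <- do.call(rbind, truth)
  list(scaffolds = scaffolds, cdna = cdna, truth = truth,
       templates = templates)
}

#' Sample uniform shotgun reads from scaffolds
#'
#' Read counts per scaffold are Poisson with mean
#' `depth * scaffold_length / read_length`; start positions are uniform.
#' Reads are error-free unless `error_rate > 0`.  Scaffolds shorter than
#' the read length are skipped with a warning.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param depth_map Named numeric vector of target mean depths per
#'   scaffold.
#' @param read_length Read length (bp).
#' @param seed Integer seed.
#' @param error_rate Per-base substitution error probability.
#' @return Named character vector of reads (`<scaffold>_r<i>`).
#' @export
simulate_reads <- function(scaffolds, depth_map, read_length = 100L,
                           seed = 1L, error_rate = 0) {
  stopifnot(all(names(scaffolds) %in% names(depth_map)))
  set.seed(seed)
  out <- list()
  for (sc in names(scaffolds)) {
    len <- nchar(scaffolds[[sc]])
    depth <- depth_map[[sc]]
    if (depth <= 0) next
    if (read_length > len) {
      warning("scaffold ", sc, " shorter than read length; skipped")
      next
    }
    n <- stats::rpois(1L, depth * len / read_length)
    if (n == 0L) next
    starts <- sample.int(len - read_length + 1L, n, replace = TRUE)
    reads <- substring(scaffolds[[sc]], starts, starts + read_length - 1L)
    if (error_rate > 0) reads <- unlist(.apply_substitutions(
      as.list(reads), error_rate))
    names(reads) <- paste0(sc, "_r", seq_len(n))
    out[[sc]] <- reads
  }
  if (!length(out)) return(stats::setNames(character(0), character(0)))
  unlist(unname(lapply(out, identity)))
}

#' Run the full generator: states, sequences and reads
#'
#' Seeds once from the config and runs [evolve_states()],
#' [build_gene_templates()], [realize_sequences()] and [simulate_reads()]
#' on consecutive derived streams.  When `out_dir` is given, writes
#' `scaffolds.fasta`, `cdna.fasta`, `reads.fasta`, `truth.tsv`,
#' `events.tsv` and `states_true.tsv`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return List with `states`, `events`, `truth`, `templates`,
#'   `scaffolds`, `cdna`, `reads`, `depth_map`, `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  evo <- evolve_states(config)
  real <- realize_sequences(evo$states, config)
  depth_map <- stats::setNames(
    ifelse(grepl("\\|mt_", names(real$scaffolds)),
           config$depth_mito, config$depth_nuc),
    names(real$scaffolds))
  reads <- simulate_reads(real$scaffolds, depth_map,
                          read_length = config$read_length,
                          seed = config$seed + 3L,
                          error_rate = config$read_error_rate)
  # attach the transfer branch to the truth table
  tb <- evo$events[evo$events$event == "transfer", , drop = FALSE]
  real$truth$transfer_branch <- NA_character_
  if (nrow(tb)) {
    desc <- .branch_descendants(config$tree)
    for (i in seq_len(nrow(tb))) {
      sps <- desc[[tb$branch[i]]]
      sel <- real$truth$gene_id == tb$gene_id[i] &
        real$truth$species %in% sps & real$truth$state == "T"
      real$truth$transfer_branch[sel] <- tb$branch[i]
    }
  }
  res <- list(states = evo$states, events = evo$events, truth = real$truth,
              templates = real$templates, scaffolds = real$scaffolds,
              cdna = real$cdna, reads = reads, depth_map = depth_map,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$scaffolds, file.path(out_dir, "scaffolds.fasta"))
    write_fasta(res$cdna, file.path(out_dir, "cdna.fasta"))
    write_fasta(res$reads, file.path(out_dir, "reads.fasta"))
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_event_table(res$events, file.path(out_dir, "events.tsv"))
    write_state_matrix(res$states, file.path(out_dir, "states_true.tsv"))
  }
  res
}

# tips descending from the branch whose child node has the given name
.branch_descendants <- function(tree) {
  tree <- name_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  node_names <- c(tree$tip.label, tree$node.label)
  kids <- function(nd) tree$edge[tree$edge[, 1L] == nd, 2L]
  rec <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    unlist(lapply(kids(nd), rec))
  }
  out <- list()
  for (nd in seq_along(node_names))
    if (nd != ntip + 1L) out[[node_names[nd]]] <- rec(nd)
  out
}
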