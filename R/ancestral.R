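# Ancestral gene-content reconstruction under an irreversible three-state
# model (M -> T, M -> L, T -> L; no reversals), plus forward event replay
# and the curated gymnosperm event table.

#' Transition cost matrix for the irreversible three-state model
#'
#' States are M (mitochondrial), T (transferred), L (lost).  Identity costs
#' 0; the permitted transitions M->T (transfer), M->L and T->L (loss) cost 1
#' by default; reverse transitions are blocked with `Inf`.  Transfer with
#' subsequent loss of the mitochondrial copy, and outright loss, are treated
#' as irreversible: a lineage never regains a lost or transferred
#' mitochondrial copy.
#'
#' @param transfer Cost of M->T.
#' @param loss_mito Cost of M->L.
#' @param loss_transferred Cost of T->L.
#' @return A 3x3 numeric matrix with dimnames `M`, `T`, `L`.
#' @export
cost_model <- function(transfer = 1, loss_mito = 1, loss_transferred = 1) {
  cm <- matrix(Inf, 3L, 3L, dimnames = list(.MTL, .MTL))
  diag(cm) <- 0
  cm["M", "T"] <- transfer
  cm["M", "L"] <- loss_mito
  cm["T", "L"] <- loss_transferred
  cm
}

.event_type <- function(from, to) {
  ifelse(from == "M" & to == "T", "transfer",
         ifelse(to == "L" & from %in% c("M", "T"), "loss", NA_character_))
}

#' Sankoff parsimony reconstruction of gene states on a species tree
#'
#' Minimum-cost ancestral labeling per gene by dynamic programming up the
#' tree followed by a top-down backtrace.  Ties are broken by a fixed state
#' priority (default M > T > L, biased toward ancestral retention and hence
#' conservative with respect to inferring transfer).  Tips observed as `"U"`
#' are uninformative for that gene (flat zero cost; a warning is issued) and
#' never generate events.  An event is emitted on every branch whose
#' endpoint states differ.
#'
#' @param tree Rooted [ape::phylo] tree whose tips match the matrix rows.
#' @param states Species-by-gene character state matrix (tips; `U` allowed).
#' @param cost Transition cost matrix from [cost_model()].
#' @param tie_break State priority used to break cost ties, most-preferred
#'   first.
#' @return A list of class `sankoff_fit`: `tree` (with labeled internals),
#'   `anc_states` (internal-node x gene matrix), `tip_states`
#'   (reconstructed, `U` tips resolved), `events` (data frame `branch`,
#'   `gene_id`, `event`, `from`, `to`) and `cost` (per-gene minimum cost).
#' @export
sankoff_reconstruct <- function(tree, states, cost = cost_model(),
                                tie_break = c("M", "T", "L")) {
  validate_state_matrix(states)
  stopifnot(setequal(rownames(states), tree$tip.label),
            identical(sort(tie_break), sort(.MTL)))
  tree <- name_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  genes <- colnames(states)
  tips <- states[tree$tip.label, , drop = FALSE]
  if (any(tips == "U"))
    warning("tips with state 'U' are uninformative and were excluded ",
            "gene-wise from the reconstruction")
  post <- stats::reorder(tree, "postorder")$edge
  pre <- stats::reorder(tree, "cladewise")$edge
  node_names <- c(tree$tip.label, tree$node.label)
  prio <- match(.MTL, tie_break)   # smaller = preferred
  root <- ntip + 1L

  anc <- matrix(NA_character_, nnode, length(genes),
                dimnames = list(tree$node.label, genes))
  tip_out <- tips
  gcost <- stats::setNames(numeric(length(genes)), genes)
  ev <- vector("list", length(genes))

  for (j in seq_along(genes)) {
    S <- matrix(0, ntip + nnode, 3L)
    obs <- tips[, j]
    known <- obs != "U"
    S[seq_len(ntip)[known], ] <- Inf
    S[cbind(seq_len(ntip)[known], match(obs[known], .MTL))] <- 0
    for (r in seq_len(nrow(post))) {
      p <- post[r, 1L]; ch <- post[r, 2L]
      S[p, ] <- S[p, ] + apply(cost + rep(S[ch, ], each = 3L), 1L, min)
    }
    best <- min(S[root, ])
    if (!is.finite(best)) stop("no finite-cost labeling for gene ", genes[j])
    lab <- integer(ntip + nnode)
    cand <- which(S[root, ] == best)
    lab[root] <- cand[which.min(prio[cand])]
    for (r in seq_len(nrow(pre))) {
      p <- pre[r, 1L]; ch <- pre[r, 2L]
      v <- cost[lab[p], ] + S[ch, ]
      cand <- which(v == min(v))
      lab[ch] <- cand[which.min(prio[cand])]
    }
    anc[, j] <- .MTL[lab[root:(ntip + nnode)]]
    tip_out[, j] <- .MTL[lab[seq_len(ntip)]]
    gcost[j] <- best
    from <- .MTL[lab[pre[, 1L]]]
    to <- .MTL[lab[pre[, 2L]]]
    chg <- which(from != to)
    if (length(chg))
      ev[[j]] <- data.frame(branch = node_names[pre[chg, 2L]],
                            gene_id = genes[j],
                            event = .event_type(from[chg], to[chg]),
                            from = from[chg], to = to[chg],
                            stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1L))])
  if (is.null(events))
    events <- data.frame(branch = character(0), gene_id = character(0),
                         event = character(0), from = character(0),
                         to = character(0), stringsAsFactors = FALSE)
  structure(list(tree = tree, anc_states = anc, tip_states = tip_out,
                 events = events, cost = gcost),
            class = "sankoff_fit")
}

#' @export
print.sankoff_fit <- function(x, ...) {
  cat("Sankoff reconstruction:", ncol(x$anc_states), "genes on",
      ape::Ntip(x$tree), "tips;", nrow(x$events), "events; total cost",
      sum(x$cost), "\n")
  invisible(x)
}

#' Replay a branch event table into tip states
#'
#' Forward simulation of an event table on a tree: the root carries the full
#' ancestral panel in state M; walking the tree in preorder, each branch's
#' events are applied (transfer M->T, loss M->L or T->L).  Events implying a
#' reversal (transfer of a non-M gene, loss of an already-lost gene) raise a
#' validation error.
#'
#' @param tree Rooted [ape::phylo] tree with (or auto-assigned) internal
#'   node labels.
#' @param events Data frame with columns `branch` (child-node name),
#'   `gene_id`, `event` (`transfer`/`loss`).
#' @param panel Character vector of ancestral gene ids (or a data frame with
#'   a `gene_id` column).
#' @return Species-by-gene character state matrix at the tips.
#' @export
apply_events <- function(tree, events, panel) {
  if (is.data.frame(panel)) panel <- panel$gene_id
  stopifnot(is.character(panel), !anyDuplicated(panel))
  tree <- name_internal_nodes(tree)
  ntip <- ape::Ntip(tree)
  node_names <- c(tree$tip.label, tree$node.label)
  if (nrow(events)) {
    bad <- setdiff(unique(events$branch), node_names[-(ntip + 1L)])
    if (length(bad))
      stop("event branch id(s) not in tree: ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(events$gene_id), panel)
    if (length(bad))
      stop("event gene id(s) not in panel: ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(events$event), c("transfer", "loss"))
    if (length(bad))
      stop("unknown event type(s): ", paste(bad, collapse = ", "))
  }
  pre <- stats::reorder(tree, "cladewise")$edge
  st <- matrix(NA_character_, ntip + tree$Nnode, length(panel),
               dimnames = list(node_names, panel))
  st[ntip + 1L, ] <- "M"
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1L]; ch <- pre[r, 2L]
    s <- st[p, ]
    here <- events[events$branch == node_names[ch], , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      g <- here$gene_id[i]
      if (here$event[i] == "transfer") {
        if (s[g] != "M")
          stop("invalid transfer of ", g, " on branch ", node_names[ch],
               ": parent state is ", s[g], " (reversals are forbidden)")
        s[g] <- "T"
      } else {
        if (!s[g] %in% c("M", "T"))
          stop("invalid loss of ", g, " on branch ", node_names[ch],
               ": gene already lost")
        s[g] <- "L"
      }
    }
    st[ch, ] <- s
  }
  st[seq_len(ntip), , drop = FALSE]
}

#' The 41-gene ancestral mitochondrial panel of seed plants
#'
#' Protein-coding genes inferred present in the seed-plant common ancestor:
#' ATP synthase (atp1-atp9), cytochrome c maturation (ccmB-ccmFn), complex
#' III/IV (cob, cox1-3), the maturase matR and transport protein mttB, NADH
#' dehydrogenase (nad1-nad9), ribosomal proteins (rpl and rps series) and
#' succinate dehydrogenase (sdh3, sdh4).
#'
#' @return Data frame with `gene_id` and functional `category` (41 rows).
#' @export
mito_gene_panel <- function() {
  genes <- c("atp1", "atp4", "atp6", "atp8", "atp9",
             "ccmB", "ccmC", "ccmFc", "ccmFn",
             "cob", "cox1", "cox2", "cox3",
             "matR", "mttB",
             "nad1", "nad2", "nad3", "nad4", "nad4L",
             "nad5", "nad6", "nad7", "nad9",
             "rpl2", "rpl5", "rpl10", "rpl16",
             "rps1", "rps2", "rps3", "rps4", "rps7", "rps10", "rps11",
             "rps12", "rps13", "rps14", "rps19",
             "sdh3", "sdh4")
  category <- rep("other", length(genes))
  category[startsWith(genes, "rps")] <- "ribosomal_small"
  category[startsWith(genes, "rpl")] <- "ribosomal_large"
  category[startsWith(genes, "nad")] <- "complexI"
  category[startsWith(genes, "sdh")] <- "complexII"
  category[genes == "cob"] <- "complexIII"
  category[startsWith(genes, "cox")] <- "complexIV"
  category[startsWith(genes, "atp")] <- "complexV"
  category[startsWith(genes, "ccm")] <- "cytochrome_maturation"
  data.frame(gene_id = genes, category = category, stringsAsFactors = FALSE)
}

.gymno_newick <- local({
  cycads_ginkgo <- "((Cycas,Zamia)Cycadales,Ginkgo)CycadsGinkgo"
  pinaceae <- "((Abies,Cedrus)AbiesCedrus,(Picea,Pinus)PiceaPinus)Pinaceae"
  gnetales <- "(Ephedra,(Gnetum,Welwitschia)GnetumWelwitschia)Gnetales"
  taxaceae <- "(Taxus,(Torreya,Amentotaxus)TorreyaAmentotaxus)Taxaceae"
  core_cup <- paste0("((", taxaceae, ",Cephalotaxus)TaxadClade,",
                     "(Cupressus,Juniperus)Cupressaceae)CoreCupressophytes")
  conifer2 <- paste0("((Araucaria,Podocarpus)AraucariaPodocarpus,",
                     "(Sciadopitys,", core_cup, ")SciadoCore)ConiferII")
  paste0("(", cycads_ginkgo, ",((", pinaceae, ",", gnetales, ")Gnepine,",
         conifer2, ")Conifers)Gymnosperms;")
})

#' Curated gymnosperm transfer/loss event table
#'
#' A 19-genus species tree covering all 13 gymnosperm families under the
#' Gnepine hypothesis (Gnetales sister to Pinaceae), the 41-gene ancestral
#' panel, and the branch events of mitochondrial gene transfer/loss in
#' gymnosperms: seven transfers in the Conifer II ancestor (rpl2, rps1,
#' rps2, rps7, rps10, rps11, rps14); sdh3 transferred within Conifer II
#' excluding Araucaria and Podocarpus, and in the Gnetales ancestor; rpl10
#' lost everywhere in Conifer II except Sciadopitys; six losses (rpl2,
#' rpl5, rpl16, rps7, rps13, rps19) plus six transfers (rps1, rps2, rps10,
#' rps11, rps14, sdh3) in the Gnetales ancestor; and, in Ephedra, loss of
#' ccmB, matR, mttB, rpl10, rps3 and rps4 plus transfer of rps12.  The
#' Ephedra absences are flagged `putative` (undetected fast-evolving
#' nuclear copies cannot be excluded); the flag annotates confidence and
#' does not change the state.
#'
#' Replaying the table with [apply_events()] yields 41 state-M genes in
#' cycads, Ginkgo and Pinaceae, 33 in Araucaria/Podocarpus/Sciadopitys, 32
#' in the remaining Conifer II genera (and in the intersection over all of
#' Conifer II), 29 in Gnetum and Welwitschia, and 22 in Ephedra.
#'
#' @return List with `tree` ([ape::phylo]), `events` (data frame `branch`,
#'   `gene_id`, `event`, `confidence`), `panel` (from [mito_gene_panel()])
#'   and `clades` (named list of tip sets).
#' @export
gymnosperm_fixture <- function() {
  tree <- name_internal_nodes(ape::read.tree(text = .gymno_newick))
  ev <- function(branch, genes, event)
    data.frame(branch = branch, gene_id = genes, event = event,
               stringsAsFactors = FALSE)
  events <- rbind(
    ev("ConiferII", c("rpl2", "rps1", "rps2", "rps7", "rps10", "rps11",
                      "rps14"), "transfer"),
    ev("SciadoCore", "sdh3", "transfer"),
    ev("AraucariaPodocarpus", "rpl10", "loss"),
    ev("CoreCupressophytes", "rpl10", "loss"),
    ev("Gnetales", c("rpl2", "rpl5", "rpl16", "rps7", "rps13", "rps19"),
       "loss"),
    ev("Gnetales", c("rps1", "rps2", "rps10", "rps11", "rps14", "sdh3"),
       "transfer"),
    ev("Ephedra", c("ccmB", "matR", "mttB", "rpl10", "rps3", "rps4"),
       "loss"),
    ev("Ephedra", "rps12", "transfer"))
  events$confidence <- ifelse(events$branch == "Ephedra" &
                                events$event == "loss",
                              "putative", "supported")
  clades <- list(
    cycads = c("Cycas", "Zamia"),
    ginkgo = "Ginkgo",
    pinaceae = c("Abies", "Cedrus", "Picea", "Pinus"),
    gnetales = c("Ephedra", "Gnetum", "Welwitschia"),
    conifer2 = c("Araucaria", "Podocarpus", "Sciadopitys", "Taxus",
                 "Torreya", "Amentotaxus", "Cephalotaxus", "Cupressus",
                 "Juniperus"))
  list(tree = tree, events = events, panel = mito_gene_panel(),
       clades = clades)
}
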