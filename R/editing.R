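# C-to-U RNA editing site calling from paired DNA/cDNA coding sequences,
# and the three-class comparison of transferred-gene bases against the
# editing sites of their mitochondrial reference homologs.

#' Call RNA editing sites from a paired DNA/cDNA coding sequence
#'
#' A C-to-U editing site is a position where the DNA has C and the cDNA T;
#' the (rare) reverse U-to-C direction is a DNA T with a cDNA C.  Any other
#' mismatch is a discordance, never an edit, which guards against
#' substitution noise.  Sequences must be intron-excised and equal length.
#'
#' @param cds_dna Genomic coding sequence (introns excised).
#' @param cds_cdna Matching cDNA sequence.
#' @param gene_id Gene id attached to the output.
#' @return Data frame of sites: `gene_id`, `cds_position` (1-based),
#'   `direction` (`CtoU`/`UtoC`), `codon_position` (1-3), with non-editing
#'   mismatches in `attr(, "discordances")`.
#' @export
call_editing <- function(cds_dna, cds_cdna, gene_id = "gene") {
  cds_dna <- toupper(cds_dna)
  cds_cdna <- toupper(cds_cdna)
  if (nchar(cds_dna) != nchar(cds_cdna))
    stop("DNA and cDNA lengths differ (", nchar(cds_dna), " vs ",
         nchar(cds_cdna), "); excise introns before calling editing sites")
  if (nchar(cds_dna) %% 3L != 0L)
    stop("CDS length must be a multiple of 3")
  d <- .chars(cds_dna)
  r <- .chars(cds_cdna)
  mism <- which(d != r)
  ctou <- mism[d[mism] == "C" & r[mism] == "T"]
  utoc <- mism[d[mism] == "T" & r[mism] == "C"]
  other <- setdiff(mism, c(ctou, utoc))
  pos <- c(ctou, utoc)
  ord <- order(pos)
  sites <- data.frame(
    gene_id = rep(gene_id, length(pos)),
    cds_position = pos[ord],
    direction = c(rep("CtoU", length(ctou)),
                  rep("UtoC", length(utoc)))[ord],
    codon_position = (pos[ord] - 1L) %% 3L + 1L,
    stringsAsFactors = FALSE)
  attr(sites, "discordances") <- data.frame(
    gene_id = rep(gene_id, length(other)),
    cds_position = other,
    dna = d[other], cdna = r[other], stringsAsFactors = FALSE)
  sites
}

# map reference positions to positions in another sequence via global
# alignment (match 1, mismatch -1, gap open 5, gap extend 1)
.align_position_map <- function(seq_from_ref_to, ref) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(seq_from_ref_to),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 1)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .chars(as.character(Biostrings::alignedSubject(aln)))
  ip <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  map <- rep(NA_integer_, nchar(ref))
  sel <- pb != "-" & pa != "-"
  map[ib[sel]] <- ip[sel]
  list(map = map,
       identity = {
         both <- pa != "-" & pb != "-"
         if (any(both)) mean(pa[both] == pb[both]) else 0
       })
}

#' Compare a transferred gene to its mitochondrial reference editing sites
#'
#' For each editing site of the mitochondrial reference, reports what the
#' transferred homolog carries at the aligned position: `converted_C_to_T`
#' (the retroprocessing signature: the edited state is hardened in the
#' DNA), `unedited_C` (DNA C, cDNA C or cDNA absent), `edited` (DNA C,
#' cDNA T), or `other` (alignment gap or a different base; gaps are
#' flagged).
#'
#' @param transferred_dna Transferred gene's coding DNA.
#' @param reference_dna Mitochondrial reference coding DNA (positions of
#'   `reference_sites` refer to this sequence).
#' @param reference_sites Integer vector of reference editing-site
#'   positions (1-based), or a data frame with a `cds_position` column.
#' @param transferred_cdna Optional cDNA of the transferred gene.
#' @param gene_id Gene id attached to the output.
#' @return Data frame: `gene_id`, `reference_position`, `class`,
#'   `in_gap`.
#' @export
compare_to_reference <- function(transferred_dna, reference_dna,
                                 reference_sites,
                                 transferred_cdna = NULL,
                                 gene_id = "gene") {
  if (is.data.frame(reference_sites))
    reference_sites <- reference_sites$cds_position
  al <- .align_position_map(transferred_dna, reference_dna)
  d <- .chars(toupper(transferred_dna))
  r <- if (!is.null(transferred_cdna)) .chars(toupper(transferred_cdna))
  rows <- lapply(reference_sites, function(p) {
    q <- if (p <= length(al$map)) al$map[p] else NA_integer_
    if (is.na(q))
      return(data.frame(gene_id = gene_id, reference_position = p,
                        class = "other", in_gap = TRUE,
                        stringsAsFactors = FALSE))
    base <- d[q]
    cls <- if (base == "T") "converted_C_to_T"
    else if (base == "C") {
      if (is.null(r)) "unedited_C"
      else if (r[q] == "T") "edited"
      else if (r[q] == "C") "unedited_C"
      else "other"
    } else "other"
    data.frame(gene_id = gene_id, reference_position = p, class = cls,
               in_gap = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-species, per-gene editing-site counts
#'
#' Tabulates called sites over an explicit species x gene grid; species or
#' genes without any site keep their zero rows, since absence of editing
#' (as in retroprocessed transferred genes) is itself the signal.
#'
#' @param sites Data frame with `species` and `gene_id` columns (one row
#'   per called site).
#' @param species,genes Level sets for the grid (defaults: observed
#'   values).
#' @return Data frame: `species`, `gene_id`, `n_sites`, complete over the
#'   grid.
#' @export
editing_summary <- function(sites, species = NULL, genes = NULL) {
  if (is.null(species)) species <- sort(unique(sites$species))
  if (is.null(genes)) genes <- sort(unique(sites$gene_id))
  tab <- table(factor(sites$species, levels = species),
               factor(sites$gene_id, levels = genes))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("species", "gene_id", "n_sites")
  out$n_sites <- as.integer(out$n_sites)
  out[order(out$species, out$gene_id), , drop = FALSE]
}
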