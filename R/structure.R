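# Exon/intron structure inference by greedy chaining of cDNA segments
# onto genomic scaffolds: intron phases, cis- vs trans-splicing mode, and
# N-terminal presequence extensions of transferred genes.

# find the best placement of cdna[pos..] among all scaffolds/strands:
# probe of length min_exon (allowing probe_mismatch mismatches), then
# X-drop rightward extension.
.best_extension <- function(qchars, pos, scaffold_chars, min_exon,
                            probe_mismatch = 2L) {
  probe <- paste(qchars[pos:(pos + min_exon - 1L)], collapse = "")
  best <- NULL
  for (sc in names(scaffold_chars)) {
    for (strand in c("+", "-")) {
      subj <- scaffold_chars[[sc]][[if (strand == "+") "fwd" else "rev"]]
      m <- Biostrings::matchPattern(probe, subj$seq,
                                    max.mismatch = probe_mismatch)
      starts <- Biostrings::start(m)
      if (length(starts) > 50L) starts <- starts[seq_len(50L)]
      for (st in starts) {
        ext <- .extend_match(qchars, pos, subj$chars, st)
        if (ext < min_exon) next
        if (is.null(best) || ext > best$len) {
          best <- list(len = ext, scaffold = sc, strand = strand,
                       subj_start = st)
        }
      }
    }
  }
  best
}

# X-drop extension from (qpos, spos): score +1 per match, -penalty per
# mismatch; the exon ends at the earliest maximum of the cumulative score,
# so isolated mismatches (RNA-edited positions, light substitution noise)
# are crossed while the dense mismatches past an intron boundary or into
# unrelated sequence terminate the exon at the boundary itself.
.extend_match <- function(qchars, qpos, schars, spos,
                          mismatch_penalty = 8, xdrop = 40) {
  n <- min(length(qchars) - qpos, length(schars) - spos) + 1L
  if (n <= 0L) return(0L)
  qs <- qchars[qpos + 0:(n - 1L)]
  ss <- schars[spos + 0:(n - 1L)]
  sc <- ifelse(qs == ss, 1, -mismatch_penalty)
  cum <- cumsum(sc)
  stop_at <- which(cum < cummax(cum) - xdrop)[1L]
  if (!is.na(stop_at)) cum <- cum[seq_len(stop_at)]
  best <- which.max(cum)
  if (cum[best] <= 0) return(0L)
  best
}

#' Map a cDNA onto genomic scaffolds as chained exons
#'
#' Greedy left-to-right chaining of maximal cDNA segments onto the
#' scaffolds, both strands.  Matching is seeded with an exact
#' `min_exon`-length probe (up to 2 mismatches, so editing sites near exon
#' starts do not break the seed) and extended until a dense mismatch run
#' (an intron boundary or unrelated sequence); isolated mismatches --
#' genomic C versus edited cDNA T -- are crossed.  Every cDNA base ends up
#' in exactly one exon or is flagged unplaced; genes with under
#' `min_placed` of their cDNA placed get a structural-failure flag and are
#' excluded from intron statistics.
#'
#' @param cdna cDNA sequence of one gene.
#' @param scaffolds Named character vector of genomic scaffolds.
#' @param min_exon Minimum exon (and probe) length, nt.
#' @param min_placed Minimum placed fraction before the gene is flagged.
#' @param gene_id Gene id attached to the output.
#' @return List of class `exon_map`: `exons` (data frame `gene_id`,
#'   `ordinal`, `scaffold_id`, `start`, `end` 0-based half-open, `strand`,
#'   `q_start`, `q_end` 1-based in the cDNA), `unplaced` (integer
#'   positions), `placed_fraction`, `structural_failure`.
#' @export
map_exons <- function(cdna, scaffolds, min_exon = 20L, min_placed = 0.9,
                      gene_id = "gene") {
  stopifnot(nchar(cdna) >= min_exon)
  qchars <- .chars(toupper(cdna))
  qlen <- length(qchars)
  scaffold_chars <- lapply(names(scaffolds), function(sc) {
    fwd <- toupper(scaffolds[[sc]])
    rev <- revcomp(fwd)
    list(fwd = list(seq = fwd, chars = .chars(fwd)),
         rev = list(seq = rev, chars = .chars(rev)))
  })
  names(scaffold_chars) <- names(scaffolds)
  exons <- list()
  unplaced <- integer(0)
  pos <- 1L
  while (pos + min_exon - 1L <= qlen) {
    hit <- .best_extension(qchars, pos, scaffold_chars, min_exon)
    if (is.null(hit)) {
      unplaced <- c(unplaced, pos)
      pos <- pos + 1L
      next
    }
    slen <- nchar(scaffolds[[hit$scaffold]])
    if (hit$strand == "+") {
      start0 <- hit$subj_start - 1L
      end0 <- start0 + hit$len
    } else {
      # coordinates on the forward strand
      end0 <- slen - hit$subj_start + 1L
      start0 <- end0 - hit$len
    }
    exons[[length(exons) + 1L]] <- data.frame(
      gene_id = gene_id, ordinal = length(exons) + 1L,
      scaffold_id = hit$scaffold, start = start0, end = end0,
      strand = hit$strand, q_start = pos, q_end = pos + hit$len - 1L,
      stringsAsFactors = FALSE)
    pos <- pos + hit$len
  }
  if (pos <= qlen) unplaced <- c(unplaced, pos:qlen)
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(gene_id = character(0), ordinal = integer(0),
               scaffold_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               q_start = integer(0), q_end = integer(0),
               stringsAsFactors = FALSE)
  placed <- if (nrow(exons)) sum(exons$q_end - exons$q_start + 1L) else 0L
  structure(list(exons = exons, unplaced = unplaced,
                 placed_fraction = placed / qlen,
                 structural_failure = placed / qlen < min_placed,
                 gene_id = gene_id, cdna_length = qlen),
            class = "exon_map")
}

#' Extract the spliced genomic coding sequence from an exon map
#'
#' Concatenates the genomic exon sequences in ordinal order; for unflagged
#' genes this reconstitutes a sequence colinear with the cDNA, differing
#' only at RNA-edited positions.
#'
#' @param exon_map From [map_exons()].
#' @param scaffolds The scaffolds the map refers to.
#' @return Nucleotide string.
#' @export
spliced_genomic_cds <- function(exon_map, scaffolds) {
  ex <- exon_map$exons
  parts <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    s <- substr(scaffolds[[ex$scaffold_id[i]]], ex$start[i] + 1L,
                ex$end[i])
    if (ex$strand[i] == "-") s <- revcomp(s)
    parts[i] <- s
  }
  paste(parts, collapse = "")
}

#' Infer introns from chained exon placements
#'
#' Between consecutive exons: cis when both sit on the same scaffold and
#' strand, colinear, with a genomic gap of at least 1 nt (the gap is the
#' intron length); trans otherwise (length unknown, reported `NA`).  The
#' insertion point is the cumulative exon length (1-based nt offset in the
#' CDS) and the phase is `insertion_point mod 3`, matching the
#' geneID + "i" + offset intron naming convention.
#'
#' @param exon_map From [map_exons()] (a structural-failure flag excludes
#'   the gene: an empty table is returned with a warning).
#' @return Data frame: `gene_id`, `index`, `name`, `insertion_point`,
#'   `phase`, `mode`, `length`.
#' @export
infer_introns <- function(exon_map) {
  empty <- data.frame(gene_id = character(0), index = integer(0),
                      name = character(0), insertion_point = integer(0),
                      phase = integer(0), mode = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (exon_map$structural_failure) {
    warning("gene ", exon_map$gene_id,
            " has a structural failure; no intron calls")
    return(empty)
  }
  ex <- exon_map$exons
  if (nrow(ex) < 2L) return(empty)
  if (any(ex$q_start[-1L] <= ex$q_end[-nrow(ex)]))
    stop("overlapping exons in cDNA coordinates")
  rows <- list()
  for (i in seq_len(nrow(ex) - 1L)) {
    a <- ex[i, ]; b <- ex[i + 1L, ]
    ip <- a$q_end           # cumulative exon length
    cis <- a$scaffold_id == b$scaffold_id && a$strand == b$strand &&
      ((a$strand == "+" && b$start >= a$end + 1L) ||
         (a$strand == "-" && a$start >= b$end + 1L))
    len <- if (!cis) NA_integer_ else if (a$strand == "+")
      b$start - a$end else a$start - b$end
    rows[[i]] <- data.frame(
      gene_id = a$gene_id, index = i,
      name = paste0(a$gene_id, "i", ip),
      insertion_point = ip, phase = ip %% 3L,
      mode = if (cis) "cis" else "trans",
      length = len, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Detect an N-terminal presequence extension on a transferred gene
#'
#' Globally aligns the transferred coding sequence to its mitochondrial
#' homolog; the extension length is the number of transferred-gene 5'
#' nucleotides upstream of the aligned homolog start, and the extension is
#' in frame when that length is a multiple of 3.  Alignments under
#' `min_identity` are refused as unreliable.
#'
#' @param transferred_cds Transferred gene's coding sequence (cDNA).
#' @param mito_homolog_cds Mitochondrial homolog coding sequence.
#' @param min_identity Minimum alignment identity (default 0.4).
#' @param gene_id Gene id attached to the output.
#' @return Data frame: `gene_id`, `extension_length_nt`, `in_frame`,
#'   `identity`.
#' @export
detect_presequence <- function(transferred_cds, mito_homolog_cds,
                               min_identity = 0.4, gene_id = "gene") {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(transferred_cds)),
    subject = Biostrings::DNAString(toupper(mito_homolog_cds)),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 1)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .chars(as.character(Biostrings::alignedSubject(aln)))
  # matches over all alignment columns (gap columns count against the
  # identity, so unrelated sequences cannot sneak past via gap placement)
  identity <- mean(pa == pb & pa != "-")
  if (identity < min_identity)
    stop("homolog alignment identity ", round(identity, 3), " below ",
         min_identity, "; presequence detection refused for ", gene_id)
  lead <- which(pb != "-")[1L] - 1L      # alignment columns before homolog
  ext <- sum(pa[seq_len(lead)] != "-")   # transferred bases among them
  data.frame(gene_id = gene_id, extension_length_nt = ext,
             in_frame = ext %% 3L == 0L, identity = identity,
             stringsAsFactors = FALSE)
}
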