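# Shared primitive types and file formats.
#
# Coordinates are 0-based half-open internally (homolog hits, exon
# placements); user-facing tables report CDS positions 1-based from the CDS
# start, matching the geneID + "i" + offset intron naming convention
# (e.g. nad2i542).  Ambiguity codes other than N are rejected.

#' Gene states used throughout the package
#'
#' `"M"` mitochondrion-encoded, `"T"` transferred to the nucleus, `"L"` lost
#' from both compartments, `"U"` unknown/ambiguous.  `"U"` is only legal in
#' observed tip matrices, never in reconstructed ancestral labelings.
#' @export
STATE_LEVELS <- c("M", "T", "L", "U")

.MTL <- c("M", "T", "L")
.DNA_OK <- "ACGTN"

#' Read a FASTA file into a named character vector
#'
#' Thin validation wrapper around [Biostrings::readBStringSet()]: sequences
#' are uppercased, ids are the first whitespace-delimited header token,
#' duplicate ids and characters outside `{A,C,G,T,N}` are rejected, and
#' malformed leading/blank-line records are reported with their line number.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_check Reject characters outside `{A,C,G,T,N}` (default
#'   `TRUE`; set `FALSE` for protein FASTA).
#' @return Named character vector of uppercase sequences (empty for an
#'   empty file).
#' @export
read_fasta <- function(path, alphabet_check = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  filled <- nzchar(trimws(lines))
  if (!any(filled)) return(stats::setNames(character(0), character(0)))
  first <- which(filled)[1L]
  if (!startsWith(lines[[first]], ">"))
    stop("malformed FASTA record at line ", first,
         ": expected a '>' header before sequence data")
  last <- max(which(filled))
  inner_blank <- which(!filled)
  inner_blank <- inner_blank[inner_blank > first & inner_blank < last]
  if (length(inner_blank))
    stop("malformed FASTA record at line ", inner_blank[1L],
         ": blank line inside a record")
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  names(out) <- ids
  if (alphabet_check) {
    bad <- grepl(paste0("[^", .DNA_OK, "]"), out)
    if (any(bad))
      stop("sequence(s) with characters outside {A,C,G,T,N}: ",
           paste(ids[bad], collapse = ", "),
           " (ambiguity codes other than N are rejected)")
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(names(seqs)) == length(seqs))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a rooted species tree from a newick file
#'
#' Wraps [ape::read.tree()].  Exactly one tree per file is allowed;
#' unbalanced parentheses raise a parse error.  Unlabeled internal nodes are
#' auto-named deterministically (`node<k>` by preorder index), so branch ids
#' (child-node names) are stable across runs.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree with all internal nodes labeled.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty newick file: ", path)
  n_open <- nchar(gsub("[^(]", "", txt))
  n_close <- nchar(gsub("[^)]", "", txt))
  if (n_open != n_close)
    stop("newick parse error: unbalanced parentheses (", n_open,
         " '(' vs ", n_close, " ')')")
  if (nchar(gsub("[^;]", "", txt)) > 1L)
    stop("expected a single tree per file: ", path)
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error in ", path)
  name_internal_nodes(tr)
}

#' Write a tree to newick, keeping internal node labels
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Deterministically label unlabeled internal nodes
#'
#' Unlabeled (or `NA`/empty) internal nodes are named `node<k>` where `k` is
#' the node's preorder index among internal nodes, so repeated reads of the
#' same newick string always produce the same branch ids.
#'
#' @param tree An [ape::phylo] tree.
#' @return The tree with a complete, unique `node.label`.
#' @export
name_internal_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  edge <- stats::reorder(tree, "cladewise")$edge
  ord <- unique(edge[, 1L])          # internal nodes in preorder
  for (k in seq_along(ord)) {
    i <- ord[k] - ntip
    if (!nzchar(lab[i])) lab[i] <- paste0("node", k)
  }
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("node labels not unique after auto-naming")
  tree$node.label <- lab
  tree
}

#' Read / write a species-by-gene state matrix (TSV)
#'
#' The TSV has one `species` column followed by one column per gene; cells
#' are states in `M`, `T`, `L`, `U`.  `write_state_matrix()` followed by
#' `read_state_matrix()` is the identity for valid matrices.
#'
#' @param path Path to the TSV file.
#' @return A character matrix, species as rows, genes as columns.
#' @export
read_state_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("state matrix TSV needs a species column plus gene columns")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  validate_state_matrix(m)
  m
}

#' @rdname read_state_matrix
#' @param m State matrix (species x genes).
#' @export
write_state_matrix <- function(m, path) {
  validate_state_matrix(m)
  df <- data.frame(species = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a state matrix
#'
#' @param m Character matrix, species x genes.
#' @param allow_U Allow the explicit unknown state `"U"` (legal for observed
#'   tip matrices only).
#' @return `m`, invisibly; errors on unknown symbols, missing dimnames or
#'   duplicated ids.
#' @export
validate_state_matrix <- function(m, allow_U = TRUE) {
  if (!is.matrix(m) || !is.character(m))
    stop("state matrix must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("state matrix needs species rownames and gene colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate species ids")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids")
  allowed <- if (allow_U) STATE_LEVELS else .MTL
  bad <- setdiff(unique(as.vector(m)), allowed)
  if (length(bad))
    stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  invisible(m)
}

#' Read / write a branch event table (TSV)
#'
#' Columns `branch` (child-node name), `gene_id`, `event`
#' (`transfer`/`loss`); extra columns are preserved.
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_event_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("branch", "gene_id", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$event), c("transfer", "loss"))
  if (length(bad))
    stop("unknown event type(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_event_table
#' @param events Event data frame.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences (names preserved).
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# split a sequence into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
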