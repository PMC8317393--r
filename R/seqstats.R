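# Gene-level sequence statistics: GC content by codon position,
# Kyte-Doolittle GRAVY hydropathy, Nei-Gojobori dN/dS with Jukes-Cantor
# correction, and time-normalised absolute substitution rates.

#' Kyte-Doolittle hydropathy values
#'
#' The standard per-residue hydropathy scale (positive = hydrophobic), as
#' used by ProtParam's GRAVY.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' GC content overall and by codon position
#'
#' Fractions of G/C at all positions and at codon positions 1-3.  `N` bases
#' are excluded from both numerator and denominator, so the overall GC is
#' the codon-position GCs weighted by their non-N base counts.
#'
#' @param cds Nucleotide string whose length is a multiple of 3.
#' @return Named numeric vector `GC`, `GC1`, `GC2`, `GC3`.
#' @export
gc_by_codon_position <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop("CDS length (", n, ") is not a positive multiple of 3")
  b <- .chars(toupper(cds))
  if (any(!b %in% c("A", "C", "G", "T", "N")))
    stop("CDS contains characters outside {A,C,G,T,N}")
  keep <- b != "N"
  pos <- rep_len(1:3, n)
  gc <- b %in% c("G", "C")
  per <- vapply(1:3, function(k) {
    i <- keep & pos == k
    if (!any(i)) NA_real_ else mean(gc[i])
  }, numeric(1L))
  c(GC = if (any(keep)) mean(gc[keep]) else NA_real_,
    GC1 = per[1L], GC2 = per[2L], GC3 = per[3L])
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over a protein's residues.
#'
#' @param protein Amino-acid string over the standard 20-letter alphabet.
#' @return GRAVY value (typically between -2 and +2).
#' @export
gravy <- function(protein) {
  if (!nzchar(protein)) stop("GRAVY is undefined for an empty protein")
  aa <- .chars(toupper(protein))
  h <- KYTE_DOOLITTLE[aa]
  if (anyNA(h))
    stop("nonstandard residue(s): ",
         paste(unique(aa[is.na(h)]), collapse = ", "))
  mean(h)
}

# ---- Nei-Gojobori (1986) ------------------------------------------------

.genetic_code <- function() Biostrings::GENETIC_CODE

# per-codon count of synonymous sites: at each codon position, the fraction
# of the three possible single-base changes that preserve the amino acid.
# Changes creating a stop codon count as nonsynonymous, so sites per codon
# always sum to 3.
.syn_site_table <- function() {
  if (!is.null(.mt_cache$syn_sites)) return(.mt_cache$syn_sites)
  gc <- .genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  s <- stats::setNames(rep(NA_real_, length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") next
    tot <- 0
    for (p in 1:3) for (b in bases) {
      if (b == substr(cd, p, p)) next
      alt <- cd
      substr(alt, p, p) <- b
      if (gc[[alt]] == gc[[cd]]) tot <- tot + 1
    }
    s[cd] <- tot / 3
  }
  .mt_cache$syn_sites <- s
  s
}

.perms <- list(`1` = list(1L),
               `2` = list(1:2, 2:1),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# average synonymous/nonsynonymous differences between two codons over all
# mutational pathways; pathways passing through a stop codon are excluded
# unless every pathway does.
.codon_path_diffs <- function(c1, c2) {
  gc <- .genetic_code()
  a <- .chars(c1); b <- .chars(c2)
  diff <- which(a != b)
  if (!length(diff)) return(c(sd = 0, nd = 0))
  res <- matrix(NA_real_, 0L, 2L)
  res_stop <- matrix(NA_real_, 0L, 2L)
  for (ord in .perms[[as.character(length(diff))]]) {
    cur <- a
    sd <- nd <- 0
    through_stop <- FALSE
    for (p in diff[ord]) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*") through_stop <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (through_stop) res_stop <- rbind(res_stop, c(sd, nd))
    else res <- rbind(res, c(sd, nd))
  }
  if (!nrow(res)) res <- res_stop
  c(sd = mean(res[, 1L]), nd = mean(res[, 2L]))
}

.jc_correct <- function(p) {
  if (p >= 0.75) NA_real_ else -0.75 * log1p(-4 * p / 3)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Synonymous and nonsynonymous site counts (`S`, `N`) are averaged over
#' both sequences by single-base mutation-fate enumeration (mutations to
#' stop codons count as nonsynonymous, so each codon contributes 3 sites);
#' observed differences (`Sd`, `Nd`) are averaged over all mutational
#' pathways between differing codons, excluding pathways through stop
#' codons when possible.  Proportions are Jukes-Cantor corrected,
#' `d = -3/4 log(1 - 4p/3)`; a proportion at or beyond the correction's
#' domain (`p >= 3/4`) is reported as saturated (`NA` distance).
#'
#' A shared terminal stop codon is dropped; internal stop codons are an
#' error.
#'
#' @param cds_a,cds_b Equal-length, gap-stripped, codon-aligned nucleotide
#'   strings.
#' @return List with `dN`, `dS`, `Nd`, `Sd`, `N`, `S`, and logical
#'   `saturated_N`, `saturated_S`.
#' @export
nei_gojobori <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must be equal length (codon-aligned, gap-stripped)")
  if (nchar(cds_a) %% 3L != 0L || nchar(cds_a) == 0L)
    stop("sequence length must be a positive multiple of 3")
  if (grepl("[^ACGT]", cds_a) || grepl("[^ACGT]", cds_b))
    stop("sequences must contain only A/C/G/T")
  gc <- .genetic_code()
  split_codons <- function(x)
    substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  nc <- length(ca)
  if (gc[ca[nc]] == "*" && gc[cb[nc]] == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]; nc <- nc - 1L
    if (!nc) stop("no codons left after dropping the terminal stop")
  }
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop("internal stop codon encountered")
  syn <- .syn_site_table()
  S <- (sum(syn[ca]) + sum(syn[cb])) / 2
  N <- 3 * nc - S
  Sd <- Nd <- 0
  for (i in which(ca != cb)) {
    d <- .codon_path_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  list(dN = .jc_correct(pN), dS = .jc_correct(pS),
       Nd = Nd, Sd = Sd, N = N, S = S,
       saturated_N = pN >= 0.75, saturated_S = pS >= 0.75)
}

#' Absolute substitution rates per branch
#'
#' Divides substitution rates by lineage divergence times:
#' `RN = dN / T`, `RS = dS / T` (substitutions per site per Myr).
#'
#' @param estimates Data frame with columns `gene_id`, `lineage`, `dN`,
#'   `dS`.
#' @param times Divergence times in Myr: a named numeric vector over
#'   lineages, or a data frame with columns `lineage` and `time_myr`.
#' @return `estimates` with `divergence_time`, `RN` and `RS` columns added.
#' @export
absolute_rates <- function(estimates, times) {
  stopifnot(all(c("gene_id", "lineage", "dN", "dS") %in% names(estimates)))
  if (is.data.frame(times)) {
    stopifnot(all(c("lineage", "time_myr") %in% names(times)))
    times <- stats::setNames(times$time_myr, times$lineage)
  }
  miss <- setdiff(unique(estimates$lineage), names(times))
  if (length(miss))
    stop("missing divergence time for lineage(s): ",
         paste(miss, collapse = ", "))
  tt <- times[estimates$lineage]
  if (any(tt <= 0)) stop("divergence times must be > 0")
  estimates$divergence_time <- unname(tt)
  estimates$RN <- estimates$dN / estimates$divergence_time
  estimates$RS <- estimates$dS / estimates$divergence_time
  estimates
}

#' Read a divergence-time table (TSV with columns lineage, time_myr)
#' @param path Path to the TSV file.
#' @return Data frame with `lineage` and `time_myr`.
#' @export
read_divergence_times <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("lineage", "time_myr") %in% names(df)))
    stop("divergence-time TSV needs columns 'lineage' and 'time_myr'")
  df
}

#' Sequence statistics for a set of coding sequences
#'
#' Length, GC content by codon position, and GRAVY of the translation for
#' each CDS.  Sequences with untranslatable codons (internal stops, N runs)
#' get `NA` GRAVY.  A terminal stop codon is excluded from the translation.
#'
#' @param cds Named character vector of coding sequences (lengths multiples
#'   of 3).
#' @return Data frame with `gene_id`, `length_nt`, `GC`, `GC1`, `GC2`,
#'   `GC3`, `GRAVY`.
#' @export
seq_stats_table <- function(cds) {
  stopifnot(is.character(cds), length(names(cds)) == length(cds))
  rows <- lapply(names(cds), function(id) {
    x <- cds[[id]]
    g <- gc_by_codon_position(x)
    gr <- tryCatch({
      p <- as.character(Biostrings::translate(
        Biostrings::DNAString(x), if.fuzzy.codon = "solve"))
      p <- sub("\\*$", "", p)
      if (grepl("\\*", p) || grepl("X", p)) NA_real_ else gravy(p)
    }, error = function(e) NA_real_)
    data.frame(gene_id = id, length_nt = nchar(x),
               GC = g[["GC"]], GC1 = g[["GC1"]], GC2 = g[["GC2"]],
               GC3 = g[["GC3"]], GRAVY = gr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
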