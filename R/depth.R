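# Homolog location by nucleotide seed-chain-extend search, per-gene k-mer
# depth estimation, and depth-ratio state classification against
# mitochondrial and nuclear single-copy controls.

# per-diagonal seed segments for one oriented query against one scaffold
.seed_segments <- function(qchars, schars, smap, k) {
  qlen <- length(qchars)
  if (qlen < k) return(NULL)
  q <- paste(qchars, collapse = "")
  qk <- substring(q, 1:(qlen - k + 1L), k:qlen)
  idx <- smap[qk]
  hit <- !vapply(idx, is.null, logical(1L))
  if (!any(hit)) return(NULL)
  qpos <- rep(which(hit), lengths(idx[hit]))
  spos <- unlist(idx[hit], use.names = FALSE)
  diag <- spos - qpos
  segs <- lapply(split(qpos, diag), function(qs) {
    c(qlo = min(qs), qhi = max(qs) + k - 1L)
  })
  d <- as.integer(names(segs))
  slen <- length(schars)
  out <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    qlo <- segs[[i]][["qlo"]]
    qhi <- segs[[i]][["qhi"]]
    # greedy exact extension along the diagonal
    while (qlo > 1L && qlo + d[i] > 1L &&
           qchars[qlo - 1L] == schars[qlo - 1L + d[i]]) qlo <- qlo - 1L
    while (qhi < length(qchars) && qhi + d[i] < slen &&
           qchars[qhi + 1L] == schars[qhi + 1L + d[i]]) qhi <- qhi + 1L
    out[[i]] <- c(d = d[i], qlo = qlo, qhi = qhi)
  }
  do.call(rbind, out)
}

# chain colinear segments; identity over aligned columns (same-diagonal
# gaps between segments are mismatch columns; diagonal jumps, i.e. intron
# insertions, contribute no columns).
.chain_segments <- function(segs, qchars, schars) {
  segs <- segs[order(segs[, "qlo"], segs[, "qhi"]), , drop = FALSE]
  chain <- list(segs[1L, ])
  for (i in seq_len(nrow(segs))[-1L]) {
    last <- chain[[length(chain)]]
    s <- segs[i, ]
    if (s[["qlo"]] > last[["qhi"]] && s[["d"]] >= last[["d"]])
      chain[[length(chain) + 1L]] <- s
  }
  matches <- 0L
  cols <- 0L
  for (i in seq_along(chain)) {
    s <- chain[[i]]
    qr <- s[["qlo"]]:s[["qhi"]]
    matches <- matches + sum(qchars[qr] == schars[qr + s[["d"]]])
    cols <- cols + length(qr)
    if (i > 1L) {
      prev <- chain[[i - 1L]]
      if (s[["d"]] == prev[["d"]] && s[["qlo"]] > prev[["qhi"]] + 1L) {
        gap <- (prev[["qhi"]] + 1L):(s[["qlo"]] - 1L)
        matches <- matches + sum(qchars[gap] == schars[gap + s[["d"]]])
        cols <- cols + length(gap)
      }
    }
  }
  first <- chain[[1L]]
  last <- chain[[length(chain)]]
  list(q_start = first[["qlo"]], q_end = last[["qhi"]],
       s_start = first[["qlo"]] + first[["d"]],
       s_end = last[["qhi"]] + last[["d"]],
       matches = matches, cols = cols,
       identity = matches / cols)
}

#' Locate gene homologs on scaffolds by seed-chain-extend search
#'
#' Exact k-mer seeds (default `seed_k = 15`) are grouped by diagonal,
#' extended ungapped, and chained colinearly per scaffold and strand; the
#' chain identity is computed over aligned columns (same-diagonal mismatch
#' stretches count as aligned, diagonal jumps such as intron insertions do
#' not).  The best-scoring chain per gene and scaffold above
#' `min_identity` is reported; hits on multiple scaffolds are all kept, as
#' required for trans-intron detection.  Coordinates are 0-based half-open
#' on the forward scaffold strand.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param queries Named character vector of query gene sequences.
#' @param seed_k Exact seed length.
#' @param min_identity Minimum chain identity to report a hit.
#' @param min_hit Minimum aligned span (nt) to report a hit.
#' @return Data frame: `gene_id`, `scaffold_id`, `start`, `end`, `strand`,
#'   `identity`, `q_start`, `q_end` (1-based on the query), `matches`.
#' @export
find_homologs <- function(scaffolds, queries, seed_k = 15L,
                          min_identity = 0.9, min_hit = 30L) {
  stopifnot(length(queries) > 0L, !is.null(names(queries)))
  res <- list()
  for (sc in names(scaffolds)) {
    sseq <- scaffolds[[sc]]
    slen <- nchar(sseq)
    if (slen < seed_k) next
    schars <- .chars(sseq)
    sk <- substring(sseq, 1:(slen - seed_k + 1L), seed_k:slen)
    smap <- split(seq_len(slen - seed_k + 1L), sk)
    for (g in names(queries)) {
      best <- NULL
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") queries[[g]] else revcomp(queries[[g]])
        qchars <- .chars(qseq)
        segs <- .seed_segments(qchars, schars, smap, seed_k)
        if (is.null(segs)) next
        ch <- .chain_segments(segs, qchars, schars)
        span <- ch$q_end - ch$q_start + 1L
        if (span < min_hit || ch$identity < min_identity) next
        qlen <- nchar(qseq)
        hit <- data.frame(
          gene_id = g, scaffold_id = sc,
          start = ch$s_start - 1L, end = ch$s_end,
          strand = strand, identity = ch$identity,
          q_start = if (strand == "+") ch$q_start else qlen - ch$q_end + 1L,
          q_end = if (strand == "+") ch$q_end else qlen - ch$q_start + 1L,
          matches = ch$matches, stringsAsFactors = FALSE)
        if (is.null(best) || hit$matches > best$matches) best <- hit
      }
      if (!is.null(best)) res[[length(res) + 1L]] <- best
    }
  }
  if (!length(res))
    return(data.frame(gene_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      q_start = integer(0), q_end = integer(0),
                      matches = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count k-mers in a read multiset
#'
#' @param reads Character vector of reads.
#' @param k K-mer size.
#' @return Named integer vector of k-mer multiplicities.
#' @export
count_kmers <- function(reads, k) {
  stopifnot(k >= 1L)
  if (!length(reads)) return(stats::setNames(integer(0), character(0)))
  kms <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character(0))
    substring(r, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (!length(kms)) return(stats::setNames(integer(0), character(0)))
  s <- sort(kms, method = "radix")
  r <- rle(s)
  stats::setNames(r$lengths, r$values)
}

#' Mean k-mer depth of a region
#'
#' Mean, over the region's positional k-mers, of each k-mer's multiplicity
#' in the read multiset; deterministic and invariant to read order and
#' relabeling.  Pass a precomputed table from [count_kmers()] via
#' `kmer_counts` to amortise counting across regions.
#'
#' @param reads Character vector of reads (ignored when `kmer_counts`
#'   given).
#' @param region Region sequence (length >= k).
#' @param k K-mer size (default 31).
#' @param kmer_counts Optional precomputed k-mer count table.
#' @return Mean k-mer depth (x coverage estimate).
#' @export
kmer_depth <- function(reads = NULL, region, k = 31L, kmer_counts = NULL) {
  n <- nchar(region)
  if (n < k) stop("region length (", n, ") shorter than k (", k, ")")
  if (is.null(kmer_counts)) kmer_counts <- count_kmers(reads, k)
  rk <- substring(region, 1:(n - k + 1L), k:n)
  hits <- kmer_counts[match(rk, names(kmer_counts))]
  hits[is.na(hits)] <- 0L
  mean(hits)
}

#' Default depth-ratio thresholds for state classification
#'
#' `band` is the depth-ratio window counted as "same depth as the control"
#' and `t_mito_max` the maximum mito-relative depth compatible with a
#' single-copy nuclear gene.  The defaults separate the >= 8-fold
#' organelle/nuclear copy-number contrast; both are explicit knobs because
#' only qualitative depth equality with the nuclear control is reported in
#' real data.
#'
#' @param band_lo,band_hi Bounds of the same-depth band.
#' @param t_mito_max Maximum `depth/control_mito` for a transferred call.
#' @return Named list of thresholds.
#' @export
depth_thresholds <- function(band_lo = 0.5, band_hi = 2,
                             t_mito_max = 0.25) {
  list(band_lo = band_lo, band_hi = band_hi, t_mito_max = t_mito_max)
}

#' Classify one gene's state from depth ratios and presence evidence
#'
#' Calls `M` when the gene's depth sits in the mitochondrial control band,
#' `T` when it sits in the nuclear control band while being well below the
#' mitochondrial control, `L` when the gene is absent from both DNA and
#' cDNA, and `U` otherwise (an explicit unknown rather than a forced
#' call).
#'
#' @param gene_id Gene id.
#' @param mean_depth Mean k-mer depth of the gene's region(s) (`NA` when
#'   not found in DNA).
#' @param control_mito_depth,control_nuc_depth Control depths (> 0).
#' @param found_in_dna,found_in_cdna Presence evidence flags.
#' @param thresholds From [depth_thresholds()].
#' @return One-row data frame: `gene_id`, `call`, `ratio_to_nuc`,
#'   `ratio_to_mito`, `found_in_dna`, `found_in_cdna`.
#' @export
classify_state <- function(gene_id, mean_depth, control_mito_depth,
                           control_nuc_depth, found_in_dna, found_in_cdna,
                           thresholds = depth_thresholds()) {
  if (is.na(control_mito_depth) || control_mito_depth <= 0 ||
      is.na(control_nuc_depth) || control_nuc_depth <= 0)
    stop("control depths must be > 0 for classification")
  th <- thresholds
  if (!found_in_dna && !found_in_cdna) {
    call <- "L"
    rm <- rn <- NA_real_
  } else {
    rm <- mean_depth / control_mito_depth
    rn <- mean_depth / control_nuc_depth
    call <- "U"
    if (found_in_dna && !is.na(rm) &&
        rm >= th$band_lo && rm <= th$band_hi) {
      call <- "M"
    } else if (found_in_dna && !is.na(rn) &&
               rn >= th$band_lo && rn <= th$band_hi &&
               !is.na(rm) && rm < th$t_mito_max) {
      call <- "T"
    }
  }
  data.frame(gene_id = gene_id, call = call, ratio_to_nuc = rn,
             ratio_to_mito = rm, found_in_dna = found_in_dna,
             found_in_cdna = found_in_cdna, stringsAsFactors = FALSE)
}

#' Classify all panel genes for one species
#'
#' Runs the homolog search against the species' scaffolds and cDNA set,
#' estimates per-gene k-mer depth (length-weighted over all of a gene's
#' scaffold hits, so trans-split genes are handled), reads the control
#' depths off the designated control genes, and applies
#' [classify_state()].
#'
#' @param scaffolds Named character vector of the species' scaffolds.
#' @param reads Character vector of the species' reads.
#' @param cdna Named character vector of the species' cDNA sequences.
#' @param queries Named character vector of panel gene query sequences
#'   (must include `control_mito` and `control_nuc`).
#' @param control_mito,control_nuc Ids of the mitochondrial and nuclear
#'   single-copy control genes within `queries`.
#' @param k K-mer size for depth estimation.
#' @param seed_k,min_identity Homolog-search parameters
#'   (see [find_homologs()]).
#' @param thresholds From [depth_thresholds()].
#' @return List: `calls` (data frame of [classify_state()] rows for every
#'   non-control query), `hits` (homolog hits), `depth` (per-gene mean
#'   depth), `controls` (named depths).
#' @export
classify_genes <- function(scaffolds, reads, cdna, queries,
                           control_mito, control_nuc,
                           k = 31L, seed_k = 15L, min_identity = 0.9,
                           thresholds = depth_thresholds()) {
  stopifnot(control_mito %in% names(queries),
            control_nuc %in% names(queries))
  hits <- find_homologs(scaffolds, queries, seed_k = seed_k,
                        min_identity = min_identity)
  # presence in the transcript set only needs one search target: the cDNA
  # entries joined by N runs (seeds never span an N)
  cdna_cat <- stats::setNames(paste(cdna, collapse = strrep("N", 40L)),
                              "cdna_pool")
  cdna_hits <- find_homologs(cdna_cat, queries, seed_k = seed_k,
                             min_identity = min_identity)
  counts <- count_kmers(reads, k)
  # one joint lookup for all hit regions (a single hash build over the
  # k-mer table instead of one per gene)
  reg_seq <- character(nrow(hits))
  for (i in seq_len(nrow(hits)))
    reg_seq[i] <- substr(scaffolds[[hits$scaffold_id[i]]],
                         hits$start[i] + 1L, hits$end[i])
  keep <- nchar(reg_seq) >= k
  reg_kmers <- lapply(reg_seq[keep], function(r)
    substring(r, 1:(nchar(r) - k + 1L), (k:nchar(r))))
  grp <- rep(seq_along(reg_kmers), lengths(reg_kmers))
  vals <- counts[match(unlist(reg_kmers, use.names = FALSE),
                       names(counts))]
  vals[is.na(vals)] <- 0L
  reg_depth <- rep(NA_real_, nrow(hits))
  if (length(grp))
    reg_depth[keep] <- as.numeric(tapply(vals, grp, mean))
  reg_w <- ifelse(keep, nchar(reg_seq), 0L)
  depth <- vapply(names(queries), function(g) {
    sel <- hits$gene_id == g & !is.na(reg_depth)
    if (!any(sel) || sum(reg_w[sel]) == 0) return(NA_real_)
    sum(reg_depth[sel] * reg_w[sel]) / sum(reg_w[sel])
  }, numeric(1L))
  controls <- c(mito = depth[[control_mito]], nuc = depth[[control_nuc]])
  panel <- setdiff(names(queries), c(control_nuc))
  calls <- do.call(rbind, lapply(panel, function(g) {
    classify_state(g, depth[[g]], controls[["mito"]], controls[["nuc"]],
                   found_in_dna = g %in% hits$gene_id,
                   found_in_cdna = g %in% cdna_hits$gene_id,
                   thresholds = thresholds)
  }))
  list(calls = calls, hits = hits, cdna_hits = cdna_hits, depth = depth,
       controls = controls)
}
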