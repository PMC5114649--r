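.dna_bases <- c("A", "C", "G", "T")

#' Build a position-frequency-matrix motif model
#'
#' Counts are converted to probabilities with a pseudocount distributed by
#' the background base frequencies, the standard PFM regularisation.
#'
#' @param motif_id Motif identifier.
#' @param counts 4 x L non-negative count matrix, rows A, C, G, T.
#' @param pseudocount Total pseudocount per column (default 0.8).
#' @param background Base frequencies summing to 1.
#' @return An object of class `motif_model` with `counts`, `probs`,
#'   `log_odds` (log2 p/background), `length`.
#' @export
motif_model <- function(motif_id, counts, pseudocount = 0.8,
                        background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L, all(counts >= 0),
            all(colSums(counts) > 0), abs(sum(background) - 1) < 1e-8)
  rownames(counts) <- .dna_bases
  probs <- sweep(counts + pseudocount * background, 2,
                 colSums(counts) + pseudocount, "/")
  lo <- log2(sweep(probs, 1, background, "/"))
  out <- list(motif_id = motif_id, counts = counts, probs = probs,
              log_odds = lo, background = background,
              length = ncol(counts))
  class(out) <- "motif_model"
  out
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif %s: length %d, %.2f bits\n", x$motif_id, x$length,
              information_content(x)))
  invisible(x)
}

#' Read motifs from JASPAR-format PFM text
#'
#' Records start with `>ID name`; four following lines give A/C/G/T counts,
#' either bare numbers or the bracketed `A [ 1 2 3 ]` style.
#'
#' @param path Path to the PFM file.
#' @param ... Passed to [motif_model()].
#' @return A named list of `motif_model` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop("JASPAR parse error: no '>' records")
  out <- list()
  for (s in starts) {
    id <- strsplit(sub("^>", "", lines[s]), "\\s+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    mat <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]?\\s*\\[?", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("[][ACGTacgt]", "", rows[1])),
                               "\\s+")[[1]]))))
    out[[id]] <- motif_model(id, mat, ...)
  }
  out
}

#' Information content (specificity) of a motif in bits
#'
#' Sum over columns of `2 + sum_b p_b log2 p_b`, using the
#' pseudocount-regularised probabilities.
#'
#' @param motif A [motif_model()].
#' @return Total bits.
#' @export
information_content <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  p <- motif$probs
  sum(2 + colSums(ifelse(p > 0, p * log2(p), 0)))
}

#' Extract merged TSS-flank regions with sequences
#'
#' Builds +/-`flank` bp windows around the strand-aware 5' position of each
#' TSS, merges overlapping windows per chromosome, clips at contig ends, and
#' extracts the sequences.
#'
#' @param tss TSS table.
#' @param genome Named character vector of contig sequences.
#' @param flank Flank size in bp.
#' @return A list of class `region_set` with `intervals` and `sequences`.
#' @export
build_regions <- function(tss, genome, flank = 500L) {
  pos <- tss_positions(tss)
  iv <- data.frame(chrom = tss$chrom,
                   start = pmax(0L, pos - flank),
                   end = pos + flank + 1L, strand = ".",
                   stringsAsFactors = FALSE)
  missing <- setdiff(unique(iv$chrom), names(genome))
  if (length(missing)) stop("build_regions: contig(s) absent from genome: ",
                            paste(missing, collapse = ", "))
  clen <- nchar(genome)[iv$chrom]
  clipped <- sum(iv$end > clen | (pos - flank) < 0)
  if (clipped) message(sprintf("build_regions: %d window(s) clipped at contig ends",
                               clipped))
  iv$end <- pmin(iv$end, clen)
  merged <- merge_intervals(iv)
  seqs <- substring(genome[merged$chrom], merged$start + 1L, merged$end)
  out <- list(intervals = merged, sequences = unname(seqs))
  class(out) <- "region_set"
  out
}

revcomp <- function(s) {
  vapply(s, function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
    character(1), USE.NAMES = FALSE)
}

seq_to_idx <- function(seq) {
  match(strsplit(seq, "")[[1]], .dna_bases)  # N and others -> NA
}

score_offsets <- function(idx, lo) {
  L <- ncol(lo)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- unname(lo[, j])[idx[seq.int(j, j + n - 1L)]]
    v[is.na(v)] <- 0  # N positions contribute no log-odds
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a motif at a relative-score threshold
#'
#' Scores the log2 odds at every offset on both strands; the relative score
#' is `(score - min) / (max - min)` over the motif's attainable score range.
#' Hits are offsets with relative score >= `rel_threshold`. Reported offsets
#' are 0-based on the forward strand; N positions contribute zero log-odds.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param motif A [motif_model()].
#' @param rel_threshold Relative score threshold in (0, 1].
#' @return `data.frame` with `offset`, `strand`, `rel_score`.
#' @export
scan_region <- function(seq, motif, rel_threshold = 0.85) {
  stopifnot(inherits(motif, "motif_model"),
            rel_threshold > 0, rel_threshold <= 1)
  lo <- motif$log_odds
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  L <- motif$length
  if (nchar(seq) < L)
    return(data.frame(offset = integer(), strand = character(),
                      rel_score = numeric()))
  idx <- seq_to_idx(toupper(seq))
  fwd <- score_offsets(idx, lo)
  rev <- score_offsets(5L - rev(idx), lo)  # reverse complement in index space
  n <- length(fwd)
  rel_f <- (fwd - smin) / (smax - smin)
  rel_r <- (rev - smin) / (smax - smin)
  hits_f <- which(rel_f >= rel_threshold)
  hits_r <- which(rel_r >= rel_threshold)
  out <- rbind(
    data.frame(offset = hits_f - 1L, strand = rep("+", length(hits_f)),
               rel_score = rel_f[hits_f]),
    data.frame(offset = n - hits_r, strand = rep("-", length(hits_r)),
               rel_score = rel_r[hits_r]))
  out[order(out$offset), , drop = FALSE]
}

region_gc <- function(seqs) {
  vapply(seqs, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    n <- sum(b %in% .dna_bases)
    if (n == 0) return(NA_real_)
    sum(b %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sample a GC- and length-matched background region set
#'
#' For each target region, draws `n_per_target` pool regions whose GC
#' content differs by at most `gc_tol` and whose length is within
#' `len_tol` relative difference, without replacement across the whole
#' draw.
#'
#' @param targets,pool `region_set` objects.
#' @param gc_tol Absolute GC-fraction tolerance.
#' @param len_tol Relative length tolerance.
#' @param n_per_target Background regions per target.
#' @param seed Integer seed.
#' @return A `region_set` of matched background regions.
#' @export
gc_length_matched_background <- function(targets, pool, gc_tol = 0.05,
                                         len_tol = 0.10, n_per_target = 10L,
                                         seed = 1L) {
  tgc <- region_gc(targets$sequences)
  tlen <- nchar(targets$sequences)
  pgc <- region_gc(pool$sequences)
  plen <- nchar(pool$sequences)
  with_seed(seed, {
    avail <- rep(TRUE, length(pgc))
    picked <- integer(0)
    for (i in seq_along(tgc)) {
      cand <- which(avail & abs(pgc - tgc[i]) <= gc_tol &
                      abs(plen - tlen[i]) / tlen[i] <= len_tol)
      if (length(cand) < n_per_target)
        stop(sprintf("matching error: target region %d has %d candidate(s), needs %d",
                     i, length(cand), n_per_target))
      take <- if (length(cand) == 1L) cand else sample(cand, n_per_target)
      avail[take] <- FALSE
      picked <- c(picked, take)
    }
    out <- list(intervals = pool$intervals[picked, , drop = FALSE],
                sequences = pool$sequences[picked])
    class(out) <- "region_set"
    out
  })
}

#' Count regions containing at least one motif hit
#'
#' @param regions A `region_set`.
#' @param motif A [motif_model()].
#' @param rel_threshold Relative score threshold.
#' @return Integer count of regions with >= 1 hit.
#' @export
count_hit_regions <- function(regions, motif, rel_threshold = 0.85) {
  sum(vapply(regions$sequences, function(s)
    nrow(scan_region(s, motif, rel_threshold)) > 0, logical(1)))
}

#' Fisher over-representation test of motif hits in target vs background
#'
#' One-tailed (enrichment) Fisher exact test on the 2 x 2 table of
#' regions-with-hit vs regions-without. The Fisher score is `-ln p`.
#'
#' @param target_hits,target_n Hit-region count and total for targets.
#' @param background_hits,background_n Same for the background.
#' @param motif_id Optional identifier carried through.
#' @return `data.frame` row with counts, `fold` (rate ratio), `p`,
#'   `fisher_score`.
#' @export
fisher_motif_test <- function(target_hits, target_n,
                              background_hits, background_n,
                              motif_id = NA_character_) {
  if (background_n == 0L) stop("error: zero background regions")
  stopifnot(target_hits <= target_n, background_hits <= background_n)
  tab <- matrix(c(target_hits, target_n - target_hits,
                  background_hits, background_n - background_hits), 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  rate_b <- background_hits / background_n
  fold <- if (rate_b == 0) ifelse(target_hits > 0, Inf, 0)
          else (target_hits / target_n) / rate_b
  data.frame(motif_id = motif_id, target_hit_regions = target_hits,
             target_regions = target_n,
             background_hit_regions = background_hits,
             background_regions = background_n,
             fold = fold, p = p, fisher_score = -log(p),
             stringsAsFactors = FALSE)
}

#' Run motif over-representation against one background
#'
#' @param targets,background `region_set` objects.
#' @param motifs List of [motif_model()] objects.
#' @param rel_threshold Relative score threshold.
#' @return `data.frame`, one row per motif, as [fisher_motif_test()].
#' @export
motif_enrichment <- function(targets, background, motifs,
                             rel_threshold = 0.85) {
  rows <- lapply(motifs, function(m) {
    fisher_motif_test(count_hit_regions(targets, m, rel_threshold),
                      length(targets$sequences),
                      count_hit_regions(background, m, rel_threshold),
                      length(background$sequences),
                      motif_id = m$motif_id)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Motifs above a Fisher-score percentile in each comparison
#'
#' Returns the motifs whose score is strictly greater than the given
#' percentile of scores per background comparison, plus the intersection
#' (top in both). With `percentile = 0` all motifs are returned.
#'
#' @param scores1,scores2 Named numeric vectors of Fisher scores per motif
#'   (same names), one per background comparison.
#' @param percentile Percentile cutoff (0-100).
#' @return List with `top1`, `top2`, `both`.
#' @export
rank_motifs <- function(scores1, scores2, percentile = 95) {
  top <- function(s) {
    if (percentile == 0) return(names(s))
    names(s)[s > stats::quantile(s, percentile / 100)]
  }
  t1 <- top(scores1); t2 <- top(scores2)
  list(top1 = t1, top2 = t2, both = intersect(t1, t2))
}
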