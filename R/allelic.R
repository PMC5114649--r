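.iupac_pairs <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' IUPAC degenerate code for a heterozygous allele pair
#'
#' @param allele_a,allele_b Distinct bases (vectorised).
#' @return Degenerate code, e.g. G/A -> "R".
#' @export
iupac_code <- function(allele_a, allele_b) {
  if (any(allele_a == allele_b)) stop("value error: identical alleles")
  key <- paste0(pmin(allele_a, allele_b), pmax(allele_a, allele_b))
  code <- .iupac_pairs[key]
  if (anyNA(code)) stop("value error: non-ACGT allele pair")
  unname(code)
}

#' Build an IUPAC personalised genome from phased heterozygous sites
#'
#' Each heterozygous position is replaced by the degenerate code of its
#' allele pair so reads from either allele align without a mismatch penalty;
#' every other base is unchanged. The reference base must match one of the
#' two alleles.
#'
#' @param ref Named character vector of contig sequences.
#' @param hets Het-site table (see [read_het_sites()]).
#' @return The personalised genome (named character vector).
#' @export
build_personalized_genome <- function(ref, hets) {
  out <- ref
  if (nrow(hets) == 0L) return(out)
  for (ch in unique(hets$chrom)) {
    if (!ch %in% names(out)) stop("consistency error: contig not in genome: ", ch)
    s <- strsplit(out[[ch]], "")[[1]]
    d <- hets[hets$chrom == ch, , drop = FALSE]
    refb <- s[d$pos + 1L]
    bad <- refb != d$allele_a & refb != d$allele_b
    if (any(bad))
      stop("consistency error: reference base mismatch at site(s) ",
           paste(d$site_id[bad], collapse = ", "))
    s[d$pos + 1L] <- iupac_code(d$allele_a, d$allele_b)
    out[[ch]] <- paste(s, collapse = "")
  }
  out
}

haplotype_sequences <- function(ref, hets) {
  mat <- pat <- ref
  for (ch in unique(hets$chrom)) {
    sm <- strsplit(mat[[ch]], "")[[1]]
    sp <- sm
    d <- hets[hets$chrom == ch, , drop = FALSE]
    pa <- ifelse(d$maternal_allele == d$allele_a, d$allele_b, d$allele_a)
    sm[d$pos + 1L] <- d$maternal_allele
    sp[d$pos + 1L] <- pa
    mat[[ch]] <- paste(sm, collapse = "")
    pat[[ch]] <- paste(sp, collapse = "")
  }
  list(maternal = mat, paternal = pat)
}

#' Enumerate all simulated reads covering heterozygous sites
#'
#' For each het site falling inside the given regions (typically peaks
#' padded by 100 bp and merged), instantiates every `read_len`-bp window
#' covering the site from both phased haplotypes and both strands — up to
#' `4 * read_len` reads per site. Windows truncated by contig ends are
#' dropped. Other het sites inside a window take the same haplotype's
#' allele.
#'
#' @param ref Reference contigs (named character vector).
#' @param hets Het-site table with `maternal_allele`.
#' @param regions Interval table restricting the sites (NULL keeps all).
#' @param read_len Read length in bp.
#' @return `data.frame` with `site_id`, `haplotype`, `allele`, `strand`,
#'   `start` (0-based window start) and `read` (sequence).
#' @export
enumerate_simulated_reads <- function(ref, hets, regions = NULL,
                                      read_len = 36L) {
  stopifnot(read_len >= 1L)
  if (!is.null(regions)) {
    inside <- points_near_intervals(hets$chrom, hets$pos, regions, 0L)
    hets <- hets[inside, , drop = FALSE]
  }
  if (nrow(hets) == 0L)
    return(data.frame(site_id = character(), haplotype = character(),
                      allele = character(), strand = character(),
                      start = integer(), read = character()))
  haps <- haplotype_sequences(ref, hets)
  out <- vector("list", nrow(hets))
  for (i in seq_len(nrow(hets))) {
    ch <- hets$chrom[i]; pos <- hets$pos[i]
    clen <- nchar(ref[[ch]])
    starts <- (pos - read_len + 1L):pos
    starts <- starts[starts >= 0L & starts + read_len <= clen]
    if (!length(starts)) next
    rows <- list()
    for (h in c("maternal", "paternal")) {
      allele <- if (h == "maternal") hets$maternal_allele[i]
                else ifelse(hets$maternal_allele[i] == hets$allele_a[i],
                            hets$allele_b[i], hets$allele_a[i])
      fwd <- substring(haps[[h]][[ch]], starts + 1L, starts + read_len)
      rows[[h]] <- rbind(
        data.frame(site_id = hets$site_id[i], haplotype = h, allele = allele,
                   strand = "+", start = starts, read = fwd,
                   stringsAsFactors = FALSE),
        data.frame(site_id = hets$site_id[i], haplotype = h, allele = allele,
                   strand = "-", start = starts, read = revcomp(fwd),
                   stringsAsFactors = FALSE))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map reads against an IUPAC genome by exhaustive exact matching
#'
#' A read matches a position when every base equals the genome base or is
#' contained in its degenerate code; matches are counted over both strands
#' of all contigs. Status is `unique` (exactly one match), `multi` (more),
#' or `unmapped` (none, or more than half the read is N).
#'
#' @param reads Character vector of read sequences.
#' @param genome IUPAC personalised genome (named character vector).
#' @return Character vector of statuses, one per read.
#' @export
toy_unique_mapper <- function(reads, genome) {
  subjects <- lapply(genome, Biostrings::DNAString)
  uniq <- unique(reads)
  counts <- vapply(uniq, function(rd) {
    if (mean(strsplit(rd, "")[[1]] == "N") > 0.5) return(NA_integer_)
    pat <- Biostrings::DNAString(rd)
    rc <- Biostrings::reverseComplement(pat)
    total <- 0L
    for (s in subjects) {
      total <- total +
        Biostrings::countPattern(pat, s, fixed = c(pattern = TRUE, subject = FALSE)) +
        Biostrings::countPattern(rc, s, fixed = c(pattern = TRUE, subject = FALSE))
    }
    total
  }, integer(1))
  status <- ifelse(is.na(counts) | counts == 0L, "unmapped",
                   ifelse(counts == 1L, "unique", "multi"))
  unname(status[match(reads, uniq)])
}

#' Count uniquely mapping simulated reads per site and allele
#'
#' Convenience wrapper combining [enumerate_simulated_reads()] and
#' [toy_unique_mapper()]. Because forward and reverse-complement reads of
#' the same window match the same positions, statuses are shared within a
#' window; counting keeps each read separately, as an aligner would.
#'
#' @param ref Reference contigs.
#' @param hets Het-site table.
#' @param genome IUPAC genome to map against (default: built from `ref`,
#'   `hets`).
#' @param regions Optional interval restriction.
#' @param read_len Read length in bp.
#' @return `data.frame` with `site_id`, `allele`, `unique_reads`.
#' @export
simulated_read_mapability <- function(ref, hets, genome = NULL,
                                      regions = NULL, read_len = 36L) {
  if (is.null(genome)) genome <- build_personalized_genome(ref, hets)
  reads <- enumerate_simulated_reads(ref, hets, regions, read_len)
  if (nrow(reads) == 0L)
    return(data.frame(site_id = character(), allele = character(),
                      unique_reads = integer()))
  reads$status <- toy_unique_mapper(reads$read, genome)
  agg <- stats::aggregate(list(unique_reads = reads$status == "unique"),
                          by = list(site_id = reads$site_id,
                                    allele = reads$allele), FUN = sum)
  agg[order(agg$site_id), , drop = FALSE]
}

#' Filter heterozygous sites by simulated-read mapability balance
#'
#' A site is kept when either allele's share of uniquely mapped simulated
#' reads lies within `[lo, hi]` (the conditions for the two alleles are
#' complementary, so one check suffices); sites with zero total unique
#' reads are dropped.
#'
#' @param mapability Output of [simulated_read_mapability()].
#' @param lo,hi Balance interval bounds, inclusive.
#' @return `data.frame` per site with `allele_fraction` and `kept`.
#' @export
mapability_filter <- function(mapability, lo = 0.4, hi = 0.6) {
  sites <- unique(mapability$site_id)
  out <- lapply(sites, function(s) {
    d <- mapability[mapability$site_id == s, , drop = FALSE]
    tot <- sum(d$unique_reads)
    frac <- if (tot == 0) NA_real_ else d$unique_reads[1] / tot
    data.frame(site_id = s, allele_fraction = frac,
               kept = !is.na(frac) && frac >= lo && frac <= hi,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign raw per-allele counts to the active and inactive X
#'
#' The count of the allele on the inactive-X haplotype becomes `Ri`, the
#' other `Ra`. Sites without phase are excluded with a message.
#'
#' @param counts Count table with `site_id`, `dataset_id`, `factor`, `lab`,
#'   `allele_a_count`, `allele_b_count`.
#' @param hets Het-site table with `maternal_allele` (`NA` = unphased).
#' @param xi_parent Which parental haplotype carries the inactive X.
#' @return Count table with `Ra`, `Ri` columns.
#' @export
assign_alleles <- function(counts, hets,
                           xi_parent = c("paternal", "maternal")) {
  xi_parent <- match.arg(xi_parent)
  m <- match(counts$site_id, hets$site_id)
  if (anyNA(m)) stop("error: counts reference unknown site_id")
  maternal <- hets$maternal_allele[m]
  unphased <- is.na(maternal)
  if (any(unphased)) {
    message(sprintf("excluding %d unphased site-count row(s)", sum(unphased)))
    counts <- counts[!unphased, , drop = FALSE]
    m <- m[!unphased]; maternal <- maternal[!unphased]
  }
  a_is_maternal <- maternal == hets$allele_a[m]
  a_is_xi <- if (xi_parent == "maternal") a_is_maternal else !a_is_maternal
  counts$Ri <- ifelse(a_is_xi, counts$allele_a_count, counts$allele_b_count)
  counts$Ra <- ifelse(a_is_xi, counts$allele_b_count, counts$allele_a_count)
  counts
}

#' Merge replicate datasets generated by the same lab
#'
#' Sums `Ra` and `Ri` within (site, factor, lab) groups; the merged
#' dataset id is `<factor>_<lab>`.
#'
#' @param counts Allelic count table with `factor` and `lab` columns.
#' @return Merged count table.
#' @export
merge_replicates <- function(counts) {
  agg <- stats::aggregate(counts[, c("Ra", "Ri")],
                          by = list(site_id = counts$site_id,
                                    factor = counts$factor,
                                    lab = counts$lab), FUN = sum)
  agg$dataset_id <- paste(agg$factor, agg$lab, sep = "_")
  agg[order(agg$dataset_id, agg$site_id),
      c("site_id", "dataset_id", "factor", "lab", "Ra", "Ri")]
}

#' Allelic imbalance score
#'
#' `log2((Ra + 1) / (Ri + 1))`; positive values indicate Xa-biased reads.
#' Antisymmetric in its arguments.
#'
#' @param Ra,Ri Non-negative read counts (vectorised).
#' @return Imbalance scores.
#' @export
imbalance_score <- function(Ra, Ri) {
  if (any(Ra < 0) || any(Ri < 0)) stop("value error: negative counts")
  log2((Ra + 1) / (Ri + 1))
}

#' Batch Fisher tests of allelic imbalance against dataset totals
#'
#' For each (site, dataset) pair with non-zero reads on both alleles, a
#' Fisher exact test (two-sided by default) of the site's `Ra`/`Ri` against
#' the rest of the dataset's totals, Benjamini-Hochberg corrected across
#' all tested pairs. The log2 odds ratio uses a Haldane +0.5 correction on
#' the 2x2 cells (never the p-value), positive toward Xa.
#'
#' @param counts Merged allelic count table (`site_id`, `dataset_id`,
#'   `Ra`, `Ri`).
#' @param fdr_alpha FDR significance level.
#' @param alternative Sidedness of the Fisher test.
#' @return `data.frame` with one row per tested pair: `raw_p`, `fdr_p`,
#'   `log2_odds`, `score`, `significant`.
#' @export
batch_imbalance_test <- function(counts, fdr_alpha = 0.05,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  rows <- vector("list", length(unique(counts$dataset_id)))
  k <- 0L
  for (ds in unique(counts$dataset_id)) {
    d <- counts[counts$dataset_id == ds, , drop = FALSE]
    tot_a <- sum(d$Ra); tot_i <- sum(d$Ri)
    if (tot_a == 0L || tot_i == 0L) {
      message("skipping dataset with a zero allele total: ", ds)
      next
    }
    d <- d[d$Ra > 0 & d$Ri > 0, , drop = FALSE]
    if (nrow(d) == 0L) next
    p <- mapply(function(ra, ri)
      stats::fisher.test(matrix(c(ra, tot_a - ra, ri, tot_i - ri), 2),
                         alternative = alternative)$p.value,
      d$Ra, d$Ri)
    lor <- log2(((d$Ra + 0.5) * (tot_i - d$Ri + 0.5)) /
                  ((d$Ri + 0.5) * (tot_a - d$Ra + 0.5)))
    k <- k + 1L
    rows[[k]] <- data.frame(site_id = d$site_id, dataset_id = ds,
                            Ra = d$Ra, Ri = d$Ri, raw_p = p,
                            log2_odds = lor,
                            score = imbalance_score(d$Ra, d$Ri),
                            stringsAsFactors = FALSE)
  }
  if (k == 0L) stop("error: no testable site-dataset pairs")
  out <- do.call(rbind, rows[seq_len(k)])
  out$fdr_p <- stats::p.adjust(out$raw_p, method = "BH")
  out$significant <- out$fdr_p <= fdr_alpha
  rownames(out) <- NULL
  out
}

#' Summarise imbalance calls per site across datasets
#'
#' Counts datasets with a significant call per site and classifies the
#' direction consistency among significant pairs by the sign of the log2
#' odds ratio: all negative = `Xi`, all positive = `Xa`, otherwise `mixed`.
#'
#' @param pairs A [batch_imbalance_test()] result.
#' @param fdr_alpha FDR significance level.
#' @return List with `per_site` (site_id, n_significant, consistency),
#'   `n_significant_sites`, `n_multi_dataset_sites`, and `long` (the
#'   heatmap-ready pair table).
#' @export
summarize_sites <- function(pairs, fdr_alpha = 0.05) {
  sig <- pairs[pairs$fdr_p <= fdr_alpha, , drop = FALSE]
  per_site <- if (nrow(sig)) {
    do.call(rbind, lapply(split(sig, sig$site_id), function(d) {
      cons <- if (all(d$log2_odds < 0)) "Xi"
              else if (all(d$log2_odds > 0)) "Xa" else "mixed"
      data.frame(site_id = d$site_id[1], n_significant = nrow(d),
                 consistency = cons, stringsAsFactors = FALSE)
    }))
  } else data.frame(site_id = character(), n_significant = integer(),
                    consistency = character())
  rownames(per_site) <- NULL
  list(per_site = per_site,
       n_significant_sites = nrow(per_site),
       n_multi_dataset_sites = sum(per_site$n_significant > 1L),
       long = pairs)
}

#' Pearson concordance of imbalance scores between replicates
#'
#' @param scores_rep1,scores_rep2 Named per-site score vectors; correlation
#'   is over the shared site names (>= 3 required).
#' @return List with `r`, `p`, `n`.
#' @export
replicate_concordance <- function(scores_rep1, scores_rep2) {
  shared <- intersect(names(scores_rep1), names(scores_rep2))
  if (length(shared) < 3L) stop("error: need >= 3 shared sites")
  x <- scores_rep1[shared]; y <- scores_rep2[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant scores")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
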