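#' Select one escapee TSS per gene
#'
#' Per escape gene, keeps the escTSS with the strongest differential
#' expression (smallest raw p); ties broken by larger absolute coefficient,
#' then lexicographic tss_id.
#'
#' @param de_results A [classify_tss()] result.
#' @param tss TSS annotation table.
#' @return TSS annotation rows of the selected escTSSs (one per gene).
#' @export
select_unique_esc <- function(de_results, tss) {
  esc <- de_results[de_results$class == "escTSS", , drop = FALSE]
  if (nrow(esc) == 0L)
    return(tss[0, , drop = FALSE])
  esc <- esc[order(esc$nearest_gene, esc$raw_p, -abs(esc$coefficient),
                   esc$tss_id), , drop = FALSE]
  keep <- esc[!duplicated(esc$nearest_gene), "tss_id"]
  tss[match(keep, tss$tss_id), , drop = FALSE]
}

#' Sample an expression-matched background TSS set
#'
#' All candidate TSSs are assigned to `n_bins` equally sized bins by
#' average-expression percentile rank; the background is drawn without
#' replacement so its per-bin proportions match the targets' (quotas by
#' largest-remainder rounding, summing exactly to `n`). For the chrX domain
#' the candidates are additionally required to have Bonferroni p exactly 1
#' (the nonDT background rule); targets are always excluded from the pool.
#'
#' @param tss_stats `data.frame` with `tss_id`, `chrom`, `mean_expr` and
#'   (for the chrX domain) `bonferroni_p`.
#' @param target_ids tss_ids of the target set.
#' @param n Number of background TSSs to draw.
#' @param domain `"chrX"` or `"autosomes"`.
#' @param nondt_required Require Bonferroni p == 1 (defaults to TRUE for
#'   chrX, FALSE otherwise).
#' @param n_bins Number of expression bins.
#' @param seed Integer seed.
#' @return Character vector of sampled background tss_ids.
#' @export
expression_matched_background <- function(tss_stats, target_ids, n,
                                          domain = c("chrX", "autosomes"),
                                          nondt_required = NULL,
                                          n_bins = 5L, seed = 1L) {
  domain <- match.arg(domain)
  if (is.null(nondt_required)) nondt_required <- domain == "chrX"
  ranks <- rank(tss_stats$mean_expr, ties.method = "first")
  bin <- ceiling(ranks / (nrow(tss_stats) / n_bins))
  bin <- pmin(bin, n_bins)
  tgt <- tss_stats$tss_id %in% target_ids
  if (!any(tgt)) stop("error: no targets found in tss_stats")
  prop <- tabulate(bin[tgt], n_bins) / sum(tgt)

  # largest-remainder quotas summing exactly to n
  raw <- prop * n
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }

  in_dom <- if (domain == "chrX") tss_stats$chrom == "chrX"
            else tss_stats$chrom != "chrX"
  pool_ok <- in_dom & !tgt
  if (nondt_required) {
    if (is.null(tss_stats$bonferroni_p))
      stop("error: bonferroni_p column required for the nonDT criterion")
    pool_ok <- pool_ok & !is.na(tss_stats$bonferroni_p) &
      tss_stats$bonferroni_p == 1
  }
  with_seed(seed, {
    out <- character(0)
    for (b in seq_len(n_bins)) {
      if (quota[b] == 0L) next
      cand <- tss_stats$tss_id[pool_ok & bin == b]
      if (length(cand) < quota[b])
        stop(sprintf("error: bin %d has %d candidate(s), quota %d",
                     b, length(cand), quota[b]))
      out <- c(out, if (length(cand) == 1L) cand else sample(cand, quota[b]))
    }
    out
  })
}

#' Peak over-representation at target vs background TSSs
#'
#' A TSS "has a peak" when any peak interval lies within +/-`window` bp of
#' its strand-aware 5' position (boundary inclusive). One-sided
#' (enrichment) Fisher exact test; the log2 ratio compares the percentage
#' of targets with peaks to the background percentage.
#'
#' @param target_tss,background_tss TSS tables.
#' @param peaks Peak interval table (as from [read_bed()]).
#' @param window Distance threshold in bp.
#' @param dataset_id Optional identifier carried through.
#' @return One-row `data.frame` with counts, `raw_p`, `log2_ratio`.
#' @export
peak_overlap_test <- function(target_tss, background_tss, peaks,
                              window = 500L, dataset_id = NA_character_) {
  if (nrow(target_tss) == 0L || nrow(background_tss) == 0L)
    stop("error: empty TSS set")
  hit_t <- if (nrow(peaks)) points_near_intervals(target_tss$chrom,
                                                  tss_positions(target_tss),
                                                  peaks, window)
           else rep(FALSE, nrow(target_tss))
  hit_b <- if (nrow(peaks)) points_near_intervals(background_tss$chrom,
                                                  tss_positions(background_tss),
                                                  peaks, window)
           else rep(FALSE, nrow(background_tss))
  a <- sum(hit_t); n1 <- length(hit_t)
  b <- sum(hit_b); n2 <- length(hit_b)
  p <- if (nrow(peaks) == 0L) 1
       else stats::fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2),
                               alternative = "greater")$p.value
  data.frame(dataset_id = dataset_id, target_with_peak = a, target_total = n1,
             bg_with_peak = b, bg_total = n2, raw_p = p,
             log2_ratio = log2((a / n1) / (b / n2)),
             stringsAsFactors = FALSE)
}

#' Run peak over-representation across a set of ChIP-seq datasets
#'
#' Applies [peak_overlap_test()] per dataset and Bonferroni-corrects across
#' the datasets tested in the run.
#'
#' @param target_tss,background_tss TSS tables.
#' @param peak_sets Named list of peak interval tables (one per dataset).
#' @param window Distance threshold in bp.
#' @param alpha Significance level on the corrected p-value.
#' @return `data.frame`, one row per dataset, with `bonferroni_p` and
#'   `significant`.
#' @export
peak_enrichment_run <- function(target_tss, background_tss, peak_sets,
                                window = 500L, alpha = 0.05) {
  rows <- lapply(names(peak_sets), function(id)
    peak_overlap_test(target_tss, background_tss, peak_sets[[id]],
                      window, dataset_id = id))
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$raw_p * nrow(out))
  out$significant <- out$bonferroni_p <= alpha
  out
}

#' Distribution tests on per-dataset log2 enrichment ratios by cell sex
#'
#' One-sample Wilcoxon signed-rank tests of each sex's log2 ratios against
#' zero, and a one-sided two-sample Wilcoxon test of female > male.
#' Non-finite ratios (zero overlap counts) are excluded with a message.
#'
#' @param female_ratios,male_ratios Numeric log2-ratio vectors.
#' @return List of three `(statistic, p)` pairs: `female_vs_zero`,
#'   `male_vs_zero`, `female_gt_male`.
#' @export
ratio_distribution_tests <- function(female_ratios, male_ratios) {
  clean <- function(x, nm) {
    bad <- !is.finite(x)
    if (any(bad)) message(sprintf("excluding %d non-finite %s ratio(s)",
                                  sum(bad), nm))
    x[!bad]
  }
  f <- clean(female_ratios, "female"); m <- clean(male_ratios, "male")
  if (!length(f) || !length(m)) stop("error: empty ratio list")
  if (all(f == 0) || all(m == 0)) stop("degenerate-test error: all-zero ratios")
  one <- function(x) {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  two <- suppressWarnings(stats::wilcox.test(f, m, alternative = "greater"))
  list(female_vs_zero = one(f), male_vs_zero = one(m),
       female_gt_male = list(statistic = unname(two$statistic),
                             p = two$p.value))
}

track_window <- function(track, chrom, center, flank) {
  blk <- track[[chrom]]
  if (is.null(blk)) return(rep(NA_real_, 2 * flank + 1))
  idx <- (center - flank):(center + flank) - blk$start + 1L
  ok <- idx >= 1L & idx <= length(blk$depth)
  out <- rep(NA_real_, 2 * flank + 1)
  out[ok] <- blk$depth[idx[ok]]
  out
}

#' Average read-depth profiles around two TSS sets and their core ratio
#'
#' Per-position mean depth across each set over +/-`flank` bp of the 5'
#' TSS positions; the core ratio compares the mean depths within
#' +/-`core` bp. Windows running off a contig contribute only their covered
#' positions.
#'
#' @param track Depth track (see [read_wig()]).
#' @param set_a,set_b TSS tables.
#' @param flank Profile half-width in bp.
#' @param core Half-width of the core window for the ratio.
#' @return List with `profile_a`, `profile_b` (length `2*flank+1`,
#'   positions relative to the TSS) and `core_ratio`.
#' @export
depth_profile_ratio <- function(track, set_a, set_b, flank = 5000L,
                                core = 50L) {
  prof <- function(set) {
    pos <- tss_positions(set)
    mats <- t(vapply(seq_len(nrow(set)), function(i)
      track_window(track, set$chrom[i], pos[i], flank),
      numeric(2 * flank + 1)))
    colMeans(mats, na.rm = TRUE)
  }
  pa <- prof(set_a); pb <- prof(set_b)
  ctr <- flank + 1L
  core_idx <- (ctr - core):(ctr + core)
  list(profile_a = pa, profile_b = pb,
       core_ratio = mean(pa[core_idx], na.rm = TRUE) /
         mean(pb[core_idx], na.rm = TRUE))
}
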