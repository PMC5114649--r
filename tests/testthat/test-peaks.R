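test_that("one escTSS per gene is selected with deterministic tie-breaks", {
  tss <- data.frame(tss_id = sprintf("t%d", 1:6), chrom = "chrX",
                    start = 1:6 * 1000L, end = 1:6 * 1000L + 1L,
                    strand = "+")
  de <- data.frame(tss_id = tss$tss_id,
                   coefficient = c(-1, -2, -0.5, -3, -3, -1),
                   raw_p = c(1e-8, 1e-4, 1e-2, 1e-5, 1e-5, 1e-3),
                   class = c(rep("escTSS", 5), "nonDT"),
                   nearest_gene = c("g1", "g1", "g1", "g2", "g2", "g3"))
  sel <- select_unique_esc(de, tss)
  expect_equal(sel$tss_id, c("t1", "t4"))  # p tie at g2: t4 = t5 on |coef|,
                                           # lexicographic tss_id decides
  expect_equal(nrow(select_unique_esc(de[de$class == "nonDT", ], tss)), 0L)
  # 30 genes give 30 selected TSSs
  de30 <- data.frame(tss_id = sprintf("e%02d", 1:60),
                     coefficient = -runif(60), raw_p = runif(60),
                     class = "escTSS",
                     nearest_gene = rep(sprintf("g%02d", 1:30), 2))
  tss30 <- data.frame(tss_id = de30$tss_id, chrom = "chrX",
                      start = 1:60 * 100L, end = 1:60 * 100L + 1L,
                      strand = "+")
  expect_equal(nrow(select_unique_esc(de30, tss30)), 30L)
})

test_that("expression-matched backgrounds satisfy exact bin quotas", {
  set.seed(31)
  n_all <- 600L
  stats_df <- data.frame(tss_id = sprintf("t%03d", 1:n_all),
                         chrom = rep(c("chrX", "chr7"), each = 300L),
                         mean_expr = runif(n_all),
                         bonferroni_p = 1)
  # targets spread over bins
  targets <- stats_df$tss_id[c(1, 2, 3, 4, 5, 150, 151, 152, 250, 251)]
  bg <- expression_matched_background(stats_df, targets, 100L, "chrX",
                                      seed = 5)
  expect_length(bg, 100L)
  expect_length(intersect(bg, targets), 0L)
  # per-bin composition equals the largest-remainder quota
  ranks <- rank(stats_df$mean_expr, ties.method = "first")
  bin <- pmin(ceiling(ranks / (n_all / 5)), 5)
  names(bin) <- stats_df$tss_id
  prop <- tabulate(bin[targets], 5) / length(targets)
  raw <- prop * 100; quota <- floor(raw)
  extra <- order(raw - quota, decreasing = TRUE)[seq_len(100 - sum(quota))]
  quota[extra] <- quota[extra] + 1
  expect_equal(unname(tabulate(bin[bg], 5)), quota)
  expect_identical(bg, expression_matched_background(stats_df, targets, 100L,
                                                     "chrX", seed = 5))
  # nonDT requirement excludes borderline TSSs from the chrX pool
  stats2 <- stats_df; stats2$bonferroni_p[stats2$chrom == "chrX"] <- 0.9
  stats2$bonferroni_p[match(targets, stats2$tss_id)] <- 1e-6
  expect_error(expression_matched_background(stats2, targets, 10L, "chrX",
                                             seed = 1), "bin")
  # all targets in the top bin draw only from the top bin
  top <- stats_df$tss_id[order(stats_df$mean_expr, decreasing = TRUE)[1:5]]
  bg_top <- expression_matched_background(stats_df, top, 20L, "autosomes",
                                          seed = 2)
  expect_true(all(bin[bg_top] == 5))
})

test_that("peak overlap uses inclusive point-to-interval distance", {
  tgt <- data.frame(tss_id = "t", chrom = "chrX", start = 10000L,
                    end = 10001L, strand = "+")
  bg <- data.frame(tss_id = sprintf("b%d", 1:4), chrom = "chrX",
                   start = c(2e4, 3e4, 4e4, 5e4), end = c(2e4, 3e4, 4e4, 5e4) + 1,
                   strand = "+")
  # peak edge exactly 500 bp away counts (peak covers [10501, 10601))
  peak <- genomic_intervals("chrX", 10500L, 10600L)
  r <- peak_overlap_test(tgt, bg, peak, window = 500L)
  expect_equal(r$target_with_peak, 1L)
  # 501 bp away does not
  peak2 <- genomic_intervals("chrX", 10501L, 10600L)
  expect_equal(peak_overlap_test(tgt, bg, peak2, 500L)$target_with_peak, 0L)
  # empty peak set: p = 1, no overlap
  empty <- genomic_intervals(character(), integer(), integer())
  r0 <- peak_overlap_test(tgt, bg, empty)
  expect_equal(r0$raw_p, 1)
  expect_equal(r0$target_with_peak, 0L)
})

test_that("the peak Fisher test matches hypergeometric enumeration", {
  mk_tss <- function(n, hit, chrom = "chrX") {
    data.frame(tss_id = sprintf("%s%d", chrom, 1:n), chrom = chrom,
               start = 1:n * 10000L, end = 1:n * 10000L + 1L, strand = "+")
  }
  tgt <- mk_tss(30); bg <- mk_tss(300, chrom = "chr9")
  hit_t <- 1:20; hit_b <- 1:60
  peaks <- rbind(
    genomic_intervals("chrX", hit_t * 10000L - 10L, hit_t * 10000L + 10L),
    genomic_intervals("chr9", hit_b * 10000L - 10L, hit_b * 10000L + 10L))
  r <- peak_overlap_test(tgt, bg, peaks)
  expect_equal(r$target_with_peak, 20L)
  expect_equal(r$bg_with_peak, 60L)
  expect_equal(r$raw_p, oracle_fisher(20, 30, 60, 300), tolerance = 1e-12)
  expect_equal(r$log2_ratio, log2((20 / 30) / (60 / 300)))
  # identical rates: zero log2 ratio
  r_eq <- peak_overlap_test(mk_tss(10), mk_tss(10, chrom = "chrX"),
                            genomic_intervals("chrX", 0L, 2e6L))
  expect_equal(r_eq$log2_ratio, 0)
})

test_that("ratio distribution tests detect the female shift", {
  set.seed(41)
  f <- rnorm(50, 1); m <- rnorm(50, 0)
  r <- ratio_distribution_tests(f, m)
  expect_lt(r$female_gt_male$p, 0.01)
  expect_lt(r$female_vs_zero$p, 1e-6)
  # symmetric around zero: large one-sample p
  sym <- c(-(1:20) / 10, (1:20) / 10)
  expect_gt(ratio_distribution_tests(sym, sym)$female_vs_zero$p, 0.5)
  # single elements compute without crashing
  expect_silent(ratio_distribution_tests(0.5, -0.5))
  # non-finite ratios are excluded with a message
  expect_message(ratio_distribution_tests(c(f, Inf), m), "non-finite")
  expect_error(ratio_distribution_tests(rep(0, 5), rep(0, 5)), "all-zero")
})

test_that("depth profiles and core ratios recover constructed tracks", {
  mk_tss <- function(pos) data.frame(tss_id = sprintf("p%d", seq_along(pos)),
                                     chrom = "chrX", start = pos,
                                     end = pos + 1L, strand = "+")
  a <- mk_tss(c(20000L, 40000L)); b <- mk_tss(c(60000L, 80000L))
  depth <- rep(1, 100000)
  for (p in c(20000, 40000)) depth[(p - 5000):(p + 5000) + 1] <- 2
  track <- list(chrX = list(start = 0L, depth = depth))
  r <- depth_profile_ratio(track, a, b, flank = 5000L, core = 50L)
  expect_equal(r$core_ratio, 2)
  expect_length(r$profile_a, 10001L)
  expect_equal(unique(r$profile_a), 2)
  # identical sets give ratio 1
  expect_equal(depth_profile_ratio(track, a, a)$core_ratio, 1)
  # constructed female-like ratios: escTSS 1.18x, X_bg 0.68x of autosomal
  esc <- mk_tss(c(150000L)); xbg <- mk_tss(c(250000L)); auto <- mk_tss(c(350000L))
  d2 <- rep(1, 400000)
  d2[(150000 - 5000):(150000 + 5000) + 1] <- 1.18
  d2[(250000 - 5000):(250000 + 5000) + 1] <- 0.68
  t2 <- list(chrX = list(start = 0L, depth = d2))
  expect_equal(depth_profile_ratio(t2, esc, auto)$core_ratio, 1.18,
               tolerance = 0.05)
  expect_equal(depth_profile_ratio(t2, xbg, auto)$core_ratio, 0.68,
               tolerance = 0.05)
})

test_that("planted positive-regulator datasets reach significance", {
  ca <- cohort_analysis()
  sel <- select_unique_esc(ca$de, ca$co$tss)
  stats_df <- data.frame(tss_id = ca$co$tss$tss_id, chrom = ca$co$tss$chrom,
                         mean_expr = rowMeans(ca$co$values))
  stats_df$bonferroni_p <- ca$de$bonferroni_p[match(stats_df$tss_id,
                                                    ca$de$tss_id)]
  bg_ids <- expression_matched_background(stats_df, sel$tss_id, 100L, "chrX",
                                          seed = 8)
  bg <- ca$co$tss[match(bg_ids, ca$co$tss$tss_id), ]
  ps <- generate_peak_sets(sel, bg, n_per_sex = 3L, seed = 12)
  run <- peak_enrichment_run(sel, bg, ps$peak_sets)
  sex <- ps$manifest$cell_sex[match(run$dataset_id, ps$manifest$dataset_id)]
  expect_gte(sum(run$significant[sex == "female"]), 2L)
  expect_true(all(run$log2_ratio[sex == "female"] > 0))
  # a uniform-rate factor stays null
  unif <- generate_peak_sets(sel, bg, n_per_sex = 1L,
                             target_rate_female = 0.15,
                             target_rate_male = 0.15, seed = 13)
  run_u <- peak_enrichment_run(sel, bg, unif$peak_sets)
  expect_false(any(run_u$significant))
})
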