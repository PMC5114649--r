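test_that("IUPAC codes and the personalised genome substitution are exact", {
  expect_equal(iupac_code("G", "A"), "R")
  expect_equal(iupac_code("C", "T"), "Y")
  expect_equal(iupac_code("A", "C"), "M")
  expect_error(iupac_code("A", "A"), "identical")

  ref <- c(chr1 = "ACGTACGT")
  hets <- data.frame(site_id = "h1", chrom = "chr1", pos = 2L,
                     allele_a = "G", allele_b = "A", maternal_allele = "G")
  pg <- build_personalized_genome(ref, hets)
  expect_equal(pg[["chr1"]], "ACRTACGT")
  # empty het list leaves the reference unchanged
  expect_equal(build_personalized_genome(ref, hets[0, ]), ref)
  # reference base must match one allele
  bad <- hets; bad$allele_a <- "C"; bad$allele_b <- "T"
  expect_error(build_personalized_genome(ref, bad), "mismatch.*h1")
})

test_that("simulated read enumeration covers 4 x read_len windows", {
  toy <- generate_toy_genome(length = 2000L, n_het = 3L, dup_len = 0L,
                             seed = 17)
  rd <- enumerate_simulated_reads(toy$ref, toy$hets, read_len = 36L)
  expect_equal(as.integer(table(rd$site_id)), rep(144L, 3L))  # 36 x 2 x 2
  expect_true(all(nchar(rd$read) == 36L))
  # a het 10 bp from the contig start only fits 11 windows
  edge <- data.frame(site_id = "e", chrom = "toy", pos = 10L,
                     allele_a = substr(toy$ref[["toy"]], 11, 11),
                     allele_b = "N", maternal_allele = "N")
  edge$allele_b <- setdiff(c("A", "C", "G", "T"), edge$allele_a)[1]
  edge$maternal_allele <- edge$allele_b
  expect_equal(nrow(enumerate_simulated_reads(toy$ref, edge, read_len = 36L)),
               2L * 2L * 11L)
  # a het outside the restricting regions yields no reads
  far <- genomic_intervals("toy", 1900L, 1950L)
  inside <- toy$hets$pos >= 1900 & toy$hets$pos < 1950
  rd2 <- enumerate_simulated_reads(toy$ref, toy$hets, regions = far)
  expect_equal(length(unique(rd2$site_id)), sum(inside))
})

test_that("the toy mapper distinguishes unique, multi and unmapped reads", {
  toy <- generate_toy_genome(length = 3000L, n_het = 5L, dup_len = 300L,
                             seed = 23)
  pg <- build_personalized_genome(toy$ref, toy$hets)
  d <- toy$dup
  uniq_read <- substr(toy$ref[["toy"]], 1000, 1035)  # outside both dup copies
  dup_read <- substr(toy$ref[["toy"]], d$src_start + 50, d$src_start + 85)
  allN <- paste(rep("N", 36), collapse = "")
  st <- toy_unique_mapper(c(uniq_read, dup_read, allN), pg)
  expect_equal(st, c("unique", "multi", "unmapped"))
})

test_that("the mapability filter drops the duplication-planted het", {
  toy <- generate_toy_genome(seed = 2)
  mp <- simulated_read_mapability(toy$ref, toy$hets)
  fl <- mapability_filter(mp)
  dup_site <- toy$hets$site_id[toy$hets$in_duplication]
  expect_false(fl$kept[fl$site_id == dup_site])
  clean <- setdiff(toy$hets$site_id, dup_site)
  expect_true(all(fl$kept[fl$site_id %in% clean]))
  expect_equal(fl$allele_fraction[fl$site_id %in% clean],
               rep(0.5, length(clean)))
  # boundary arithmetic: 100:44 is outside [0.4, 0.6], 72:72 inside
  man <- data.frame(site_id = c("a", "a", "b", "b"),
                    allele = c("A", "G", "C", "T"),
                    unique_reads = c(100L, 44L, 72L, 72L))
  fl2 <- mapability_filter(man)
  expect_equal(fl2$kept, c(FALSE, TRUE))
})

test_that("allele assignment follows the Xi parent and drops unphased sites", {
  hets <- data.frame(site_id = c("h1", "h2"), chrom = "chrX",
                     pos = c(10L, 20L), allele_a = c("G", "C"),
                     allele_b = c("A", "T"),
                     maternal_allele = c("G", NA))
  counts <- data.frame(site_id = c("h1", "h2"), dataset_id = "d1",
                       factor = "YY1", lab = "lab1",
                       allele_a_count = c(3L, 9L),
                       allele_b_count = c(474L, 1L))
  # paternal Xi: allele_b (paternal) of h1 is Xi
  got <- suppressMessages(assign_alleles(counts, hets, "paternal"))
  expect_equal(nrow(got), 1L)  # unphased h2 dropped
  expect_equal(got$Ra, 3L)
  expect_equal(got$Ri, 474L)
  flipped <- suppressMessages(assign_alleles(counts, hets, "maternal"))
  expect_equal(flipped$Ra, 474L)
  expect_equal(flipped$Ri, 3L)
})

test_that("replicate merging sums within (factor, lab) only", {
  counts <- data.frame(site_id = "s1",
                       dataset_id = c("r1", "r2", "r3"),
                       factor = "YY1",
                       lab = c("haib", "haib", "sydh"),
                       Ra = c(10L, 7L, 2L), Ri = c(5L, 3L, 1L))
  m <- merge_replicates(counts)
  expect_equal(nrow(m), 2L)
  haib <- m[m$lab == "haib", ]
  expect_equal(haib$Ra, 17L)
  expect_equal(haib$Ri, 8L)
  expect_equal(m[m$lab == "sydh", ]$Ra, 2L)
  single <- merge_replicates(counts[3, ])
  expect_equal(single$Ra, 2L)
})

test_that("the imbalance score is antisymmetric and matches printed pairs", {
  expect_equal(imbalance_score(0, 0), 0)
  expect_equal(imbalance_score(3, 474), log2(4 / 475))
  expect_equal(imbalance_score(3, 474), -6.8919, tolerance = 1e-4)
  expect_equal(imbalance_score(140, 0), log2(141))
  expect_equal(imbalance_score(140, 0), 7.1394, tolerance = 1e-4)
  for (i in 1:20) {
    set.seed(600 + i)
    a <- rpois(1, 50); b <- rpois(1, 50)
    expect_equal(imbalance_score(a, b), -imbalance_score(b, a))
  }
})

test_that("batch imbalance Fisher p-values equal enumeration", {
  counts <- data.frame(site_id = c("s1", "s2"), dataset_id = "d",
                       Ra = c(5L, 995L), Ri = c(50L, 950L))
  got <- batch_imbalance_test(counts)
  want <- oracle_fisher(5, 1000, 50, 1000, alternative = "two.sided")
  expect_equal(got$raw_p[got$site_id == "s1"], want, tolerance = 1e-10)
  # sign convention: s1 has fewer Xa reads than the dataset norm
  expect_lt(got$log2_odds[got$site_id == "s1"], 0)
  expect_gt(got$log2_odds[got$site_id == "s2"], 0)
  # zero-count pairs are not tested
  z <- data.frame(site_id = c("a", "b"), dataset_id = "d",
                  Ra = c(0L, 10L), Ri = c(5L, 5L))
  expect_equal(batch_imbalance_test(z)$site_id, "b")
})

test_that("designated Xi sites rank top and pass FDR on simulated data", {
  sim <- simulate_allelic_counts(allelic_sim_config(seed = 9))
  bt <- batch_imbalance_test(sim$counts)
  xi <- sim$truth$site_id[sim$truth$class == "xi"]
  called_sites <- unique(bt$site_id[bt$significant])
  expect_true(all(xi %in% called_sites))
  # the most significant sites are the designated Xi sites
  best <- bt[order(bt$raw_p), ]
  expect_true(all(unique(best$site_id)[1:3] %in%
                    sim$truth$site_id[sim$truth$class != "xa_norm"]))
  # significant Xi pairs carry negative log2 odds
  expect_true(all(bt$log2_odds[bt$significant & bt$site_id %in% xi] < 0))
})

test_that("site summaries classify direction consistency", {
  pairs <- data.frame(site_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
                      dataset_id = sprintf("d%d", c(1, 2, 3, 1, 2, 1)),
                      raw_p = 1e-6, fdr_p = c(rep(1e-5, 5), 0.5),
                      log2_odds = c(-2, -1, -3, -1, 2, 1))
  s <- summarize_sites(pairs)
  expect_equal(s$n_significant_sites, 2L)
  expect_equal(s$n_multi_dataset_sites, 2L)
  expect_equal(s$per_site$consistency[s$per_site$site_id == "s1"], "Xi")
  expect_equal(s$per_site$consistency[s$per_site$site_id == "s2"], "mixed")
  empty <- summarize_sites(pairs[pairs$fdr_p > 0.9, ])
  expect_equal(empty$n_significant_sites, 0L)
})

test_that("replicate concordance recovers shared allele fractions", {
  # identical replicates: r = 1
  x <- c(a = 1, b = -2, c = 3, d = 0.5)
  expect_equal(replicate_concordance(x, x)$r, 1)
  # independent noise: small |r|
  set.seed(5)
  n1 <- rnorm(100); n2 <- rnorm(100)
  names(n1) <- names(n2) <- sprintf("s%d", 1:100)
  expect_lt(abs(replicate_concordance(n1, n2)$r), 0.25)
  # shared binomial truth at 67 sites: r >= 0.8
  set.seed(6)
  f <- c(rbeta(60, 8, 2), rbeta(7, 1, 30))  # Xa-skewed plus Xi-like sites
  tot1 <- rnbinom(67, mu = 60, size = 5) + 1
  tot2 <- rnbinom(67, mu = 60, size = 5) + 1
  r1 <- rbinom(67, tot1, f); r2 <- rbinom(67, tot2, f)
  s1 <- imbalance_score(r1, tot1 - r1); s2 <- imbalance_score(r2, tot2 - r2)
  names(s1) <- names(s2) <- sprintf("h%02d", 1:67)
  expect_gte(replicate_concordance(s1, s2)$r, 0.8)
  expect_error(replicate_concordance(x[1:2], x[1:2]), "3 shared")
  const <- c(a = 1, b = 1, c = 1)
  expect_error(replicate_concordance(const, const), "constant")
})

test_that("peak restriction never increases the tested site count", {
  sim <- simulate_allelic_counts(allelic_sim_config(n_sites = 60L,
                                                    n_datasets = 2L,
                                                    seed = 14))
  all_pairs <- batch_imbalance_test(sim$counts)
  keep <- sprintf("site%03d", 1:20)
  sub <- batch_imbalance_test(sim$counts[sim$counts$site_id %in% keep, ])
  expect_lte(length(unique(sub$site_id)), length(unique(all_pairs$site_id)))
  expect_lte(nrow(sub), nrow(all_pairs))
})
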