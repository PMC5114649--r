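#' Configuration for the synthetic CAGE cohort generator
#'
#' Defaults describe the simulated study conditions: 100 samples per sex,
#' 500 X-linked and 500 autosomal TSSs, 20 escapee TSSs transcribed roughly
#' twice as high in females (approximating bi-allelic output from Xa and Xi),
#' and an XIST-like TSS expressed only in females. Samples belong to
#' overlapping cell-category groups whose effects the principal-component
#' covariates of the differential test are meant to absorb.
#'
#' @param n_female,n_male Samples per sex.
#' @param n_tss_x,n_tss_auto TSS counts on chrX (non-PAR) and autosomes.
#' @param n_escapee Number of escapee TSSs planted on chrX.
#' @param escapee_female_fold Multiplicative fold on the female mean TPM at
#'   escapee TSSs (default 2, the bi-allelic two-dose approximation).
#' @param xist_like Add one female-only TSS (male TPM exactly 0)?
#' @param xist_silenced_female_frac Fraction of females whose XIST-like TSS
#'   is silenced (emulating cancer lines that have lost the Xi); escapee
#'   signal is left intact in those samples.
#' @param n_categories Number of overlapping cell-category terms.
#' @param category_effect_sd SD of per-(category, TSS) effects, log10 units.
#' @param noise_sd Residual SD of log10 TPM per sample.
#' @param baseline_log_mean_sd Mean and SD of per-TSS baseline log10 TPM.
#' @param escapee_log_mean_sd Mean and SD of escapee baseline log10 TPM;
#'   escapees are detectable, moderately expressed promoters.
#' @param repeat_fraction Fraction of non-escapee TSSs flagged as overlapping
#'   repetitive elements (excluded from testing downstream).
#' @param seed Integer seed.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 100L, n_male = 100L,
                          n_tss_x = 500L, n_tss_auto = 500L,
                          n_escapee = 20L, escapee_female_fold = 2,
                          xist_like = TRUE, xist_silenced_female_frac = 0,
                          n_categories = 10L, category_effect_sd = 0.3,
                          noise_sd = 0.2,
                          baseline_log_mean_sd = c(1.0, 0.5),
                          escapee_log_mean_sd = c(1.2, 0.3),
                          repeat_fraction = 0.2, seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_escapee > cfg$n_tss_x)
    stop("config error: n_escapee > n_tss_x")
  if (cfg$escapee_female_fold <= 0) stop("config error: fold must be > 0")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1)
    stop("config error: repeat_fraction outside [0,1]")
  if (cfg$xist_silenced_female_frac < 0 || cfg$xist_silenced_female_frac > 1)
    stop("config error: xist_silenced_female_frac outside [0,1]")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic sex-labelled CAGE cohort
#'
#' Per-TSS baseline log10 expression is drawn once; each sample's log10 TPM
#' is baseline + the sum of its category effects + a sex effect + Gaussian
#' noise, then back-transformed (non-negative by construction). Escapee TSSs
#' add `log10(escapee_female_fold)` to the female mean; the XIST-like TSS has
#' male TPM exactly 0. Repeat flags are placed only on non-escapee,
#' non-XIST TSSs so the planted truth stays in the tested universe.
#'
#' @param config A [cohort_config()].
#' @return A list with `values` (TSS x sample TPM matrix), `tss` (annotation
#'   table), `samples` (sample table), `categories` (sample x category 0/1
#'   membership matrix) and `truth` (per-TSS class:
#'   escapee / xist / null_x / autosomal).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_x <- config$n_tss_x + as.integer(config$xist_like)
    n_tss <- n_x + config$n_tss_auto
    n_s <- config$n_female + config$n_male

    tss_id <- sprintf("tss%04d", seq_len(n_tss))
    chrom <- rep(c("chrX", "chr7"), c(n_x, config$n_tss_auto))
    start <- c(seq_len(n_x), seq_len(config$n_tss_auto)) * 10000L
    strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    gene <- sprintf("G%s%03d", ifelse(chrom == "chrX", "X", "A"),
                    ceiling(c(seq_len(n_x), seq_len(config$n_tss_auto)) / 2))

    cls <- rep("null_x", n_tss)
    cls[chrom == "chr7"] <- "autosomal"
    esc_idx <- sample(config$n_tss_x, config$n_escapee)
    cls[esc_idx] <- "escapee"
    xist_idx <- integer(0)
    if (config$xist_like) {
      xist_idx <- n_x
      cls[xist_idx] <- "xist"
      gene[xist_idx] <- "XIST_LIKE"
    }
    gene[esc_idx] <- sprintf("GESC%03d", seq_along(esc_idx))

    rep_ok <- !(cls %in% c("escapee", "xist"))
    repeat_overlap <- rep(FALSE, n_tss)
    repeat_overlap[rep_ok] <- stats::runif(sum(rep_ok)) < config$repeat_fraction

    tss <- data.frame(tss_id = tss_id, chrom = chrom, start = start,
                      end = start + 1L, strand = strand, nearest_gene = gene,
                      par_flag = FALSE, repeat_overlap = repeat_overlap,
                      stringsAsFactors = FALSE)

    sample_id <- sprintf("s%03d", seq_len(n_s))
    sex <- rep(c("female", "male"), c(config$n_female, config$n_male))
    samples <- data.frame(sample_id = sample_id, sex = sex,
                          donor_id = sample_id, replicate_index = 1L,
                          treated = FALSE, categories = "",
                          stringsAsFactors = FALSE)

    # overlapping category structure: one primary term plus random extras
    memb <- matrix(0L, n_s, config$n_categories,
                   dimnames = list(sample_id,
                                   sprintf("cat%02d", seq_len(config$n_categories))))
    primary <- sample(config$n_categories, n_s, replace = TRUE)
    memb[cbind(seq_len(n_s), primary)] <- 1L
    extra <- matrix(stats::runif(n_s * config$n_categories) < 0.15,
                    n_s, config$n_categories)
    memb[extra] <- 1L
    samples$categories <- apply(memb, 1, function(r)
      paste(colnames(memb)[r == 1L], collapse = ","))

    baseline <- stats::rnorm(n_tss, config$baseline_log_mean_sd[1],
                             config$baseline_log_mean_sd[2])
    baseline[esc_idx] <- stats::rnorm(length(esc_idx),
                                      config$escapee_log_mean_sd[1],
                                      config$escapee_log_mean_sd[2])
    if (length(xist_idx)) baseline[xist_idx] <- 1.5

    cat_eff <- matrix(stats::rnorm(n_tss * config$n_categories,
                                   sd = config$category_effect_sd),
                      n_tss, config$n_categories)
    logv <- matrix(baseline, n_tss, n_s) +
      cat_eff %*% t(memb) +
      matrix(stats::rnorm(n_tss * n_s, sd = config$noise_sd), n_tss, n_s)

    is_f <- sex == "female"
    if (length(esc_idx))
      logv[esc_idx, is_f] <- logv[esc_idx, is_f, drop = FALSE] +
        log10(config$escapee_female_fold)

    values <- 10^logv
    if (length(xist_idx)) {
      values[xist_idx, !is_f] <- 0
      if (config$xist_silenced_female_frac > 0) {
        fem <- which(is_f)
        silenced <- fem[stats::runif(length(fem)) <
                          config$xist_silenced_female_frac]
        values[xist_idx, silenced] <- 0
      }
    }
    dimnames(values) <- list(tss_id, sample_id)

    list(values = values, tss = tss, samples = samples, categories = memb,
         truth = data.frame(tss_id = tss_id, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Configuration for the synthetic methylation generator
#'
#' Class means follow promoter methylation on chrX: subject-gene promoters
#' are methylated on the Xi (female intermediate, male low); escapee
#' promoters are unmethylated on both X's in both sexes; the XIST-like
#' promoter is methylated on the single active X in males and
#' hemi-methylated in females. The majority of array probes on chrX are not
#' promoter-CpG-island probes: these "body" probes are highly methylated in
#' males and intermediate in females (Xi gene-body hypomethylation), and they
#' carry the positive M-A trend observed on real chrX arrays.
#'
#' @param n_female,n_male Samples per sex.
#' @param n_subject,n_escapee,n_body chrX probe counts per class.
#' @param n_auto,n_auto_diff Autosomal probes (total / sex-differential).
#' @param xist_like Include one XIST-like promoter probe?
#' @param concentration Beta-distribution concentration (mean * c, (1-mean) * c).
#' @param auto_sex_logit Logit-scale sex effect at differential autosomal probes.
#' @param age_logit_sd,stage_logit_sd SDs of per-probe age (per year) and
#'   stage (per level) effects on the logit scale, autosomal probes only.
#' @param seed Integer seed.
#' @export
methylation_config <- function(n_female = 50L, n_male = 50L,
                               n_subject = 160L, n_escapee = 25L,
                               n_body = 325L, n_auto = 600L,
                               n_auto_diff = 20L, xist_like = TRUE,
                               concentration = 50,
                               auto_sex_logit = 1.0,
                               age_logit_sd = 0.004, stage_logit_sd = 0.05,
                               seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$concentration <= 0) stop("config error: concentration must be > 0")
  if (cfg$n_auto_diff > cfg$n_auto) stop("config error: n_auto_diff > n_auto")
  class(cfg) <- "methylation_config"
  cfg
}

.class_means <- list(
  subject = c(male = 0.05, female = 0.40),
  escapee = c(male = 0.05, female = 0.05),
  body    = c(male = 0.85, female = 0.55),
  xist    = c(male = 0.90, female = 0.50))

#' Generate a synthetic 450k-style methylation dataset
#'
#' Beta values are drawn from Beta distributions parameterised by the class
#' mean and a concentration; autosomal probes get additional small additive
#' age and stage effects on the logit scale (plus a sex effect at the
#' designated differential subset) for the nested-model F test. chrX probes
#' are positioned within 50 bp of a synthetic TSS of the matching class so
#' probe-to-TSS assignment can be exercised end to end.
#'
#' @param config A [methylation_config()].
#' @return A list with `betas` (probe x sample matrix), `probes` (probe_id,
#'   chrom, pos (0-based), class), `tss` (synthetic TSS table, chrX),
#'   `covars` (sample_id, sex, age, stage) and `truth` (per-probe class).
#' @export
generate_methylation <- function(config = methylation_config()) {
  stopifnot(inherits(config, "methylation_config"))
  with_seed(config$seed, {
    n_s <- config$n_female + config$n_male
    sex <- rep(c("female", "male"), c(config$n_female, config$n_male))
    covars <- data.frame(sample_id = sprintf("m%03d", seq_len(n_s)),
                         sex = sex,
                         age = round(stats::runif(n_s, 40, 80)),
                         stage = sample(1:4, n_s, replace = TRUE),
                         stringsAsFactors = FALSE)

    cls <- rep(c("subject", "escapee", "body"),
               c(config$n_subject, config$n_escapee, config$n_body))
    if (config$xist_like) cls <- c(cls, "xist")
    n_x <- length(cls)
    n_p <- n_x + config$n_auto

    probe_id <- sprintf("cg%06d", seq_len(n_p))
    chrom <- rep(c("chrX", "chr7"), c(n_x, config$n_auto))

    # chrX probes sit near a TSS of their class; promoter classes matter for
    # probe-to-TSS assignment, body probes are placed away from TSSs
    tss_pos <- seq_len(n_x) * 5000L
    tss <- data.frame(tss_id = sprintf("mtss%04d", seq_len(n_x)),
                      chrom = "chrX", start = tss_pos, end = tss_pos + 1L,
                      strand = "+", nearest_gene = sprintf("MG%04d", seq_len(n_x)),
                      par_flag = FALSE, repeat_overlap = FALSE,
                      class = cls, stringsAsFactors = FALSE)
    offset <- sample(-40:40, n_x, replace = TRUE)
    pos_x <- ifelse(cls == "body", tss_pos + 2500L, tss_pos + offset)
    pos <- c(pos_x, seq_len(config$n_auto) * 5000L)

    is_f <- sex == "female"
    mu <- matrix(NA_real_, n_p, n_s)
    for (k in names(.class_means)) {
      idx <- which(cls == k)
      if (!length(idx)) next
      mu[idx, is_f] <- .class_means[[k]]["female"]
      mu[idx, !is_f] <- .class_means[[k]]["male"]
    }

    # autosomal: bimodal base means, logit-scale covariate effects
    auto_idx <- n_x + seq_len(config$n_auto)
    base <- ifelse(stats::runif(config$n_auto) < 0.5, 0.10, 0.85)
    b_age <- stats::rnorm(config$n_auto, 0, config$age_logit_sd)
    b_stage <- stats::rnorm(config$n_auto, 0, config$stage_logit_sd)
    diff_idx <- sample(config$n_auto, config$n_auto_diff)
    b_sex <- numeric(config$n_auto)
    b_sex[diff_idx] <- config$auto_sex_logit * sample(c(-1, 1),
                                                      config$n_auto_diff,
                                                      replace = TRUE)
    age_c <- covars$age - mean(covars$age)
    stage_c <- covars$stage - mean(covars$stage)
    lg <- outer(stats::qlogis(base), rep(1, n_s)) +
      outer(b_age, age_c) + outer(b_stage, stage_c) +
      outer(b_sex, as.numeric(is_f))
    mu[auto_idx, ] <- stats::plogis(lg)

    a <- mu * config$concentration
    b <- (1 - mu) * config$concentration
    betas <- matrix(stats::rbeta(n_p * n_s, a, b), n_p, n_s,
                    dimnames = list(probe_id, covars$sample_id))

    auto_cls <- rep("auto_null", config$n_auto)
    auto_cls[diff_idx] <- "auto_diff"
    truth <- data.frame(probe_id = probe_id, class = c(cls, auto_cls),
                        stringsAsFactors = FALSE)
    probes <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                         stringsAsFactors = FALSE)
    list(betas = betas, probes = probes, tss = tss, covars = covars,
         truth = truth)
  })
}

#' Generate a toy phased diploid genome with a mapability trap
#'
#' A random sequence carrying one exact duplicated segment (reads from inside
#' it cannot map uniquely) and phased heterozygous sites, at least one of
#' which is planted inside the duplication.
#'
#' @param length Contig length in bp.
#' @param n_het Number of heterozygous sites.
#' @param dup_len Length of the duplicated segment (0 disables it).
#' @param seed Integer seed.
#' @return A list with `ref` (named character vector, one contig `toy`),
#'   `hets` (het-site table with `in_duplication` flag), and `dup`
#'   (`src_start`, `dst_start`, `len`, 0-based).
#' @export
generate_toy_genome <- function(length = 6000L, n_het = 12L,
                                dup_len = 400L, seed = 1L) {
  if (dup_len >= length / 2) stop("config error: dup_len must be < length/2")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seq <- sample(bases, length, replace = TRUE)
    dup <- NULL
    if (dup_len > 0) {
      src <- as.integer(length * 0.15)
      dst <- as.integer(length * 0.65)
      seq[(dst + 1):(dst + dup_len)] <- seq[(src + 1):(src + dup_len)]
      dup <- data.frame(src_start = src, dst_start = dst, len = dup_len)
    }
    # het positions: clear of contig ends; one inside the duplication copy
    margin <- 100L
    pool <- setdiff(seq.int(margin, length - margin), integer(0))
    if (!is.null(dup)) {
      inside <- seq.int(dup$dst_start + 50L, dup$dst_start + dup_len - 50L)
      outside <- setdiff(pool, c(seq.int(dup$src_start, dup$src_start + dup_len),
                                 seq.int(dup$dst_start, dup$dst_start + dup_len)))
      pos <- sort(c(sample(inside, 1L),
                    sample(outside, n_het - 1L)))
    } else {
      pos <- sort(sample(pool, n_het))
    }
    ref_allele <- seq[pos + 1L]
    alt_allele <- vapply(ref_allele, function(r)
      sample(setdiff(bases, r), 1L), character(1))
    maternal <- ifelse(stats::runif(n_het) < 0.5, ref_allele, alt_allele)
    hets <- data.frame(site_id = sprintf("h%02d", seq_len(n_het)),
                       chrom = "toy", pos = pos,
                       allele_a = ref_allele, allele_b = alt_allele,
                       maternal_allele = maternal,
                       in_duplication = if (!is.null(dup))
                         pos >= dup$dst_start & pos < dup$dst_start + dup_len
                       else FALSE,
                       stringsAsFactors = FALSE)
    ref <- c(toy = paste(seq, collapse = ""))
    list(ref = ref, hets = hets, dup = dup)
  })
}

#' Generate ChIP-seq peak sets enriched near target TSSs
#'
#' Plants a peak (of width `2 * halfwidth + 1` centred on the 5' position)
#' at each target TSS with probability `target_rate` and at each background
#' TSS with probability `bg_rate`. Default rates encode the bi-allelic
#' effect: in female cells a positive regulator binds the bi-allelically
#' active escapee TSSs on both X's, so its peak rate at targets is roughly
#' double the male-cell rate, while mono-allelic background TSSs stay at
#' the base rate in both sexes.
#'
#' @param target_tss,background_tss TSS tables.
#' @param n_per_sex Datasets per cell sex.
#' @param target_rate_female,target_rate_male Peak probability at targets.
#' @param bg_rate Peak probability at background TSSs (both sexes).
#' @param halfwidth Peak half-width in bp.
#' @param seed Integer seed.
#' @return A list with `peak_sets` (named list of interval tables) and
#'   `manifest` (`dataset_id`, `factor`, `cell_sex`, `lab`).
#' @export
generate_peak_sets <- function(target_tss, background_tss, n_per_sex = 20L,
                               target_rate_female = 0.6,
                               target_rate_male = 0.3, bg_rate = 0.15,
                               halfwidth = 100L, seed = 1L) {
  with_seed(seed, {
    mk <- function(rate_t) {
      plant <- function(tss, rate) {
        pos <- tss_positions(tss)
        hit <- stats::runif(nrow(tss)) < rate
        if (!any(hit)) return(NULL)
        data.frame(chrom = tss$chrom[hit],
                   start = pmax(0L, pos[hit] - halfwidth),
                   end = pos[hit] + halfwidth + 1L, strand = ".",
                   stringsAsFactors = FALSE)
      }
      out <- rbind(plant(target_tss, rate_t),
                   plant(background_tss, bg_rate))
      if (is.null(out))
        out <- data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character())
      out
    }
    ids <- c(sprintf("female_ds%02d", seq_len(n_per_sex)),
             sprintf("male_ds%02d", seq_len(n_per_sex)))
    sexes <- rep(c("female", "male"), each = n_per_sex)
    peak_sets <- lapply(seq_along(ids), function(i)
      mk(if (sexes[i] == "female") target_rate_female else target_rate_male))
    names(peak_sets) <- ids
    manifest <- data.frame(dataset_id = ids,
                           factor = sprintf("TF%02d", seq_along(ids)),
                           cell_sex = sexes,
                           lab = "simlab", stringsAsFactors = FALSE)
    list(peak_sets = peak_sets, manifest = manifest)
  })
}

#' Configuration for the allelic read-count simulator
#'
#' Emulates allele-specific ChIP-seq read counts at phased heterozygous
#' sites in a female cell line with skewed X inactivation: most sites are
#' Xa-biased (the norm the batch test compares against), a designated few
#' are strongly Xi-biased (XIST/FIRRE-like), and the remainder are balanced.
#' Read depths follow a negative binomial; defaults (mean 20 reads,
#' dispersion 5, 8 datasets) reflect typical allelic coverage at individual
#' het sites once replicates are merged.
#'
#' @param n_sites Number of heterozygous sites.
#' @param n_datasets Number of (factor, lab) datasets.
#' @param frac_xa_biased Fraction of sites in the Xa-biased norm class.
#' @param n_xi_sites Number of designated Xi-biased sites.
#' @param mean_total_reads Negative-binomial mean of per-(site, dataset) depth.
#' @param dispersion Negative-binomial size parameter.
#' @param xa_fraction_biased True Xa read fraction at norm sites.
#' @param xi_fraction_at_xi_sites True Xi read fraction at designated Xi sites.
#' @param seed Integer seed.
#' @export
allelic_sim_config <- function(n_sites = 200L, n_datasets = 8L,
                               frac_xa_biased = 0.8, n_xi_sites = 5L,
                               mean_total_reads = 20, dispersion = 5,
                               xa_fraction_biased = 0.8,
                               xi_fraction_at_xi_sites = 0.97, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("frac_xa_biased", "xa_fraction_biased", "xi_fraction_at_xi_sites"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config error: ", f, " outside (0,1)")
  n_xa <- round(cfg$frac_xa_biased * cfg$n_sites)
  if (n_xa + cfg$n_xi_sites > cfg$n_sites)
    stop("config error: Xa + Xi site counts exceed n_sites")
  class(cfg) <- "allelic_sim_config"
  cfg
}

#' Simulate allele-assigned read counts at heterozygous sites
#'
#' Per (site, dataset): total reads ~ NB(mean, dispersion), Xa reads ~
#' Binomial(total, f) with f set by the site's class (norm / designated Xi /
#' balanced).
#'
#' @param config An [allelic_sim_config()].
#' @return A list with `counts` (site_id, dataset_id, factor, lab, Ra, Ri)
#'   and `truth` (site_id, class in xa_norm / xi / balanced, true_xa_fraction).
#' @export
simulate_allelic_counts <- function(config = allelic_sim_config()) {
  stopifnot(inherits(config, "allelic_sim_config"))
  with_seed(config$seed, {
    n_xa <- round(config$frac_xa_biased * config$n_sites)
    n_xi <- config$n_xi_sites
    n_bal <- config$n_sites - n_xa - n_xi
    cls <- rep(c("xa_norm", "xi", "balanced"), c(n_xa, n_xi, n_bal))
    cls <- sample(cls)  # interleave site classes along the chromosome
    f <- c(xa_norm = config$xa_fraction_biased,
           xi = 1 - config$xi_fraction_at_xi_sites,
           balanced = 0.5)[cls]
    site_id <- sprintf("site%03d", seq_len(config$n_sites))
    counts <- vector("list", config$n_datasets)
    for (d in seq_len(config$n_datasets)) {
      tot <- stats::rnbinom(config$n_sites, mu = config$mean_total_reads,
                            size = config$dispersion)
      ra <- stats::rbinom(config$n_sites, tot, f)
      counts[[d]] <- data.frame(site_id = site_id,
                                dataset_id = sprintf("ds%02d", d),
                                factor = sprintf("TF%02d", d),
                                lab = sprintf("lab%02d", (d - 1L) %% 4L + 1L),
                                Ra = ra, Ri = tot - ra,
                                stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, counts),
         truth = data.frame(site_id = site_id, class = cls,
                            true_xa_fraction = unname(f),
                            stringsAsFactors = FALSE))
  })
}
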