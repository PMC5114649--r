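#' Array beta value from methylated/unmethylated intensities
#'
#' `Meth / (Meth + Unmeth + offset)` with the standard offset of 100.
#'
#' @param meth,unmeth Non-negative intensities (vectorised).
#' @param offset Stabilising offset.
#' @return Beta values in `[0, 1)`.
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0) || any(unmeth < 0))
    stop("value error: negative intensity")
  meth / (meth + unmeth + offset)
}

#' M/A transform of per-sex mean beta values
#'
#' M (difference) is `log2(beta_male / beta_female)`; A (magnitude) is
#' `log2((beta_male + beta_female) / 2)`. Probes with a non-positive mean in
#' either sex get `NA` in both components and are expected to be excluded
#' from the fit.
#'
#' @param beta_male,beta_female Per-probe mean beta values by sex.
#' @return `data.frame` with columns `M` and `A`.
#' @export
ma_transform <- function(beta_male, beta_female) {
  ok <- beta_male > 0 & beta_female > 0
  M <- A <- rep(NA_real_, length(beta_male))
  M[ok] <- log2(beta_male[ok] / beta_female[ok])
  A[ok] <- log2((beta_male[ok] + beta_female[ok]) / 2)
  data.frame(M = M, A = A)
}

#' Robust regression of M on A with Tukey's bisquare
#'
#' Iteratively reweighted least squares for `M = d0 + d1 A`: initialised by
#' ordinary least squares, with the residual scale re-estimated each
#' iteration as MAD/0.6745 and bisquare weights
#' `(1 - (r/(c*s))^2)^2` (exactly zero beyond `tuning_c` scaled residuals).
#' The residuals are the DNA-methylation sex-similarity scores: probes far
#' above the chrX trend (M near 0 at low A) have similar methylation in both
#' sexes, the signature of bi-allelically active escapee promoters.
#'
#' @param M,A Numeric vectors (NA pairs are dropped).
#' @param tuning_c Bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficient change.
#' @return An object of class `ma_fit` with `d0`, `d1`, `weights`,
#'   `residuals` (similarity scores, NA where input was NA), `rho` (Pearson
#'   correlation of the complete M, A pairs), `converged`, `iterations`.
#' @export
robust_fit <- function(M, A, tuning_c = 4.685, max_iter = 50L, tol = 1e-8) {
  stopifnot(length(M) == length(A))
  ok <- stats::complete.cases(M, A)
  if (sum(ok) < 3L) stop("robust_fit: need >= 3 complete probes")
  m <- M[ok]; a <- A[ok]
  X <- cbind(1, a)
  beta <- stats::lm.fit(X, m)$coefficients
  converged <- FALSE
  iter <- 0L
  w <- rep(1, length(m))
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- as.numeric(m - X %*% beta)
    s <- stats::median(abs(r)) / 0.6745  # MAD about zero: r are fit residuals
    if (s == 0) { converged <- TRUE; break }
    u <- abs(r / (tuning_c * s))
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2L) break
    newbeta <- stats::lm.wfit(X, m, w)$coefficients
    if (max(abs(newbeta - beta)) < tol) {
      beta <- newbeta; converged <- TRUE; break
    }
    beta <- newbeta
  }
  res_all <- rep(NA_real_, length(M))
  res_all[ok] <- M[ok] - (beta[1] + beta[2] * A[ok])
  w_all <- rep(NA_real_, length(M))
  w_all[ok] <- w
  out <- list(d0 = unname(beta[1]), d1 = unname(beta[2]),
              weights = w_all, residuals = res_all,
              rho = stats::cor(m, a), converged = converged,
              iterations = iter, n = sum(ok))
  class(out) <- "ma_fit"
  out
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("robust M-on-A fit: M = %.4f + %.4f A  (n = %d, rho = %.3f)\n",
              x$d0, x$d1, x$n, x$rho))
  if (!x$converged) cat("  warning: IRLS did not converge\n")
  invisible(x)
}

#' @export
coef.ma_fit <- function(object, ...) c(d0 = object$d0, d1 = object$d1)

#' @export
residuals.ma_fit <- function(object, ...) object$residuals

#' Average similarity score of probes near each TSS
#'
#' Probes within `window` bp (boundary inclusive) of the strand-aware 5'
#' TSS position are assigned to the TSS; the mean similarity score is
#' returned. TSSs with no assigned probe are omitted.
#'
#' @param scores Per-probe similarity scores (named by probe or aligned with
#'   `probes` rows).
#' @param probes Probe table with `chrom`, `pos` (0-based).
#' @param tss TSS table with `chrom`, `start`, `end`, `strand`, `tss_id`.
#' @param window Assignment window in bp.
#' @return `data.frame` with `tss_id`, `n_probes`, `mean_score`.
#' @export
probe_tss_similarity <- function(scores, probes, tss, window = 50L) {
  stopifnot(length(scores) == nrow(probes))
  pos5 <- tss_positions(tss)
  out <- lapply(seq_len(nrow(tss)), function(i) {
    sel <- probes$chrom == tss$chrom[i] &
      abs(probes$pos - pos5[i]) <= window
    sc <- scores[sel]
    sc <- sc[!is.na(sc)]
    if (!length(sc)) return(NULL)
    data.frame(tss_id = tss$tss_id[i], n_probes = length(sc),
               mean_score = mean(sc), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(tss_id = character(), n_probes = integer(),
                      mean_score = numeric())
  res
}

#' Compare similarity scores of escapee vs nonDT TSSs
#'
#' One-sided two-sample Wilcoxon rank-sum test of the hypothesis that
#' escapee similarity scores are higher than nonDT scores.
#'
#' @param esc_scores,nondt_scores Numeric score vectors.
#' @return A list with `statistic` and `p`.
#' @export
compare_similarity <- function(esc_scores, nondt_scores) {
  if (!length(esc_scores) || !length(nondt_scores))
    stop("error: both score groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(esc_scores, nondt_scores,
                                            alternative = "greater"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Nested-model F test for sex-differential autosomal methylation
#'
#' Compares OLS fits with covariates age and stage, with and without the
#' sex indicator: `F = ((RSS_r - RSS_f)/1) / (RSS_f/(n - p_f))`. Applied to
#' each row of a beta matrix; Bonferroni correction across the tested
#' probes.
#'
#' @param betas Probe x sample matrix (or a single probe vector).
#' @param sex Character or 0/1 indicator per sample.
#' @param age,stage Numeric covariates per sample.
#' @return `data.frame` with `probe_id`, `F`, `raw_p`, `bonferroni_p`.
#' @export
autosomal_dm_test <- function(betas, sex, age, stage) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1,
                                           dimnames = list("probe", NULL))
  n <- ncol(betas)
  if (n <= 4L) stop("error: need n > 4 samples")
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(as.character(sex) == "male")
  Xr <- cbind(1, age, stage)
  Xf <- cbind(Xr, sex)
  qr_r <- qr(Xr); qr_f <- qr(Xf)
  if (qr_f$rank < ncol(Xf)) stop("fit error: rank-deficient design")
  rss_r <- colSums(qr.resid(qr_r, t(betas))^2)
  rss_f <- colSums(qr.resid(qr_f, t(betas))^2)
  df2 <- n - ncol(Xf)
  Fstat <- (rss_r - rss_f) / (rss_f / df2)
  raw_p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  raw_p[rss_f == 0] <- 0
  data.frame(probe_id = rownames(betas), F = unname(Fstat),
             raw_p = unname(raw_p),
             bonferroni_p = pmin(1, raw_p * nrow(betas)),
             stringsAsFactors = FALSE, row.names = NULL)
}
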