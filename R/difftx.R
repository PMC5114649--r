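#' Transcription-level transform for per-TSS regression
#'
#' `log10(TPM + 5)`; the +5 pseudocount stabilises low-expression TSSs.
#'
#' @param tpm Non-negative tags-per-million values.
#' @return Transformed values.
#' @export
transform_expression <- function(tpm) {
  if (any(tpm < 0)) stop("value error: negative expression")
  log10(tpm + 5)
}

#' Principal components of cell-category membership
#'
#' PCA of the sample x category indicator matrix (centred; scaling optional).
#' Retains the smallest number of components whose cumulative explained
#' variance strictly exceeds `variance_threshold`; with a threshold of 1 the
#' full positive-variance rank is returned.
#'
#' @param membership Sample x category 0/1 matrix.
#' @param variance_threshold Cumulative-variance cutoff in (0, 1].
#' @param scale. Scale the indicators to unit variance before PCA?
#' @return A list of class `category_pcs` with `n_components`,
#'   `variance_explained` (all components) and `scores` (sample x retained
#'   component matrix).
#' @export
category_pcs <- function(membership, variance_threshold = 0.90, scale. = FALSE) {
  stopifnot(nrow(membership) >= 2L,
            variance_threshold > 0, variance_threshold <= 1)
  sds <- apply(membership, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate-input error: constant membership matrix")
  if (scale.) membership <- membership[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(membership, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  pos <- sum(pc$sdev^2 > max(pc$sdev^2) * 1e-12)
  above <- which(cumsum(ve) > variance_threshold)
  k <- if (length(above)) min(above) else pos
  k <- min(k, pos)
  out <- list(n_components = k, variance_explained = ve,
              scores = pc$x[, seq_len(k), drop = FALSE])
  class(out) <- "category_pcs"
  out
}

#' @export
print.category_pcs <- function(x, ...) {
  cat(sprintf("category PCs: %d components, %.1f%% variance\n",
              x$n_components, 100 * sum(x$variance_explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Per-TSS linear model of transformed expression on covariates and sex
#'
#' Ordinary least squares of y on `[intercept, PC scores, sex indicator]`
#' with sex coded male = 1, female = 0, so a negative sex coefficient means
#' higher expression in females. The p-value is the two-sided t-test on the
#' sex coefficient. `fit_tss_models` fits all rows of a matrix against the
#' shared design in one QR decomposition.
#'
#' @param y Transformed expression, one value per sample.
#' @param pcs A [category_pcs()] result, or `NULL` for no covariates.
#' @param sex Character (`"male"`/`"female"`) or 0/1 indicator per sample.
#' @return For `fit_tss_model`: list with `coefficient` and `raw_p`. For
#'   `fit_tss_models`: `data.frame` with `tss_id`, `coefficient`, `raw_p`.
#' @export
fit_tss_model <- function(y, pcs, sex) {
  res <- fit_tss_models(matrix(y, nrow = 1,
                               dimnames = list("y", names(y))), pcs, sex)
  list(coefficient = res$coefficient, raw_p = res$raw_p)
}

#' @rdname fit_tss_model
#' @param Y TSS x sample matrix of transformed expression.
#' @export
fit_tss_models <- function(Y, pcs, sex) {
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(as.character(sex) == "male")
  n <- ncol(Y)
  scores <- if (is.null(pcs)) NULL else pcs$scores
  X <- cbind(`(Intercept)` = 1, scores, sex = sex)
  p <- ncol(X)
  if (n <= p + 1L)
    stop("fit error: need n_samples > n_components + 2")
  qx <- qr(X)
  if (qx$rank < p) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("fit error: rank-deficient design, collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  coefs <- qr.coef(qx, t(Y))                # p x nTSS
  resid <- t(Y) - X %*% coefs
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  XtXinv_sex <- chol2inv(qr.R(qx))[p, p]    # (X'X)^{-1} diagonal, sex term
  se <- sqrt(sigma2 * XtXinv_sex)
  b <- coefs[p, ]
  tval <- ifelse(se > 0, b / se, ifelse(b == 0, 0, sign(b) * Inf))
  raw_p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.frame(tss_id = rownames(Y), coefficient = unname(b),
             raw_p = unname(raw_p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call escapee TSSs from per-TSS sex coefficients
#'
#' Repeat-overlapping TSSs are excluded before correction; Bonferroni is
#' taken over the retained X-non-PAR universe. A TSS is an `escTSS` when its
#' corrected p-value is <= `alpha` (boundary inclusive) and the sex
#' coefficient is negative (higher female expression); `male_biased` with a
#' positive coefficient; otherwise `nonDT`. TSSs with corrected p exactly 1
#' form the nonDT background used downstream.
#'
#' @param fits Output of [fit_tss_models()] for the X-non-PAR TSSs.
#' @param tss TSS annotation table (needs `tss_id`, `repeat_overlap`,
#'   `nearest_gene`).
#' @param alpha Significance level on the corrected p-value.
#' @return `data.frame` with `tss_id`, `coefficient`, `raw_p`,
#'   `bonferroni_p`, `class`, `nearest_gene`.
#' @export
classify_tss <- function(fits, tss, alpha = 0.05) {
  m <- merge(fits, tss[, c("tss_id", "repeat_overlap", "nearest_gene")],
             by = "tss_id", sort = FALSE)
  retained <- !m$repeat_overlap
  if (!any(retained)) stop("error: empty retained TSS universe")
  n_tests <- sum(retained)
  m$bonferroni_p <- NA_real_
  m$bonferroni_p[retained] <- pmin(1, m$raw_p[retained] * n_tests)
  m$class <- "excluded_repeat"
  sig <- retained & m$bonferroni_p <= alpha
  m$class[retained] <- "nonDT"
  m$class[sig & m$coefficient < 0] <- "escTSS"
  m$class[sig & m$coefficient > 0] <- "male_biased"
  m[, c("tss_id", "coefficient", "raw_p", "bonferroni_p", "class",
        "nearest_gene")]
}

#' Collapse escapee TSSs to unique gene symbols
#'
#' @param de_results A [classify_tss()] result.
#' @return Character vector of unique nearest-gene symbols of escTSSs.
#' @export
gene_rollup <- function(de_results) {
  unique(de_results$nearest_gene[de_results$class == "escTSS"])
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

#' Benchmark a predicted escapee gene set against published lists
#'
#' True escapees are genes reported by at least two of the four approaches
#' (the predicted list itself counts as one approach alongside the three
#' published lists). Precision is the fraction of predicted genes that are
#' true; recall the fraction of true escapees predicted. Reported values are
#' rounded half-up to two decimals; full precision is kept in
#' `precision_full` / `recall_full`.
#'
#' @param predicted Character vector of predicted escapee genes.
#' @param published List of three character vectors (published escapee sets).
#' @return A list with `true_escapees`, `per_list_overlap`, `precision`,
#'   `recall` and the unrounded values.
#' @export
benchmark_escapees <- function(predicted, published) {
  if (length(predicted) == 0L)
    stop("precision undefined error: empty predicted set")
  stopifnot(length(published) == 3L)
  all_lists <- c(list(unique(predicted)), lapply(published, unique))
  genes <- unique(unlist(all_lists))
  counts <- rowSums(vapply(all_lists, function(l) genes %in% l,
                           logical(length(genes))))
  true_esc <- genes[counts >= 2L]
  tp <- intersect(predicted, true_esc)
  precision <- length(tp) / length(unique(predicted))
  recall <- length(tp) / length(true_esc)
  list(true_escapees = true_esc,
       per_list_overlap = vapply(published, function(l)
         length(intersect(predicted, l)), integer(1)),
       precision = round_half_up(precision), recall = round_half_up(recall),
       precision_full = precision, recall_full = recall)
}

#' Male/female expression log2 ratio with a stabilising constant
#'
#' `log2((mean_male + c) / (mean_female + c))` with `c` conventionally the
#' 5th-percentile expression, avoiding zero denominators.
#'
#' @param mean_male,mean_female Non-negative mean expression values.
#' @param c Positive constant.
#' @return log2 ratio (vectorised).
#' @export
expression_log2_ratio <- function(mean_male, mean_female, c) {
  if (any(c <= 0)) stop("value error: constant must be > 0")
  log2((mean_male + c) / (mean_female + c))
}
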