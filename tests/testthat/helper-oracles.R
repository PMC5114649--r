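# Independent oracles used across the suite. These deliberately avoid the
# code paths (and where possible the library routines) they are checking.

# Hypergeometric tail enumeration from binomial coefficients only.
# Table: [a, n1 - a; b, n2 - b], testing enrichment of the first row.
oracle_fisher <- function(a, n1, b, n2, alternative = "greater") {
  k <- a + b
  lo <- max(0L, k - n2)
  hi <- min(n1, k)
  supp <- lo:hi
  logp <- lchoose(n1, supp) + lchoose(n2, k - supp) - lchoose(n1 + n2, k)
  d <- exp(logp - max(logp))
  d <- d / sum(d)
  obs <- d[supp == a]
  if (alternative == "greater") sum(d[supp >= a])
  else if (alternative == "less") sum(d[supp <= a])
  else sum(d[d <= obs * (1 + 1e-7)])  # same tie rule as fisher.test
}

# OLS of y on X by explicit normal equations, with the t-test on the last
# coefficient.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tv <- as.numeric(b[length(b)] / se[length(se)])
  list(coef = as.numeric(b), t = tv,
       p = 2 * pt(abs(tv), df, lower.tail = FALSE))
}

# Bisquare IRLS coded independently: explicit normal equations with weight
# matrices, same algorithm contract (OLS init, MAD/0.6745 about zero).
oracle_irls <- function(M, A, c = 4.685, max_iter = 50, tol = 1e-8) {
  X <- cbind(1, A)
  b <- solve(t(X) %*% X, t(X) %*% M)
  for (i in seq_len(max_iter)) {
    r <- as.numeric(M - X %*% b)
    s <- median(abs(r)) / 0.6745
    if (s == 0) break
    u <- abs(r / (c * s))
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    W <- diag(w)
    nb <- solve(t(X) %*% W %*% X, t(X) %*% W %*% M)
    if (max(abs(nb - b)) < tol) { b <- nb; break }
    b <- nb
  }
  as.numeric(b)
}

# Exhaustive per-offset motif scoring on one strand of a sequence.
oracle_scan_strand <- function(seq, lo) {
  bases <- strsplit(seq, "")[[1]]
  L <- ncol(lo)
  n <- length(bases) - L + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(off) {
    s <- 0
    for (j in seq_len(L)) {
      b <- bases[off + j - 1]
      if (b %in% c("A", "C", "G", "T")) s <- s + lo[b, j]
    }
    s
  }, numeric(1))
}

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

make_region_set <- function(seqs, chrom = "c", gap = 1000L) {
  starts <- (seq_along(seqs) - 1L) * (max(nchar(seqs)) + gap)
  structure(list(
    intervals = genomic_intervals(rep(chrom, length(seqs)), starts,
                                  starts + nchar(seqs)),
    sequences = seqs), class = "region_set")
}

# Small deterministic motif from a consensus string.
consensus_motif <- function(id, consensus, depth = 20) {
  L <- nchar(consensus)
  cm <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L))
    cm[substr(consensus, j, j), j] <- depth
  motif_model(id, cm)
}

plant_motif <- function(seqs, consensus, which_idx) {
  L <- nchar(consensus)
  for (i in which_idx) {
    p <- sample(nchar(seqs[i]) - L, 1)
    seqs[i] <- paste0(substr(seqs[i], 1, p), consensus,
                      substr(seqs[i], p + L + 1, nchar(seqs[i])))
  }
  seqs
}

# Shared mid-size cohort analysis, memoised so the expensive pieces run once
# per test session.
.fixture_env <- new.env(parent = emptyenv())

cohort_analysis <- function(seed = 7) {
  key <- paste0("cohort", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  co <- generate_cohort(cohort_config(seed = seed))
  xmask <- co$tss$chrom == "chrX" & !co$tss$par_flag
  Y <- transform_expression(co$values[xmask, , drop = FALSE])
  pcs <- category_pcs(co$categories)
  fits <- fit_tss_models(Y, pcs, co$samples$sex)
  de <- classify_tss(fits, co$tss)
  out <- list(co = co, xmask = xmask, Y = Y, pcs = pcs, fits = fits, de = de)
  .fixture_env[[key]] <- out
  out
}
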