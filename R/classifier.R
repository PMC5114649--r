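#' Train the Random-Forest sex classifier on X-linked TSS expression
#'
#' Features are the X-non-PAR TSS expression values; the response is the
#' labelled sex. Performance is estimated out of bag (OOB): the OOB error
#' rate, the balanced accuracy of OOB predictions, and the proximity matrix
#' (fraction of trees in which two samples land in the same terminal node,
#' restricted to trees where both are out of bag).
#'
#' @param values TSS x sample expression matrix (rows = features).
#' @param labels Sex per sample, `"female"`/`"male"` (same order as columns).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed for the forest.
#' @return An object of class `sex_classifier` with elements `model`,
#'   `oob_error`, `balanced_accuracy`, `proximity`, `oob_votes`,
#'   `feature_ids`, `sample_ids`, `labels`.
#' @export
train_sex_classifier <- function(values, labels, n_trees = 500L, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("training error: need two classes in labels")
  if (min(table(labels)) < 2L)
    stop("training error: need >= 2 samples per class")
  x <- t(values)
  rf <- with_seed(seed,
    randomForest::randomForest(x = x, y = labels, ntree = n_trees,
                               proximity = TRUE, oob.prox = TRUE))
  conf <- table(truth = labels, pred = rf$predicted)
  res <- list(model = rf,
              oob_error = unname(rf$err.rate[n_trees, "OOB"]),
              balanced_accuracy = balanced_accuracy(conf),
              proximity = rf$proximity,
              oob_votes = rf$votes[, , drop = FALSE],
              feature_ids = rownames(values),
              sample_ids = colnames(values),
              labels = as.character(labels))
  class(res) <- "sex_classifier"
  res
}

#' @export
print.sex_classifier <- function(x, ...) {
  cat("Random-Forest sex classifier\n")
  cat(sprintf("  samples: %d  features: %d  trees: %d\n",
              length(x$sample_ids), length(x$feature_ids), x$model$ntree))
  cat(sprintf("  OOB error: %.4f  balanced accuracy: %.4f\n",
              x$oob_error, x$balanced_accuracy))
  invisible(x)
}

#' Balanced accuracy of a confusion table
#'
#' The mean of per-class recalls (rows = true class, columns = predicted).
#'
#' @param confusion A square count table with both true classes present.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  rs <- rowSums(confusion)
  if (any(rs == 0))
    stop("undefined error: a true class has zero row sum")
  mean(diag(confusion) / rs)
}

#' Detect labelled samples whose OOB vote contradicts their label
#'
#' A sample is an outlier when the strict OOB majority class differs from
#' its label; exact 50/50 vote ties are not outliers. Results are sorted by
#' decreasing vote margin (majority-class fraction minus label-class
#' fraction).
#'
#' @param fit A [train_sex_classifier()] result.
#' @return `data.frame` with `sample_id`, `labeled_sex`, `predicted_sex`,
#'   `vote_margin`.
#' @export
detect_outliers <- function(fit) {
  stopifnot(inherits(fit, "sex_classifier"))
  votes <- fit$oob_votes
  maj <- colnames(votes)[max.col(votes, ties.method = "first")]
  top <- apply(votes, 1, max)
  lab_frac <- votes[cbind(seq_len(nrow(votes)),
                          match(fit$labels, colnames(votes)))]
  is_out <- maj != fit$labels & top > lab_frac  # strict majority only
  out <- data.frame(sample_id = fit$sample_ids[is_out],
                    labeled_sex = fit$labels[is_out],
                    predicted_sex = maj[is_out],
                    vote_margin = top[is_out] - lab_frac[is_out],
                    stringsAsFactors = FALSE)
  out[order(-out$vote_margin), , drop = FALSE]
}

#' Embed a proximity matrix by classical multidimensional scaling
#'
#' Runs metric MDS on the dissimilarity `1 - proximity`; coordinates are
#' centred at the origin.
#'
#' @param proximity Symmetric matrix in `[0, 1]` with unit diagonal.
#' @param dims Number of output dimensions.
#' @return Sample x `dims` coordinate matrix.
#' @export
embed_proximity <- function(proximity, dims = 2L) {
  proximity <- as.matrix(proximity)
  if (!isSymmetric(unname(proximity), tol = 1e-8))
    stop("validation error: proximity matrix must be symmetric")
  coords <- stats::cmdscale(stats::as.dist(1 - proximity), k = dims)
  sweep(coords, 2, colMeans(coords))
}

#' Predict sex for unlabelled samples
#'
#' @param fit A [train_sex_classifier()] result.
#' @param values TSS x sample expression matrix; rows must match the
#'   training features.
#' @return Character vector of predicted sexes (empty input gives empty
#'   output).
#' @export
predict_sex <- function(fit, values) {
  stopifnot(inherits(fit, "sex_classifier"))
  if (is.null(dim(values)) || ncol(values) == 0L) return(character(0))
  if (!identical(rownames(values), fit$feature_ids))
    stop("schema error: feature ids do not match training features")
  as.character(stats::predict(fit$model, newdata = t(values)))
}
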