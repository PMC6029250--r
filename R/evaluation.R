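# Evaluation protocol: EC-number ground truth, ROC/AUC with
# accuracy/precision/recall versus score cutoff, and Pearson comparison of
# scoring configurations.

#' EC-number similarity label
#'
#' Two reactions count as similar when their EC numbers agree through the
#' first `level` dot-separated fields (default 3: through the sub-subclass).
#'
#' @param ecA,ecB EC number strings.
#' @param level number of leading fields compared.
#' @return logical.
#' @export
ec_similar <- function(ecA, ecB, level = 3L) {
  fa <- strsplit(ecA, ".", fixed = TRUE)[[1]]
  fb <- strsplit(ecB, ".", fixed = TRUE)[[1]]
  if (length(fa) < level || length(fb) < level)
    rs_error(sprintf("EC number with fewer than %d fields ('%s' vs '%s')",
                     level, ecA, ecB), "rs_ec_error")
  identical(fa[seq_len(level)], fb[seq_len(level)])
}

#' ROC curve, AUC and cutoff-dependent classification metrics
#'
#' Cutoffs are all distinct scores plus 0 and 1; a pair is called positive
#' when `score >= cutoff` (closed threshold).  AUC is the trapezoidal
#' integral over (FPR, TPR).  Precision at cutoffs with no positive calls is
#' recorded as `NA`, not 0.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels logical (or 0/1) ground-truth labels.
#' @return list with `curve` (data.frame: cutoff, tp, fp, tn, fn, tpr, fpr,
#'   precision, accuracy) and `auc`.
#' @export
roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || !length(scores))
    rs_error("scores and labels must be equal-length and non-empty",
             "rs_validation_error")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0)
    rs_error("ROC needs at least one positive and one negative label",
             "rs_degenerate_labels_error")
  # sorted cumulative counts: O(n log n) for arbitrarily many cutoffs
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  runs <- c(which(diff(s) != 0), length(s))  # last index of each score run
  cutoff <- s[runs]
  tp <- cumsum(l)[runs]
  fp <- cumsum(!l)[runs]
  if (!any(cutoff == 1)) { cutoff <- c(1, cutoff); tp <- c(0, tp); fp <- c(0, fp) }
  if (!any(cutoff == 0)) { cutoff <- c(cutoff, 0); tp <- c(tp, P); fp <- c(fp, N) }
  curve <- data.frame(cutoff = cutoff, tp = tp, fp = fp,
                      tn = N - fp, fn = P - tp,
                      tpr = tp / P, fpr = fp / N,
                      precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
                      accuracy = (tp + (N - fp)) / (P + N))
  # trapezoid over (fpr, tpr), ordered by increasing fpr
  ord <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[ord]; y <- curve$tpr[ord]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(curve = curve, auc = auc)
}

# independent normalisation of the Mann-Whitney U statistic; used as the
# AUC oracle in the test-suite and exposed for cross-checks
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Pearson correlation matrix of scoring configurations
#'
#' @param score_table data.frame or matrix: one column of scores per
#'   configuration, rows = the same reaction pairs in the same order.
#' @return symmetric correlation matrix; entries involving a zero-variance
#'   column are `NA`.
#' @export
pearson_matrix <- function(score_table) {
  m <- as.matrix(score_table)
  if (ncol(m) < 2 || nrow(m) < 3)
    rs_error("need >= 2 configurations scored on >= 3 common pairs",
             "rs_validation_error")
  out <- suppressWarnings(stats::cor(m, method = "pearson"))
  zero_var <- apply(m, 2, stats::sd) == 0
  out[zero_var, ] <- NA_real_
  out[, zero_var] <- NA_real_
  diag(out) <- 1
  out
}

#' Label scored reaction pairs by EC agreement and evaluate by ROC
#'
#' @param pairs data.frame with columns `score`, `ecA`, `ecB`.
#' @param level EC agreement level (default 3).
#' @return as [roc()], plus the labelled pair table; pairs with incomplete
#'   EC numbers are excluded with a warning.
#' @export
evaluate_ec_roc <- function(pairs, level = 3L) {
  lab <- vapply(seq_len(nrow(pairs)), function(q) {
    tryCatch(ec_similar(pairs$ecA[q], pairs$ecB[q], level),
             error = function(e) NA)
  }, NA)
  if (anyNA(lab)) {
    rs_warn(sprintf("%d pair(s) excluded: EC number shorter than %d fields",
                    sum(is.na(lab)), level))
  }
  keep <- !is.na(lab)
  res <- roc(pairs$score[keep], lab[keep])
  res$pairs <- cbind(pairs[keep, , drop = FALSE], label = lab[keep])
  res
}
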