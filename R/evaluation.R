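#' Aggregate video-level scores into study-level predictions
#'
#' Disease labels describe a study, while the model scores individual video
#' clips; at inference time the per-video scores of a study are averaged into
#' one study-level prediction.
#'
#' @param video_scores Numeric vector of per-video scores in \[0, 1\].
#' @param study_ids Character vector (same length) mapping each video to its
#'   study.
#' @param labels Optional named vector (by study id) of 0/1 study labels.
#' @return Data frame (study_id, score, n_videos\[, label\]), one row per
#'   study.
#' @export
aggregate_study_predictions <- function(video_scores, study_ids, labels = NULL) {
  stopifnot(length(video_scores) == length(study_ids), length(video_scores) > 0L,
            all(video_scores >= 0 & video_scores <= 1))
  pooled <- tapply(video_scores, study_ids, mean)
  out <- data.frame(study_id = names(pooled), score = as.numeric(pooled),
                    n_videos = as.integer(table(study_ids)[names(pooled)]),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.integer(labels[out$study_id])
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one half; computed from midranks.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step-wise average precision)
#'
#' Non-interpolated average precision: the sum over descending score
#' thresholds of precision times the recall increment.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("AUPR undefined: no positives")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  # evaluate only at the last index of each tied-score group
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Percentile-bootstrap confidence interval for a study-level metric
#'
#' Draws `B` resamples of the studies with replacement (same size as the
#' input), recomputes the metric on each, and reports the 2.5th and 97.5th
#' percentiles. Resamples containing a single class are skipped and counted.
#'
#' @param labels 0/1 study labels (n >= 10).
#' @param scores Study-level scores.
#' @param metric `"auroc"` or `"aupr"`.
#' @param B Number of bootstrap replicates (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List of class `metric_result`: `metric`, `point`, `ci` (lo, hi),
#'   `B`, `n_skipped`, `seed`.
#' @export
bootstrap_ci <- function(labels, scores, metric = c("auroc", "aupr"),
                         B = 10000L, conf = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(labels) == length(scores), length(labels) >= 10L)
  if (B < 100L) warning("fewer than 100 bootstrap replicates; CI will be unstable")
  fn <- if (metric == "auroc") auroc else aupr
  point <- fn(labels, scores)
  set.seed(seed)
  n <- length(labels)
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- labels[idx]
    if (all(lb == lb[1L])) next
    vals[b] <- fn(lb, scores[idx])
  }
  ok <- !is.na(vals)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(vals[ok], c(alpha, 1 - alpha), names = FALSE)
  if (point < ci[1L] || point > ci[2L])
    message("point estimate lies outside the percentile CI (logged, not fatal)")
  structure(list(metric = metric, point = point, ci = ci, B = B,
                 n_skipped = sum(!ok), seed = seed),
            class = "metric_result")
}

#' One-sided bootstrap test for an AUROC difference
#'
#' Paired study-level bootstrap of `D = (AUROC_A - AUROC_B) / sd`, where `sd`
#' is the standard deviation of the resampled AUROC differences; the p-value
#' is the upper normal tail `1 - pnorm(D)` for the alternative that model A's
#' AUROC exceeds model B's.
#'
#' @param labels 0/1 study labels.
#' @param scores_a,scores_b Paired study-level scores of the two models.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return List: `p` (one-sided), `d` (standardized difference), `delta`
#'   (observed AUROC_A - AUROC_B), `B`.
#' @export
bootstrap_auroc_pvalue <- function(labels, scores_a, scores_b, B = 2000L, seed = 1L) {
  stopifnot(length(labels) == length(scores_a),
            length(labels) == length(scores_b))
  delta <- auroc(labels, scores_a) - auroc(labels, scores_b)
  set.seed(seed)
  n <- length(labels)
  diffs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    lb <- labels[idx]
    if (all(lb == lb[1L])) next
    diffs[b] <- auroc(lb, scores_a[idx]) - auroc(lb, scores_b[idx])
  }
  sdd <- stats::sd(diffs, na.rm = TRUE)
  if (!is.finite(sdd) || sdd == 0) {
    if (delta == 0) return(list(p = 0.5, d = 0, delta = delta, B = B))
    return(list(p = if (delta > 0) 0 else 1, d = sign(delta) * Inf,
                delta = delta, B = B))
  }
  d <- delta / sdd
  list(p = 1 - stats::pnorm(d), d = d, delta = delta, B = B)
}
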