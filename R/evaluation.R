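## Evaluation: k-fold cross-validation with pooled (micro) metrics,
## per-cause F1 from the pooled confusion counts, the F1 distribution
## summary, and the share of records answered directly by the sink route.

#' Split records into k folds
#'
#' Seeded shuffle followed by round-robin assignment; fold sizes differ by
#' at most one and the folds partition the input.
#'
#' @param records `death_records` (or anything with rows).
#' @param k Number of folds, default 17.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids (1..k), one per record.
#' @export
kfold_split <- function(records, k = 17, seed = 1) {
  n <- nrow(records)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k records (", n, " < ", k, ")", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  fold
}

#' Classification metrics from true and predicted labels
#'
#' Pooled confusion-count metrics: accuracy; per-cause precision, recall
#' and F1 for every cause appearing as a true label; macro precision and
#' recall (unweighted means over those causes, a cause never predicted
#' contributing precision 0); micro precision/recall (equal to accuracy in
#' this single-label setting) as a diagnostic; the F1 distribution summary
#' of [f1_distribution()]; and the fraction of predictions answered by the
#' sink route when routes are supplied.
#'
#' @param true Character vector of adjudicated underlying causes.
#' @param predicted Character vector of inferred causes, same length.
#' @param route Optional character vector of routes taken
#'   (`"sink"`/`"cf"`/`"fallback"`).
#' @param fold_count Number of CV folds the predictions were pooled from.
#' @return An `eval_report` list.
#' @export
eval_metrics <- function(true, predicted, route = NULL, fold_count = 1L) {
  stopifnot(length(true) == length(predicted), length(true) > 0)
  accuracy <- mean(true == predicted)
  causes <- sort(unique(true))
  tp <- vapply(causes, function(c) sum(true == c & predicted == c), 0)
  fn <- vapply(causes, function(c) sum(true == c & predicted != c), 0)
  fp <- vapply(causes, function(c) sum(true != c & predicted == c), 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- tp / (tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  names(f1) <- causes
  dist <- f1_distribution(f1)
  structure(list(
    accuracy = accuracy,
    precision_macro = mean(precision),
    recall_macro = mean(recall),
    precision_micro = accuracy,
    recall_micro = accuracy,
    per_cause_f1 = f1,
    per_cause_precision = stats::setNames(precision, causes),
    per_cause_recall = stats::setNames(recall, causes),
    f1_gt_095_frac = dist[["f1_gt_095_frac"]],
    f1_lt_07_frac = dist[["f1_lt_07_frac"]],
    sink_route_frac = if (is.null(route)) NA_real_ else mean(route == "sink"),
    n = length(true),
    fold_count = as.integer(fold_count)
  ), class = "eval_report")
}

#' Summarize a per-cause F1 distribution
#'
#' The two generalizability summaries: the fraction of causes whose F1
#' exceeds 0.95 (strictly, "larger than") and the fraction strictly below
#' 0.7.
#'
#' @param per_cause_f1 Named numeric vector of per-cause F1 scores.
#' @return Named vector `c(f1_gt_095_frac =, f1_lt_07_frac =)`.
#' @export
f1_distribution <- function(per_cause_f1) {
  if (length(per_cause_f1) == 0) {
    stop("empty per-cause F1 mapping", call. = FALSE)
  }
  c(f1_gt_095_frac = mean(per_cause_f1 > 0.95),
    f1_lt_07_frac = mean(per_cause_f1 < 0.7))
}

#' k-fold cross-validation of the Sink-CF pipeline
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' records; metrics are pooled over all held-out predictions (micro
#' pooling), with per-cause F1 from the pooled confusion counts. Also
#' reports two reference accuracies computed on the same folds: the
#' stratified majority-class baseline (most frequent training label in the
#' record's age-gender stratum) and the plain sink strategy with CF
#' disabled (the sink answer for every record).
#'
#' @param records Labeled `death_records`.
#' @param config A [sinkcf_config()].
#' @param k Number of folds, default 17.
#' @param seed Seed for the fold shuffle.
#' @return An `eval_report` with additional fields
#'   `baseline_majority_accuracy`, `sink_only_accuracy` and the pooled
#'   per-record `predictions` data.frame.
#' @export
cross_validate <- function(records, config = sinkcf_config(), k = 17,
                           seed = 1) {
  records <- death_records(records)
  if (any(is.na(records$underlying))) {
    stop("cross-validation requires labeled records", call. = FALSE)
  }
  fold <- kfold_split(records, k = k, seed = seed)
  strata <- stratum_id(age_group(records$age), records$gender)

  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    model <- sinkcf_train(records[train_idx, , drop = FALSE], config)
    p <- predict(model, records[test_idx, , drop = FALSE])
    p$true <- records$underlying[test_idx]
    p$fold <- f
    ## stratified majority-class baseline from this fold's training labels
    maj <- tapply(records$underlying[train_idx], strata[train_idx],
                  function(v) names(sort(table(v), decreasing = TRUE))[1])
    overall <- names(sort(table(records$underlying[train_idx]),
                          decreasing = TRUE))[1]
    m <- maj[strata[test_idx]]
    p$baseline_majority <- ifelse(is.na(m), overall, m)
    preds[[f]] <- p
  }
  pooled <- do.call(rbind, preds)
  report <- eval_metrics(pooled$true, pooled$cause, route = pooled$route,
                         fold_count = k)
  report$baseline_majority_accuracy <-
    mean(pooled$true == pooled$baseline_majority)
  report$sink_only_accuracy <- mean(pooled$true == pooled$sink_top)
  report$predictions <- pooled
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n = ", x$n, ", folds = ", x$fold_count, "\n",
      sprintf("  accuracy            %.4f\n", x$accuracy),
      sprintf("  precision (macro)   %.4f\n", x$precision_macro),
      sprintf("  recall (macro)      %.4f\n", x$recall_macro),
      sprintf("  F1 > 0.95 causes    %.2f%%\n", 100 * x$f1_gt_095_frac),
      sprintf("  F1 < 0.7 causes     %.2f%%\n", 100 * x$f1_lt_07_frac),
      if (!is.na(x$sink_route_frac))
        sprintf("  sink-route share    %.2f%%\n", 100 * x$sink_route_frac)
      else "", sep = "")
  if (!is.null(x$baseline_majority_accuracy)) {
    cat(sprintf("  majority baseline   %.4f\n", x$baseline_majority_accuracy),
        sprintf("  sink-only accuracy  %.4f\n", x$sink_only_accuracy),
        sep = "")
  }
  invisible(x)
}
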