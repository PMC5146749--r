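# Imbalance-aware evaluation: confusion counts, sensitivity/specificity/GM,
# ROC/AUC, class-scatter diagnostics, and the cross-validated experiment
# harness (feature selection and resampling fit inside the training folds
# only, so held-out folds stay untouched and imbalanced).

#' Confusion counts
#'
#' TP = toxic predicted toxic, FN = toxic missed, TN = non-toxic predicted
#' non-toxic, FP = non-toxic flagged toxic.
#'
#' @param labels_true,labels_pred equal-length binary vectors
#' @return object of class `confusion_counts`
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop_toxbalance("label vectors differ in length", "toxbalance_schema_error")
  t <- as.integer(labels_true); p <- as.integer(labels_pred)
  if (!all(c(t, p) %in% c(0L, 1L)))
    stop_toxbalance("labels must be strictly binary", "toxbalance_label_error")
  structure(list(TP = sum(t == 1L & p == 1L), FN = sum(t == 1L & p == 0L),
                 TN = sum(t == 0L & p == 0L), FP = sum(t == 0L & p == 1L)),
            class = "confusion_counts")
}

add_confusion <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FN = a$FN + b$FN,
                 TN = a$TN + b$TN, FP = a$FP + b$FP),
            class = "confusion_counts")
}

#' Imbalance-aware metric set
#'
#' Accuracy, sensitivity (TPR), specificity (TNR), FPR and the geometric mean
#' GM = sqrt(sensitivity * specificity). Requires at least one sample of each
#' class; an empty class makes sensitivity or specificity undefined and is an
#' error rather than a silent zero.
#'
#' @param counts a [confusion()] result
#' @return object of class `metric_set`
#' @export
metrics <- function(counts) {
  with(counts, {
    if (TP + FN == 0 || TN + FP == 0)
      stop_toxbalance("metrics undefined: a class has no samples",
                      "toxbalance_metric_error")
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    structure(list(
      accuracy = (TP + TN) / (TP + TN + FP + FN),
      sensitivity = sens, specificity = spec,
      fpr = FP / (FP + TN),
      gm = sqrt(sens * spec)
    ), class = "metric_set")
  })
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  FPR %.3f  GM %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$fpr, x$gm))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (descending); tied scores step
#' simultaneously. The curve runs from (0, 0) to (1, 1) in (FPR, TPR); AUC is
#' the trapezoidal area, equal to the probability a random positive outscores
#' a random negative (ties counted half).
#'
#' @param labels_true binary vector with both classes present
#' @param scores numeric scores, higher = more positive
#' @return object of class `roc_curve` with `points` (data frame `fpr`, `tpr`,
#'   `threshold`) and `auc`
#' @export
roc_auc <- function(labels_true, scores) {
  y <- as.integer(labels_true)
  if (length(unique(y)) < 2L)
    stop_toxbalance("ROC undefined for single-class input",
                    "toxbalance_metric_error")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, 0))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr,
                                     threshold = c(Inf, thr)),
                 auc = auc),
            class = "roc_curve")
}

#' Class-scatter diagnostic
#'
#' Between-class scatter `sum_c n_c ||mu_c - mu||^2` and within-class scatter
#' `sum_c sum_{x in c} ||x - mu_c||^2`; the two add up to the total scatter
#' about the grand mean. Per-sample (count-normalized) versions are reported
#' alongside for comparing pools of different sizes, as after resampling.
#'
#' @param pool a [sample_pool()] with both classes present
#' @return object of class `scatter_diagnostic`
#' @export
scatter_diagnostic <- function(pool) {
  check_two_classes(pool)
  x <- pool$features
  mu <- colMeans(x)
  between <- 0; within <- 0
  for (cls in unique(pool$labels)) {
    xc <- x[pool$labels == cls, , drop = FALSE]
    muc <- colMeans(xc)
    between <- between + nrow(xc) * sum((muc - mu)^2)
    within <- within + sum(sweep(xc, 2, muc)^2)
  }
  n <- nrow(x)
  structure(list(between_class_variance = between,
                 within_class_variance = within,
                 between_per_sample = between / n,
                 within_per_sample = within / n),
            class = "scatter_diagnostic")
}

#' Cross-validated pipeline evaluation
#'
#' Runs the selection -> resampling -> bagging pipeline under stratified
#' k-fold cross-validation. Everything data-dependent is fit on the training
#' folds only: discretization and attribute reduction use training rows, the
#' resampler balances the training rows, and the held-out fold is evaluated
#' untouched (imbalanced). Reports per-fold confusion counts and metrics,
#' pooled (micro-averaged, from summed counts) and macro-averaged metrics,
#' and a pooled ROC over held-out scores.
#'
#' @param table a [descriptor_table()]
#' @param endpoint endpoint name
#' @param fs_method `"none"`, `"qrfs"`, `"ebfs"` or `"dmfs"`
#' @param sampling_method `"none"`, `"rus"`, `"ros"`, `"smote"` or `"its"`
#' @param k_folds number of folds (default 5)
#' @param T number of weak learners (default 3)
#' @param learner_spec weak learner (default [tree_learner()])
#' @param n_bins discretization bins for feature selection
#' @param k_init ITS initial neighborhood size
#' @param k_neighbors SMOTE neighbor count
#' @param seed RNG seed driving folds, resampling and bagging
#' @return object of class `evaluation_report`
#' @export
cross_validate <- function(table, endpoint,
                           fs_method = c("none", "qrfs", "ebfs", "dmfs"),
                           sampling_method = c("none", "rus", "ros", "smote", "its"),
                           k_folds = 5, T = 3, learner_spec = tree_learner(),
                           n_bins = 3, k_init = 15, k_neighbors = 5, seed = 1) {
  fs_method <- match.arg(fs_method)
  sampling_method <- match.arg(sampling_method)
  pool_all <- as_sample_pool(table, endpoint)
  labels <- pool_all$labels
  plan <- make_folds(labels, k = k_folds, stratified = TRUE, seed = seed)

  folds <- vector("list", k_folds)
  pooled_counts <- structure(list(TP = 0L, FN = 0L, TN = 0L, FP = 0L),
                             class = "confusion_counts")
  all_scores <- numeric(length(labels))
  tested <- logical(length(labels))
  for (f in seq_len(k_folds)) {
    test_idx <- which(plan$assignments == f)
    train_idx <- which(plan$assignments != f)
    x_train <- pool_all$features[train_idx, , drop = FALSE]
    y_train <- labels[train_idx]

    selected <- colnames(x_train)
    reduct <- NULL
    if (fs_method != "none") {
      dt <- discretize(x_train, y_train, n_bins = n_bins)
      reduct <- select_features(dt, fs_method)
      if (length(reduct$selected) > 0) selected <- reduct$selected
    }
    x_train_sel <- x_train[, selected, drop = FALSE]
    x_test_sel <- pool_all$features[test_idx, selected, drop = FALSE]

    train_pool <- sample_pool(x_train_sel, y_train)
    train_pool <- balance_pool(train_pool, sampling_method,
                               k_init = k_init, k_neighbors = k_neighbors,
                               seed = derive_seed(seed, 100L + f))
    model <- train_bagging(train_pool, T = T, learner_spec = learner_spec,
                           seed = derive_seed(seed, 200L + f))
    pred <- predict(model, x_test_sel)
    cc <- confusion(labels[test_idx], pred$label)
    pooled_counts <- add_confusion(pooled_counts, cc)
    all_scores[test_idx] <- pred$score
    tested[test_idx] <- TRUE
    folds[[f]] <- list(fold = f, test_indices = test_idx,
                       selected = selected, reduct = reduct,
                       counts = cc, metrics = metrics(cc))
  }
  stopifnot(all(tested))
  macro <- {
    ms <- lapply(folds, `[[`, "metrics")
    structure(lapply(stats::setNames(nm = names(ms[[1]])), function(k)
      mean(vapply(ms, `[[`, 0, k))), class = "metric_set")
  }
  structure(list(
    endpoint = endpoint, fs_method = fs_method,
    sampling_method = sampling_method, k_folds = as.integer(k_folds),
    seed = as.integer(seed), folds = folds,
    pooled_counts = pooled_counts,
    pooled = metrics(pooled_counts), macro = macro,
    roc = roc_auc(labels, all_scores)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: endpoint=%s fs=%s sampling=%s (%d-fold, seed %d)\n",
              x$endpoint, x$fs_method, x$sampling_method, x$k_folds, x$seed))
  cat("pooled:  "); print(x$pooled)
  cat("macro:   "); print(x$macro)
  cat(sprintf("AUC (pooled scores): %.3f\n", x$roc$auc))
  invisible(x)
}

#' Export an evaluation report as JSON (plus ROC points as TSV)
#'
#' @param report an `evaluation_report`
#' @param path JSON output path
#' @param roc_path optional TSV path for the ROC points
#' @return `path`, invisibly
#' @export
export_report_json <- function(report, path, roc_path = NULL) {
  out <- list(
    endpoint = report$endpoint, fs_method = report$fs_method,
    sampling_method = report$sampling_method, k_folds = report$k_folds,
    seed = report$seed,
    pooled_counts = unclass(report$pooled_counts),
    pooled = unclass(report$pooled), macro = unclass(report$macro),
    auc = report$roc$auc,
    folds = lapply(report$folds, function(f) list(
      fold = f$fold, selected = f$selected, counts = unclass(f$counts),
      metrics = unclass(f$metrics)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(roc_path))
    utils::write.table(report$roc$points, roc_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}
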