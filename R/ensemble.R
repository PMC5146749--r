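# Bagging ensemble: T weak learners trained on bootstrap replicates of the
# training pool, combined by majority vote. The vote fraction doubles as the
# score thresholded for ROC curves.

#' Train a bagging ensemble
#'
#' Each of the `T` learners is fit on a bootstrap sample (same size as the
#' pool, drawn with replacement — so some originals repeat and others are left
#' out). Per-learner seeds are derived from `seed`, making training
#' deterministic. The default configuration (three decision-tree weak
#' learners) matches the reference pipeline.
#'
#' @param pool a [sample_pool()] containing both classes
#' @param T number of weak learners (default 3)
#' @param learner_spec a learner such as [tree_learner()]
#' @param seed RNG seed
#' @param bootstrap set `FALSE` to train every learner on the full pool
#'   (test hook: with `T = 1` the ensemble then equals the weak learner)
#' @return object of class `bagging_model`
#' @export
train_bagging <- function(pool, T = 3, learner_spec = tree_learner(),
                          seed = 1, bootstrap = TRUE) {
  if (T < 1) stop_toxbalance("T must be >= 1", "toxbalance_parameter_error")
  if (length(unique(pool$labels)) < 2L)
    stop_toxbalance("training pool has a single class",
                    "toxbalance_training_error")
  n <- length(pool$labels)
  seeds <- vapply(seq_len(T), function(t) derive_seed(seed, t), 0L)
  learners <- vector("list", T)
  for (t in seq_len(T)) {
    idx <- if (bootstrap)
      with_seed(seeds[t], sample.int(n, n, replace = TRUE))
    else seq_len(n)
    learners[[t]] <- learner_spec$fit(pool$features[idx, , drop = FALSE],
                                      pool$labels[idx])
  }
  structure(list(learners = learners, bootstrap_seeds = seeds,
                 learner_spec = learner_spec, T = as.integer(T),
                 n_features = ncol(pool$features),
                 vote_threshold = 0.5),
            class = "bagging_model")
}

#' Predict with a bagging ensemble
#'
#' Each learner votes; `score` is the fraction of positive votes and the
#' label is positive when the score strictly exceeds the vote threshold
#' (default 0.5), so tied votes with even `T` go to the negative class.
#'
#' @param object a `bagging_model`
#' @param samples feature matrix (or `sample_pool`)
#' @param ... unused
#' @return data frame with columns `label` and `score`
#' @export
predict.bagging_model <- function(object, samples, ...) {
  x <- if (inherits(samples, "sample_pool")) samples$features else as.matrix(samples)
  if (ncol(x) != object$n_features)
    stop_toxbalance("feature dimensionality does not match training",
                    "toxbalance_predict_error")
  votes <- vapply(object$learners,
                  function(l) object$learner_spec$predict(l, x),
                  integer(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x))
  score <- rowMeans(votes == 1L)
  data.frame(label = as.integer(score > object$vote_threshold), score = score)
}

#' @export
print.bagging_model <- function(x, ...) {
  cat(sprintf("bagging_model: %d x %s weak learner(s), %d features\n",
              x$T, x$learner_spec$kind, x$n_features))
  invisible(x)
}
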