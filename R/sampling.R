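# Class rebalancing: random under-/over-sampling, SMOTE interpolation, and
# the iterative hybrid sampler (Danger-based removal/replication followed by
# Tomek-link cleaning).
#
# All distance-based steps use Euclidean distance on z-score-standardized
# features: molecular descriptors span wildly different scales (molecular
# weight vs. ring counts) and unstandardized distances would be dominated by
# the largest-scale descriptor. Standardization parameters are fit once on
# the pool at entry and held fixed across iterations.

#' Construct a sample pool
#'
#' A feature matrix with binary labels and identified minority/majority
#' partitions. Roles are derived from counts, never from label polarity: the
#' minority class is whichever class has fewer samples (ties: the positive
#' class).
#'
#' @param features numeric matrix, samples x features
#' @param labels binary vector (1 = positive)
#' @return object of class `sample_pool`
#' @export
sample_pool <- function(features, labels) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop_toxbalance("labels length must match feature rows", "toxbalance_schema_error")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop_toxbalance("labels must be strictly binary", "toxbalance_label_error")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  minority_label <- if (n1 <= n0) 1L else 0L
  structure(list(
    features = features, labels = labels,
    minority_label = minority_label,
    minority_indices = which(labels == minority_label),
    majority_indices = which(labels != minority_label)
  ), class = "sample_pool")
}

#' @export
print.sample_pool <- function(x, ...) {
  cat(sprintf("sample_pool: %d samples (%d minority / %d majority), %d features\n",
              length(x$labels), length(x$minority_indices),
              length(x$majority_indices), ncol(x$features)))
  invisible(x)
}

#' Coerce a descriptor table endpoint into a sample pool
#'
#' @param table a [descriptor_table()]
#' @param endpoint endpoint name present in `table$labels`
#' @return a [sample_pool()]
#' @export
as_sample_pool <- function(table, endpoint) {
  if (!endpoint %in% names(table$labels))
    stop_toxbalance(sprintf("unknown endpoint '%s'", endpoint),
                    "toxbalance_schema_error")
  sample_pool(table$values, table$labels[[endpoint]])
}

check_two_classes <- function(pool) {
  if (length(pool$minority_indices) == 0L || length(pool$majority_indices) == 0L)
    stop_toxbalance("degenerate pool: a class is empty",
                    "toxbalance_degenerate_error")
}

#' Random under-sampling (RUS)
#'
#' Uniformly discards majority samples (without replacement) until the classes
#' are equal; minority samples are untouched.
#'
#' @param pool a [sample_pool()]
#' @param seed RNG seed
#' @return balanced `sample_pool`
#' @export
random_undersample <- function(pool, seed = 1) {
  check_two_classes(pool)
  n_min <- length(pool$minority_indices)
  keep_maj <- with_seed(seed, sample(pool$majority_indices, n_min))
  keep <- sort(c(pool$minority_indices, keep_maj))
  out <- sample_pool(pool$features[keep, , drop = FALSE], pool$labels[keep])
  attr(out, "kept_indices") <- keep
  out
}

#' Random over-sampling (ROS)
#'
#' Replicates minority samples (with replacement) until the classes are equal;
#' majority samples are untouched.
#'
#' @inheritParams random_undersample
#' @return balanced `sample_pool`
#' @export
random_oversample <- function(pool, seed = 1) {
  check_two_classes(pool)
  need <- length(pool$majority_indices) - length(pool$minority_indices)
  extra <- if (need > 0)
    with_seed(seed, sample(pool$minority_indices, need, replace = TRUE))
  else integer(0)
  keep <- c(seq_along(pool$labels), extra)
  out <- sample_pool(pool$features[keep, , drop = FALSE], pool$labels[keep])
  attr(out, "source_indices") <- keep
  out
}

#' SMOTE over-sampling
#'
#' Synthesizes minority samples on the segment between a minority point
#' `x_i` and one of its `k` nearest minority neighbors `x_hat`:
#' `x_new = x_i + delta * (x_hat - x_i)` with `delta ~ U(0, 1)` drawn once per
#' synthetic sample. Enough samples are synthesized to equalize the classes.
#' Neighbors are searched within the minority class only, excluding the point
#' itself, by Euclidean distance on standardized features.
#'
#' The returned pool carries a `smote_log` attribute recording, per synthetic
#' row, the base index `i`, the neighbor index, and `delta`, so every
#' synthetic point can be reconstructed exactly.
#'
#' @inheritParams random_undersample
#' @param k_neighbors number of minority neighbors considered (default 5)
#' @return balanced `sample_pool` with attribute `smote_log`
#' @export
smote <- function(pool, k_neighbors = 5, seed = 1) {
  check_two_classes(pool)
  min_idx <- pool$minority_indices
  need <- length(pool$majority_indices) - length(min_idx)
  if (need <= 0) return(pool)
  if (length(min_idx) == 1L) {
    warning("single minority sample: SMOTE falls back to replication")
    out <- random_oversample(pool, seed = seed)
    attr(out, "smote_log") <- NULL
    return(out)
  }
  k_eff <- min(k_neighbors, length(min_idx) - 1L)
  if (k_eff < k_neighbors)
    warning(sprintf("k_neighbors reduced to %d (minority size)", k_eff))
  z <- standardize_features(pool$features)
  zmin <- z[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(zmin))
  diag(dm) <- Inf
  # k nearest minority neighbors per minority sample (local indices)
  nn <- t(apply(dm, 1, function(row) order(row)[seq_len(k_eff)]))
  synth <- with_seed(seed, {
    base_local <- c(rep(seq_along(min_idx), need %/% length(min_idx)),
                    sample(seq_along(min_idx), need %% length(min_idx)))
    nb_pick <- vapply(base_local,
                      function(b) nn[b, sample.int(k_eff, 1L)], 0L)
    delta <- stats::runif(need)
    list(base_local = base_local, nb_local = nb_pick, delta = delta)
  })
  xi <- pool$features[min_idx[synth$base_local], , drop = FALSE]
  xh <- pool$features[min_idx[synth$nb_local], , drop = FALSE]
  new_rows <- xi + synth$delta * (xh - xi)
  feats <- rbind(pool$features, new_rows)
  labs <- c(pool$labels, rep(pool$minority_label, need))
  out <- sample_pool(feats, labs)
  attr(out, "smote_log") <- data.frame(
    base = min_idx[synth$base_local],
    neighbor = min_idx[synth$nb_local],
    delta = synth$delta,
    synthetic_row = nrow(pool$features) + seq_len(need))
  out
}

# k-nearest-neighbor label matrix machinery -------------------------------

# Pairwise Euclidean distances on (already standardized) features.
pool_dist <- function(z) as.matrix(stats::dist(z))

# For each row: is the sample "Danger", i.e. does the class OPPOSITE to the
# sample's own label hold a strict majority among its k nearest neighbors
# (self excluded)? For a majority sample that means a minority-dominated
# neighborhood (borderline/noisy, removal candidate); for a minority sample a
# majority-dominated neighborhood (borderline, not replicated). Ties (k even,
# split vote) are NOT Danger: no removal, no blocked replication.
danger_flags <- function(dm, labels, minority_label, k) {
  n <- nrow(dm)
  if (k >= n)
    stop_toxbalance("k must be smaller than the pool size",
                    "toxbalance_parameter_error")
  vapply(seq_len(n), function(i) {
    d <- dm[i, ]; d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    sum(labels[nb] != labels[i]) > k / 2
  }, TRUE)
}

#' Is a sample a Danger sample?
#'
#' A sample is Danger when the class opposite its own holds a strict majority
#' among its `k` nearest neighbors in the full pool (itself excluded;
#' Euclidean distance on standardized features). For a majority sample this
#' means a minority-dominated neighborhood (borderline or noisy — the removal
#' candidates); for a minority sample a majority-dominated neighborhood
#' (borderline — excluded from replication). Split votes (even `k`) are not
#' Danger.
#'
#' @param pool a [sample_pool()]
#' @param index sample row index (may be a vector)
#' @param k neighborhood size (>= 1, < pool size)
#' @return logical vector
#' @export
is_danger <- function(pool, index, k) {
  z <- standardize_features(pool$features)
  flags <- danger_flags(pool_dist(z), pool$labels, pool$minority_label, k)
  flags[index]
}

#' Iterative Danger-based sampling step
#'
#' Iterates a decreasing neighborhood size `k = k_init, k_init - 1, ...`; in
#' each iteration every majority sample that is Danger is removed and every
#' minority sample that is NOT Danger is replicated once (flags computed
#' simultaneously at iteration entry). The loop stops as soon as the classes
#' are equal; when an iteration would overshoot equality, a seeded random
#' subset of that iteration's removals/replications is applied so the pool
#' lands exactly on balance. If `k` reaches 0 before equality the pool is
#' force-balanced by random under-/over-sampling, with a warning.
#'
#' Standardization for the neighbor search is fit once at entry and reused in
#' every iteration.
#'
#' @param pool a [sample_pool()]
#' @param k_init initial neighborhood size (default 15)
#' @param seed RNG seed
#' @return list with the balanced `pool` and a `trace` data frame (class
#'   `its_trace`) of per-iteration k, class sizes, removal and replication
#'   counts, plus per-iteration scatter diagnostics
#' @export
its_sampling_step <- function(pool, k_init = 15, seed = 1) {
  check_two_classes(pool)
  if (k_init < 1)
    stop_toxbalance("k_init must be >= 1", "toxbalance_parameter_error")
  center <- colMeans(pool$features)
  scl <- apply(pool$features, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1

  cur <- pool
  trace <- list()
  k <- as.integer(k_init)
  iter <- 0L
  while (length(cur$majority_indices) != length(cur$minority_indices) && k >= 1L) {
    iter <- iter + 1L
    z <- standardize_features(cur$features, center, scl)
    k_use <- min(k, nrow(z) - 1L)
    flags <- danger_flags(pool_dist(z), cur$labels, cur$minority_label, k_use)
    remove_idx <- intersect(which(flags), cur$majority_indices)
    replicate_idx <- intersect(which(!flags), cur$minority_indices)
    gap <- length(cur$majority_indices) - length(cur$minority_indices)
    n_actions <- length(remove_idx) + length(replicate_idx)
    if (n_actions > gap) {
      # trim: each removal and each replication closes the gap by one
      pick <- with_seed(derive_seed(seed, iter), sample.int(n_actions, gap))
      actions <- c(remove_idx, replicate_idx)
      is_removal <- seq_len(n_actions) <= length(remove_idx)
      remove_idx <- actions[pick[is_removal[pick]]]
      replicate_idx <- actions[pick[!is_removal[pick]]]
    }
    keep <- setdiff(seq_along(cur$labels), remove_idx)
    keep <- c(keep, replicate_idx)          # replicated rows appended once
    nxt <- sample_pool(cur$features[keep, , drop = FALSE], cur$labels[keep])
    sc <- scatter_diagnostic(sample_pool(
      standardize_features(nxt$features, center, scl), nxt$labels))
    trace[[iter]] <- data.frame(
      phase = "sampling", k = k_use,
      n_majority = length(nxt$majority_indices),
      n_minority = length(nxt$minority_indices),
      removed = length(remove_idx), replicated = length(replicate_idx),
      between_class_variance = sc$between_class_variance,
      within_class_variance = sc$within_class_variance,
      between_per_sample = sc$between_per_sample,
      within_per_sample = sc$within_per_sample)
    cur <- nxt
    k <- k - 1L
  }
  if (length(cur$majority_indices) != length(cur$minority_indices)) {
    warning("k exhausted before balance; forcing balance by random sampling")
    if (length(cur$majority_indices) > length(cur$minority_indices))
      cur <- random_undersample(cur, seed = derive_seed(seed, 9999L))
    else
      cur <- random_oversample(cur, seed = derive_seed(seed, 9999L))
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = character(0), k = integer(0), n_majority = integer(0),
               n_minority = integer(0), removed = integer(0),
               replicated = integer(0), between_class_variance = numeric(0),
               within_class_variance = numeric(0),
               between_per_sample = numeric(0), within_per_sample = numeric(0))
  class(trace_df) <- c("its_trace", "data.frame")
  attr(cur, "standardization") <- list(center = center, scale = scl)
  list(pool = cur, trace = trace_df)
}

#' Find Tomek links
#'
#' A pair of opposite-class samples (i, j) is a Tomek link when no third
#' sample is strictly closer to either endpoint than they are to each other
#' (Euclidean distance on standardized features; the pool's own
#' standardization unless `standardization` supplies fixed parameters).
#'
#' @param pool a [sample_pool()]
#' @param standardization optional list(center, scale) fit elsewhere
#' @return data frame with columns `i`, `j`, `distance` (class `tomek_links`)
#' @export
find_tomek_links <- function(pool, standardization = NULL) {
  n <- length(pool$labels)
  if (length(unique(pool$labels)) < 2L || n < 2L)
    return(structure(data.frame(i = integer(0), j = integer(0),
                                distance = numeric(0)),
                     class = c("tomek_links", "data.frame")))
  z <- if (is.null(standardization)) standardize_features(pool$features)
       else standardize_features(pool$features, standardization$center,
                                 standardization$scale)
  dm <- pool_dist(z)
  diag(dm) <- Inf
  # nearest-other distance per sample
  nearest <- apply(dm, 1, min)
  links <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pool$labels[i] != pool$labels[j] &&
          dm[i, j] <= nearest[i] && dm[i, j] <= nearest[j]) {
        links[[length(links) + 1L]] <- c(i, j, dm[i, j])
      }
    }
  }
  out <- if (length(links)) {
    m <- do.call(rbind, links)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), distance = m[, 3])
  } else data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  structure(out, class = c("tomek_links", "data.frame"))
}

#' Tomek-link cleaning
#'
#' Repeatedly finds Tomek links and removes BOTH endpoints of every link until
#' none remain. Pairwise removal deletes equally many samples from each class,
#' so a balanced pool stays balanced. Idempotent once clean. If a removal
#' round would empty a class, cleaning stops early with a warning.
#'
#' @inheritParams find_tomek_links
#' @return list with the cleaned `pool`, `removed` (total per-class counts:
#'   named vector `minority`/`majority`) and `rounds`
#' @export
tomek_clean <- function(pool, standardization = NULL) {
  removed_min <- 0L; removed_maj <- 0L; rounds <- 0L
  repeat {
    links <- find_tomek_links(pool, standardization)
    if (nrow(links) == 0L) break
    drop <- unique(c(links$i, links$j))
    lab_drop <- pool$labels[drop]
    n_min_drop <- sum(lab_drop == pool$minority_label)
    n_maj_drop <- length(drop) - n_min_drop
    if (n_min_drop >= length(pool$minority_indices) ||
        n_maj_drop >= length(pool$majority_indices)) {
      warning("Tomek cleaning would empty a class; stopping early")
      break
    }
    keep <- setdiff(seq_along(pool$labels), drop)
    pool <- sample_pool(pool$features[keep, , drop = FALSE], pool$labels[keep])
    removed_min <- removed_min + n_min_drop
    removed_maj <- removed_maj + n_maj_drop
    rounds <- rounds + 1L
  }
  list(pool = pool,
       removed = c(minority = removed_min, majority = removed_maj),
       rounds = rounds)
}

#' Iterative sampling (sampling step + Tomek cleaning)
#'
#' Runs [its_sampling_step()] to balance the pool by Danger-based removal and
#' replication, then [tomek_clean()] to strip the class overlap the sampling
#' step may leave behind. The cleaning step reuses the standardization fit at
#' sampling entry. The trace records both phases.
#'
#' @inheritParams its_sampling_step
#' @return list with balanced, cleaned `pool` and `trace` (class `its_trace`);
#'   the trace's final row is the cleaning record
#' @export
its <- function(pool, k_init = 15, seed = 1) {
  step <- its_sampling_step(pool, k_init = k_init, seed = seed)
  std <- attr(step$pool, "standardization")
  cleaned <- tomek_clean(step$pool, standardization = std)
  sc <- scatter_diagnostic(sample_pool(
    standardize_features(cleaned$pool$features, std$center, std$scale),
    cleaned$pool$labels))
  clean_row <- data.frame(
    phase = "cleaning", k = NA_integer_,
    n_majority = length(cleaned$pool$majority_indices),
    n_minority = length(cleaned$pool$minority_indices),
    removed = sum(cleaned$removed), replicated = 0L,
    between_class_variance = sc$between_class_variance,
    within_class_variance = sc$within_class_variance,
    between_per_sample = sc$between_per_sample,
    within_per_sample = sc$within_per_sample)
  trace <- rbind(as.data.frame(step$trace), clean_row)
  class(trace) <- c("its_trace", "data.frame")
  attr(trace, "tomek_removed") <- cleaned$removed
  out <- cleaned$pool
  attr(out, "standardization") <- std
  list(pool = out, trace = trace)
}

#' Apply a rebalancing method by name
#'
#' @param pool a [sample_pool()]
#' @param method `"none"`, `"rus"`, `"ros"`, `"smote"` or `"its"`
#' @param k_init ITS initial neighborhood size
#' @param k_neighbors SMOTE neighbor count
#' @param seed RNG seed
#' @return a `sample_pool` (for `"its"`, the trace is attached as attribute
#'   `its_trace`)
#' @export
balance_pool <- function(pool, method = c("none", "rus", "ros", "smote", "its"),
                         k_init = 15, k_neighbors = 5, seed = 1) {
  method <- match.arg(method)
  switch(method,
         none = pool,
         rus = random_undersample(pool, seed = seed),
         ros = random_oversample(pool, seed = seed),
         smote = smote(pool, k_neighbors = k_neighbors, seed = seed),
         its = {
           res <- its(pool, k_init = k_init, seed = seed)
           attr(res$pool, "its_trace") <- res$trace
           res$pool
         })
}
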