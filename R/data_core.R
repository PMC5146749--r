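# Dataset representation, CSV I/O, class-distribution accounting and
# cross-validation fold construction.

#' Construct a descriptor table
#'
#' A `descriptor_table` holds one row per compound, a matrix of continuous
#' molecular descriptors, and one or more binary endpoint label vectors
#' (1 = toxic/positive, 0 = non-toxic/negative).
#'
#' @param values numeric matrix, samples x features
#' @param labels named list of binary integer vectors, one per endpoint
#' @param feature_names character vector; defaults to `colnames(values)` or
#'   the canonical 31-descriptor vocabulary when the width matches
#' @param sample_ids unique identifiers; defaults to `s1..sn`
#' @return object of class `descriptor_table`
#' @export
descriptor_table <- function(values, labels, feature_names = NULL,
                             sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- if (ncol(values) == length(DESCRIPTOR_NAMES))
        DESCRIPTOR_NAMES else paste0("f", seq_len(ncol(values)))
    }
  }
  if (length(feature_names) != ncol(values))
    stop_toxbalance("feature_names length does not match feature count",
                    "toxbalance_schema_error")
  if (anyNA(values))
    stop_toxbalance("descriptor values contain missing entries; impute or drop first",
                    "toxbalance_schema_error")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (anyDuplicated(sample_ids))
    stop_toxbalance("sample_ids must be unique", "toxbalance_schema_error")
  if (!is.list(labels)) labels <- list(endpoint = labels)
  labels <- lapply(labels, function(y) {
    y <- as.integer(y)
    if (length(y) != nrow(values))
      stop_toxbalance("label length does not match sample count",
                      "toxbalance_label_error")
    if (anyNA(y) || !all(y %in% c(0L, 1L)))
      stop_toxbalance("labels must be strictly binary (0/1)",
                      "toxbalance_label_error")
    y
  })
  colnames(values) <- feature_names
  rownames(values) <- sample_ids
  structure(list(sample_ids = sample_ids, feature_names = feature_names,
                 values = values, labels = labels),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d samples x %d features; endpoints: %s\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}

#' Load a descriptor CSV
#'
#' Reads an RFC-4180 CSV with a header row. Descriptor columns are resolved by
#' name against `feature_names` (default: the canonical 31-descriptor
#' vocabulary); endpoint columns must be codable as binary.
#'
#' @param path CSV file path
#' @param endpoint_columns character vector of label column names
#' @param feature_names expected descriptor column names; `NULL` infers them
#'   as every column that is not an endpoint or the id column
#' @param id_column optional column holding sample identifiers
#' @param impute `"none"` (reject missing values) or `"median"`
#' @return a [descriptor_table()]
#' @export
load_descriptor_csv <- function(path, endpoint_columns,
                                feature_names = descriptor_names(),
                                id_column = NULL, impute = c("none", "median")) {
  impute <- match.arg(impute)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(feature_names))
    feature_names <- setdiff(names(df), c(endpoint_columns, id_column, "sample_id"))
  missing_feats <- setdiff(feature_names, names(df))
  if (length(missing_feats))
    stop_toxbalance(paste0("missing descriptor column(s): ",
                           paste(missing_feats, collapse = ", ")),
                    "toxbalance_schema_error")
  missing_eps <- setdiff(endpoint_columns, names(df))
  if (length(missing_eps))
    stop_toxbalance(paste0("missing endpoint column(s): ",
                           paste(missing_eps, collapse = ", ")),
                    "toxbalance_schema_error")
  vals <- as.matrix(df[, feature_names, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (impute == "median") {
      for (j in seq_len(ncol(vals))) {
        nas <- is.na(vals[, j])
        if (any(nas)) vals[nas, j] <- stats::median(vals[, j], na.rm = TRUE)
      }
    } else {
      stop_toxbalance("missing descriptor values; use impute = \"median\" to fill",
                      "toxbalance_schema_error")
    }
  }
  labels <- lapply(endpoint_columns, function(ep) {
    y <- df[[ep]]
    bad <- which(!(y %in% c(0, 1, "0", "1", TRUE, FALSE)))
    if (length(bad))
      stop_toxbalance(sprintf("endpoint '%s' has non-binary values at rows: %s",
                              ep, paste(utils::head(bad, 10), collapse = ", ")),
                      "toxbalance_label_error")
    as.integer(as.numeric(y))
  })
  names(labels) <- endpoint_columns
  ids <- if (!is.null(id_column)) as.character(df[[id_column]]) else NULL
  descriptor_table(vals, labels, feature_names = feature_names, sample_ids = ids)
}

#' Write a descriptor table to CSV
#'
#' Full-precision write so that write-then-load is the identity.
#'
#' @param table a [descriptor_table()]
#' @param path output path
#' @param id_column name for the identifier column (`NULL` to omit)
#' @return `path`, invisibly
#' @export
write_descriptor_csv <- function(table, path, id_column = "sample_id") {
  df <- as.data.frame(table$values, check.names = FALSE)
  for (ep in names(table$labels)) df[[ep]] <- table$labels[[ep]]
  if (!is.null(id_column)) df <- cbind(stats::setNames(
    data.frame(table$sample_ids, stringsAsFactors = FALSE), id_column), df)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Class-distribution accounting
#'
#' Counts, percentages and the imbalance ratio (majority count per minority
#' sample) of a binary label vector. Percentages and the ratio are reported
#' rounded half-up to 2 decimals, matching how such tables are printed; the
#' raw values are kept alongside.
#'
#' @param labels binary vector (1 = positive)
#' @return object of class `class_distribution` with fields `n_positive`,
#'   `n_negative`, `pct_positive`, `pct_negative`, `imbalance_ratio` and the
#'   unrounded `*_raw` counterparts
#' @export
class_distribution <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop_toxbalance("labels must be strictly binary", "toxbalance_label_error")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_toxbalance("degenerate distribution: a class is empty",
                    "toxbalance_degenerate_error")
  n <- n_pos + n_neg
  pct_pos <- 100 * n_pos / n
  pct_neg <- 100 * n_neg / n
  ir <- max(n_pos, n_neg) / min(n_pos, n_neg)
  structure(list(
    n_positive = n_pos, n_negative = n_neg,
    pct_positive = round_half_up(pct_pos, 2),
    pct_negative = round_half_up(pct_neg, 2),
    imbalance_ratio = round_half_up(ir, 2),
    pct_positive_raw = pct_pos, pct_negative_raw = pct_neg,
    imbalance_ratio_raw = ir,
    minority_label = if (n_pos <= n_neg) 1L else 0L
  ), class = "class_distribution")
}

#' @export
print.class_distribution <- function(x, ...) {
  cat(sprintf("positive: %d (%.2f%%)  negative: %d (%.2f%%)  imbalance ratio: %.2f\n",
              x$n_positive, x$pct_positive, x$n_negative, x$pct_negative,
              x$imbalance_ratio))
  invisible(x)
}

#' Build a cross-validation fold plan
#'
#' Partitions samples into `k` folds of near-equal size. Stratified by default
#' so every test fold contains minority samples even at imbalance ratios above
#' 7. Deterministic given `seed`.
#'
#' @param labels binary vector
#' @param k number of folds (>= 2)
#' @param stratified preserve the class ratio within each fold
#' @param seed RNG seed
#' @return object of class `fold_plan` with per-sample fold `assignments`
#' @export
make_folds <- function(labels, k = 5, stratified = TRUE, seed = 1) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (k < 2) stop_toxbalance("k must be >= 2", "toxbalance_fold_error")
  if (k > n) stop_toxbalance("k exceeds sample count", "toxbalance_fold_error")
  assignments <- integer(n)
  if (stratified) {
    fold_load <- integer(k)
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop_toxbalance(sprintf("class %d has fewer than k = %d samples", cls, k),
                        "toxbalance_fold_error")
      idx <- with_seed(derive_seed(seed, cls + 11L), sample(idx))
      base <- length(idx) %/% k
      rem <- length(idx) %% k
      alloc <- rep.int(base, k)
      if (rem > 0) {
        # send class remainders to the currently least-loaded folds so total
        # fold sizes never differ by more than 1
        ord <- order(fold_load, seq_len(k))
        alloc[ord[seq_len(rem)]] <- base + 1L
      }
      assignments[idx] <- rep(seq_len(k), times = alloc)
      fold_load <- fold_load + alloc
    }
  } else {
    idx <- with_seed(seed, sample.int(n))
    assignments[idx] <- rep_len(seq_len(k), n)
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Export class distributions or fold plans as JSON
#'
#' @param x a `class_distribution` or `fold_plan`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
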