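# Rough-set decision-table machinery: indiscernibility partitions, lower and
# upper approximations, positive region / dependency degree, conditional
# entropy, and three reduct-search strategies (quick reduct, entropy-based,
# discernibility-matrix set cover).
#
# All operations work on a `decision_table`: integer-coded condition
# attributes plus a categorical decision. Continuous descriptors must be
# discretized first (see `discretize`).

#' Construct a decision table
#'
#' @param cells integer matrix (objects x condition attributes), discrete codes
#' @param decision categorical vector, one value per object
#' @param attribute_names optional attribute labels
#' @return object of class `decision_table`
#' @export
decision_table <- function(cells, decision, attribute_names = NULL) {
  cells <- as.matrix(cells)
  if (!is.numeric(cells) || any(cells != floor(cells)))
    stop_toxbalance("cells must hold discrete integer codes",
                    "toxbalance_schema_error")
  storage.mode(cells) <- "integer"
  if (length(decision) != nrow(cells))
    stop_toxbalance("decision length must equal object count",
                    "toxbalance_schema_error")
  if (is.null(attribute_names))
    attribute_names <- colnames(cells)
  if (is.null(attribute_names))
    attribute_names <- paste0("a", seq_len(ncol(cells)))
  colnames(cells) <- attribute_names
  structure(list(cells = cells, decision = as.vector(decision),
                 attribute_names = attribute_names),
            class = "decision_table")
}

#' Discretize continuous features into a decision table
#'
#' Maps each column to integer bin codes. Equal-frequency binning (the
#' default) cuts at quantiles so skewed descriptor distributions still spread
#' across bins; equal-width cuts the range evenly. Codes are monotone in the
#' underlying value. Constant columns collapse to a single code 0.
#'
#' @param values numeric matrix (samples x features)
#' @param decision decision vector (e.g. endpoint labels)
#' @param n_bins number of bins per attribute (>= 2)
#' @param method `"equal-frequency"` or `"equal-width"`
#' @return a [decision_table()]
#' @export
discretize <- function(values, decision, n_bins = 3,
                       method = c("equal-frequency", "equal-width")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (n_bins < 2) stop_toxbalance("n_bins must be >= 2", "toxbalance_schema_error")
  codes <- apply(values, 2, function(x) {
    if (length(unique(x)) == 1L) return(rep.int(0L, length(x)))
    breaks <- if (method == "equal-frequency") {
      unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                             type = 7, names = FALSE))
    } else {
      seq(min(x), max(x), length.out = n_bins + 1)
    }
    if (length(breaks) < 3) {
      # quantiles collapsed (heavy ties): fall back to a two-bin split at the
      # median value
      as.integer(x > stats::median(x))
    } else {
      as.integer(cut(x, breaks = breaks, include.lowest = TRUE,
                     labels = FALSE)) - 1L
    }
  })
  decision_table(codes, decision, attribute_names = colnames(values))
}

# Integer block id per object for the partition induced by attribute set B.
block_ids <- function(table, B) {
  sub <- table$cells[, B, drop = FALSE]
  if (ncol(sub) == 1L) return(match(sub[, 1], unique(sub[, 1])))
  key <- do.call(paste, c(as.data.frame(sub), sep = "\r"))
  match(key, unique(key))
}

#' Indiscernibility partition
#'
#' Groups objects that agree on every attribute in `B` (the equivalence
#' classes of IND(B)).
#'
#' @param table a [decision_table()]
#' @param B attribute subset (indices or names); must be non-empty
#' @return object of class `rough_partition`: a list of integer index blocks
#' @export
indiscernibility_partition <- function(table, B) {
  if (length(B) == 0) stop_toxbalance("B must be non-empty", "toxbalance_schema_error")
  ids <- block_ids(table, B)
  blocks <- split(seq_along(ids), ids)
  names(blocks) <- NULL
  structure(blocks, class = "rough_partition")
}

#' Lower and upper approximation of an object set
#'
#' The lower approximation is the union of partition blocks entirely inside
#' `X`; the upper approximation is the union of blocks that intersect `X`.
#' Their difference is the boundary region.
#'
#' @param partition a [indiscernibility_partition()] result (or plain list of
#'   index blocks)
#' @param X integer vector of object indices
#' @return list with sorted integer vectors `lower`, `upper`, `boundary`
#' @export
lower_upper_approximation <- function(partition, X) {
  X <- as.integer(X)
  lower <- integer(0); upper <- integer(0)
  for (blk in partition) {
    inside <- sum(blk %in% X)
    if (inside == length(blk)) lower <- c(lower, blk)
    if (inside > 0) upper <- c(upper, blk)
  }
  list(lower = sort(lower), upper = sort(upper),
       boundary = sort(setdiff(upper, lower)))
}

#' Dependency degree of the decision on an attribute subset
#'
#' gamma_P(d) = |POS_P(d)| / |U|, where the positive region POS is the union
#' of P-blocks whose objects all share one decision value (objects classifiable
#' with certainty).
#'
#' @param table a [decision_table()]
#' @param P non-empty attribute subset
#' @return numeric in \[0, 1\]
#' @export
dependency_degree <- function(table, P) {
  if (length(P) == 0) stop_toxbalance("P must be non-empty", "toxbalance_schema_error")
  counts <- block_decision_counts(table, P)
  pure <- rowSums(counts > 0) == 1L
  sum(counts[pure, , drop = FALSE]) / length(table$decision)
}

# blocks x decision-values contingency table for the partition induced by P
block_decision_counts <- function(table, P) {
  ids <- block_ids(table, P)
  d <- match(table$decision, unique(table$decision))
  B <- max(ids); C <- max(d)
  matrix(tabulate((d - 1L) * B + ids, nbins = B * C), nrow = B)
}

#' Conditional entropy of the decision given an attribute subset
#'
#' H(d | P) = sum over P-blocks of (|block|/|U|) * H(decision within block),
#' base 2. Zero iff every block is decision-pure.
#'
#' @inheritParams dependency_degree
#' @return non-negative numeric
#' @export
conditional_entropy <- function(table, P) {
  if (length(P) == 0) stop_toxbalance("P must be non-empty", "toxbalance_schema_error")
  counts <- block_decision_counts(table, P)
  n <- length(table$decision)
  bs <- rowSums(counts)
  p <- counts / bs
  hb <- -rowSums(ifelse(counts > 0, p * log2(p), 0))
  sum(bs / n * hb)
}

# Marginal decision entropy H(d), base 2.
decision_entropy <- function(decision) {
  p <- table(decision) / length(decision)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Backward-elimination minimality pass: drop any attribute whose removal
# preserves gamma. Scanning from the last-added attribute keeps early greedy
# picks when either could go. Returns the pruned (still ordered) subset.
minimality_pass <- function(table, R, gamma_target) {
  if (length(R) <= 1) return(R)
  for (a in rev(R)) {
    cand <- setdiff(R, a)
    if (length(cand) == 0) next
    if (dependency_degree(table, cand) >= gamma_target) R <- cand
  }
  R
}

reduct_result <- function(table, selected, trace, method, measure) {
  gamma_full <- dependency_degree(table, table$attribute_names)
  structure(list(
    selected = selected,
    dependency_trace = trace,
    gamma_full = gamma_full,
    gamma_reduct = if (length(selected)) dependency_degree(table, selected) else 0,
    reduction_rate = 100 * (1 - length(selected) / ncol(table$cells)),
    method = method, measure = measure
  ), class = "reduct_result")
}

#' @export
print.reduct_result <- function(x, ...) {
  cat(sprintf("%s reduct: {%s}  (%d of %d attributes, reduction %.1f%%, gamma %.3f/%.3f)\n",
              x$method, paste(x$selected, collapse = ", "), length(x$selected),
              round(length(x$selected) / (1 - x$reduction_rate / 100 + 1e-12)),
              x$reduction_rate, x$gamma_reduct, x$gamma_full))
  invisible(x)
}

#' Quick-reduct attribute selection
#'
#' Greedy forward selection on the dependency degree: at each step add the
#' attribute that maximizes gamma of the grown subset (ties to the lowest
#' attribute index) until gamma equals that of the full attribute set, then a
#' backward minimality pass removes attributes whose deletion preserves gamma.
#'
#' @param table a discretized [decision_table()]
#' @return a `reduct_result` with the selected attribute names, the per-step
#'   gamma trace, and the reduction rate (percent)
#' @export
quick_reduct <- function(table) {
  A <- table$attribute_names
  gamma_full <- dependency_degree(table, A)
  R <- character(0); trace <- numeric(0)
  repeat {
    gamma_R <- if (length(R)) dependency_degree(table, R) else 0
    if (gamma_R >= gamma_full) break
    rest <- setdiff(A, R)
    gains <- vapply(rest, function(a) dependency_degree(table, c(R, a)), 0)
    best <- rest[which.max(gains)]           # which.max -> lowest index on tie
    if (max(gains) <= gamma_R && length(R) > 0) {
      # no single attribute improves gamma; add best anyway to make progress
      # (can happen on tables where only attribute combinations discriminate)
      best <- rest[which.max(gains)]
    }
    R <- c(R, best)
    trace <- c(trace, max(gains))
    if (length(R) == length(A)) break
  }
  R <- minimality_pass(table, R, gamma_full)
  reduct_result(table, R, trace, "QRFS", "gamma")
}

#' Entropy-based attribute selection
#'
#' Greedy forward selection minimizing the conditional entropy H(d | R);
#' stops when H(d | R) reaches H(d | A) (exact equality on discrete tables),
#' then applies the same backward minimality pass as [quick_reduct()].
#' If every attribute is constant the selection is empty, with a warning.
#'
#' @inheritParams quick_reduct
#' @return a `reduct_result`; `dependency_trace` holds the entropy path
#' @export
entropy_reduct <- function(table) {
  A <- table$attribute_names
  h_full <- conditional_entropy(table, A)
  h_marginal <- decision_entropy(table$decision)
  if (abs(h_full - h_marginal) < 1e-12 &&
      all(apply(table$cells, 2, function(x) length(unique(x)) == 1L))) {
    warning("all attributes constant; entropy cannot drop below H(d)")
    return(reduct_result(table, character(0), numeric(0), "EBFS", "entropy"))
  }
  R <- character(0); trace <- numeric(0)
  repeat {
    h_R <- if (length(R)) conditional_entropy(table, R) else h_marginal
    if (h_R <= h_full + 1e-12) break
    rest <- setdiff(A, R)
    hs <- vapply(rest, function(a) conditional_entropy(table, c(R, a)), 0)
    best <- rest[which.min(hs)]
    R <- c(R, best)
    trace <- c(trace, min(hs))
    if (length(R) == length(A)) break
  }
  gamma_full <- dependency_degree(table, A)
  R <- minimality_pass(table, R, gamma_full)
  reduct_result(table, R, trace, "EBFS", "entropy")
}

#' Discernibility matrix
#'
#' For each unordered object pair with differing decisions, the set of
#' condition attributes on which the two objects differ. An empty entry marks
#' an inconsistent pair (identical condition values, different decisions).
#'
#' @param table a [decision_table()]
#' @return object of class `discernibility_matrix`: list with `entries`
#'   (list of attribute-name vectors) and `pairs` (2-column matrix)
#' @export
discernibility_matrix <- function(table) {
  n <- nrow(table$cells)
  d <- table$decision
  discordant <- outer(d, d, "!=") & upper.tri(matrix(TRUE, n, n))
  pairs <- which(discordant, arr.ind = TRUE)        # col > row by upper.tri
  pairs <- cbind(pairs[, 1], pairs[, 2])
  entries <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    table$attribute_names[table$cells[i, ] != table$cells[j, ]]
  })
  structure(list(entries = entries, pairs = pairs),
            class = "discernibility_matrix")
}

#' Discernibility-matrix attribute selection
#'
#' Builds the discernibility matrix over decision-discordant pairs and covers
#' its non-empty entries greedily (repeatedly picking the attribute present in
#' the most uncovered entries; ties to the lowest index), then prunes with the
#' backward minimality pass. Inconsistent pairs (empty entries) cannot be
#' covered; they are excluded with a warning.
#'
#' @inheritParams quick_reduct
#' @return a `reduct_result`; `dependency_trace` holds covered-entry counts
#' @export
discernibility_reduct <- function(table) {
  A <- table$attribute_names
  dm <- discernibility_matrix(table)
  entries <- dm$entries
  empty <- vapply(entries, length, 0L) == 0L
  if (any(empty)) {
    warning(sprintf("%d inconsistent object pair(s) excluded from cover", sum(empty)))
    entries <- entries[!empty]
  }
  R <- character(0); trace <- numeric(0)
  # incidence matrix entries x attributes for fast greedy cover
  inc <- matrix(FALSE, nrow = length(entries), ncol = length(A),
                dimnames = list(NULL, A))
  for (r in seq_along(entries)) inc[r, entries[[r]]] <- TRUE
  uncovered <- rep(TRUE, length(entries))
  while (any(uncovered)) {
    counts <- colSums(inc[uncovered, , drop = FALSE])
    best <- A[which.max(counts)]
    R <- c(R, best)
    uncovered <- uncovered & !inc[, best]
    trace <- c(trace, length(entries) - sum(uncovered))
  }
  gamma_full <- dependency_degree(table, A)
  if (length(R)) R <- minimality_pass(table, R, gamma_full)
  reduct_result(table, R, trace, "DMFS", "cover")
}

#' Run one of the reduct strategies by name
#'
#' @param table a discretized [decision_table()]
#' @param method `"qrfs"`, `"ebfs"` or `"dmfs"`
#' @return a `reduct_result`
#' @export
select_features <- function(table, method = c("qrfs", "ebfs", "dmfs")) {
  method <- match.arg(method)
  switch(method,
         qrfs = quick_reduct(table),
         ebfs = entropy_reduct(table),
         dmfs = discernibility_reduct(table))
}

#' Export a reduct result as JSON
#'
#' @param x a `reduct_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
export_reduct_json <- function(x, path) {
  jsonlite::write_json(list(
    method = x$method, selected = x$selected, trace = x$dependency_trace,
    gamma_full = x$gamma_full, gamma_reduct = x$gamma_reduct,
    reduction_rate = x$reduction_rate
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
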