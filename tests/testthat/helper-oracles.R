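# Independent oracles and fixture builders. These deliberately use the
# slowest, most literal formulation of each definition so they stay
# independent of the implementation paths they check.

# -- rough-set oracles ------------------------------------------------------

# Exhaustive O(n^2) pairwise-equality partition.
oracle_partition <- function(cells, B) {
  n <- nrow(cells)
  sub <- cells[, B, drop = FALSE]
  assigned <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    next_id <- next_id + 1L
    assigned[i] <- next_id
    if (i < n) for (j in (i + 1):n)
      if (all(sub[i, ] == sub[j, ])) assigned[j] <- next_id
  }
  unname(split(seq_len(n), assigned))
}

canonical_blocks <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, 0L))]
}

# Brute-force positive-region dependency degree: enumerate blocks, keep those
# whose objects share a decision.
oracle_gamma <- function(cells, decision, P) {
  blocks <- oracle_partition(cells, P)
  pos <- 0L
  for (blk in blocks)
    if (length(unique(decision[blk])) == 1L) pos <- pos + length(blk)
  pos / nrow(cells)
}

# Direct summation conditional entropy.
oracle_cond_entropy <- function(cells, decision, P) {
  blocks <- oracle_partition(cells, P)
  h <- 0
  for (blk in blocks) {
    p <- as.numeric(table(decision[blk])) / length(blk)
    h <- h + (length(blk) / nrow(cells)) * (-sum(p * log2(p)))
  }
  h
}

# All true reducts by exhaustive subset search: subsets R with
# gamma_R = gamma_A from which no single attribute can be dropped.
oracle_all_reducts <- function(cells, decision) {
  A <- seq_len(ncol(cells))
  g_full <- oracle_gamma(cells, decision, A)
  is_reduct <- function(R) {
    if (oracle_gamma(cells, decision, R) < g_full) return(FALSE)
    if (length(R) == 1L) return(TRUE)
    for (a in R)
      if (oracle_gamma(cells, decision, setdiff(R, a)) >= g_full) return(FALSE)
    TRUE
  }
  reducts <- list()
  for (m in seq_along(A)) {
    for (R in utils::combn(A, m, simplify = FALSE))
      if (is_reduct(R)) reducts[[length(reducts) + 1L]] <- R
  }
  reducts
}

# Seeded random small decision table (possibly inconsistent).
random_decision_table <- function(n_obj, n_attr, n_vals = 2, seed = 1) {
  set.seed(seed)
  cells <- matrix(sample.int(n_vals, n_obj * n_attr, replace = TRUE) - 1L,
                  nrow = n_obj)
  decision <- sample(0:1, n_obj, replace = TRUE)
  list(cells = cells, decision = decision)
}

# -- sampling oracles -------------------------------------------------------

# O(n^3) literal Tomek-link check on a raw coordinate matrix.
oracle_tomek_links <- function(z, labels) {
  n <- nrow(z)
  dm <- as.matrix(stats::dist(z))
  links <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) next
    ok <- TRUE
    for (e in seq_len(n)) {
      if (e == i || e == j) next
      if (dm[i, e] < dm[i, j] || dm[j, e] < dm[i, j]) { ok <- FALSE; break }
    }
    if (ok) links[[length(links) + 1L]] <- c(i, j)
  }
  links
}

# Balanced 1-D/2-D pool with two guaranteed Tomek links (pairs at x = 0/0.5
# and 10/10.6) and a link-free remainder, used to exercise cleaning.
crafted_link_pool <- function() {
  x <- cbind(c(0, 10, 50, 51, 0.5, 10.6, 80, 81), 0)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sample_pool(x, y)
}

# -- evaluation oracles -----------------------------------------------------

# AUC as the pairwise-ranking probability: correctly ordered positive/negative
# pairs plus half the ties, normalized.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small two-blob pool: minority at `shift`, majority at origin.
blob_pool <- function(n_min, n_maj, shift, sd = 1, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_maj * p, 0, sd), ncol = p),
             matrix(rnorm(n_min * p, shift, sd), ncol = p))
  sample_pool(x, c(rep(0L, n_maj), rep(1L, n_min)))
}
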