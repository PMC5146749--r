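# sampling: RUS/ROS/SMOTE, Danger detection, the iterative sampler and
# Tomek-link cleaning, with brute-force oracles for the geometric parts.

test_that("random undersampling equalizes by discarding majority rows only", {
  pool <- blob_pool(90, 463, shift = 2, seed = 1, p = 4)
  out <- random_undersample(pool, seed = 5)
  expect_identical(length(out$minority_indices), 90L)
  expect_identical(length(out$majority_indices), 90L)
  # minority untouched, majority subset of original majority rows
  expect_identical(out$features[out$minority_indices, ],
                   pool$features[pool$minority_indices, ])
  orig_maj <- apply(pool$features[pool$majority_indices, ], 1, paste, collapse = ",")
  kept_maj <- apply(out$features[out$majority_indices, ], 1, paste, collapse = ",")
  expect_true(all(kept_maj %in% orig_maj))
  expect_false(anyDuplicated(kept_maj) > 0)

  balanced <- blob_pool(20, 20, shift = 2, seed = 2)
  expect_identical(random_undersample(balanced, 1)$features, balanced$features)
  expect_error(sample_pool(matrix(rnorm(10), 5), rep(1, 5)) |>
                 random_undersample(), class = "toxbalance_degenerate_error")
})

test_that("random oversampling replicates minority rows to parity", {
  pool <- blob_pool(90, 463, shift = 2, seed = 3, p = 4)
  out <- random_oversample(pool, seed = 5)
  expect_identical(length(out$minority_indices), 463L)
  expect_identical(length(out$majority_indices), 463L)
  # majority untouched; every new minority row duplicates an original
  expect_identical(out$features[seq_len(553), ], pool$features)
  orig_min <- apply(pool$features[pool$minority_indices, ], 1, paste, collapse = ",")
  new_min <- apply(out$features[554:926, , drop = FALSE], 1, paste, collapse = ",")
  expect_true(all(new_min %in% orig_min))

  balanced <- blob_pool(20, 20, shift = 2, seed = 2)
  expect_identical(random_oversample(balanced, 1)$features, balanced$features)
})

test_that("SMOTE synthetics lie on recorded minority segments, reconstructed exactly", {
  pool <- blob_pool(15, 60, shift = 3, seed = 4, p = 5)
  out <- smote(pool, k_neighbors = 5, seed = 9)
  expect_identical(length(out$minority_indices), 60L)
  log <- attr(out, "smote_log")
  expect_identical(nrow(log), 45L)
  for (r in seq_len(nrow(log))) {
    xi <- pool$features[log$base[r], ]
    xh <- pool$features[log$neighbor[r], ]
    expect_identical(out$features[log$synthetic_row[r], ],
                     xi + log$delta[r] * (xh - xi))
    # neighbor really is a minority sample distinct from the base
    expect_true(log$neighbor[r] %in% pool$minority_indices)
    expect_true(log$neighbor[r] != log$base[r])
  }
  # delta endpoints of the interpolation formula
  xi <- c(0, 0); xh <- c(2, 4)
  expect_identical(xi + 0 * (xh - xi), xi)
  expect_identical(xi + 1 * (xh - xi), xh)
  expect_identical(xi + 0.5 * (xh - xi), c(1, 2))
  # majority rows identical to input majority rows
  expect_identical(out$features[out$majority_indices, ],
                   pool$features[pool$majority_indices, ])
})

test_that("SMOTE degenerate minorities fall back with a warning", {
  pool <- sample_pool(rbind(c(0, 0), matrix(rnorm(20), ncol = 2)),
                      c(1, rep(0, 10)))
  expect_warning(out <- smote(pool, seed = 1), "replication")
  expect_identical(length(out$minority_indices), 10L)
  pool3 <- sample_pool(rbind(matrix(0:5, ncol = 2), matrix(rnorm(20), ncol = 2)),
                       c(1, 1, 1, rep(0, 10)))
  expect_warning(out3 <- smote(pool3, k_neighbors = 5, seed = 1), "k_neighbors")
  expect_identical(length(out3$minority_indices), 10L)
})

test_that("Danger detection follows the strict-majority neighbor vote", {
  # majority point at origin surrounded by 3 minority; far majority cluster
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(-0.1, 0),
             c(10, 10), c(10.1, 10), c(10, 10.1), c(10.2, 10.2))
  y <- c(0, 1, 1, 1, 0, 0, 0, 0)
  pool <- sample_pool(x, y)
  expect_true(is_danger(pool, 1, k = 3))     # all 3 nearest are minority
  expect_false(is_danger(pool, 5, k = 3))    # deep inside majority cluster
  # k = 2 with one neighbor of each class: tie -> NOT danger
  x2 <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(30, 0), c(31, 0), c(60, 0))
  y2 <- c(0, 1, 0, 1, 0, 1)
  expect_false(is_danger(sample_pool(x2, y2), 1, k = 2))
  expect_error(is_danger(pool, 1, k = 8), class = "toxbalance_parameter_error")
})

test_that("the iterative sampling step balances classes with a monotone trace", {
  # two well-separated blobs, 12 points: no Danger anywhere, so one iteration
  # replicates all 4 minority samples and removes nothing
  x <- rbind(matrix(c(0, 0, 0.2, 0, 0, 0.2, 0.2, 0.2, 0.1, 0.1,
                      0, 0.1, 0.1, 0, 0.2, 0.1), ncol = 2, byrow = TRUE),
             matrix(c(50, 50, 50.2, 50, 50, 50.2, 50.2, 50.2), ncol = 2,
                    byrow = TRUE))
  pool <- sample_pool(x, c(rep(0, 8), rep(1, 4)))
  res <- its_sampling_step(pool, k_init = 3, seed = 1)
  expect_identical(nrow(res$trace), 1L)
  expect_identical(res$trace$removed, 0L)
  expect_identical(res$trace$replicated, 4L)
  expect_identical(length(res$pool$minority_indices), 8L)
  expect_identical(length(res$pool$majority_indices), 8L)

  # already balanced input: zero iterations, identity
  bal <- blob_pool(10, 10, shift = 3, seed = 2)
  res_bal <- its_sampling_step(bal, k_init = 15, seed = 1)
  expect_identical(nrow(res_bal$trace), 0L)
  expect_identical(res_bal$pool$features, bal$features)

  # overlap fixture: balance postcondition + monotone class sizes
  fix <- generate_pool(generator_spec(n_minority = 40, n_majority = 160,
                                      n_features = 8, separation = 1.2,
                                      overlap_fraction = 0.3, seed = 6))
  res_fix <- its_sampling_step(fix$pool, k_init = 15, seed = 3)
  expect_identical(length(res_fix$pool$minority_indices),
                   length(res_fix$pool$majority_indices))
  expect_true(all(diff(res_fix$trace$n_majority) <= 0))
  expect_true(all(diff(res_fix$trace$n_minority) >= 0))
  expect_error(its_sampling_step(fix$pool, k_init = 0),
               class = "toxbalance_parameter_error")
})

test_that("Tomek links match the literal O(n^3) definition", {
  # one sample per class: always a link
  p1 <- sample_pool(rbind(c(0, 0), c(1, 1)), c(1, 0))
  expect_identical(nrow(find_tomek_links(p1)), 1L)

  # 1-D: minority {0}, majority {1, 1.1}: d(1, 1.1) < d(0, 1) kills the link
  p2 <- sample_pool(cbind(c(0, 1, 1.1)), c(1, 0, 0))
  z2 <- toxbalance:::standardize_features(p2$features)
  expect_identical(nrow(find_tomek_links(p2)), length(oracle_tomek_links(z2, p2$labels)))
  expect_identical(nrow(find_tomek_links(p2)), 0L)

  # single-class pool: empty set
  p3 <- sample_pool(matrix(rnorm(12), ncol = 2), rep(1, 6))
  expect_identical(nrow(find_tomek_links(p3)), 0L)

  # randomized pools vs oracle
  for (s in 1:5) {
    pool <- blob_pool(8, 14, shift = 0.8, seed = 40 + s, p = 3)
    got <- find_tomek_links(pool)
    want <- oracle_tomek_links(toxbalance:::standardize_features(pool$features),
                               pool$labels)
    expect_identical(nrow(got), length(want),
                     label = sprintf("link count, seed %d", s))
    if (length(want)) {
      want_m <- do.call(rbind, want)
      expect_identical(got$i, as.integer(want_m[, 1]))
      expect_identical(got$j, as.integer(want_m[, 2]))
    }
  }
})

test_that("Tomek cleaning removes link endpoints pairwise until none remain", {
  pool <- crafted_link_pool()
  pre <- find_tomek_links(pool)
  expect_identical(nrow(pre), 2L)
  res <- tomek_clean(pool)
  expect_identical(nrow(find_tomek_links(res$pool)), 0L)
  expect_identical(unname(res$removed["minority"]), unname(res$removed["majority"]))
  expect_identical(length(res$pool$labels), 4L)

  # idempotence
  res2 <- tomek_clean(res$pool)
  expect_identical(res2$pool$features, res$pool$features)
  expect_identical(sum(res2$removed), 0L)

  # pool with no links: identity
  clean <- blob_pool(6, 6, shift = 20, seed = 1)
  expect_identical(tomek_clean(clean)$pool$features, clean$features)

  # interleaved 1-D region plus stable same-class cores: cleaning proceeds in
  # rounds until the oracle re-check finds no links
  inter <- sample_pool(cbind(c(0, 2.05, 40, 41, 1.1, 3.2, 80, 81)),
                       c(1, 1, 1, 1, 0, 0, 0, 0))
  res3 <- tomek_clean(inter)
  expect_gte(res3$rounds, 2L)
  expect_identical(nrow(find_tomek_links(res3$pool)), 0L)
  expect_length(oracle_tomek_links(
    toxbalance:::standardize_features(res3$pool$features), res3$pool$labels), 0L)
})

test_that("full ITS balances, cleans and preserves class parity", {
  # balanced crafted pool with links: sampling is a no-op, cleaning shrinks it
  pool <- crafted_link_pool()
  res <- its(pool, k_init = 3, seed = 1)
  expect_lt(length(res$pool$labels), length(pool$labels))
  expect_identical(length(res$pool$minority_indices),
                   length(res$pool$majority_indices))
  expect_identical(nrow(find_tomek_links(res$pool,
                                         attr(res$pool, "standardization"))), 0L)
  expect_identical(res$trace$phase[nrow(res$trace)], "cleaning")

  # benchmark-shaped fixture: postconditions at scale
  fix <- table2_fixture("reproductive", seed = 8)
  res2 <- its(fix$pool, k_init = 15, seed = 2)
  expect_identical(length(res2$pool$minority_indices),
                   length(res2$pool$majority_indices))
  expect_identical(nrow(find_tomek_links(res2$pool,
                                         attr(res2$pool, "standardization"))), 0L)
})

test_that("ITS moves class scatter apart on the overlap fixture", {
  fix <- generate_pool(generator_spec(n_minority = 40, n_majority = 160,
                                      n_features = 8, separation = 1.2,
                                      overlap_fraction = 0.3, seed = 5))
  res <- its(fix$pool, k_init = 15, seed = 5)
  std <- attr(res$pool, "standardization")
  before <- scatter_diagnostic(sample_pool(
    toxbalance:::standardize_features(fix$pool$features, std$center, std$scale),
    fix$pool$labels))
  tr <- res$trace
  expect_gte(min(tr$between_per_sample), before$between_per_sample)
  expect_lte(max(tr$within_per_sample), before$within_per_sample)
})

test_that("stochastic sampling operations are seed-deterministic", {
  pool <- blob_pool(30, 100, shift = 1.5, seed = 7, p = 6)
  for (method in c("rus", "ros", "smote", "its")) {
    a <- balance_pool(pool, method, seed = 11)
    b <- balance_pool(pool, method, seed = 11)
    expect_identical(a$features, b$features, label = paste(method, "same seed"))
    expect_identical(a$labels, b$labels)
  }
  # different seeds pick different random subsets for the random methods
  expect_false(identical(balance_pool(pool, "rus", seed = 11)$features,
                         balance_pool(pool, "rus", seed = 12)$features))
  expect_false(identical(balance_pool(pool, "smote", seed = 11)$features,
                         balance_pool(pool, "smote", seed = 12)$features))
})
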