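# Synthetic imbalanced descriptor tables: Gaussian class modes with
# controllable separation, an overlap subpopulation of minority samples
# placed at the majority mode (a "Danger-sample factory" that exercises the
# iterative sampler), and optional label noise. Feature columns are given
# heterogeneous scales so that distance standardization actually matters.

#' Generator specification
#'
#' @param n_minority,n_majority class sizes
#' @param n_features feature count (default 31, the descriptor vocabulary)
#' @param separation distance between class means in pooled-standard-deviation
#'   units (Euclidean, spread evenly across features)
#' @param overlap_fraction share of minority samples drawn at the majority
#'   mode (borderline/noisy "Danger" factory), in \[0, 1\]
#' @param noise_fraction share of samples whose labels are swapped pairwise
#'   across classes (keeps class counts exact), in \[0, 1\]
#' @param seed RNG seed
#' @return a `generator_spec` list
#' @export
generator_spec <- function(n_minority = 90, n_majority = 463, n_features = 31,
                           separation = 1.5, overlap_fraction = 0.3,
                           noise_fraction = 0, seed = 1) {
  stopifnot(n_minority >= 1, n_majority >= 1, n_features >= 1,
            separation >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_fraction >= 0, noise_fraction <= 1)
  structure(list(n_minority = as.integer(n_minority),
                 n_majority = as.integer(n_majority),
                 n_features = as.integer(n_features),
                 separation = separation,
                 overlap_fraction = overlap_fraction,
                 noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic imbalanced descriptor table
#'
#' Majority samples are drawn from a standard Gaussian mode; minority samples
#' from a mode displaced by `separation` pooled standard deviations, except
#' for an `overlap_fraction` share drawn at the majority mode. Each feature
#' is then affinely rescaled (lognormal scale, uniform offset) so columns
#' have realistic, very different magnitudes. Deterministic given the spec's
#' seed: the same seed reproduces the table bit-for-bit.
#'
#' @param spec a [generator_spec()]
#' @param endpoint label name to attach (default `"endpoint"`)
#' @return list with a [descriptor_table()] (`table`) and a [sample_pool()]
#'   (`pool`); minority = positive = label 1
#' @export
generate_pool <- function(spec, endpoint = "endpoint") {
  p <- spec$n_features
  shift <- spec$separation / sqrt(p)   # per-feature shift; Euclidean gap = separation
  with_seed(spec$seed, {
    n_overlap <- round(spec$overlap_fraction * spec$n_minority)
    n_core <- spec$n_minority - n_overlap
    maj <- matrix(stats::rnorm(spec$n_majority * p), ncol = p)
    min_core <- matrix(stats::rnorm(n_core * p, mean = shift), ncol = p)
    min_ovl <- matrix(stats::rnorm(n_overlap * p), ncol = p)
    x <- rbind(maj, min_core, min_ovl)
    y <- c(rep(0L, spec$n_majority), rep(1L, spec$n_minority))
    if (spec$noise_fraction > 0) {
      n_flip <- floor(spec$noise_fraction *
                        min(spec$n_minority, spec$n_majority) / 2) * 2L
      n_sw <- n_flip / 2L
      if (n_sw >= 1) {
        sw_min <- sample(which(y == 1L), n_sw)
        sw_maj <- sample(which(y == 0L), n_sw)
        y[sw_min] <- 0L; y[sw_maj] <- 1L   # pairwise swap keeps counts exact
      }
    }
    scales <- stats::rlnorm(p, meanlog = 1, sdlog = 1.2)
    offsets <- stats::runif(p, -5, 50)
    x <- sweep(sweep(x, 2, scales, "*"), 2, offsets, "+")
    ord <- sample.int(nrow(x))              # shuffle so classes are interleaved
    x <- x[ord, , drop = FALSE]; y <- y[ord]
    feature_names <- if (p <= length(DESCRIPTOR_NAMES))
      DESCRIPTOR_NAMES[seq_len(p)] else paste0("f", seq_len(p))
    colnames(x) <- feature_names
    tab <- descriptor_table(x, stats::setNames(list(y), endpoint))
    list(table = tab, pool = sample_pool(x, y))
  })
}

# Printed class counts of the four endpoints in the reference benchmark
# (553 liver-biotransformed drugs): positive / negative.
TABLE2_COUNTS <- list(
  mutagenic = c(pos = 90L, neg = 463L),
  tumorigenic = c(pos = 90L, neg = 463L),
  irritant = c(pos = 67L, neg = 486L),
  reproductive = c(pos = 187L, neg = 366L)
)

#' Synthetic fixture with the benchmark endpoint class counts
#'
#' Builds a synthetic pool whose class counts match the published benchmark
#' distribution for the chosen endpoint (90/463, 90/463, 67/486, 187/366).
#' Default separation 1.5 and overlap 0.3 give a hard-but-learnable problem
#' with genuine borderline samples.
#'
#' @param endpoint one of `"mutagenic"`, `"tumorigenic"`, `"irritant"`,
#'   `"reproductive"`
#' @param separation,overlap_fraction,noise_fraction,seed see [generator_spec()]
#' @return list with `table` and `pool` as in [generate_pool()]
#' @export
table2_fixture <- function(endpoint, separation = 1.5, overlap_fraction = 0.3,
                           noise_fraction = 0, seed = 1) {
  if (!endpoint %in% names(TABLE2_COUNTS))
    stop_toxbalance(sprintf("unknown endpoint '%s'", endpoint),
                    "toxbalance_schema_error")
  cnt <- TABLE2_COUNTS[[endpoint]]
  spec <- generator_spec(n_minority = cnt["pos"], n_majority = cnt["neg"],
                         n_features = 31, separation = separation,
                         overlap_fraction = overlap_fraction,
                         noise_fraction = noise_fraction, seed = seed)
  generate_pool(spec, endpoint = endpoint)
}
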