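#' @keywords internal
"_PACKAGE"

# Canonical 31 molecular-descriptor names (DataWarrior property vocabulary).
# Order is canonical throughout the package: feature i of a synthetic table
# always carries the same name.
DESCRIPTOR_NAMES <- c(
  "Total Molecular Weight", "Molecular Weight", "Absolute Weight",
  "cLogP", "cLogS", "H-Acceptors", "H-Donors",
  "Total Surface Area", "Polar Surface Area", "Druglikeness",
  "Molecular Shape Index", "Molecular Flexibility", "Molecular Complexity",
  "Non Hydrogen Atoms", "Non-Carbon/Hydrogen Atoms", "Metal Atoms",
  "Electron Negative Atoms", "Stereo Centers", "Rotatable Bonds",
  "Rings", "Aromatic Rings", "Aromatic Atoms", "sp3-Atoms",
  "Symmetric atoms", "Amides", "Amines", "AlkylAmines",
  "Aromatic Amines", "Aromatic Nitrogen", "Basic Nitrogen", "Acidic Oxygen"
)

ENDPOINTS <- c("mutagenic", "tumorigenic", "irritant", "reproductive")

#' Descriptor vocabulary
#'
#' The 31 canonical molecular-descriptor names used for synthetic tables and
#' expected (by name) in loaded CSVs, and the four toxicity endpoints.
#'
#' @return Character vector of names.
#' @export
descriptor_names <- function() DESCRIPTOR_NAMES

#' @rdname descriptor_names
#' @export
endpoint_names <- function() ENDPOINTS

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; printed tables in this domain
#' conventionally round 0.5 up. Used for all reported percentages/ratios.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations funnel through this so that a given seed
# yields byte-identical results regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629L) + 1L
}

# z-score standardization; constant columns map to 0 rather than NaN.
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

stop_toxbalance <- function(msg, class) {
  stop(structure(class = c(class, "toxbalance_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
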