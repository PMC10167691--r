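# Internal helpers shared across modules.

#' Derive a stage-specific random seed from a global seed
#'
#' The pipeline fans a single user-supplied seed out to its stochastic stages
#' (genetic algorithm, rule sampling, permutation null) so that each stage is
#' independently reproducible. The derivation is a small deterministic hash of
#' the stage label mixed with the global seed; results stay in `[1, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param label Character stage label, e.g. `"ga:PathwayA"`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by the Lehmer generator
  h <- (abs(seed) %% m)
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271) %% m
  as.integer(max(1, h))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package use this
# so that a user-visible seed argument never clobbers the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Uppercase, whitespace-stripped gene identifiers. No alias resolution: inputs
# are assumed pre-mapped to HGNC-style symbols.
normalize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
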