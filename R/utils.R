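#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named RNG substream seed from a global seed
#'
#' A single pipeline seed is fanned out to independent, stably named
#' substreams (one per assay, per bootstrap cell, per Monte-Carlo stage) by
#' hashing the stream name into the 31-bit seed space.  Adding a stream never
#' perturbs the draws of any other stream.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "assay_A") != substream_seed(1, "assay_B")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(name) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(name))) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Adjusted Rand index between two flat partitions (label vectors).
# Hubert & Arabie normalisation of the pair-counting Rand index.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial
  (sum_ij - expected) / denom
}

# internal: stop() with a consistent prefix-free message builder
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
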