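# Internal helpers shared across modules.

# The seven Greengenes ranks, in order, and their lineage prefixes.
.gg_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
.gg_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Lineage rank names
#'
#' The seven Greengenes-style taxonomic ranks used throughout the package,
#' from kingdom down to species.
#'
#' @return Character vector of rank names.
#' @export
#' @examples
#' taxa_ranks()
taxa_ranks <- function() .gg_ranks

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Deterministically derive a sub-stream seed (one per sample, per network
# pair, ...) from a base seed. Kept strictly below 2^31 so it is always a
# valid R integer seed; arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  i <- as.numeric(index) %% 2147483647
  as.integer((s * 48271 + i * 8191 + 1) %% 2147483647)
}

# Is x a whole number (vectorised, NA-safe)?
is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
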