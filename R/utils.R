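# Internal helpers shared across the pipeline.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps all package-level randomness reproducible
# without clobbering the user's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seed derived from a parent seed and a stage offset,
# kept inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) + 7919 * offset) %% .Machine$integer.max)
}

# Gaussian draws truncated below at `lower`, by rejection with vectorized
# refills. Means/sds recycle over n.
rnorm_trunc <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 10000L) {
      abort("truncated-normal rejection sampling failed to converge",
            class = "mepmix_internal_error")
    }
  }
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "mepmix_argument_error")
  }
  invisible(x)
}

# log(sum(exp(x))) along rows of a matrix, guarded against underflow.
row_logsumexp <- function(lx) {
  m <- apply(lx, 1L, max)
  m + log(rowSums(exp(lx - m)))
}

block_levels <- function() c("B1", "B2", paste0("P", 1:6))
post_blocks <- function() paste0("P", 1:6)
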