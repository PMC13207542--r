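# seed scoping: set the RNG inside a function without disturbing the
# caller's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# deterministic per-item child seeds, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483563) + 1L
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary_mask <- function(mask) all(mask == 0 | mask == 1)
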