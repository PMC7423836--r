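# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from a master seed; kept < 2^31 - 1.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 104729 * seq_len(n)) %% 2147483629 + 1
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ctcscope stores rasters as R matrices with matrix row = image row
# (0-based (row, col) coordinates in the API). EBImage indexes [x, y],
# i.e. its first dimension is the image column, so conversion transposes.
as_ebi <- function(m, maxval = 1) EBImage::Image(t(m) / maxval)
from_ebi <- function(img) t(EBImage::imageData(img))

max_intensity <- function(bit_depth) 2^bit_depth - 1

stopf <- function(...) stop(sprintf(...), call. = FALSE)
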