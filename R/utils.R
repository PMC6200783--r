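#' @keywords internal
"_PACKAGE"

# Round half away from zero for non-negative values; the convention used
# everywhere depth coordinates or mean intensities are mapped to integers.
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-stream seed derived from a master seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919 + 12345) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_pixel_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(x <= 255)
}
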