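# Independent brute-force oracles used across the suite. These stay naive
# on purpose: per-pixel double loops and first-principles rank arithmetic,
# never calling the implementation paths they check.

# Bernsen local threshold by scanning every pixel's circular neighbourhood.
brute_bernsen <- function(px, radius, contrast_threshold) {
  n <- nrow(px); m <- ncol(px)
  out <- matrix(FALSE, n, m)
  for (r in seq_len(n)) {
    for (c in seq_len(m)) {
      vals <- c()
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          rr <- r + dr; cc <- c + dc
          if (dr * dr + dc * dc <= radius * radius &&
              rr >= 1 && rr <= n && cc >= 1 && cc <= m)
            vals <- c(vals, px[rr, cc])
        }
      }
      lo <- min(vals); hi <- max(vals)
      mid <- (lo + hi) / 2
      out[r, c] <- if ((hi - lo) < contrast_threshold) mid >= 128
                   else px[r, c] >= mid
    }
  }
  out
}

# Average ranks from first principles: count of smaller values plus half
# the tied group (including self).
brute_ranks <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

brute_spearman_rho <- function(x, y) {
  rx <- brute_ranks(x); ry <- brute_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Count of integer grid points inside an ellipse, by enumeration.
brute_oval_count <- function(dim, center, semi_axes) {
  count <- 0L
  for (r in seq_len(dim[1]))
    for (c in seq_len(dim[2]))
      if (((r - center[1]) / semi_axes[1])^2 +
          ((c - center[2]) / semi_axes[2])^2 <= 1)
        count <- count + 1L
  count
}

# A small random flat-surface phantom volume for geometry tests.
make_test_volume <- function(rows = 8, cols = 8, ndepth = 40,
                             axial_pitch = 10, seed = 42) {
  flow <- with_test_seed(seed, array(sample(0:255, rows * cols * ndepth,
                                            replace = TRUE),
                                     c(rows, cols, ndepth)))
  octa_volume(flow, axial_pitch_um = axial_pitch, lateral_pitch_um = 12)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
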