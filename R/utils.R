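clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Linear indices (1-based, column-major) of pixels within a disc.
# Returns integer(0) when the disc lies entirely outside the image.
disc_indices <- function(center, radius, shape, inner = 0) {
  r0 <- center[1L]; c0 <- center[2L]
  rows <- max(1L, floor(r0 - radius)):min(shape[1L], ceiling(r0 + radius))
  cols <- max(1L, floor(c0 - radius)):min(shape[2L], ceiling(c0 + radius))
  if (!length(rows) || !length(cols) || rows[1L] > rows[length(rows)]) {
    return(integer(0))
  }
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  d2 <- (rr - r0)^2 + (cc - c0)^2
  keep <- d2 <= radius^2 & d2 >= inner^2
  rr[keep] + (cc[keep] - 1L) * shape[1L]
}

# Annulus |d - radius| <= half_width.
annulus_indices <- function(center, radius, half_width, shape) {
  disc_indices(center, radius + half_width, shape,
               inner = max(radius - half_width, 0))
}

# Grayscale max filter with a (2w+1) x (2w+1) square window, edge-replicated:
# w iterations of a separable 3x3 running maximum.  Used for non-maximum
# suppression in the ring accumulator.
max_filter2 <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(w)) {
    up   <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    down <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    m <- pmax(m, up, down)
    left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
    m <- pmax(m, left, right)
  }
  m
}

# Robust background scale: median and MAD (consistent with a normal sd).
robust_stats <- function(x) {
  m <- stats::median(x)
  list(median = m, mad = stats::mad(x, center = m))
}
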