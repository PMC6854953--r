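# Small in-code fixtures shared across the test files.

# A stack of pure Gaussian noise (clamped at zero) in the named channels.
noise_stack <- function(shape = c(256L, 256L), sigma = 0.02,
                        channels = c("nuclear", "wfa", "comparison", "pv"),
                        pixel_size = 0.3, seed = 99L) {
  withr::with_seed(seed, {
    ch <- lapply(channels, function(nm) {
      matrix(pmax(rnorm(prod(shape), 0, sigma), 0), shape[1L], shape[2L])
    })
    names(ch) <- channels
    image_stack(ch, pixel_size)
  })
}

# Paint a uniform annulus (radius +/- half_width, 0-based center) of the
# given value into a matrix.
paint_annulus <- function(m, center, radius, half_width = 2, value = 0.6) {
  idx <- pnnquant:::annulus_indices(center + 1, radius, half_width, dim(m))
  m[idx] <- value
  m
}

# Paint a soft-edged disc (0-based center).
paint_disc <- function(m, center, radius, value = 0.6, edge = 0.5) {
  pnnquant:::add_soft_disc(m, center + 1, radius, value, edge = edge)
}

# Greedy 1:1 matching of detections to ground-truth PNN cells.
match_detections <- function(detected, truth, tol_center = 3,
                             tol_radius = 3) {
  truth <- truth[truth$has_pnn, ]
  used <- rep(FALSE, nrow(truth))
  match_of <- rep(NA_integer_, nrow(detected))
  for (i in seq_len(nrow(detected))) {
    d <- sqrt((truth$row - detected$row[i])^2 +
                (truth$col - detected$col[i])^2)
    ok <- which(!used & d <= tol_center &
                  abs(truth$pnn_radius - detected$radius[i]) <= tol_radius)
    if (length(ok)) {
      j <- ok[which.min(d[ok])]
      used[j] <- TRUE
      match_of[i] <- j
    }
  }
  list(match_of = match_of,
       tp = sum(!is.na(match_of)),
       recall = sum(used) / max(nrow(truth), 1L),
       precision = sum(!is.na(match_of)) / max(nrow(detected), 1L),
       truth = truth)
}

# Ground-truth-positioned objects, bypassing the detectors: used to test
# measurement/classification in isolation from detection errors.
truth_objects <- function(scene, half_width = 2.5) {
  tr <- scene$truth
  nuclei <- tibble::tibble(
    nucleus_id = tr$cell_id, row = tr$row, col = tr$col,
    area = round(pi * tr$nucleus_radius^2),
    equivalent_radius = tr$nucleus_radius,
    mask = lapply(seq_len(nrow(tr)), function(i) {
      pnnquant:::disc_indices(c(tr$row[i], tr$col[i]) + 1,
                              tr$nucleus_radius[i], dim(scene$stack))
    }))
  pn <- tr[tr$has_pnn, ]
  pnns <- tibble::tibble(
    pnn_id = pn$cell_id, row = pn$row, col = pn$col,
    radius = pn$pnn_radius, score = 1, nucleus_id = pn$cell_id)
  pnns <- segment_rings(scene$stack, pnns, half_width = half_width)
  list(pnns = pnns, nuclei = nuclei, truth = tr)
}

# Independent Spearman oracle: midranks computed by hand, then the
# closed-form Pearson sum formula.
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}
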