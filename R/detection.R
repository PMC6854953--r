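#' Detect nuclei in the nuclear (Hoechst) channel
#'
#' Gaussian smoothing, robust global thresholding (median + `k` * MAD) and
#' connected-component labelling, followed by an area filter.  The result
#' gates ring candidates: a PNN is only accepted when a nucleus lies inside
#' its circle.
#'
#' @param stack An [image_stack()] with a nuclear channel.
#' @param channel Channel name (default `"nuclear"`).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param k Threshold offset in robust SD units above the background median.
#' @param level_fraction The threshold is also lifted to this fraction of
#'   the (smoothed) dynamic range, so masks track the half-maximum contour
#'   of the stain instead of its faint smoothed skirt.
#' @param area_range Keep components with pixel area inside this range.
#' @return A tibble sorted by centroid (row, then col) with columns
#'   `nucleus_id`, `row`, `col` (0-based centroid), `area`,
#'   `equivalent_radius` and a list-column `mask` of linear pixel indices.
#' @export
detect_nuclei <- function(stack, channel = "nuclear", smooth_sigma = 2,
                          k = 4, level_fraction = 0.5,
                          area_range = c(20, 2000)) {
  img <- get_channel(stack, channel)
  sm <- unclass(EBImage::gblur(img, sigma = smooth_sigma))
  bg <- robust_stats(sm)
  thr <- max(bg$median + k * bg$mad,
             bg$median + level_fraction * (max(sm) - bg$median))
  lab <- EBImage::bwlabel(sm > thr)
  n <- max(lab)
  if (n == 0L) return(empty_nuclei())
  idx_all <- which(lab > 0)
  idx_by_lab <- split(idx_all, lab[idx_all])
  areas <- lengths(idx_by_lab)
  keep <- which(areas >= area_range[1L] & areas <= area_range[2L])
  if (!length(keep)) return(empty_nuclei())
  nr <- nrow(img)
  out <- purrr::map_dfr(keep, function(j) {
    idx <- idx_by_lab[[j]]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    tibble::tibble(row = mean(rows) - 1, col = mean(cols) - 1,
                   area = length(idx),
                   equivalent_radius = sqrt(length(idx) / pi),
                   mask = list(idx))
  })
  out <- out[order(out$row, out$col), ]
  out$nucleus_id <- seq_len(nrow(out))
  out[, c("nucleus_id", "row", "col", "area", "equivalent_radius", "mask")]
}

empty_nuclei <- function() {
  tibble::tibble(nucleus_id = integer(0), row = numeric(0), col = numeric(0),
                 area = integer(0), equivalent_radius = numeric(0),
                 mask = list())
}

empty_rings <- function() {
  tibble::tibble(row = numeric(0), col = numeric(0), radius = numeric(0),
                 score = numeric(0))
}

# One-pixel-wide circle kernel of radius r, normalized to sum 1.
ring_kernel <- function(r) {
  ext <- ceiling(r) + 1L
  size <- 2L * ext + 1L
  d <- sqrt(outer((seq_len(size) - ext - 1)^2, (seq_len(size) - ext - 1)^2,
                  `+`))
  k <- matrix(as.numeric(abs(d - r) <= 0.5), size, size)
  k / sum(k)
}

#' Detect ring-shaped PNN candidates in the WFA channel
#'
#' A circular accumulator over a radius range: the smoothed WFA channel is
#' thresholded into a foreground map (median + `fg_k` * MAD), and for every
#' radius the fraction of a one-pixel circle covered by foreground is
#' computed at every center by convolution.  Per-pixel the best radius is
#' kept, local maxima of the score map above `score_threshold` become
#' candidates, and overlapping candidates are suppressed greedily (higher
#' score wins).  Deterministic: ties broken by (score desc, row asc,
#' col asc).
#'
#' @param stack An [image_stack()] with a WFA channel.
#' @param channel Channel name (default `"wfa"`).
#' @param r_min,r_max Radius search range in pixels.
#' @param score_threshold Minimum perimeter-coverage fraction in `[0, 1]`.
#' @param nms_spacing Minimum distance between accepted candidate centers;
#'   default `r_min`.
#' @param smooth_sigma Gaussian smoothing sigma before thresholding.
#' @param fg_k Foreground threshold offset in robust SD units.
#' @param overlap_band,overlap_frac A candidate is discarded when the
#'   fraction of its circle path lying within `overlap_band` pixels of
#'   higher-scoring accepted circles reaches `overlap_frac` of its own
#'   coverage score — off-center circles grazing an already-claimed thick
#'   ring explain no new structure.
#' @return Tibble of unvalidated candidates: `row`, `col` (0-based),
#'   `radius`, `score`, ordered by score (desc) then position.
#' @export
detect_rings <- function(stack, channel = "wfa", r_min = 8, r_max = 30,
                         score_threshold = 0.35, nms_spacing = NULL,
                         smooth_sigma = 1, fg_k = 3, overlap_band = 6,
                         overlap_frac = 0.5) {
  if (!is.finite(r_min) || !is.finite(r_max) || r_min >= r_max) {
    abort("`r_min` must be smaller than `r_max`.")
  }
  nms_spacing <- nms_spacing %||% r_min
  img <- get_channel(stack, channel)
  sm <- unclass(EBImage::gblur(img, sigma = smooth_sigma))
  bg <- robust_stats(sm)
  fg <- matrix(as.numeric(sm > bg$median + fg_k * bg$mad), nrow(img))
  if (!any(fg > 0)) return(empty_rings())
  radii <- seq(ceiling(r_min), floor(r_max))
  score <- matrix(-Inf, nrow(img), ncol(img))
  best_r <- matrix(NA_real_, nrow(img), ncol(img))
  for (r in radii) {
    acc <- unclass(EBImage::filter2(fg, ring_kernel(r)))
    upd <- acc > score
    score[upd] <- acc[upd]
    best_r[upd] <- r
  }
  peaks <- which(score >= score_threshold &
                   score >= max_filter2(score, ceiling(nms_spacing)))
  if (!length(peaks)) return(empty_rings())
  nr <- nrow(img)
  cand <- tibble::tibble(
    row = ((peaks - 1L) %% nr + 1L) - 1,
    col = ((peaks - 1L) %/% nr + 1L) - 1,
    radius = best_r[peaks],
    score = score[peaks])
  cand <- cand[order(-cand$score, cand$row, cand$col), ]
  theta <- seq(0, 2 * pi, length.out = 73L)[-73L]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    if (min(d2) < nms_spacing^2) next
    # circle-path overlap with already-accepted rings
    py <- cand$row[i] + cand$radius[i] * sin(theta)
    px <- cand$col[i] + cand$radius[i] * cos(theta)
    in_band <- rep(FALSE, length(theta))
    for (k in which(keep)) {
      dk <- sqrt((py - cand$row[k])^2 + (px - cand$col[k])^2)
      in_band <- in_band | abs(dk - cand$radius[k]) <= overlap_band
    }
    if (mean(in_band) < overlap_frac * cand$score[i]) keep[i] <- TRUE
  }
  cand <- cand[keep, ]
  refine_candidates(cand, score, fg, sm, r_min, r_max)
}

# Subpixel refinement: a least-squares (Kasa) circle fit to the foreground
# pixels of the annulus around each accumulator candidate, iterated twice so
# the annulus window re-centers on the fitted circle.
refine_candidates <- function(cand, score, fg, sm, r_min, r_max, band = 3.5) {
  if (!nrow(cand)) return(cand)
  shape <- dim(fg)
  for (i in seq_len(nrow(cand))) {
    ctr <- c(cand$row[i], cand$col[i]) + 1
    r <- cand$radius[i]
    for (it in 1:3) {
      idx <- annulus_indices(ctr, r, band, shape)
      idx <- idx[fg[idx] > 0]
      if (length(idx) < 6L) break
      y <- (idx - 1L) %% shape[1L] + 1L   # rows
      x <- (idx - 1L) %/% shape[1L] + 1L  # cols
      fit <- tryCatch(kasa_circle(y, x, sm[idx]), error = function(e) NULL)
      if (is.null(fit) || !all(is.finite(fit)) ||
          fit[3L] < r_min - 1 || fit[3L] > r_max + 1 ||
          sum((fit[1:2] - ctr)^2) > band^2) break
      ctr <- fit[1:2]
      r <- fit[3L]
    }
    cand$row[i] <- ctr[1L] - 1
    cand$col[i] <- ctr[2L] - 1
    cand$radius[i] <- r
  }
  cand
}

# Algebraic circle fit: minimize sum(w * ((y-a)^2 + (x-b)^2 - R^2)^2),
# linear in (a, b, a^2 + b^2 - R^2).
kasa_circle <- function(y, x, w = NULL) {
  A <- cbind(2 * y, 2 * x, 1)
  b <- y^2 + x^2
  if (!is.null(w)) {
    A <- A * w
    b <- b * w
  }
  sol <- solve(crossprod(A), crossprod(A, b))
  c(sol[1L], sol[2L], sqrt(max(sol[3L] + sol[1L]^2 + sol[2L]^2, 0)))
}

#' Validate ring candidates against detected nuclei
#'
#' Keeps a candidate if and only if at least one nucleus centroid lies
#' within its circle (distance from the candidate center smaller than
#' `radius * gate_factor`).  The nearest such nucleus is assigned; each
#' nucleus backs at most one candidate, with the higher-scoring candidate
#' winning.  The gate can only remove candidates, never add them.
#'
#' @param candidates Ring candidates from [detect_rings()].
#' @param nuclei Nuclei from [detect_nuclei()].
#' @param gate_factor Scale applied to the radius in the gate predicate.
#' @return Tibble of validated PNN objects: `pnn_id`, `row`, `col`,
#'   `radius`, `score`, `nucleus_id`.
#' @export
validate_rings <- function(candidates, nuclei, gate_factor = 1.0) {
  if (nrow(candidates) == 0L || nrow(nuclei) == 0L) {
    return(tibble::tibble(pnn_id = integer(0), row = numeric(0),
                          col = numeric(0), radius = numeric(0),
                          score = numeric(0), nucleus_id = integer(0)))
  }
  cand <- candidates[order(-candidates$score, candidates$row,
                           candidates$col), ]
  assigned <- rep(FALSE, nrow(nuclei))
  rows <- integer(0)
  nuc_of <- integer(0)
  for (i in seq_len(nrow(cand))) {
    d <- sqrt((nuclei$row - cand$row[i])^2 + (nuclei$col - cand$col[i])^2)
    eligible <- which(d < cand$radius[i] * gate_factor & !assigned)
    if (!length(eligible)) next
    j <- eligible[which.min(d[eligible])]
    assigned[j] <- TRUE
    rows <- c(rows, i)
    nuc_of <- c(nuc_of, nuclei$nucleus_id[j])
  }
  out <- cand[rows, ]
  out$nucleus_id <- nuc_of
  out$pnn_id <- seq_len(nrow(out))
  out[, c("pnn_id", "row", "col", "radius", "score", "nucleus_id")]
}

#' Segment the WFA-positive ring area of validated PNN objects
#'
#' For each object, pixels of the annulus `radius +/- half_width` whose WFA
#' intensity exceeds a local background threshold (median + `bg_k` * MAD of
#' an annular background shell just outside the ring) form the ring mask.
#' Objects whose mask comes out empty are dropped with a logged reason.
#'
#' @param stack An [image_stack()].
#' @param pnns Validated objects from [validate_rings()].
#' @param channel Channel used for segmentation (default `"wfa"`).
#' @param half_width Half-width of the segmentation annulus in pixels.
#' @param bg_shell Inner and outer offsets (pixels, beyond
#'   `radius + half_width`) of the background shell.
#' @param bg_k Threshold offset in robust SD units above the shell median.
#' @param quiet Suppress the per-object drop messages.
#' @return `pnns` with added columns `ring_mask` (list of linear pixel
#'   indices), `ring_area_px`, `bg_median`, `bg_mad`; dropped objects are
#'   recorded in the `"dropped"` attribute.
#' @export
segment_rings <- function(stack, pnns, channel = "wfa", half_width = 2,
                          bg_shell = c(2, 6), bg_k = 2, quiet = FALSE) {
  img <- get_channel(stack, channel)
  shape <- dim(img)
  masks <- vector("list", nrow(pnns))
  bg_med <- bg_mad <- rep(NA_real_, nrow(pnns))
  dropped <- character(0)
  for (i in seq_len(nrow(pnns))) {
    ctr <- c(pnns$row[i], pnns$col[i]) + 1
    idx <- annulus_indices(ctr, pnns$radius[i], half_width, shape)
    if (!length(idx)) {
      abort(sprintf("annulus of pnn_id %d lies entirely outside the image.",
                    pnns$pnn_id[i]))
    }
    shell <- disc_indices(ctr, pnns$radius[i] + half_width + bg_shell[2L],
                          shape,
                          inner = pnns$radius[i] + half_width + bg_shell[1L])
    bg <- robust_stats(img[shell])
    thr <- bg$median + bg_k * bg$mad
    m <- idx[img[idx] > thr]
    if (!length(m)) {
      dropped <- c(dropped, sprintf("pnn_id %d: empty ring mask",
                                    pnns$pnn_id[i]))
      next
    }
    masks[[i]] <- m
    bg_med[i] <- bg$median
    bg_mad[i] <- bg$mad
  }
  keep <- !vapply(masks, is.null, logical(1))
  if (length(dropped) && !quiet) {
    inform(paste0("dropped ", length(dropped), " object(s): ",
                  paste(dropped, collapse = "; ")))
  }
  out <- pnns[keep, ]
  out$ring_mask <- masks[keep]
  out$ring_area_px <- lengths(out$ring_mask)
  out$bg_median <- bg_med[keep]
  out$bg_mad <- bg_mad[keep]
  attr(out, "dropped") <- dropped
  out
}
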