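#' Image-level background statistics outside the detected cells
#'
#' Mean and SD of a channel over pixels that belong to no detected ring
#' (discs of `radius + margin` around every PNN center are excluded, as are
#' nucleus masks).  These statistics put the surface and puncta thresholds
#' on a per-image footing.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param pnns Validated/segmented PNN objects.
#' @param nuclei Optional nuclei table whose masks are excluded too.
#' @param margin Extra radius (pixels) added around each PNN disc.
#' @param smooth_sigma If positive, statistics are also returned for the
#'   Gaussian-smoothed channel (used by the puncta detector).
#' @return List with `mean`, `sd`, and (if smoothed) `mean_smooth`,
#'   `sd_smooth`.
#' @export
background_stats <- function(stack, channel = "comparison", pnns = NULL,
                             nuclei = NULL, margin = 4, smooth_sigma = 1) {
  img <- get_channel(stack, channel)
  shape <- dim(img)
  excluded <- rep(FALSE, length(img))
  if (!is.null(pnns) && nrow(pnns)) {
    for (i in seq_len(nrow(pnns))) {
      excluded[disc_indices(c(pnns$row[i], pnns$col[i]) + 1,
                            pnns$radius[i] + margin, shape)] <- TRUE
    }
  }
  if (!is.null(nuclei) && nrow(nuclei)) {
    excluded[unlist(nuclei$mask)] <- TRUE
  }
  keep <- which(!excluded)
  if (!length(keep)) abort("no background pixels left after exclusion.")
  out <- list(mean = mean(img[keep]), sd = stats::sd(img[keep]))
  if (smooth_sigma > 0) {
    sm <- unclass(EBImage::gblur(img, sigma = smooth_sigma))
    out$mean_smooth <- mean(sm[keep])
    out$sd_smooth <- stats::sd(sm[keep])
  }
  out
}

#' Classify comparison-channel signal on the PNN surface
#'
#' The surface score of a PNN is the z-score of its comparison-channel ring
#' mean against the image background:
#' `(ring mean - background mean) / background SD`.  A cell is called
#' surface-positive when the score reaches `k_surface`.
#'
#' @param records Measurement tibble from [measure_pnns()] containing a
#'   `mean_<channel>` column.
#' @param background Background statistics from [background_stats()] for
#'   the same channel.
#' @param channel Comparison channel name.
#' @param k_surface Positive-call threshold in background SD units.
#' @return `records` with added `surface_score` and `surface_positive`.
#' @export
classify_surface <- function(records, background, channel = "comparison",
                             k_surface = 3) {
  col <- paste0("mean_", channel)
  if (!col %in% names(records)) abort(sprintf("records lack %s.", col))
  if (!is.finite(background$sd) || background$sd <= 0) {
    abort("background SD is zero or undefined; cannot score surfaces.")
  }
  records$surface_score <- (records[[col]] - background$mean) / background$sd
  records$surface_positive <- records$surface_score >= k_surface
  records
}

#' Detect intracellular vesicle-like puncta inside PNN cells
#'
#' The soma region of a PNN object is the disc interior of its ring
#' (radius minus the segmentation half-width minus `soma_margin`) with the
#' nucleus removed.  Puncta are local maxima of the lightly smoothed
#' comparison channel inside that region that exceed the smoothed
#' background by `k_puncta` SD and are at least `min_spacing` apart.  A
#' cell is called intracellular-punctate when at least `min_count` puncta
#' are found.
#'
#' @param stack An [image_stack()].
#' @param pnns Validated PNN objects (with `nucleus_id`).
#' @param nuclei Nuclei table from [detect_nuclei()].
#' @param channel Comparison channel name.
#' @param background Background statistics from [background_stats()]
#'   (with smoothed moments); computed on the fly when `NULL`.
#' @param smooth_sigma Gaussian sigma (pixels) applied before peak finding.
#' @param k_puncta Threshold in smoothed-background SD units.
#' @param min_spacing Minimum distance between accepted puncta (pixels).
#' @param min_count Minimum puncta count for a positive call.
#' @param ring_half_width Segmentation half-width used to bound the soma.
#' @param soma_margin Extra clearance (pixels) between the soma region and
#'   the inner ring edge, keeping ring texture out of the peak search.
#' @return Tibble `pnn_id`, `puncta_count`, `intracellular_punctate`.
#' @export
detect_puncta <- function(stack, pnns, nuclei, channel = "comparison",
                          background = NULL, smooth_sigma = 0.8, k_puncta = 6,
                          min_spacing = 3, min_count = 3,
                          ring_half_width = 2.5, soma_margin = 3) {
  img <- get_channel(stack, channel)
  shape <- dim(img)
  sm <- unclass(EBImage::gblur(img, sigma = smooth_sigma))
  if (is.null(background)) {
    background <- background_stats(stack, channel, pnns, nuclei,
                                   smooth_sigma = smooth_sigma)
  }
  thr <- background$mean_smooth + k_puncta * background$sd_smooth
  nr <- shape[1L]
  nbr <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  counts <- integer(nrow(pnns))
  for (i in seq_len(nrow(pnns))) {
    ctr <- c(pnns$row[i], pnns$col[i]) + 1
    soma_r <- pnns$radius[i] - ring_half_width - soma_margin
    if (soma_r <= 0) abort(sprintf("empty soma region for pnn_id %d.",
                                   pnns$pnn_id[i]))
    idx <- disc_indices(ctr, soma_r, shape)
    nuc <- nuclei[nuclei$nucleus_id == pnns$nucleus_id[i], ]
    if (nrow(nuc) == 1L) {
      excl <- disc_indices(c(nuc$row, nuc$col) + 1,
                           nuc$equivalent_radius + 0.5, shape)
      idx <- setdiff(idx, union(excl, nuc$mask[[1L]]))
    }
    idx <- idx[idx > nr & idx <= length(img) - nr &
                 (idx - 1L) %% nr > 0L & (idx - 1L) %% nr < nr - 1L]
    if (!length(idx)) abort(sprintf("empty soma region for pnn_id %d.",
                                    pnns$pnn_id[i]))
    v <- sm[idx]
    cand <- idx[v > thr]
    if (!length(cand)) next
    is_max <- vapply(cand, function(p) all(sm[p] >= sm[p + nbr]), logical(1))
    cand <- cand[is_max]
    if (!length(cand)) next
    cand <- cand[order(-sm[cand])]
    crow <- (cand - 1L) %% nr + 1L
    ccol <- (cand - 1L) %/% nr + 1L
    kept <- integer(0)
    for (j in seq_along(cand)) {
      if (!length(kept) ||
          min((crow[kept] - crow[j])^2 + (ccol[kept] - ccol[j])^2) >=
            min_spacing^2) {
        kept <- c(kept, j)
      }
    }
    counts[i] <- length(kept)
  }
  tibble::tibble(pnn_id = pnns$pnn_id, puncta_count = counts,
                 intracellular_punctate = counts >= min_count)
}

#' Phenotype every detected PNN cell
#'
#' Combines [classify_surface()] and [detect_puncta()] into one phenotype
#' table.  The two calls are independent: a cell may be surface-positive,
#' intracellular-punctate, both, or neither.
#'
#' @param stack An [image_stack()].
#' @param pnns Segmented PNN objects.
#' @param nuclei Nuclei table.
#' @param records Optional precomputed measurements (from
#'   [measure_pnns()]); computed when `NULL`.
#' @param channel Comparison channel name.
#' @param k_surface,k_puncta,min_count,min_spacing Classification
#'   thresholds, see [classify_surface()] and [detect_puncta()].
#' @return Tibble `pnn_id`, `surface_score`, `surface_positive`,
#'   `puncta_count`, `intracellular_punctate`.
#' @export
phenotype_cells <- function(stack, pnns, nuclei, records = NULL,
                            channel = "comparison", k_surface = 3,
                            k_puncta = 6, min_count = 3, min_spacing = 3) {
  if (is.null(records)) records <- measure_pnns(stack, pnns)
  bg <- background_stats(stack, channel, pnns, nuclei)
  rec <- classify_surface(records, bg, channel, k_surface)
  pun <- detect_puncta(stack, pnns, nuclei, channel, background = bg,
                       k_puncta = k_puncta, min_spacing = min_spacing,
                       min_count = min_count)
  dplyr::left_join(
    rec[, c("pnn_id", "surface_score", "surface_positive")],
    pun, by = "pnn_id")
}

#' Phenotype census of the PNN-positive population
#'
#' Percentages of PNN-bearing cells that carry comparison-channel signal on
#' their net and that show the intracellular punctate pattern.  The
#' denominator (number of WFA-validated PNN cells) is recorded alongside.
#'
#' @param phenotypes Tibble from [phenotype_cells()].
#' @return An object of class `pnn_census` with `n_pnn_cells`,
#'   `pct_surface_positive`, `pct_intracellular` (0-100 scale).
#' @export
census <- function(phenotypes) {
  if (!nrow(phenotypes)) abort("no phenotypes: empty input.")
  structure(list(
    n_pnn_cells = nrow(phenotypes),
    pct_surface_positive = 100 * mean(phenotypes$surface_positive),
    pct_intracellular = 100 * mean(phenotypes$intracellular_punctate)),
    class = "pnn_census")
}

#' @export
print.pnn_census <- function(x, ...) {
  cat(sprintf(
    "<pnn_census> n = %d PNN cells: %.1f%% surface-positive, %.1f%% intracellular-punctate\n",
    x$n_pnn_cells, x$pct_surface_positive, x$pct_intracellular))
  invisible(x)
}

#' @export
tidy.pnn_census <- function(x, ...) {
  tibble::tibble(
    phenotype = c("surface_positive", "intracellular_punctate"),
    percent = c(x$pct_surface_positive, x$pct_intracellular),
    n_pnn_cells = x$n_pnn_cells)
}
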