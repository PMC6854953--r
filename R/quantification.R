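#' Mean intensity of one channel over a ring mask
#'
#' The arithmetic mean of the channel over the mask pixels — the same
#' region for every channel, so that cross-channel comparisons are made on
#' identical support.  No background subtraction is applied unless a
#' `background` value is supplied.
#'
#' @param stack An [image_stack()].
#' @param mask Integer vector of linear (column-major) pixel indices.
#' @param channel Channel name.
#' @param background Optional scalar subtracted from the mean.
#' @return The mean intensity (a single double).
#' @export
measure_intensity <- function(stack, mask, channel, background = 0) {
  if (!length(mask)) abort("empty mask.")
  img <- get_channel(stack, channel)
  if (any(mask < 1L) || any(mask > length(img))) {
    abort("mask indices out of range.")
  }
  mean(img[mask]) - background
}

#' Measure every segmented PNN object in every channel
#'
#' One row per object; per-channel means are computed over the identical
#' ring mask.  Areas are reported in pixels and in square micrometres via
#' the stack's pixel size.
#'
#' @param stack An [image_stack()].
#' @param pnns Segmented objects from [segment_rings()].
#' @param channels Channels to measure (default: all channels of the stack).
#' @param image_id Optional identifier stored with each record.
#' @return A tibble with columns `pnn_id`, `nucleus_id`, `row`, `col`,
#'   `radius`, `area_px`, `area_um2`, `image_id`, and one `mean_<channel>`
#'   column per measured channel.
#' @export
measure_pnns <- function(stack, pnns, channels = NULL, image_id = NA) {
  channels <- channels %||% names(stack$channels)
  if (is.null(pnns$ring_mask)) {
    abort("`pnns` has no ring_mask column; run segment_rings() first.")
  }
  base <- tibble::tibble(
    image_id = rep(image_id, nrow(pnns)),
    pnn_id = pnns$pnn_id,
    nucleus_id = pnns$nucleus_id,
    row = pnns$row, col = pnns$col, radius = pnns$radius,
    area_px = lengths(pnns$ring_mask),
    area_um2 = lengths(pnns$ring_mask) * stack$pixel_size^2)
  for (ch in channels) {
    base[[paste0("mean_", ch)]] <- vapply(
      pnns$ring_mask, function(m) measure_intensity(stack, m, ch), numeric(1))
  }
  base
}

#' Spearman rank correlation of paired measurements
#'
#' The Pearson correlation of average-assigned (midrank) ranks, exact under
#' ties.  Degenerate inputs (fewer than 3 pairs, or a constant variable)
#' raise an error rather than returning `NA` silently.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 pairs for a rank correlation.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("non-finite values in the input pairs.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("rank correlation undefined: a variable is constant.")
  }
  stats::cor(x, y, method = "spearman")
}

#' Object-based two-channel colocalization
#'
#' The pipeline's colocalization statistic: the Spearman rank correlation
#' between the per-PNN mean intensities of two channels, pooled over all
#' records by default (records from several images or animals are
#' combined into one coefficient).  Optionally a permutation p-value is
#' attached (label shuffles of one channel, seeded).
#'
#' @param records Measurement tibble from [measure_pnns()] (rows may be
#'   pooled across images).
#' @param channel_a,channel_b Channel names (matched against
#'   `mean_<channel>` columns).
#' @param by Optional grouping column name; when given, one coefficient is
#'   computed per group instead of pooling.
#' @param n_perm If positive, a permutation p-value with this many shuffles.
#' @param perm_seed Seed for the permutation draw.
#' @return An object of class `pnn_coloc` (or a tibble of them when `by`
#'   is used) with fields `rho`, `n`, `channel_pair`, and optionally
#'   `p_value`.
#' @export
colocalize <- function(records, channel_a = "wfa", channel_b = "comparison",
                       by = NULL, n_perm = 0, perm_seed = 1L) {
  ca <- paste0("mean_", channel_a)
  cb <- paste0("mean_", channel_b)
  if (!all(c(ca, cb) %in% names(records))) {
    abort(sprintf("records lack columns %s / %s.", ca, cb))
  }
  one <- function(df) {
    rho <- spearman_rho(df[[ca]], df[[cb]])
    res <- structure(list(rho = rho, n = nrow(df),
                          channel_pair = c(channel_a, channel_b),
                          p_value = NA_real_),
                     class = "pnn_coloc")
    if (n_perm > 0) {
      res$p_value <- withr::with_seed(perm_seed, {
        perm <- vapply(seq_len(n_perm), function(i) {
          spearman_rho(df[[ca]], sample(df[[cb]]))
        }, numeric(1))
        (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
      })
    }
    res
  }
  if (is.null(by)) return(one(records))
  groups <- split(records, records[[by]])
  out <- purrr::map_dfr(names(groups), function(g) {
    r <- one(groups[[g]])
    tibble::tibble(group = g, rho = r$rho, n = r$n, p_value = r$p_value)
  })
  out
}

#' @export
print.pnn_coloc <- function(x, ...) {
  cat(sprintf("<pnn_coloc> rho = %.3f (Spearman), n = %d PNNs, %s vs %s\n",
              x$rho, x$n, x$channel_pair[1L], x$channel_pair[2L]))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pnn_coloc <- function(x, ...) {
  tibble::tibble(channel_a = x$channel_pair[1L],
                 channel_b = x$channel_pair[2L],
                 estimate = x$rho, n = x$n, p_value = x$p_value,
                 method = "spearman")
}

#' @export
glance.pnn_coloc <- function(x, ...) {
  tibble::tibble(rho = x$rho, n = x$n, p_value = x$p_value)
}
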