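#' Configuration for the synthetic fluorescence scene generator
#'
#' Describes a single-plane, multi-channel fluorescence scene of cortical
#' cells, a subset of which carry a perineuronal net (PNN): a punctate
#' WFA-positive annulus around the soma.  Surface-positive cells carry the
#' same annular texture in the comparison channel, with a per-cell level
#' whose rank correlation with the WFA level is controlled by
#' `coupling_rho`; intracellular-punctate cells carry vesicle-like puncta
#' inside the soma in the comparison channel.  Parvalbumin-positive cells
#' show a filled soma in the `pv` channel.
#'
#' All coordinates are `(row, col)` pixels, 0-based, origin top-left; all
#' radii in pixels; `pixel_size` converts to micrometres.
#'
#' @param image_shape Integer `(rows, cols)` of the scene in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_cells Number of cells to place.
#' @param frac_pnn Fraction of cells bearing a PNN.
#' @param frac_surface_positive Fraction of PNN-bearing cells with
#'   comparison-channel signal on the net.
#' @param frac_intracellular Fraction of PNN-bearing cells with
#'   intracellular vesicle-like puncta in the comparison channel.
#' @param coupling_rho Target population Spearman correlation between the
#'   per-cell WFA level and comparison-channel surface level among
#'   surface-positive PNN cells, in `[-1, 1]`.  Implemented with a Gaussian
#'   copula at the Pearson value `2 * sin(pi * rho / 6)` that induces the
#'   requested Spearman correlation for continuous marginals.
#' @param wfa_intensity,comparison_intensity Length-2 vectors
#'   `(mean, sd)` of the truncated-normal per-cell intensity marginals, on
#'   the `[0, 1]` scale.
#' @param intensity_bounds Truncation bounds of the intensity marginals.
#' @param nuclear_level,pv_level Peak intensity of the nuclear stain and of
#'   the parvalbumin soma fill.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param shot_noise If `TRUE`, apply Poisson shot noise (at `shot_scale`
#'   photons per unit intensity) before the Gaussian read noise.
#' @param shot_scale Photons corresponding to intensity 1.0.
#' @param nucleus_radius_range,pnn_radius_range Per-cell radii are drawn
#'   uniformly from these ranges (pixels).  The PNN radius must exceed the
#'   nucleus radius.
#' @param pnn_thickness Half-width of the PNN annulus (pixels): the ring
#'   occupies radii `pnn_radius +/- pnn_thickness`.
#' @param ring_dot_density Dots per pixel^2 of annulus area in the punctate
#'   ring texture.
#' @param ring_dot_sigma Gaussian sigma (pixels) of one texture dot.
#' @param ring_dot_spacing Minimum spacing between texture dots (pixels).
#' @param puncta_sigma Gaussian sigma (pixels) of an intracellular punctum.
#' @param puncta_level Peak intensity of an intracellular punctum.
#' @param n_puncta_range Target puncta count per intracellular cell, drawn
#'   uniformly from this integer range; the realized (placed) count is
#'   recorded in the ground truth.
#' @param puncta_min_spacing Minimum spacing between puncta (pixels).
#' @param min_center_spacing Minimum distance between cell centers; the
#'   default `2 * (max(pnn_radius_range) + pnn_thickness) + 2` guarantees
#'   non-overlapping rings.
#' @param frac_pv Fraction of cells that are parvalbumin-positive.
#' @param frac_pnn_given_pv Optional PNN fraction among PV cells; when set,
#'   `frac_pnn` applies only to non-PV cells.
#' @param n_ring_artifacts Number of nucleus-free ring artefacts to render
#'   in the WFA channel (for testing the nuclear gate).
#' @param ring_intensity_scale Named multipliers applied to the drawn ring
#'   levels, e.g. `c(wfa = 0.3, comparison = 0.3)` emulates enzymatic PNN
#'   digestion.
#' @param exact_counts If `TRUE`, phenotype counts equal
#'   `round(frac * n)` exactly instead of being binomial draws.
#' @param seed Integer seed; the same configuration and seed give
#'   bit-identical scenes.
#'
#' @return A validated object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(512L, 512L),
                         pixel_size = 0.3,
                         n_cells = 40L,
                         frac_pnn = 0.7,
                         frac_surface_positive = 0.66,
                         frac_intracellular = 0.29,
                         coupling_rho = 0.816,
                         wfa_intensity = c(0.55, 0.12),
                         comparison_intensity = c(0.50, 0.12),
                         intensity_bounds = c(0.15, 0.95),
                         nuclear_level = 0.6,
                         pv_level = 0.5,
                         noise_sigma = 0.02,
                         shot_noise = FALSE,
                         shot_scale = 2000,
                         nucleus_radius_range = c(3.5, 4.5),
                         pnn_radius_range = c(14, 20),
                         pnn_thickness = 2,
                         ring_dot_density = 0.12,
                         ring_dot_sigma = 1.2,
                         ring_dot_spacing = 2,
                         puncta_sigma = 1.3,
                         puncta_level = 0.7,
                         n_puncta_range = c(4L, 7L),
                         puncta_min_spacing = 5,
                         min_center_spacing = NULL,
                         frac_pv = 0,
                         frac_pnn_given_pv = NULL,
                         n_ring_artifacts = 0L,
                         ring_intensity_scale = c(wfa = 1, comparison = 1),
                         exact_counts = FALSE,
                         seed = NULL) {
  cfg <- list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), frac_pnn = frac_pnn,
    frac_surface_positive = frac_surface_positive,
    frac_intracellular = frac_intracellular, coupling_rho = coupling_rho,
    wfa_intensity = wfa_intensity, comparison_intensity = comparison_intensity,
    intensity_bounds = intensity_bounds, nuclear_level = nuclear_level,
    pv_level = pv_level, noise_sigma = noise_sigma, shot_noise = shot_noise,
    shot_scale = shot_scale, nucleus_radius_range = nucleus_radius_range,
    pnn_radius_range = pnn_radius_range, pnn_thickness = pnn_thickness,
    ring_dot_density = ring_dot_density, ring_dot_sigma = ring_dot_sigma,
    ring_dot_spacing = ring_dot_spacing, puncta_sigma = puncta_sigma,
    puncta_level = puncta_level,
    n_puncta_range = as.integer(n_puncta_range),
    puncta_min_spacing = puncta_min_spacing,
    min_center_spacing = min_center_spacing %||%
      (2 * (max(pnn_radius_range) + pnn_thickness) + 2),
    frac_pv = frac_pv, frac_pnn_given_pv = frac_pnn_given_pv,
    n_ring_artifacts = as.integer(n_ring_artifacts),
    ring_intensity_scale = ring_intensity_scale,
    exact_counts = isTRUE(exact_counts), seed = seed)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  num_ok <- function(x) all(is.finite(x))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape <= 0L)) {
    abort("`image_shape` must be two positive integers.")
  }
  if (!num_ok(cfg$pixel_size) || cfg$pixel_size <= 0) {
    abort("`pixel_size` must be positive.")
  }
  if (is.na(cfg$n_cells) || cfg$n_cells < 0L) abort("`n_cells` must be >= 0.")
  for (f in c("frac_pnn", "frac_surface_positive", "frac_intracellular",
              "frac_pv")) {
    v <- cfg[[f]]
    if (!num_ok(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f))
    }
  }
  if (!is.null(cfg$frac_pnn_given_pv) &&
      (!num_ok(cfg$frac_pnn_given_pv) || cfg$frac_pnn_given_pv < 0 ||
       cfg$frac_pnn_given_pv > 1)) {
    abort("`frac_pnn_given_pv` must lie in [0, 1].")
  }
  if (!num_ok(cfg$coupling_rho) || abs(cfg$coupling_rho) > 1) {
    abort("`coupling_rho` must lie in [-1, 1].")
  }
  if (!num_ok(cfg$noise_sigma) || cfg$noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.")
  }
  if (min(cfg$pnn_radius_range) <= max(cfg$nucleus_radius_range)) {
    abort("PNN radii must exceed nucleus radii.")
  }
  if (any(cfg$wfa_intensity <= 0) || any(cfg$comparison_intensity <= 0) ||
      !num_ok(c(cfg$wfa_intensity, cfg$comparison_intensity))) {
    abort("intensity marginals must be finite and positive.")
  }
  if (cfg$intensity_bounds[1L] <= 0 || diff(cfg$intensity_bounds) <= 0) {
    abort("`intensity_bounds` must be increasing and positive.")
  }
  if (!all(c("wfa", "comparison") %in% names(cfg$ring_intensity_scale)) ||
      any(cfg$ring_intensity_scale < 0)) {
    abort("`ring_intensity_scale` needs non-negative 'wfa' and 'comparison' entries.")
  }
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d x %d px, %d cells (PNN %.0f%%, surface %.0f%%, intracellular %.0f%%), rho = %.3f\n",
    x$image_shape[1L], x$image_shape[2L], x$n_cells, 100 * x$frac_pnn,
    100 * x$frac_surface_positive, 100 * x$frac_intracellular,
    x$coupling_rho))
  invisible(x)
}

# Quantile of a normal truncated to [a, b].
qtruncnorm <- function(p, mean, sd, a, b) {
  pa <- stats::pnorm(a, mean, sd); pb <- stats::pnorm(b, mean, sd)
  stats::qnorm(pa + p * (pb - pa), mean, sd)
}

# Phenotype assignment: Bernoulli draw or exact round(frac * n) positives.
assign_fraction <- function(n, frac, exact) {
  if (n == 0L) return(logical(0))
  if (exact) {
    k <- round(frac * n)
    out <- rep(FALSE, n)
    out[sample.int(n, k)] <- TRUE
    out
  } else {
    stats::runif(n) < frac
  }
}

# Rejection-sample cell centers at the configured minimum spacing.
place_centers <- function(n, shape, margin, spacing, max_tries = 200L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  lo <- c(margin, margin)
  hi <- c(shape[1L] - margin, shape[2L] - margin)
  if (any(hi <= lo)) {
    abort("image too small for the configured cell radii and margin.")
  }
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  total <- n * max_tries
  while (placed < n && tries < total) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, lo[1L], hi[1L]), stats::runif(1, lo[2L], hi[2L]))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1L] - cand[1L])^2 +
            (centers[seq_len(placed), 2L] - cand[2L])^2) >= spacing^2) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n) {
    abort(sprintf(
      "could only place %d of %d cells at min_center_spacing = %.1f px.",
      placed, n, spacing))
  }
  centers
}

# Draw the per-cell ground truth (no rendering, no seeding).
draw_truth <- function(cfg) {
  n <- cfg$n_cells
  margin <- max(cfg$pnn_radius_range) + cfg$pnn_thickness + 8
  # cells sit on the pixel grid so rendered patches and the geometric truth
  # masks coincide exactly
  centers <- round(place_centers(n, cfg$image_shape, margin,
                                 cfg$min_center_spacing))
  is_pv <- assign_fraction(n, cfg$frac_pv, cfg$exact_counts)
  has_pnn <- rep(FALSE, n)
  if (is.null(cfg$frac_pnn_given_pv)) {
    has_pnn <- assign_fraction(n, cfg$frac_pnn, cfg$exact_counts)
  } else {
    has_pnn[is_pv] <- assign_fraction(sum(is_pv), cfg$frac_pnn_given_pv,
                                      cfg$exact_counts)
    has_pnn[!is_pv] <- assign_fraction(sum(!is_pv), cfg$frac_pnn,
                                       cfg$exact_counts)
  }
  n_pnn <- sum(has_pnn)
  surface <- rep(FALSE, n)
  intra <- rep(FALSE, n)
  surface[has_pnn] <- assign_fraction(n_pnn, cfg$frac_surface_positive,
                                      cfg$exact_counts)
  intra[has_pnn] <- assign_fraction(n_pnn, cfg$frac_intracellular,
                                    cfg$exact_counts)

  # Gaussian copula: Pearson value inducing the requested Spearman.
  r_pearson <- 2 * sin(pi * cfg$coupling_rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r_pearson * z1 + sqrt(max(0, 1 - r_pearson^2)) * stats::rnorm(n)
  b <- cfg$intensity_bounds
  wfa_level <- qtruncnorm(stats::pnorm(z1), cfg$wfa_intensity[1L],
                          cfg$wfa_intensity[2L], b[1L], b[2L])
  comp_level <- qtruncnorm(stats::pnorm(z2), cfg$comparison_intensity[1L],
                           cfg$comparison_intensity[2L], b[1L], b[2L])
  wfa_level[!has_pnn] <- 0
  comp_level[!(has_pnn & surface)] <- 0
  wfa_level <- wfa_level * cfg$ring_intensity_scale[["wfa"]]
  comp_level <- comp_level * cfg$ring_intensity_scale[["comparison"]]

  n_puncta <- integer(n)
  puncta_choices <- cfg$n_puncta_range[1L]:cfg$n_puncta_range[2L]
  n_puncta[intra] <- puncta_choices[
    sample.int(length(puncta_choices), sum(intra), replace = TRUE)]
  tibble::tibble(
    cell_id = seq_len(n),
    row = centers[, 1L] - 1,  # 0-based user-facing coordinates
    col = centers[, 2L] - 1,
    nucleus_radius = stats::runif(n, cfg$nucleus_radius_range[1L],
                                  cfg$nucleus_radius_range[2L]),
    is_pv = is_pv,
    has_pnn = has_pnn,
    pnn_radius = ifelse(has_pnn,
                        stats::runif(n, cfg$pnn_radius_range[1L],
                                     cfg$pnn_radius_range[2L]), NA_real_),
    pnn_thickness = ifelse(has_pnn, cfg$pnn_thickness, NA_real_),
    wfa_level = wfa_level,
    surface_positive = surface,
    comparison_surface_level = comp_level,
    intracellular_punctate = intra,
    n_puncta = n_puncta)
}

#' Draw a ground-truth cell table without rendering images
#'
#' Useful for checking the statistical properties of the generator (rank
#' coupling, phenotype fractions) at large `n_cells` cheaply.
#'
#' @param config A [scene_config()].
#' @return A tibble with one row per cell.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, draw_truth(config))
  } else {
    draw_truth(config)
  }
}

# Add a logistic-edged disc into `mat` (1-based center).
add_soft_disc <- function(mat, center, radius, level, edge = 0.8) {
  shape <- dim(mat)
  ext <- radius + 4 * edge
  rows <- max(1L, floor(center[1L] - ext)):min(shape[1L], ceiling(center[1L] + ext))
  cols <- max(1L, floor(center[2L] - ext)):min(shape[2L], ceiling(center[2L] + ext))
  d <- sqrt(outer((rows - center[1L])^2, (cols - center[2L])^2, `+`))
  mat[rows, cols] <- mat[rows, cols] + level / (1 + exp((d - radius) / edge))
  mat
}

# Dart-throwing of dot positions in an annular band (polar sampling with a
# minimum spacing); returns a matrix of (row, col) offsets from the center.
sample_annulus_dots <- function(n_target, r_inner, r_outer, spacing,
                                max_tries_per_dot = 40L) {
  pts <- matrix(NA_real_, n_target, 2L)
  placed <- 0L
  tries <- 0L
  total <- n_target * max_tries_per_dot
  while (placed < n_target && tries < total) {
    tries <- tries + 1L
    rad <- sqrt(stats::runif(1, r_inner^2, r_outer^2))
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(rad * cos(th), rad * sin(th))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1L] - cand[1L])^2 +
            (pts[seq_len(placed), 2L] - cand[2L])^2) >= spacing^2) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts[seq_len(placed), , drop = FALSE]
}

# Render a punctate annular texture patch for one cell.  Returns the patch
# and its top-left (1-based) position; patch mean over the geometric ring
# mask is normalized to 1 so callers scale it by the per-channel level.
render_ring_patch <- function(radius, thickness, cfg) {
  t <- thickness
  ext <- ceiling(radius + t + 3 * cfg$ring_dot_sigma)
  size <- 2L * ext + 1L
  ctr <- ext + 1
  area <- pi * ((radius + t)^2 - (radius - t)^2)
  n_dots <- max(6L, ceiling(cfg$ring_dot_density * area))
  dots <- sample_annulus_dots(n_dots, radius - t, radius + t,
                              cfg$ring_dot_spacing)
  patch <- matrix(0, size, size)
  s2 <- 2 * cfg$ring_dot_sigma^2
  half <- ceiling(3 * cfg$ring_dot_sigma)
  for (i in seq_len(nrow(dots))) {
    dr <- ctr + dots[i, 1L]; dc <- ctr + dots[i, 2L]
    rows <- max(1L, floor(dr - half)):min(size, ceiling(dr + half))
    cols <- max(1L, floor(dc - half)):min(size, ceiling(dc + half))
    patch[rows, cols] <- patch[rows, cols] +
      exp(-outer((rows - dr)^2, (cols - dc)^2, `+`) / s2)
  }
  idx <- annulus_indices(c(ctr, ctr), radius, t, c(size, size))
  mu <- mean(patch[idx])
  if (mu > 0) patch <- patch / mu
  patch
}

add_patch <- function(mat, patch, center) {
  ext <- (nrow(patch) - 1L) / 2L
  shape <- dim(mat)
  r0 <- round(center[1L]); c0 <- round(center[2L])
  rows <- max(1L, r0 - ext):min(shape[1L], r0 + ext)
  cols <- max(1L, c0 - ext):min(shape[2L], c0 + ext)
  pr <- rows - (r0 - ext) + 1L
  pc <- cols - (c0 - ext) + 1L
  mat[rows, cols] <- mat[rows, cols] + patch[pr, pc]
  mat
}

render_scene <- function(truth, cfg) {
  shape <- cfg$image_shape
  ch <- list(nuclear = matrix(0, shape[1L], shape[2L]),
             wfa = matrix(0, shape[1L], shape[2L]),
             comparison = matrix(0, shape[1L], shape[2L]),
             pv = matrix(0, shape[1L], shape[2L]))
  puncta_log <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cell <- truth[i, ]
    ctr <- c(cell$row, cell$col) + 1  # back to 1-based
    lvl <- cfg$nuclear_level * stats::runif(1, 0.9, 1.1)
    ch$nuclear <- add_soft_disc(ch$nuclear, ctr, cell$nucleus_radius, lvl,
                                edge = 0.5)
    if (cell$is_pv) {
      ch$pv <- add_soft_disc(ch$pv, ctr, cell$nucleus_radius + 4,
                             cfg$pv_level * stats::runif(1, 0.9, 1.1))
    }
    if (cell$has_pnn) {
      patch <- render_ring_patch(cell$pnn_radius, cell$pnn_thickness, cfg)
      if (cell$wfa_level > 0) {
        ch$wfa <- add_patch(ch$wfa, patch * cell$wfa_level, ctr)
      }
      if (cell$surface_positive && cell$comparison_surface_level > 0) {
        ch$comparison <- add_patch(
          ch$comparison, patch * cell$comparison_surface_level, ctr)
      }
      if (cell$n_puncta > 0L) {
        inner <- cell$nucleus_radius + 3.5
        outer <- cell$pnn_radius - cell$pnn_thickness - 4
        dots <- sample_annulus_dots(cell$n_puncta, inner, max(outer, inner + 0.5),
                                    cfg$puncta_min_spacing)
        s2 <- 2 * cfg$puncta_sigma^2
        half <- ceiling(3 * cfg$puncta_sigma)
        for (k in seq_len(nrow(dots))) {
          dr <- ctr[1L] + dots[k, 1L]; dc <- ctr[2L] + dots[k, 2L]
          rows <- max(1L, floor(dr - half)):min(shape[1L], ceiling(dr + half))
          cols <- max(1L, floor(dc - half)):min(shape[2L], ceiling(dc + half))
          ch$comparison[rows, cols] <- ch$comparison[rows, cols] +
            cfg$puncta_level * exp(-outer((rows - dr)^2, (cols - dc)^2, `+`) / s2)
        }
        puncta_log[[i]] <- nrow(dots)
      }
    }
  }
  truth$n_puncta <- vapply(seq_len(nrow(truth)), function(i) {
    p <- puncta_log[[i]]
    if (is.null(p)) 0L else as.integer(p)
  }, integer(1))
  truth$intracellular_punctate <- truth$intracellular_punctate &
    truth$n_puncta > 0L

  # nucleus-free ring artefacts, spaced away from the cells
  artifacts <- NULL
  if (cfg$n_ring_artifacts > 0L) {
    margin <- max(cfg$pnn_radius_range) + cfg$pnn_thickness + 8
    existing <- if (nrow(truth)) cbind(truth$row + 1, truth$col + 1)
    pos <- place_extra_centers(cfg$n_ring_artifacts, existing, shape, margin,
                               cfg$min_center_spacing)
    rads <- stats::runif(cfg$n_ring_artifacts, cfg$pnn_radius_range[1L],
                         cfg$pnn_radius_range[2L])
    for (k in seq_len(cfg$n_ring_artifacts)) {
      patch <- render_ring_patch(rads[k], cfg$pnn_thickness, cfg)
      ch$wfa <- add_patch(ch$wfa, patch * cfg$wfa_intensity[1L], pos[k, ])
    }
    artifacts <- tibble::tibble(row = pos[, 1L] - 1, col = pos[, 2L] - 1,
                                radius = rads)
  }

  # true noiseless ring means per channel, over the geometric ring mask
  truth$ring_mean_wfa <- NA_real_
  truth$ring_mean_comparison <- NA_real_
  for (i in which(truth$has_pnn)) {
    idx <- annulus_indices(c(truth$row[i], truth$col[i]) + 1,
                           truth$pnn_radius[i], truth$pnn_thickness[i], shape)
    truth$ring_mean_wfa[i] <- mean(ch$wfa[idx])
    truth$ring_mean_comparison[i] <- mean(ch$comparison[idx])
  }

  for (nm in names(ch)) {
    x <- ch[[nm]]
    if (cfg$shot_noise) {
      x <- stats::rpois(length(x), pmax(x, 0) * cfg$shot_scale) / cfg$shot_scale
      dim(x) <- shape
    }
    if (cfg$noise_sigma > 0) {
      x <- x + stats::rnorm(length(x), 0, cfg$noise_sigma)
    }
    ch[[nm]] <- pmax(x, 0)
  }
  list(stack = image_stack(ch, cfg$pixel_size), truth = truth,
       artifacts = artifacts)
}

place_extra_centers <- function(n, existing, shape, margin, spacing) {
  pos <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < n * 400L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, shape[1L] - margin),
              stats::runif(1, margin, shape[2L] - margin))
    all_pts <- rbind(existing, pos[seq_len(placed), , drop = FALSE])
    if (is.null(all_pts) || nrow(all_pts) == 0L ||
        min((all_pts[, 1L] - cand[1L])^2 +
            (all_pts[, 2L] - cand[2L])^2) >= spacing^2) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  if (placed < n) {
    abort(sprintf("could only place %d of %d ring artefacts.", placed, n))
  }
  pos
}

#' Generate a synthetic multi-channel fluorescence scene with ground truth
#'
#' Renders the four channels (`nuclear`, `wfa`, `comparison`, `pv`)
#' described by a [scene_config()] and returns them together with the
#' per-cell ground truth.  With a fixed `seed` in the configuration the
#' output is bit-identical across calls.
#'
#' @param config A [scene_config()].
#' @return An object of class `pnn_scene`: a list with elements `stack`
#'   (an [image_stack()]), `truth` (tibble, one row per cell, including the
#'   realized noiseless mean ring intensity per channel), `artifacts`
#'   (tibble of nucleus-free ring artefacts, or `NULL`) and `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  run <- function() {
    truth <- draw_truth(config)
    out <- render_scene(truth, config)
    structure(list(stack = out$stack, truth = out$truth,
                   artifacts = out$artifacts, config = config),
              class = "pnn_scene")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

#' @export
print.pnn_scene <- function(x, ...) {
  cat(sprintf("<pnn_scene> %d cells (%d with PNN)\n", nrow(x$truth),
              sum(x$truth$has_pnn)))
  print(x$stack)
  invisible(x)
}

#' True (geometric) ring mask of a ground-truth cell
#'
#' @param scene A `pnn_scene`.
#' @param cell_id Cell identifier in the truth table.
#' @return Integer vector of linear (column-major) pixel indices of the
#'   annulus `pnn_radius +/- pnn_thickness`.
#' @export
true_ring_mask <- function(scene, cell_id) {
  stopifnot(inherits(scene, "pnn_scene"))
  cell <- scene$truth[scene$truth$cell_id == cell_id, ]
  if (nrow(cell) != 1L || !cell$has_pnn) {
    abort("cell_id not found or cell has no PNN.")
  }
  annulus_indices(c(cell$row, cell$col) + 1, cell$pnn_radius,
                  cell$pnn_thickness, dim(scene$stack))
}

#' Write / read the ground-truth cell table
#'
#' Plain CSV with a header, one row per cell, stable column order,
#' round-trippable at full precision.
#'
#' @param truth A truth tibble (or a `pnn_scene`, whose `$truth` is used).
#' @param path CSV path.
#' @return `path` invisibly; [read_ground_truth()] returns the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  if (inherits(truth, "pnn_scene")) truth <- truth$truth
  stopifnot(is.data.frame(truth))
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(c("cell_id", "n_puncta"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
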