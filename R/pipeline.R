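#' Detection and classification parameters for a pipeline run
#'
#' One place for every tunable of the per-image pipeline, with the package
#' defaults.  Any entry can be overridden by name.
#'
#' @param ... Named overrides, e.g. `pnn_params(r_max = 22, k_surface = 2)`.
#' @return A named list of class `pnn_params`.
#' @export
pnn_params <- function(...) {
  p <- list(
    # nucleus detection
    nucleus_channel = "nuclear", nucleus_sigma = 2, nucleus_k = 4,
    nucleus_level_fraction = 0.5, nucleus_area_range = c(20, 2000),
    # ring detection
    wfa_channel = "wfa", r_min = 8, r_max = 30, score_threshold = 0.35,
    nms_spacing = NULL, ring_sigma = 1, fg_k = 3,
    # gating + segmentation
    gate_factor = 1.0, half_width = 2, bg_shell = c(2, 6), bg_k = 2,
    # classification
    comparison_channel = "comparison", k_surface = 3, k_puncta = 6,
    puncta_min_spacing = 3, puncta_min_count = 3)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) {
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }
  p[names(over)] <- over
  structure(p, class = c("pnn_params", "list"))
}

#' Run the per-image PNN pipeline: detect, gate, segment
#'
#' The detection procedure: find circular candidates in the WFA channel,
#' keep those enclosing a detected nucleus, then segment each ring's
#' WFA-positive area.
#'
#' @param stack An [image_stack()].
#' @param params A [pnn_params()] list.
#' @param quiet Suppress segmentation drop messages.
#' @return List with `nuclei`, `candidates`, `pnns` (segmented) and
#'   `counts` (objects surviving each stage).
#' @export
detect_pnns <- function(stack, params = pnn_params(), quiet = TRUE) {
  nuclei <- detect_nuclei(stack, channel = params$nucleus_channel,
                          smooth_sigma = params$nucleus_sigma,
                          k = params$nucleus_k,
                          level_fraction = params$nucleus_level_fraction,
                          area_range = params$nucleus_area_range)
  cand <- detect_rings(stack, channel = params$wfa_channel,
                       r_min = params$r_min, r_max = params$r_max,
                       score_threshold = params$score_threshold,
                       nms_spacing = params$nms_spacing,
                       smooth_sigma = params$ring_sigma, fg_k = params$fg_k)
  validated <- validate_rings(cand, nuclei, gate_factor = params$gate_factor)
  pnns <- segment_rings(stack, validated, channel = params$wfa_channel,
                        half_width = params$half_width,
                        bg_shell = params$bg_shell, bg_k = params$bg_k,
                        quiet = quiet)
  list(nuclei = nuclei, candidates = cand, pnns = pnns,
       counts = c(nuclei = nrow(nuclei), candidates = nrow(cand),
                  validated = nrow(validated), segmented = nrow(pnns)))
}

normalize_inputs <- function(inputs) {
  if (inherits(inputs, c("image_stack", "pnn_scene"))) inputs <- list(inputs)
  purrr::imap(inputs, function(x, i) {
    if (is.character(x)) {
      if (!file.exists(x)) abort(sprintf("input image not found: %s", x))
      list(stack = read_stack(x), id = x)
    } else if (inherits(x, "pnn_scene")) {
      list(stack = x$stack, id = paste0("scene_", i))
    } else if (inherits(x, "image_stack")) {
      list(stack = x, id = paste0("image_", i))
    } else {
      abort("inputs must be paths, image_stack or pnn_scene objects.")
    }
  })
}

run_stage <- function(stage, image_id, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed on input '%s': %s", stage, image_id,
                  conditionMessage(e)))
  })
}

#' End-to-end colocalization run over a set of images
#'
#' For every input image: detect nuclei and rings, gate, segment, measure
#' all channels, phenotype each PNN cell.  Records are pooled across
#' images; the pooled per-PNN intensity pairs give one Spearman
#' colocalization coefficient (mirroring an analysis that pools objects
#' over several animals), and the pooled phenotypes give the census.
#'
#' @param inputs A list of [image_stack()]s, `pnn_scene`s or TIFF paths.
#' @param params A [pnn_params()] list.
#' @param channel_a,channel_b Channels for the colocalization coefficient.
#' @param out_dir When given, writes `measurements.csv`, `phenotypes.csv`,
#'   `census.json`, `colocalization.json` and `run_log.json` there.
#' @param seed Recorded in the run log (the pipeline itself is
#'   deterministic; a seed only matters for simulated inputs).
#' @return A report list: `records`, `phenotypes`, `census`, `coloc`,
#'   `counts`, `params`.
#' @export
run_coloc <- function(inputs, params = pnn_params(), channel_a = "wfa",
                      channel_b = "comparison", out_dir = NULL,
                      seed = NULL) {
  items <- normalize_inputs(inputs)
  records <- list()
  phenos <- list()
  counts <- list()
  for (it in items) {
    det <- run_stage("detection", it$id, detect_pnns(it$stack, params))
    counts[[it$id]] <- det$counts
    if (nrow(det$pnns) == 0L) next
    rec <- run_stage("measurement", it$id,
                     measure_pnns(it$stack, det$pnns, image_id = it$id))
    ph <- run_stage("classification", it$id,
                    phenotype_cells(it$stack, det$pnns, det$nuclei,
                                    records = rec,
                                    channel = params$comparison_channel,
                                    k_surface = params$k_surface,
                                    k_puncta = params$k_puncta,
                                    min_count = params$puncta_min_count,
                                    min_spacing = params$puncta_min_spacing))
    ph$image_id <- it$id
    records[[it$id]] <- rec
    phenos[[it$id]] <- ph
  }
  records <- dplyr::bind_rows(records)
  phenos <- dplyr::bind_rows(phenos)
  cens <- if (nrow(phenos)) census(phenos) else NULL
  coloc <- if (nrow(records) >= 3L) {
    colocalize(records, channel_a, channel_b)
  }
  report <- list(records = records, phenotypes = phenos, census = cens,
                 coloc = coloc, counts = counts, params = unclass(params),
                 seed = seed)
  if (!is.null(out_dir)) write_coloc_report(report, out_dir)
  report
}

write_coloc_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_measurements(report$records, file.path(out_dir, "measurements.csv"))
  readr::write_csv(drop_list_columns(report$phenotypes),
                   file.path(out_dir, "phenotypes.csv"))
  cens <- if (is.null(report$census)) {
    list(n_pnn_cells = 0L, note = "no objects")
  } else unclass(report$census)
  jsonlite::write_json(cens, file.path(out_dir, "census.json"),
                       auto_unbox = TRUE, digits = NA)
  col <- if (is.null(report$coloc)) {
    list(note = "fewer than 3 objects; no coefficient")
  } else {
    list(rho = report$coloc$rho, n = report$coloc$n,
         channel_pair = report$coloc$channel_pair, grouping = "pooled")
  }
  jsonlite::write_json(col, file.path(out_dir, "colocalization.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(params = report$params, seed = report$seed, counts = report$counts),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Culture-side run: density, size, intensity and group comparisons
#'
#' @param manifest A data frame with columns `condition`, `dish_id` and
#'   either `path` (TIFF file) or a list-column `stack` of
#'   [image_stack()]s / `pnn_scene`s.
#' @param params A [pnn_params()] list.
#' @param control Control condition label (default: first in sort order).
#' @param intensity_channel Channel for the intensity readout.
#' @param pv If `TRUE`, compute the PV-gated PNN fraction per image.
#' @param out_dir When given, writes the dish summary CSV, the relative
#'   measurement CSV and a comparisons JSON there.
#' @return List with `dishes` (per-image summaries), `records` (per-PNN
#'   with relative values), `comparisons` (tibble over readouts).
#' @export
run_culture <- function(manifest, params = pnn_params(), control = NULL,
                        intensity_channel = "wfa", pv = FALSE,
                        out_dir = NULL) {
  stopifnot(is.data.frame(manifest),
            all(c("condition", "dish_id") %in% names(manifest)))
  n_per <- table(manifest$condition)
  if (any(n_per < 2L)) {
    abort(sprintf("condition '%s' has fewer than 2 images.",
                  names(n_per)[which(n_per < 2L)[1L]]))
  }
  control <- control %||% sort(unique(manifest$condition))[1L]
  dishes <- list()
  records <- list()
  for (i in seq_len(nrow(manifest))) {
    x <- if ("stack" %in% names(manifest)) {
      manifest$stack[[i]]
    } else {
      if (!file.exists(manifest$path[i])) {
        abort(sprintf("manifest image not found: %s", manifest$path[i]))
      }
      read_stack(manifest$path[i])
    }
    if (inherits(x, "pnn_scene")) x <- x$stack
    id <- manifest$dish_id[i]
    det <- run_stage("detection", id, detect_pnns(x, params))
    area_mm2 <- prod(dim(x)) * (x$pixel_size / 1000)^2
    pvfrac <- NA_real_
    if (pv) {
      pvfrac <- run_stage("pv_fraction", id,
                          as.numeric(pv_pnn_fraction(stack = x,
                                                     pnns = det$pnns,
                                                     nuclei = det$nuclei)))
    }
    dishes[[i]] <- tibble::tibble(
      dish_id = id, condition = manifest$condition[i],
      pnn_count = nrow(det$pnns), imaged_area_mm2 = area_mm2,
      density_per_50mm2 = density_per_50mm2(nrow(det$pnns), area_mm2),
      pv_pnn_pct = pvfrac)
    if (nrow(det$pnns)) {
      rec <- run_stage("measurement", id,
                       measure_pnns(x, det$pnns, image_id = id))
      rec$condition <- manifest$condition[i]
      rec$dish_id <- id
      records[[i]] <- rec
    }
  }
  dishes <- dplyr::bind_rows(dishes)
  records <- dplyr::bind_rows(records)
  if (nrow(records)) {
    records <- pnn_size_intensity(records, control = control,
                                  intensity_channel = intensity_channel)
  }
  comparisons <- culture_comparisons(dishes, records, control,
                                     intensity_channel, pv)
  out <- list(dishes = dishes, records = records, comparisons = comparisons,
              control = control)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(dishes, file.path(out_dir, "dish_summary.csv"))
    readr::write_csv(drop_list_columns(records),
                     file.path(out_dir, "pnn_records.csv"))
    jsonlite::write_json(comparisons, file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

culture_comparisons <- function(dishes, records, control,
                                intensity_channel, pv) {
  conditions <- sort(unique(dishes$condition))
  treated <- setdiff(conditions, control)
  if (length(treated) != 1L || !nrow(records)) return(tibble::tibble())
  ctrl_rec <- records[records$condition == control, ]
  trt_rec <- records[records$condition == treated, ]
  one <- function(readout, a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    cmp <- compare_groups(a, b, test = "t")
    tibble::tibble(readout = readout, statistic = cmp$statistic,
                   p_value = cmp$p_value,
                   effect_direction = cmp$effect_direction,
                   mean_control = unname(cmp$group_means[1L]),
                   mean_treated = unname(cmp$group_means[2L]),
                   n_control = length(a), n_treated = length(b))
  }
  rows <- list(
    one("density_per_50mm2",
        dishes$density_per_50mm2[dishes$condition == control],
        dishes$density_per_50mm2[dishes$condition == treated]),
    one("relative_area", ctrl_rec$relative_area, trt_rec$relative_area),
    one("relative_intensity", ctrl_rec$relative_intensity,
        trt_rec$relative_intensity))
  if (pv) {
    rows <- c(rows, list(
      one("pv_pnn_pct", dishes$pv_pnn_pct[dishes$condition == control],
          dishes$pv_pnn_pct[dishes$condition == treated])))
  }
  dplyr::bind_rows(rows)
}

#' Parameter-recovery experiment for the colocalization coefficient
#'
#' Generates synthetic scenes in which every cell bears a surface-positive
#' PNN with a known rank coupling between the WFA and comparison ring
#' levels, runs the full pipeline, and reports the recovered pooled
#' Spearman coefficient.
#'
#' @param coupling_rho Ground-truth population Spearman coupling.
#' @param n_images Number of scenes.
#' @param n_cells Cells per scene.
#' @param image_shape Scene size in pixels.
#' @param seed Base seed; scene `i` uses `seed + i`.
#' @param params A [pnn_params()] list.
#' @return List: `rho` (recovered), `n` (pooled PNNs), `coloc`, `records`.
#' @export
recover_coloc <- function(coupling_rho = 0.816, n_images = 6, n_cells = 90,
                          image_shape = c(1024L, 1024L), seed = 1L,
                          params = pnn_params()) {
  scenes <- lapply(seq_len(n_images), function(i) {
    simulate_scene(scene_config(
      image_shape = image_shape, n_cells = n_cells, frac_pnn = 1,
      frac_surface_positive = 1, frac_intracellular = 0.29,
      coupling_rho = coupling_rho, seed = seed + i))
  })
  report <- run_coloc(scenes, params = params)
  list(rho = report$coloc$rho, n = report$coloc$n, coloc = report$coloc,
       records = report$records)
}

#' Parameter-recovery experiment for the phenotype census
#'
#' Exact-count scenes of PNN-bearing cells at configured surface-positive
#' and intracellular-punctate fractions; the pipeline census is compared
#' against those settings.
#'
#' @param frac_surface_positive,frac_intracellular Ground-truth fractions.
#' @param n_images Number of scenes.
#' @param n_cells Cells per scene (all PNN-bearing).
#' @param image_shape Scene size in pixels.
#' @param seed Base seed.
#' @param params A [pnn_params()] list.
#' @return List: `census` (`pnn_census`), `phenotypes`, `n`.
#' @export
recover_census <- function(frac_surface_positive = 0.66,
                           frac_intracellular = 0.29, n_images = 10,
                           n_cells = 100, image_shape = c(1024L, 1024L),
                           seed = 1L, params = pnn_params()) {
  scenes <- lapply(seq_len(n_images), function(i) {
    simulate_scene(scene_config(
      image_shape = image_shape, n_cells = n_cells, frac_pnn = 1,
      frac_surface_positive = frac_surface_positive,
      frac_intracellular = frac_intracellular, exact_counts = TRUE,
      seed = seed + i))
  })
  report <- run_coloc(scenes, params = params)
  list(census = report$census, phenotypes = report$phenotypes,
       n = report$census$n_pnn_cells)
}
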