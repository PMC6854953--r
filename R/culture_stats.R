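#' PNN density scaled to a 50 mm^2 reference area
#'
#' @param pnn_count Number of validated PNNs counted.
#' @param imaged_area_mm2 Imaged area in mm^2 (must be positive).
#' @return PNNs per 50 mm^2 (linear in count, inversely linear in area).
#' @export
density_per_50mm2 <- function(pnn_count, imaged_area_mm2) {
  if (any(!is.finite(imaged_area_mm2)) || any(imaged_area_mm2 <= 0)) {
    abort("`imaged_area_mm2` must be positive.")
  }
  if (any(pnn_count < 0)) abort("`pnn_count` must be >= 0.")
  pnn_count * 50 / imaged_area_mm2
}

#' Values relative to the control-group mean
#'
#' The "relative" size and intensity convention: every measurement is
#' divided by the mean of the control group, so the control group has mean
#' 1 by construction.
#'
#' @param values Numeric vector to normalize.
#' @param reference Numeric vector of control-group values.
#' @return `values / mean(reference)`.
#' @export
relative_to_control <- function(values, reference) {
  m <- mean(reference)
  if (!is.finite(m) || m == 0) abort("control mean is zero or undefined.")
  values / m
}

#' Per-PNN size and intensity, normalized to the control group
#'
#' @param records Measurement tibble (from [measure_pnns()], possibly
#'   row-bound over images) with a `condition` column.
#' @param control Label of the control condition (default: first condition
#'   in the data, in factor/sort order).
#' @param intensity_channel Channel whose mean is the intensity readout.
#' @return `records` with added `relative_area` and `relative_intensity`.
#' @export
pnn_size_intensity <- function(records, control = NULL,
                               intensity_channel = "wfa") {
  if (!"condition" %in% names(records)) {
    abort("records need a `condition` column.")
  }
  col <- paste0("mean_", intensity_channel)
  control <- control %||% sort(unique(records$condition))[1L]
  ctrl <- records[records$condition == control, ]
  if (!nrow(ctrl)) abort(sprintf("no records for control '%s'.", control))
  records$relative_area <- relative_to_control(records$area_um2,
                                               ctrl$area_um2)
  records$relative_intensity <- relative_to_control(records[[col]],
                                                    ctrl[[col]])
  records
}

#' Identify parvalbumin-positive cells among detected nuclei
#'
#' A nucleus is PV-positive when the mean parvalbumin intensity of a soma
#' disc around its centroid exceeds the image background by `k` SD — the
#' same robust-threshold logic the nucleus detector uses.
#'
#' @param stack An [image_stack()] with a `pv` channel.
#' @param nuclei Nuclei from [detect_nuclei()].
#' @param channel PV channel name.
#' @param soma_offset Soma disc radius = nucleus equivalent radius +
#'   `soma_offset` pixels.
#' @param k Threshold in background SD units.
#' @return `nuclei` with added `pv_mean` and `is_pv` columns.
#' @export
pv_positive_cells <- function(stack, nuclei, channel = "pv", soma_offset = 4,
                              k = 3) {
  img <- get_channel(stack, channel)
  shape <- dim(img)
  excl <- rep(FALSE, length(img))
  for (i in seq_len(nrow(nuclei))) {
    excl[disc_indices(c(nuclei$row[i], nuclei$col[i]) + 1,
                      nuclei$equivalent_radius[i] + soma_offset + 2,
                      shape)] <- TRUE
  }
  bg_px <- img[!excl]
  bg_mean <- mean(bg_px); bg_sd <- stats::sd(bg_px)
  nuclei$pv_mean <- vapply(seq_len(nrow(nuclei)), function(i) {
    idx <- disc_indices(c(nuclei$row[i], nuclei$col[i]) + 1,
                        nuclei$equivalent_radius[i] + soma_offset, shape)
    mean(img[idx])
  }, numeric(1))
  nuclei$is_pv <- nuclei$pv_mean > bg_mean + k * bg_sd
  nuclei
}

#' Fraction of PV interneurons that carry a PNN
#'
#' Either supply the counts directly, or a stack plus detection results:
#' PV cells are identified with [pv_positive_cells()] and a PV cell "has a
#' PNN" when a validated PNN object is linked to its nucleus.
#'
#' @param pv_count,pv_with_pnn_count Direct counts (scalar integers).
#' @param stack,pnns,nuclei Image-based inputs (used when counts are
#'   missing).
#' @param ... Passed to [pv_positive_cells()].
#' @return Percentage in `[0, 100]`, with counts attached as attributes.
#' @export
pv_pnn_fraction <- function(pv_count = NULL, pv_with_pnn_count = NULL,
                            stack = NULL, pnns = NULL, nuclei = NULL, ...) {
  if (is.null(pv_count)) {
    if (is.null(stack) || is.null(pnns) || is.null(nuclei)) {
      abort("supply counts, or stack + pnns + nuclei.")
    }
    nuc <- pv_positive_cells(stack, nuclei, ...)
    pv_count <- sum(nuc$is_pv)
    pv_with_pnn_count <- sum(nuc$is_pv &
                               nuc$nucleus_id %in% pnns$nucleus_id)
  }
  if (pv_count <= 0) abort("no PV cells: fraction undefined.")
  if (pv_with_pnn_count > pv_count) {
    abort("pv_with_pnn_count exceeds pv_count.")
  }
  structure(100 * pv_with_pnn_count / pv_count,
            pv_count = pv_count, pv_with_pnn_count = pv_with_pnn_count)
}

#' Two-group comparison (Student's t or one-way ANOVA)
#'
#' Classic pooled-variance two-sample t-test, or a one-way ANOVA when more
#' than two groups are supplied as a list.  Degenerate input (all values
#' identical across groups) yields statistic 0 and p = 1 with a flag
#' rather than an error.
#'
#' @param values_a Control-group values, or a named list of >= 2 groups
#'   (then `values_b` is ignored and ANOVA may compare several groups).
#' @param values_b Second-group values.
#' @param test `"t"` (pooled-variance Student's t) or `"anova"` (one-way
#'   F).  `"welch"` gives the unequal-variance t as an option.
#' @param alpha Significance level used only for the printed summary.
#' @return An object of class `group_comparison` with `test_name`,
#'   `statistic`, `p_value`, `group_means`, `group_ns`,
#'   `effect_direction` (`"increase"`/`"decrease"`/`"none"`, group B
#'   relative to group A) and `degenerate` flag.
#' @export
compare_groups <- function(values_a, values_b = NULL,
                           test = c("t", "anova", "welch"), alpha = 0.05) {
  test <- match.arg(test)
  groups <- if (is.list(values_a)) values_a else list(a = values_a,
                                                      b = values_b)
  if (length(groups) < 2L) abort("need at least two groups.")
  ns <- lengths(groups)
  if (any(ns < 2L)) abort("every group needs at least 2 observations.")
  means <- vapply(groups, mean, numeric(1))
  direction <- if (length(groups) == 2L) {
    d <- means[2L] - means[1L]
    if (d == 0) "none" else if (d > 0) "increase" else "decrease"
  } else "none"
  pooled_var <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                           numeric(1))) / (sum(ns) - length(groups))
  degenerate <- pooled_var == 0
  if (test %in% c("t", "welch")) {
    if (length(groups) != 2L) abort("the t-test needs exactly two groups.")
    if (degenerate) {
      stat <- if (means[1L] == means[2L]) 0 else Inf * sign(means[2L] - means[1L])
      p <- if (means[1L] == means[2L]) 1 else 0
    } else {
      ht <- stats::t.test(groups[[2L]], groups[[1L]],
                          var.equal = test == "t")
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    name <- if (test == "t") "two-sample t (pooled variance)" else "Welch t"
  } else {
    if (degenerate && length(unique(means)) == 1L) {
      stat <- 0; p <- 1
    } else {
      df <- data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups) %||% seq_along(groups), ns)))
      ht <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    name <- "one-way ANOVA"
  }
  structure(list(test_name = name, statistic = stat, p_value = p,
                 group_means = means, group_ns = ns,
                 effect_direction = direction, degenerate = degenerate,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (%s)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$p_value < x$alpha) "significant" else "not significant"))
  cat("  group means:", paste(sprintf("%.4g", x$group_means), collapse = ", "),
      " (n =", paste(x$group_ns, collapse = ", "), ")\n")
  if (x$degenerate) cat("  note: zero pooled variance (degenerate input)\n")
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, effect_direction = x$effect_direction,
                 degenerate = x$degenerate)
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' Enzyme-treatment effect on relative ring intensities
#'
#' Compares control and treated per-PNN intensity records channel by
#' channel, after normalizing both groups to the control mean (the
#' "relative intensity" convention).  Reports the test, direction and
#' significance per channel — the readout for enzymatic PNN digestion,
#' which should reduce both the WFA and the bound comparison-channel
#' signal.
#'
#' @param control_records,treated_records Measurement tibbles carrying
#'   `mean_<channel>` columns.
#' @param channels Channels to compare.
#' @param test Passed to [compare_groups()].
#' @param alpha Significance level.
#' @return A tibble with one row per channel: relative means, statistic,
#'   p-value, direction, and `significant`.
#' @export
enzyme_reduction_analysis <- function(control_records, treated_records,
                                      channels = c("wfa", "comparison"),
                                      test = "t", alpha = 0.05) {
  purrr::map_dfr(channels, function(ch) {
    col <- paste0("mean_", ch)
    ctrl <- control_records[[col]]
    trt <- treated_records[[col]]
    rel_ctrl <- relative_to_control(ctrl, ctrl)
    rel_trt <- relative_to_control(trt, ctrl)
    cmp <- compare_groups(rel_ctrl, rel_trt, test = test, alpha = alpha)
    tibble::tibble(
      channel = ch,
      relative_mean_control = mean(rel_ctrl),
      relative_mean_treated = mean(rel_trt),
      n_control = length(ctrl), n_treated = length(trt),
      statistic = cmp$statistic, p_value = cmp$p_value,
      effect_direction = cmp$effect_direction,
      significant = cmp$p_value < alpha)
  })
}
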