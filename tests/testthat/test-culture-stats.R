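test_that("density scales linearly to the 50 mm^2 reference", {
  expect_equal(density_per_50mm2(10, 50), 10)
  expect_equal(density_per_50mm2(5, 25), 10)
  expect_equal(density_per_50mm2(0, 3.7), 0)
  expect_error(density_per_50mm2(5, 0), "positive")
  expect_error(density_per_50mm2(-1, 5), ">= 0")
  # linear in count, inversely linear in area
  withr::with_seed(2, {
    for (rep in 1:20) {
      n <- sample(0:100, 1); a <- runif(1, 0.5, 100); k <- runif(1, 0.1, 5)
      expect_equal(density_per_50mm2(k * n, a), k * density_per_50mm2(n, a))
      expect_equal(density_per_50mm2(n, k * a), density_per_50mm2(n, a) / k)
    }
  })
})

test_that("areas convert by pixel size and control-relative values center at 1", {
  # 200 mask pixels at 0.5 um/px -> 50 um^2
  m <- matrix(0.5, 64, 64)
  st <- image_stack(list(wfa = m), pixel_size = 0.5)
  pnns <- tibble::tibble(pnn_id = 1L, nucleus_id = 1L, row = 31, col = 31,
                         radius = 10, score = 1, ring_mask = list(1:200))
  rec <- measure_pnns(st, pnns)
  expect_equal(rec$area_um2, 50)

  rec2 <- tibble::tibble(condition = rep(c("control", "treated"), each = 5),
                         area_um2 = c(rnorm(5, 100, 5), rnorm(5, 150, 5)),
                         mean_wfa = runif(10, 0.4, 0.6))
  out <- pnn_size_intensity(rec2, control = "control")
  expect_equal(mean(out$relative_area[out$condition == "control"]), 1)
  expect_equal(mean(out$relative_intensity[out$condition == "control"]), 1)
  expect_error(relative_to_control(1:3, c(0, 0)), "zero")
})

test_that("treated scenes with 1.3x ring radius recover the generative area ratio", {
  rel <- truth_ratio <- c()
  for (s in 1:3) {
    ctrl <- simulate_scene(scene_config(n_cells = 12, frac_pnn = 1,
                                        seed = 600 + s))
    trt <- simulate_scene(scene_config(
      n_cells = 12, frac_pnn = 1,
      pnn_radius_range = 1.3 * c(14, 20),
      min_center_spacing = 2 * (1.3 * 20 + 2) + 2,
      image_shape = c(640L, 640L), seed = 700 + s))
    rc <- run_coloc(list(ctrl, trt))$records
    rc$condition <- ifelse(rc$image_id == "scene_1", "control", "treated")
    out <- pnn_size_intensity(rc, control = "control")
    rel <- c(rel, mean(out$relative_area[out$condition == "treated"]))
    truth_ratio <- c(truth_ratio,
                     mean(vapply(trt$truth$cell_id, function(id)
                       length(true_ring_mask(trt, id)), numeric(1))) /
                       mean(vapply(ctrl$truth$cell_id, function(id)
                         length(true_ring_mask(ctrl, id)), numeric(1))))
  }
  expect_lt(abs(mean(rel) / mean(truth_ratio) - 1), 0.10)
})

test_that("PV-gated PNN fractions come out right from counts and from images", {
  expect_equal(as.numeric(pv_pnn_fraction(10, 3)), 30)
  expect_error(pv_pnn_fraction(0, 0), "no PV cells")
  expect_error(pv_pnn_fraction(5, 7), "exceeds")

  sc <- simulate_scene(scene_config(
    image_shape = c(1024L, 1024L), n_cells = 60, frac_pv = 0.5,
    frac_pnn = 0.2, frac_pnn_given_pv = 0.4, exact_counts = TRUE,
    seed = 83))
  det <- detect_pnns(sc$stack)
  got <- pv_pnn_fraction(stack = sc$stack, pnns = det$pnns,
                         nuclei = det$nuclei)
  truth_pct <- 100 * sum(sc$truth$is_pv & sc$truth$has_pnn) /
    sum(sc$truth$is_pv)
  expect_equal(truth_pct, 40)
  expect_lt(abs(as.numeric(got) - truth_pct), 5)

  no_pv <- image_stack(list(nuclear = matrix(0.1, 32, 32)))
  expect_error(pv_pnn_fraction(stack = no_pv, pnns = det$pnns,
                               nuclei = det$nuclei), "unknown")
})

test_that("t and F statistics match hand-evaluated closed forms", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_groups(a, b, test = "t")
  # pooled-variance Student's t evaluated from the textbook formula
  sp2 <- (sum((a - 2)^2) + sum((b - 5)^2)) / 4
  t_hand <- (5 - 2) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  expect_equal(res$effect_direction, "increase")

  g <- list(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 7, 9))
  resf <- compare_groups(g, test = "anova")
  gm <- mean(unlist(g))
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(resf$statistic, f_hand, tolerance = 1e-10)
  expect_equal(resf$p_value, stats::pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("degenerate and identical groups are handled explicitly", {
  res <- compare_groups(c(2, 2, 2), c(2, 2, 2), test = "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$effect_direction, "none")
  expect_true(res$degenerate)

  shifted <- compare_groups(c(2, 2, 2), c(3, 3, 3), test = "t")
  expect_true(is.infinite(shifted$statistic))
  expect_equal(shifted$p_value, 0)

  expect_error(compare_groups(1, 1:5), "at least 2")
  expect_error(compare_groups(list(a = 1:3)), "two groups")
})

test_that("the pooled t-test is calibrated under the null and at a 1-SD shift", {
  n <- 20L
  reps <- 5000L
  res <- withr::with_seed(555, {
    p_null <- vapply(seq_len(reps), function(i) {
      compare_groups(rnorm(n), rnorm(n), test = "t")$p_value
    }, numeric(1))
    p_alt <- vapply(seq_len(reps), function(i) {
      compare_groups(rnorm(n), rnorm(n, mean = 1), test = "t")$p_value
    }, numeric(1))
    list(null = mean(p_null < 0.05), power = mean(p_alt < 0.05))
  })
  expect_lt(abs(res$null - 0.05), 0.015)
  # closed-form power of the two-sided pooled t at delta = 1 SD
  ncp <- 1 / sqrt(2 / n)
  crit <- stats::qt(0.975, df = 2 * n - 2)
  power <- 1 - stats::pt(crit, df = 2 * n - 2, ncp = ncp) +
    stats::pt(-crit, df = 2 * n - 2, ncp = ncp)
  expect_lt(abs(res$power - power), 0.05)
})

test_that("enzyme reduction analysis flags the scaled channels only", {
  withr::with_seed(31, {
    ctrl <- tibble::tibble(mean_wfa = rnorm(20, 0.55, 0.05),
                           mean_comparison = rnorm(20, 0.5, 0.05))
    both <- tibble::tibble(mean_wfa = 0.3 * rnorm(20, 0.55, 0.05),
                           mean_comparison = 0.3 * rnorm(20, 0.5, 0.05))
    only_cmp <- tibble::tibble(mean_wfa = rnorm(20, 0.55, 0.05),
                               mean_comparison = 0.3 * rnorm(20, 0.5, 0.05))
  })
  res <- enzyme_reduction_analysis(ctrl, both)
  expect_true(all(res$significant))
  expect_true(all(res$effect_direction == "decrease"))
  expect_equal(res$relative_mean_control, c(1, 1))

  res_same <- enzyme_reduction_analysis(ctrl, ctrl)
  expect_false(any(res_same$significant))

  res_one <- enzyme_reduction_analysis(ctrl, only_cmp)
  expect_false(res_one$significant[res_one$channel == "wfa"])
  expect_true(res_one$significant[res_one$channel == "comparison"])
})
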