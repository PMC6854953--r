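test_that("surface score is zero at background level and errors on zero SD", {
  rec <- tibble::tibble(pnn_id = 1L, mean_comparison = 0.05)
  bg <- list(mean = 0.05, sd = 0.01)
  out <- classify_surface(rec, bg)
  expect_equal(out$surface_score, 0)
  expect_false(out$surface_positive)
  expect_error(classify_surface(rec, list(mean = 0.05, sd = 0)), "zero")
  expect_error(classify_surface(tibble::tibble(x = 1), bg), "lack")
})

test_that("rendered surface-positive cells are called positive at default levels", {
  sc <- simulate_scene(scene_config(n_cells = 10, frac_pnn = 1,
                                    frac_surface_positive = 1, seed = 23))
  obj <- truth_objects(sc)
  rec <- measure_pnns(sc$stack, obj$pnns)
  bg <- background_stats(sc$stack, "comparison", obj$pnns, obj$nuclei)
  out <- classify_surface(rec, bg)
  expect_true(all(out$surface_positive))
  expect_true(all(out$surface_score > 3))
})

test_that("a cell with well-separated puncta is counted to within one", {
  st <- noise_stack(shape = c(128L, 128L), seed = 29)
  # soma of radius 24 around (64, 64); 8 puncta on a circle of radius 12
  st$channels$nuclear <- paint_disc(st$channels$nuclear, c(64, 64), 4, 0.6)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  for (k in seq_along(th)) {
    pr <- 64 + 12 * sin(th[k]); pc <- 64 + 12 * cos(th[k])
    rows <- (round(pr) - 3):(round(pr) + 3) + 1
    cols <- (round(pc) - 3):(round(pc) + 3) + 1
    st$channels$comparison[rows, cols] <-
      st$channels$comparison[rows, cols] +
      0.7 * exp(-outer((rows - pr - 1)^2, (cols - pc - 1)^2, `+`) /
                  (2 * 1.3^2))
  }
  nuclei <- detect_nuclei(st)
  pnns <- tibble::tibble(pnn_id = 1L, row = 64, col = 64, radius = 24,
                         score = 1, nucleus_id = nuclei$nucleus_id[1])
  out <- detect_puncta(st, pnns, nuclei)
  expect_gte(out$puncta_count, 7L)
  expect_lte(out$puncta_count, 9L)
  expect_true(out$intracellular_punctate)
})

test_that("clean and surface-only somata are negative for puncta", {
  sc <- simulate_scene(scene_config(n_cells = 12, frac_pnn = 1,
                                    frac_surface_positive = 1,
                                    frac_intracellular = 0, seed = 31))
  obj <- truth_objects(sc)
  out <- detect_puncta(sc$stack, obj$pnns, obj$nuclei)
  expect_true(all(out$puncta_count < 3))
  expect_false(any(out$intracellular_punctate))
})

test_that("phenotype calls match ground truth on exact-count scenes", {
  acc_surface <- acc_intra <- c()
  for (s in 1:6) {
    sc <- simulate_scene(scene_config(
      image_shape = c(900L, 900L), n_cells = 60, frac_pnn = 1,
      frac_surface_positive = 0.66, frac_intracellular = 0.29,
      exact_counts = TRUE, seed = 300 + s))
    obj <- truth_objects(sc)
    ph <- phenotype_cells(sc$stack, obj$pnns, obj$nuclei)
    tr <- obj$truth[match(ph$pnn_id, obj$truth$cell_id), ]
    acc_surface <- c(acc_surface,
                     mean(ph$surface_positive == tr$surface_positive))
    acc_intra <- c(acc_intra,
                   mean(ph$intracellular_punctate ==
                          tr$intracellular_punctate))
  }
  expect_gte(mean(acc_surface), 0.97)
  expect_gte(mean(acc_intra), 0.97)
})

test_that("classification accuracy degrades as noise grows", {
  acc_at <- function(sigma) {
    sc <- simulate_scene(scene_config(
      image_shape = c(700L, 700L), n_cells = 30, frac_pnn = 1,
      frac_surface_positive = 0.5, frac_intracellular = 0.5,
      exact_counts = TRUE, noise_sigma = sigma, seed = 404))
    obj <- truth_objects(sc)
    ph <- phenotype_cells(sc$stack, obj$pnns, obj$nuclei)
    tr <- obj$truth[match(ph$pnn_id, obj$truth$cell_id), ]
    mean(c(ph$surface_positive == tr$surface_positive,
           ph$intracellular_punctate == tr$intracellular_punctate))
  }
  accs <- vapply(c(0.02, 0.15, 0.45), acc_at, numeric(1))
  expect_gte(accs[1], 0.95)
  # monotone degradation (small slack for sampling noise)
  expect_lte(accs[2], accs[1] + 0.02)
  expect_lte(accs[3], accs[2] + 0.02)
  expect_lt(accs[3], 0.9)
})

test_that("the census is an exact function of the boolean labels", {
  ph <- tibble::tibble(
    pnn_id = 1:8,
    surface_positive = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    intracellular_punctate = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                               FALSE, TRUE))
  cs <- census(ph)
  # brute-force counting oracle
  expect_equal(cs$pct_surface_positive, 100 * 6 / 8)
  expect_equal(cs$pct_intracellular, 100 * 3 / 8)
  expect_equal(cs$n_pnn_cells, 8L)
  expect_equal(tidy(cs)$percent, c(75, 37.5))

  all_pos <- tibble::tibble(pnn_id = 1:3, surface_positive = TRUE,
                            intracellular_punctate = TRUE)
  expect_equal(census(all_pos)$pct_surface_positive, 100)
  expect_error(census(ph[0, ]), "empty")
})

test_that("a silent comparison channel yields a zero census", {
  sc <- simulate_scene(scene_config(n_cells = 10, frac_pnn = 1,
                                    frac_surface_positive = 0,
                                    frac_intracellular = 0, seed = 37))
  obj <- truth_objects(sc)
  ph <- phenotype_cells(sc$stack, obj$pnns, obj$nuclei)
  cs <- census(ph)
  expect_equal(cs$pct_surface_positive, 0)
  expect_equal(cs$pct_intracellular, 0)
})
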