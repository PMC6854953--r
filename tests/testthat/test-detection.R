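test_that("a blank nuclear channel yields no nuclei", {
  st <- noise_stack(seed = 5)
  expect_equal(nrow(detect_nuclei(st)), 0L)
})

test_that("a single rendered nucleus is found within 2 px of its center", {
  st <- noise_stack(shape = c(128L, 128L), seed = 6)
  st$channels$nuclear <- paint_disc(st$channels$nuclear, c(64, 64), 4, 0.6)
  nuc <- detect_nuclei(st)
  expect_equal(nrow(nuc), 1L)
  expect_lt(sqrt((nuc$row - 64)^2 + (nuc$col - 64)^2), 2)
  expect_gt(nuc$equivalent_radius, 0)
})

test_that("50 non-overlapping nuclei are matched 1:1 within 3 px", {
  sc <- simulate_scene(scene_config(image_shape = c(900L, 900L),
                                    n_cells = 50, frac_pnn = 0, seed = 31))
  nuc <- detect_nuclei(sc$stack)
  expect_equal(nrow(nuc), 50L)
  used <- rep(FALSE, 50L)
  for (i in seq_len(nrow(nuc))) {
    d <- sqrt((sc$truth$row - nuc$row[i])^2 + (sc$truth$col - nuc$col[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    expect_false(used[j])
    used[j] <- TRUE
  }
  # output ordering contract: by centroid row, then col
  expect_equal(order(nuc$row, nuc$col), seq_len(nrow(nuc)))
})

test_that("a noise-only WFA channel yields no ring candidates", {
  st <- noise_stack(seed = 7)
  expect_equal(nrow(detect_rings(st)), 0L)
  expect_error(detect_rings(st, r_min = 10, r_max = 10), "smaller")
})

test_that("a single planted annulus is recovered within 2 px", {
  st <- noise_stack(shape = c(200L, 200L), seed = 8)
  st$channels$wfa <- paint_annulus(st$channels$wfa, c(100, 100), 12,
                                   half_width = 2, value = 0.6)
  cand <- detect_rings(st)
  expect_equal(nrow(cand), 1L)
  expect_lt(sqrt((cand$row - 100)^2 + (cand$col - 100)^2), 2)
  expect_lt(abs(cand$radius - 12), 2)
})

test_that("20 planted annuli are matched 1:1 within 3 px", {
  sc <- simulate_scene(scene_config(image_shape = c(700L, 700L),
                                    n_cells = 20, frac_pnn = 1, seed = 41))
  cand <- detect_rings(sc$stack)
  m <- match_detections(cand, sc$truth)
  expect_equal(m$tp, 20L)
  expect_equal(m$recall, 1.0)
})

test_that("the nucleus gate keeps exactly the candidates around a cell", {
  cand <- tibble::tibble(row = c(50, 150), col = c(50, 150),
                         radius = c(15, 15), score = c(1, 0.9))
  nuclei <- tibble::tibble(nucleus_id = 1L, row = 52, col = 51,
                           area = 50L, equivalent_radius = 4,
                           mask = list(integer(0)))
  kept <- validate_rings(cand, nuclei)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$nucleus_id, 1L)
  expect_equal(kept$row, 50)

  # no nucleus inside any circle: all rejected
  far <- tibble::tibble(nucleus_id = 1L, row = 120, col = 120, area = 50L,
                        equivalent_radius = 4, mask = list(integer(0)))
  expect_equal(nrow(validate_rings(cand, far)), 0L)
  # nucleus within the second circle only
  near2 <- tibble::tibble(nucleus_id = 1L, row = 145, col = 148, area = 50L,
                          equivalent_radius = 4, mask = list(integer(0)))
  expect_equal(validate_rings(cand, near2)$row, 150)

  # each nucleus backs at most one candidate; gating never adds candidates
  dup <- dplyr::bind_rows(cand[1, ], cand[1, ])
  dup$score <- c(1, 0.5)
  kept2 <- validate_rings(dup, nuclei)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$score, 1)
  expect_lte(nrow(validate_rings(cand, nuclei)), nrow(cand))
})

test_that("nucleus-free ring artefacts are rejected, PNN-bearing cells kept", {
  sc <- simulate_scene(scene_config(
    image_shape = c(1024L, 1024L), n_cells = 30, frac_pnn = 20 / 30,
    exact_counts = TRUE, n_ring_artifacts = 3, seed = 51))
  expect_equal(sum(sc$truth$has_pnn), 20L)
  det <- detect_pnns(sc$stack)
  expect_equal(nrow(det$pnns), 20L)
  m <- match_detections(det$pnns, sc$truth)
  expect_equal(m$tp, 20L)
  # every surviving object satisfies the gate predicate literally
  for (i in seq_len(nrow(det$pnns))) {
    nuc <- det$nuclei[det$nuclei$nucleus_id == det$pnns$nucleus_id[i], ]
    d <- sqrt((nuc$row - det$pnns$row[i])^2 + (nuc$col - det$pnns$col[i])^2)
    expect_lt(d, det$pnns$radius[i])
  }
})

test_that("segmentation of a uniform annulus equals the geometric annulus", {
  st <- noise_stack(shape = c(200L, 200L), sigma = 0, seed = 9)
  st$channels$wfa <- paint_annulus(st$channels$wfa, c(100, 100), 14,
                                   half_width = 2.5, value = 0.5)
  pnns <- tibble::tibble(pnn_id = 1L, row = 100, col = 100, radius = 14,
                         score = 1, nucleus_id = 1L)
  seg <- segment_rings(st, pnns, half_width = 2.5)
  expected <- pnnquant:::annulus_indices(c(101, 101), 14, 2.5, dim(st))
  expect_setequal(seg$ring_mask[[1]], expected)
})

test_that("a zero-signal annulus is dropped with an empty-ring-mask reason", {
  st <- noise_stack(shape = c(200L, 200L), sigma = 0, seed = 10)
  pnns <- tibble::tibble(pnn_id = 1L, row = 100, col = 100, radius = 14,
                         score = 1, nucleus_id = 1L)
  expect_message(seg <- segment_rings(st, pnns, quiet = FALSE),
                 "empty ring mask")
  expect_equal(nrow(seg), 0L)
  expect_match(attr(seg, "dropped"), "empty ring mask")

  # annulus entirely outside the image is an error, not a silent drop
  off <- tibble::tibble(pnn_id = 1L, row = 500, col = 500, radius = 10,
                        score = 1, nucleus_id = 1L)
  expect_error(segment_rings(st, off), "outside")
})

test_that("segmented mask area tracks the true rendered ring area", {
  sc <- simulate_scene(scene_config(n_cells = 12, frac_pnn = 1, seed = 61))
  det <- detect_pnns(sc$stack)
  m <- match_detections(det$pnns, sc$truth)
  expect_gte(m$tp, 11L)
  for (i in which(!is.na(m$match_of))) {
    truth_area <- length(true_ring_mask(sc, m$truth$cell_id[m$match_of[i]]))
    expect_lt(abs(det$pnns$ring_area_px[i] - truth_area) / truth_area, 0.15)
  }
})

test_that("detection is deterministic for identical input", {
  sc <- simulate_scene(scene_config(n_cells = 15, frac_pnn = 1, seed = 71))
  a <- detect_pnns(sc$stack)
  b <- detect_pnns(sc$stack)
  expect_identical(a$pnns, b$pnns)
  expect_identical(a$nuclei, b$nuclei)
})
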