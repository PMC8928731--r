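test_that("three well-separated beads are recovered with sub-pixel accuracy", {
  px <- 4
  spec <- scene_spec(768, 768, px, "brightfield", noise_sd = 0.01, seed = 21)
  beads <- list(bead_spec(160.3, 170.2, 560),
                bead_spec(540.7, 180.4, 624),
                bead_spec(350.2, 560.6, 700))
  out <- render_brightfield_scene(spec, beads)
  det <- detect_beads(out$scene)
  expect_equal(nrow(det), 3)
  m <- beadmetrics:::match_detections(det, out$truth$beads, 3)
  expect_true(all(!is.na(m$truth_row)))
  for (i in seq_len(3)) {
    tr <- out$truth$beads[m$truth_row[i], ]
    expect_lt(abs(det$diameter_um[i] - tr$diameter_um), 2 * px)
  }
})

test_that("a blank scene and an empty edge map yield empty detections", {
  spec <- scene_spec(256, 256, 4, "brightfield", noise_sd = 0.01, seed = 2)
  out <- render_brightfield_scene(spec, list())
  det <- detect_beads(out$scene)
  expect_equal(nrow(det), 0)
  em <- matrix(0L, 128, 128)
  attr(em, "grad_x") <- matrix(0, 128, 128)
  attr(em, "grad_y") <- matrix(0, 128, 128)
  expect_equal(nrow(hough_detect(em, detection_config(), 4)), 0)
})

test_that("concentric rim hypotheses collapse to one detection at the outer radius", {
  # the rim produces two concentric edge rings; suppression plus outer-ring
  # refinement must return exactly one circle at the bead diameter
  out <- single_bead_scene(noise_sd = 0, seed = 3)
  det <- detect_beads(out$scene)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$diameter_um - 650), 8)
})

test_that("detection is invariant to affine intensity rescaling", {
  out <- single_bead_scene(seed = 13)
  s2 <- out$scene
  s2$image <- 0.5 * s2$image + 0.2
  d1 <- detect_beads(out$scene)
  d2 <- detect_beads(s2)
  expect_equal(d1$center_x_px, d2$center_x_px, tolerance = 1e-10)
  expect_equal(d1$radius_px, d2$radius_px, tolerance = 1e-10)
})

test_that("radius band narrower than two steps is rejected", {
  em <- matrix(0L, 64, 64)
  attr(em, "grad_x") <- matrix(0, 64, 64)
  attr(em, "grad_y") <- matrix(0, 64, 64)
  cfg <- detection_config(radius_min_um = 150, radius_max_um = 152,
                          radius_step_px = 2)
  expect_error(hough_detect(em, cfg, 4), "2 radius steps")
})

test_that("satellite flagging is a pure diameter gate preserving order", {
  beads <- data.frame(bead_id = 1:2, center_x_px = c(10, 50),
                      center_y_px = c(10, 50), radius_px = c(15, 80),
                      diameter_um = c(120, 650), accumulator_score = 1,
                      malformed_flag = NA, satellite_flag = NA)
  fl <- flag_satellites(beads, 200)
  expect_equal(fl$satellite_flag, c(TRUE, FALSE))
  expect_equal(fl$bead_id, beads$bead_id)
  expect_equal(nrow(flag_satellites(beads[0, ], 200)), 0)
  expect_true(all(flag_satellites(beads, 1000)$satellite_flag))
})

test_that("perimeter support separates well-formed from gap-rim beads", {
  # perfect noiseless circle: near-full support, not malformed at 0.8
  good <- single_bead_scene(noise_sd = 0, seed = 5)
  dg <- detect_beads(good$scene)
  expect_gte(dg$accumulator_score[1], 0.95)
  expect_false(dg$malformed_flag[1])

  # 120-degree rim gap: support ~2/3, malformed at 0.8
  gap <- single_bead_scene(noise_sd = 0, seed = 6, interior_contrast = 0,
                           rim_gap_arcs = data.frame(start_deg = 40,
                                                     end_deg = 160))
  dm <- detect_beads(gap$scene)
  expect_equal(nrow(dm), 1)
  expect_lte(dm$accumulator_score[1], 0.75)
  expect_true(dm$malformed_flag[1])
})

test_that("seeded multi-bead scenes are detected with high precision and recall", {
  # compact version of the oracle suite (the full 50-scene suite runs in
  # the acceptance tests)
  tp <- fp <- fn <- 0
  errs <- c()
  for (s in 1:6) {
    n <- 1 + (s %% 4)
    pop <- sample_bead_population(n, 650, 40, seed = 100 + s,
                                  field_width_px = 768,
                                  field_height_px = 768)
    sc <- render_scene_set(pop, noise_sd = 0.02, seed = 200 + s)
    for (f in sc) {
      det <- detect_beads(f$scene)
      m <- beadmetrics:::match_detections(det, f$truth$beads, 5)
      matched <- sum(!is.na(m$truth_row))
      tp <- tp + matched
      fp <- fp + nrow(det) - matched
      fn <- fn + nrow(f$truth$beads) - matched
      ok <- !is.na(m$truth_row)
      errs <- c(errs, abs(det$diameter_um[ok] -
                            f$truth$beads$diameter_um[m$truth_row[ok]]))
      # reported centres respect the minimum separation
      if (nrow(det) > 1) {
        D <- sqrt(outer(det$center_x_px, det$center_x_px, "-")^2 +
                    outer(det$center_y_px, det$center_y_px, "-")^2)
        diag(D) <- Inf
        expect_true(all(D * 4 >= 300))
      }
    }
  }
  expect_gte(tp / (tp + fp), 0.95)
  expect_gte(tp / (tp + fn), 0.95)
  expect_lte(mean(errs), 2 * 4)
})
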