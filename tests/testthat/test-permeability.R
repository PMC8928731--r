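test_that("centre intensity reads the linear permeation construction", {
  spec <- scene_spec(256, 256, 4, "fluorescence", noise_sd = 0,
                     background_level = 0.9, seed = 1)
  bead <- bead_spec(127.5, 127.5, 650, permeation_fraction = 0.5)
  o <- render_fluorescence_scene(spec, bead, dark_floor = 0.02)
  db <- beads_from_truth(o$truth)
  expect_equal(center_intensity(o$scene, db[1, ]), 0.46, tolerance = 1e-12)
  # ROI size does not matter on a uniform interior
  expect_lt(abs(center_intensity(o$scene, db[1, ], 0.5) -
                  center_intensity(o$scene, db[1, ], 0.1)), 1e-6)
})

test_that("background intensity uses only the bead-free area", {
  spec <- scene_spec(256, 256, 4, "fluorescence", noise_sd = 0.01,
                     background_level = 0.9, seed = 3)
  # blank scene: global mean
  blank <- render_fluorescence_scene(spec, list())
  expect_equal(background_intensity(blank$scene, blank$truth$beads[0, ]),
               mean(blank$scene$image))
  # one centred bead occupying < 20% of the field
  bead <- bead_spec(127.5, 127.5, 450, permeation_fraction = 0.2)
  o <- render_fluorescence_scene(spec, bead)
  db <- beads_from_truth(o$truth)
  bg <- background_intensity(o$scene, db)
  npix_free <- 256^2 - pi * (1.5 * db$radius_px[1])^2
  expect_lt(abs(bg - 0.9), 3 * 0.01 / sqrt(npix_free))
  # beads covering almost the whole field leave too little background
  big <- db
  big$radius_px <- 500
  expect_error(background_intensity(o$scene, big), "insufficient")
})

test_that("two-anchor normalization maps the ladder linearly with clamping", {
  r <- c("4 kDa" = 0.95, "150 kDa" = 0.50, "2 MDa" = 0.05)
  pct <- normalize_permeation(r)
  expect_equal(unname(pct[c("4 kDa", "150 kDa", "2 MDa")]), c(100, 50, 0))
  # a probe at the 100% anchor ratio maps to exactly 100
  r2 <- c(r, "70 kDa" = 0.95)
  expect_equal(unname(normalize_permeation(r2)[["70 kDa"]]), 100)
  # below the 0% anchor clamps to 0
  r3 <- c(r, "5 MDa" = 0.01)
  expect_equal(unname(normalize_permeation(r3)[["5 MDa"]]), 0)
  # equal or inverted anchors are rejected
  expect_error(normalize_permeation(c("4 kDa" = 0.5, "2 MDa" = 0.5)),
               "inverted")
  expect_error(normalize_permeation(c("4 kDa" = 0.2, "2 MDa" = 0.8)),
               "inverted")
  expect_error(normalize_permeation(c("4 kDa" = 0.9)), "anchor")
})

test_that("normalization is invariant to global linear intensity rescaling", {
  probes <- c("4 kDa" = 1, "150 kDa" = 0.5, "2 MDa" = 0)
  lad <- simulate_permeability_ladder(probes, n_beads = 3, seed = 5,
                                      noise_sd = 0, field_width_px = 512,
                                      field_height_px = 512,
                                      use_truth_positions = TRUE)
  pct1 <- normalize_permeation(lad$mean_ratios)
  # rescaling every scene rescales every ratio's numerator and denominator
  pct2 <- normalize_permeation(lad$mean_ratios * 1.7)
  expect_equal(pct1, pct2, tolerance = 1e-9)
})

test_that("rendered permeation fractions are recovered on the 0-100 scale", {
  probes <- c("4 kDa" = 1, "70 kDa" = 0.75, "150 kDa" = 0.5,
              "500 kDa" = 0.25, "2 MDa" = 0)
  lad <- simulate_permeability_ladder(probes, n_beads = 4, seed = 7,
                                      noise_sd = 0.02, field_width_px = 512,
                                      field_height_px = 512,
                                      use_truth_positions = TRUE)
  pct <- normalize_permeation(lad$mean_ratios)
  expect_true(all(abs(pct - 100 * probes[names(pct)]) <= 5))
})

test_that("estimated ladders preserve the permeation ordering", {
  # strictly decreasing true fractions must give non-increasing estimates
  probes <- c("4 kDa" = 0.95, "70 kDa" = 0.75, "150 kDa" = 0.5,
              "500 kDa" = 0.25, "2 MDa" = 0.05)
  viol <- 0; comps <- 0
  for (s in 1:5) {
    # detection-based at the fluorescence imaging noise default
    lad <- simulate_permeability_ladder(probes, n_beads = 3, seed = 20 + s,
                                        noise_sd = 0.01,
                                        field_width_px = 512,
                                        field_height_px = 512)
    pct <- normalize_permeation(lad$mean_ratios)
    difs <- diff(unname(pct[names(probes)]))
    viol <- viol + sum(difs > 0)
    comps <- comps + length(difs)
    # estimator chain alone at higher noise, beads localized from truth
    lad2 <- simulate_permeability_ladder(probes, n_beads = 3, seed = 40 + s,
                                         noise_sd = 0.02,
                                         field_width_px = 512,
                                         field_height_px = 512,
                                         use_truth_positions = TRUE)
    difs2 <- diff(unname(normalize_permeation(lad2$mean_ratios)[names(probes)]))
    viol <- viol + sum(difs2 > 0)
    comps <- comps + length(difs2)
  }
  expect_lte(viol / comps, 0.01)
})

test_that("group comparison delegates to Welch's test with n >= 2 required", {
  res <- compare_groups_permeability(c(10, 12, 14), c(10, 12, 14))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_two_sided, 1)
  expect_error(compare_groups_permeability(5, c(1, 2)), "n >= 2")
  # separated groups (3 pooled SDs, n = 11) are detected almost always
  hits <- 0
  set.seed(99)
  for (i in 1:500) {
    a <- rnorm(11, 0, 1); b <- rnorm(11, 3, 1)
    if (compare_groups_permeability(a, b)$p_two_sided < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / 500, 0.95)
})
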