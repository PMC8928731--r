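test_that("an empty scene is uniform at the background level", {
  spec <- scene_spec(128, 128, 4, "brightfield", noise_sd = 0.02,
                     background_level = 0.85, seed = 2)
  out <- render_brightfield_scene(spec, list())
  expect_lt(abs(mean(out$scene$image) - 0.85),
            3 * 0.02 / sqrt(128 * 128))
  expect_equal(nrow(out$truth$beads), 0)
})

test_that("bead geometry is rendered at the calibrated scale", {
  spec <- scene_spec(512, 512, 2, "brightfield", noise_sd = 0,
                     background_level = 0.85, seed = 1)
  bead <- bead_spec(255.5, 255.5, 700, rim_contrast = 0.35)
  out <- render_brightfield_scene(spec, bead)
  expect_equal(out$truth$beads$diameter_um / 2 / 2, 175)  # 350 px diameter
  img <- out$scene$image
  # rim pixels darker than background by rim_contrast before noise
  expect_equal(img[256, 256 + 172], 0.85 - 0.35)
  expect_equal(img[256, 256 + 180], 0.85)           # outside
  expect_equal(img[256, 256], 0.85 - 0.1)           # interior
})

test_that("rendering is bit-identical for identical spec and seed", {
  mk <- function() {
    single_bead_scene(seed = 42, spheroids = data.frame(
      offset_x_um = 0, offset_y_um = 50, diameter_um = 150, contrast = 0.25),
      overgrowth_arcs = overgrowth_arc(0.4))
  }
  a <- mk(); b <- mk()
  expect_identical(a$scene$image, b$scene$image)
  expect_identical(a$truth$beads, b$truth$beads)
  c <- single_bead_scene(seed = 43, overgrowth_arcs = overgrowth_arc(0.4))
  expect_false(identical(a$scene$image, c$scene$image))
})

test_that("out-of-bounds and overlapping beads are rejected with the bead index", {
  spec <- scene_spec(256, 256, 4, "brightfield", seed = 1)
  good <- bead_spec(127, 127, 650)
  bad <- bead_spec(10, 127, 650)
  expect_error(render_brightfield_scene(spec, list(good, bad)), "bead 2")
  b2 <- bead_spec(160, 127, 650)
  expect_error(render_brightfield_scene(spec, list(good, b2)),
               "overlap")
})

test_that("fluorescence interiors follow the linear permeation model", {
  # permeation 0.5, noiseless: centre exactly (dark_floor + background)/2
  spec <- scene_spec(256, 256, 4, "fluorescence", noise_sd = 0,
                     background_level = 0.9, seed = 1)
  bead <- bead_spec(127.5, 127.5, 650, permeation_fraction = 0.5)
  out <- render_fluorescence_scene(spec, bead, dark_floor = 0.02)
  expect_equal(out$scene$image[128, 128], (0.02 + 0.9) / 2)

  # permeation 1: interior mean matches exterior mean within noise
  spec2 <- scene_spec(256, 256, 4, "fluorescence", noise_sd = 0.01,
                      background_level = 0.9, seed = 5)
  b1 <- bead_spec(127.5, 127.5, 650, permeation_fraction = 1)
  o1 <- render_fluorescence_scene(spec2, b1)
  db <- beads_from_truth(o1$truth)
  inner <- center_intensity(o1$scene, db[1, ], 0.4)
  outer <- background_intensity(o1$scene, db)
  expect_lt(abs(inner - outer), 3 * 0.01 / sqrt(100))

  # permeation 0: interior at the dark floor
  b0 <- bead_spec(127.5, 127.5, 650, permeation_fraction = 0)
  o0 <- render_fluorescence_scene(spec2, b0)
  d0 <- beads_from_truth(o0$truth)
  expect_lt(abs(center_intensity(o0$scene, d0[1, ]) - 0.02), 0.005)
})

test_that("brightfield intensity ordering holds at zero noise", {
  out <- single_bead_scene(noise_sd = 0, seed = 1,
                           overgrowth_arcs = overgrowth_arc(1))
  img <- out$scene$image
  px <- 4; R <- 650 / 2 / px; rimw <- 20 / px
  ctr <- 127.5
  X <- matrix(0:255, 256, 256, byrow = TRUE) - ctr
  Y <- matrix(0:255, 256, 256) - ctr
  D <- sqrt(X^2 + Y^2)
  band_mean <- mean(img[D > R & D <= R + 40 / px])
  rim_mean <- mean(img[D <= R & D > R - rimw])
  interior_mean <- mean(img[D <= R - rimw])
  bg_mean <- mean(img[D > R + 40 / px + 2])
  expect_true(band_mean < rim_mean)
  expect_true(rim_mean < interior_mean)
  expect_true(interior_mean < bg_mean)
})

test_that("ground-truth coverage equals the summed arc length", {
  set.seed(11)
  for (i in 1:20) {
    n_arc <- sample(1:3, 1)
    starts <- sort(runif(n_arc, 0, 300))
    lens <- runif(n_arc, 1, (360 - max(starts)) / n_arc / 2)
    arcs <- data.frame(start_deg = starts,
                       end_deg = starts + lens,
                       band_width_um = 40, contrast = 0.6)
    b <- bead_spec(127.5, 127.5, 600, overgrowth_arcs = arcs)
    expect_equal(bead_coverage_fraction(b), sum(lens) / 360,
                 tolerance = 1e-9)
  }
})

test_that("sampled populations reproduce the requested diameter law", {
  # degenerate draw
  p1 <- sample_bead_population(1, 700, 0, seed = 1)
  expect_equal(p1[[1]]$diameter_um, 700)
  expect_equal(length(p1), 1L)

  # batch conditions: 699 +/- 17 um
  p200 <- sample_bead_population(200, 699, 17, seed = 3)
  d <- vapply(p200, `[[`, numeric(1), "diameter_um")
  expect_lt(abs(mean(d) - 699), 3 * 17 / sqrt(200))
  expect_true(all(d >= 100 & d <= 1000))

  # spheroid_rate = 0 gives no spheroids
  expect_true(all(vapply(p200, function(b) is.null(b$spheroids),
                         logical(1))))
  # non-overlap within each field
  fields <- vapply(p200, `[[`, integer(1), "field_index")
  px <- attr(p200, "layout")$pixel_size_um
  for (f in unique(fields)) {
    bb <- p200[fields == f]
    if (length(bb) < 2) next
    xs <- vapply(bb, `[[`, numeric(1), "center_x_px")
    ys <- vapply(bb, `[[`, numeric(1), "center_y_px")
    rs <- vapply(bb, `[[`, numeric(1), "diameter_um") / 2
    D <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2) * px
    lim <- outer(rs, rs, "+")
    diag(D) <- Inf
    expect_true(all(D >= lim))
  }
})

test_that("placement failure names the achieved bead count", {
  expect_error(
    sample_bead_population(2, 990, 0, seed = 1, field_width_px = 256,
                           field_height_px = 256, pixel_size_um = 1),
    "placed 0 of 2")
})

test_that("scenes and ground truth round-trip through TIFF and JSON", {
  out <- single_bead_scene(seed = 8)
  td <- withr::local_tempdir()
  img_path <- file.path(td, "scene.tif")
  tr_path <- file.path(td, "scene.json")
  write_scene(out$scene, img_path)
  write_truth(out$truth, tr_path)
  back <- read_scene(img_path, 4, "brightfield")
  expect_equal(dim(back$image), dim(out$scene$image))
  expect_lt(max(abs(back$image - pmin(pmax(out$scene$image, 0), 1))),
            1 / 65535)
  tr <- read_truth(tr_path)
  expect_equal(tr$beads$diameter_um, out$truth$beads$diameter_um)
  expect_equal(tr$seed, out$truth$seed)
})
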