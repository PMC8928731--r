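#' Sample a synthetic microbead population
#'
#' Draws bead diameters from a normal law truncated to [100, 1000] um,
#' spheroid counts from a Poisson law, and non-overlapping bead placements by
#' rejection sampling.  When a field cannot accommodate the next bead within
#' \code{max_attempts} placement attempts, a new field is opened; beads carry
#' a \code{field_index} so the population can be rendered as a set of scenes
#' with [render_scene_set()].
#'
#' @param n Number of beads (>= 1).
#' @param diameter_mean_um,diameter_sd_um Mean and SD of the (untruncated)
#'   diameter law, in micrometres.  \code{diameter_sd_um = 0} gives every
#'   bead exactly the mean diameter.
#' @param spheroid_rate Poisson mean of the number of encapsulated spheroids
#'   per bead.  Spheroid diameters are drawn uniformly in [100, 200] um and
#'   placed uniformly within the bead interior.
#' @param seed Integer RNG seed.
#' @param field_width_px,field_height_px Field dimensions in pixels.
#' @param pixel_size_um Physical calibration of the fields.
#' @param min_gap_um Minimum edge-to-edge gap between beads.
#' @param max_attempts Placement attempts per bead before opening a new
#'   field; failure to place a bead in an empty field is an error naming the
#'   achieved count.
#' @param spheroid_contrast Rendered darkening of spheroids below the bead
#'   interior.
#'
#' @return A list of [bead_spec()] objects, each with an extra
#'   \code{field_index} element; attributes \code{n_fields} and
#'   \code{layout} describe the scene grid.
#' @export
sample_bead_population <- function(n, diameter_mean_um, diameter_sd_um,
                                   spheroid_rate = 0, seed = 1L,
                                   field_width_px = 1024,
                                   field_height_px = 1024,
                                   pixel_size_um = 4, min_gap_um = 60,
                                   max_attempts = 2000,
                                   spheroid_contrast = 0.25) {
  stop_if_not_scalar(n, "n", lower = 1)
  stop_if_not_scalar(diameter_sd_um, "diameter_sd_um", lower = 0)
  stop_if_not_scalar(spheroid_rate, "spheroid_rate", lower = 0)
  n <- as.integer(n)
  lo <- 100; hi <- 1000
  withr::with_seed(as.integer(seed), {
    if (diameter_sd_um == 0) {
      if (diameter_mean_um < lo || diameter_mean_um > hi)
        stop("diameter_mean_um outside the [100, 1000] um generator range")
      diams <- rep(diameter_mean_um, n)
    } else {
      # exact truncated normal via inverse-CDF sampling
      p <- runif(n, pnorm(lo, diameter_mean_um, diameter_sd_um),
                 pnorm(hi, diameter_mean_um, diameter_sd_um))
      diams <- qnorm(p, diameter_mean_um, diameter_sd_um)
    }
    counts <- if (spheroid_rate > 0) rpois(n, spheroid_rate) else integer(n)

    px <- pixel_size_um
    beads <- vector("list", n)
    field <- 1L
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    for (k in seq_len(n)) {
      r_um <- diams[k] / 2
      margin <- r_um / px + 3
      if (2 * margin >= min(field_width_px, field_height_px))
        stop(sprintf("bead too large for the field; placed %d of %d beads",
                     k - 1L, n))
      ok <- FALSE
      attempts_left <- max_attempts
      while (!ok) {
        cx <- runif(1, margin, field_width_px - 1 - margin)
        cy <- runif(1, margin, field_height_px - 1 - margin)
        clear <- !length(placed_x) ||
          all(sqrt((placed_x - cx)^2 + (placed_y - cy)^2) * px >=
                placed_r + r_um + min_gap_um)
        if (clear) {
          ok <- TRUE
        } else {
          attempts_left <- attempts_left - 1
          if (attempts_left == 0) {
            if (!length(placed_x))
              stop(sprintf("placement failed; placed %d of %d beads",
                           k - 1L, n))
            field <- field + 1L
            placed_x <- numeric(0); placed_y <- numeric(0)
            placed_r <- numeric(0)
            attempts_left <- max_attempts
          }
        }
      }
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      placed_r <- c(placed_r, r_um)

      sph <- NULL
      if (counts[k] > 0) {
        r_int <- r_um - 20  # default rim width
        keep <- 0L
        off_x <- off_y <- sdiam <- numeric(0)
        for (s in seq_len(counts[k])) {
          ds <- runif(1, 100, 200)
          max_off <- r_int - ds / 2
          if (max_off <= 0) next
          th <- runif(1, 0, 2 * pi)
          rr <- max_off * sqrt(runif(1))
          off_x <- c(off_x, rr * cos(th)); off_y <- c(off_y, rr * sin(th))
          sdiam <- c(sdiam, ds); keep <- keep + 1L
        }
        counts[k] <- keep
        if (keep > 0)
          sph <- data.frame(offset_x_um = off_x, offset_y_um = off_y,
                            diameter_um = sdiam,
                            contrast = spheroid_contrast)
      }
      b <- bead_spec(cx, cy, diams[k], spheroids = sph)
      b$field_index <- field
      beads[[k]] <- b
    }
  })
  attr(beads, "n_fields") <- field
  attr(beads, "layout") <- list(field_width_px = field_width_px,
                                field_height_px = field_height_px,
                                pixel_size_um = pixel_size_um)
  beads
}

#' Render a sampled bead population as a set of scenes
#'
#' Renders each field of a [sample_bead_population()] result as one scene
#' (brightfield by default) with its ground-truth record.  Scene seeds are
#' derived as \code{seed + field_index} so the whole set is reproducible.
#'
#' @param population Result of [sample_bead_population()].
#' @param modality \code{"brightfield"} or \code{"fluorescence"}.
#' @param noise_sd,background_level Passed to [scene_spec()].
#' @param seed Base seed for the scene renderings.
#' @param ... Passed on to the renderer (e.g. \code{speckle_density}).
#' @return A list with one element per field, each a list with
#'   \code{scene} and \code{truth}.
#' @export
render_scene_set <- function(population, modality = "brightfield",
                             noise_sd = 0.02, background_level = 0.85,
                             seed = 1L, ...) {
  layout <- attr(population, "layout")
  if (is.null(layout)) stop("'population' lacks a layout attribute")
  n_fields <- attr(population, "n_fields")
  fields <- vapply(population, `[[`, integer(1), "field_index")
  lapply(seq_len(n_fields), function(f) {
    spec <- scene_spec(layout$field_width_px, layout$field_height_px,
                       layout$pixel_size_um, modality = modality,
                       noise_sd = noise_sd,
                       background_level = background_level,
                       seed = as.integer(seed) + f)
    beads <- population[fields == f]
    if (modality == "brightfield")
      render_brightfield_scene(spec, beads, ...)
    else
      render_fluorescence_scene(spec, beads, ...)
  })
}
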