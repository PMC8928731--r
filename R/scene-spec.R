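#' Scene specification for synthetic microbead imaging
#'
#' Describes one synthetic microscopy field: its pixel grid, physical
#' calibration, imaging modality and noise model.  Intensities are scalar in
#' \code{[0, 1]}; images are rendered to 16-bit on write.
#'
#' @param image_width_px,image_height_px Image dimensions in pixels (>= 64).
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @param modality Either \code{"brightfield"} or \code{"fluorescence"}.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian pixel noise,
#'   as a fraction of the dynamic range; must be < 0.5.
#' @param background_level Intensity of the bead-free area in \code{[0, 1]}.
#'   In brightfield this is the bright illumination background; in
#'   fluorescence it is the free probe solution.
#' @param seed Integer seed controlling all randomness of the rendering
#'   (speckle texture and pixel noise).
#'
#' @return An object of class \code{"scene_spec"}.
#' @seealso [bead_spec()], [render_brightfield_scene()],
#'   [render_fluorescence_scene()]
#' @export
scene_spec <- function(image_width_px, image_height_px, pixel_size_um,
                       modality = c("brightfield", "fluorescence"),
                       noise_sd = 0.02, background_level = 0.85, seed = 1L) {
  modality <- match.arg(modality)
  stop_if_not_scalar(image_width_px, "image_width_px", lower = 64)
  stop_if_not_scalar(image_height_px, "image_height_px", lower = 64)
  stop_if_not_scalar(pixel_size_um, "pixel_size_um", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_scalar(noise_sd, "noise_sd", lower = 0, upper = 0.5 - 1e-12)
  stop_if_not_scalar(background_level, "background_level", lower = 0, upper = 1)
  stop_if_not_scalar(seed, "seed")
  structure(list(
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    pixel_size_um = pixel_size_um,
    modality = modality,
    noise_sd = noise_sd,
    background_level = background_level,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Specification of a single rendered microbead
#'
#' Geometry and contrast of one alginate microbead.  Coordinates are 0-based
#' pixel positions (x = column, y = row, origin at the top-left pixel centre);
#' all physical quantities are in micrometres.  Sub-pixel centres are allowed;
#' rasterization uses a pixel-centre-in-disk test.
#'
#' @param center_x_px,center_y_px Bead centre in 0-based pixel coordinates.
#' @param diameter_um Bead diameter; the generator accepts 100--1000 um
#'   (the encapsulation process targets beads below 700 um).
#' @param rim_width_um Width of the darker alginate rim annulus.
#' @param rim_contrast Darkening of the rim below the background, in [0, 1].
#' @param interior_contrast Darkening of the bead interior below background.
#' @param spheroids Optional data.frame with one row per encapsulated
#'   cell spheroid: columns \code{offset_x_um}, \code{offset_y_um} (centre
#'   offset from the bead centre), \code{diameter_um} (must lie in
#'   [100, 200]) and \code{contrast} (darkening below the bead interior).
#'   Spheroids must lie wholly inside the bead interior disk.
#' @param permeation_fraction For fluorescence scenes: fraction of the
#'   background (free probe) intensity reached inside the bead, in [0, 1].
#' @param overgrowth_arcs Optional data.frame describing fibrotic overgrowth
#'   as dark textured annular segments outside the rim: columns
#'   \code{start_deg}, \code{end_deg} (angles in [0, 360), measured from the
#'   +x axis toward +y), \code{band_width_um} and \code{contrast}.  Arcs must
#'   not overlap and their summed length must not exceed 360 degrees.
#' @param rim_gap_arcs Optional data.frame with columns \code{start_deg},
#'   \code{end_deg}: angular sectors where the rim is missing (used to build
#'   malformed-bead fixtures).
#'
#' @return An object of class \code{"bead_spec"}.
#' @export
bead_spec <- function(center_x_px, center_y_px, diameter_um,
                      rim_width_um = 20, rim_contrast = 0.35,
                      interior_contrast = 0.1, spheroids = NULL,
                      permeation_fraction = NA_real_,
                      overgrowth_arcs = NULL, rim_gap_arcs = NULL) {
  stop_if_not_scalar(center_x_px, "center_x_px")
  stop_if_not_scalar(center_y_px, "center_y_px")
  stop_if_not_scalar(diameter_um, "diameter_um", lower = 100, upper = 1000)
  stop_if_not_scalar(rim_width_um, "rim_width_um", lower = 0,
                     strict_lower = TRUE)
  stop_if_not_scalar(rim_contrast, "rim_contrast", lower = 0, upper = 1)
  stop_if_not_scalar(interior_contrast, "interior_contrast", lower = 0,
                     upper = 1)
  if (!is.na(permeation_fraction))
    stop_if_not_scalar(permeation_fraction, "permeation_fraction",
                       lower = 0, upper = 1)
  if (!is.null(spheroids) && nrow(spheroids)) {
    need <- c("offset_x_um", "offset_y_um", "diameter_um", "contrast")
    if (!all(need %in% names(spheroids)))
      stop("'spheroids' must have columns ", paste(need, collapse = ", "))
    if (any(spheroids$diameter_um < 100 | spheroids$diameter_um > 200))
      stop("spheroid diameters must lie in [100, 200] um")
    r_int <- diameter_um / 2 - rim_width_um
    reach <- sqrt(spheroids$offset_x_um^2 + spheroids$offset_y_um^2) +
      spheroids$diameter_um / 2
    if (any(reach > r_int + 1e-9))
      stop("spheroids must lie wholly inside the bead interior disk")
  }
  if (!is.null(overgrowth_arcs) && nrow(overgrowth_arcs)) {
    need <- c("start_deg", "end_deg", "band_width_um", "contrast")
    if (!all(need %in% names(overgrowth_arcs)))
      stop("'overgrowth_arcs' must have columns ", paste(need, collapse = ", "))
    lens <- mapply(arc_length_deg, overgrowth_arcs$start_deg,
                   overgrowth_arcs$end_deg)
    if (sum(lens) > 360 + 1e-9)
      stop("summed overgrowth arc length exceeds 360 degrees")
    if (any(overgrowth_arcs$start_deg < 0 | overgrowth_arcs$start_deg >= 360))
      stop("arc start angles must lie in [0, 360)")
  }
  structure(list(
    center_x_px = center_x_px, center_y_px = center_y_px,
    diameter_um = diameter_um, rim_width_um = rim_width_um,
    rim_contrast = rim_contrast, interior_contrast = interior_contrast,
    spheroids = spheroids, permeation_fraction = permeation_fraction,
    overgrowth_arcs = overgrowth_arcs, rim_gap_arcs = rim_gap_arcs
  ), class = "bead_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px @ %.3g um/px, %s, bg %.2f, noise %.3g, seed %d\n",
              x$image_width_px, x$image_height_px, x$pixel_size_um,
              x$modality, x$background_level, x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf("<bead_spec> centre (%.1f, %.1f) px, diameter %.1f um, %d spheroid(s), %d arc(s)\n",
              x$center_x_px, x$center_y_px, x$diameter_um,
              if (is.null(x$spheroids)) 0L else nrow(x$spheroids),
              if (is.null(x$overgrowth_arcs)) 0L else nrow(x$overgrowth_arcs)))
  invisible(x)
}

new_scene <- function(image, spec) {
  structure(list(
    image = image,
    pixel_size_um = spec$pixel_size_um,
    modality = spec$modality,
    background_level = spec$background_level,
    noise_sd = spec$noise_sd,
    seed = spec$seed
  ), class = "bead_scene")
}

#' @export
print.bead_scene <- function(x, ...) {
  cat(sprintf("<bead_scene> %s, %d x %d px @ %.3g um/px\n", x$modality,
              ncol(x$image), nrow(x$image), x$pixel_size_um))
  invisible(x)
}

# Total ground-truth perimeter coverage fraction of a bead spec.
bead_coverage_fraction <- function(bead) {
  if (is.null(bead$overgrowth_arcs) || !nrow(bead$overgrowth_arcs)) return(0)
  sum(mapply(arc_length_deg, bead$overgrowth_arcs$start_deg,
             bead$overgrowth_arcs$end_deg)) / 360
}
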