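#' Per-batch size-distribution statistics
#'
#' Summarizes detected bead diameters: mean, SD (n - 1 denominator), median,
#' and a fixed-width histogram spanning floor(min) to ceiling(max).
#' Satellite and malformed fractions are always computed over the full input
#' list, regardless of whether satellites are excluded from the size
#' statistics.
#'
#' @param beads A \code{"detected_beads"} data.frame (flags may be NA).
#' @param bin_width_um Histogram bin width, default 10 um.
#' @param include_satellites If \code{FALSE} (default), satellite-flagged
#'   beads are excluded from the size statistics.
#' @return A list of class \code{"population_stats"}: \code{n_beads},
#'   \code{mean_diameter_um}, \code{sd_diameter_um},
#'   \code{median_diameter_um}, \code{histogram} (data.frame with
#'   \code{bin_low_um}, \code{bin_high_um}, \code{count}),
#'   \code{satellite_fraction}, \code{malformed_fraction}, and
#'   \code{sd_degenerate} (TRUE when n = 1, where the SD is reported as 0
#'   with a warning).
#' @export
population_stats <- function(beads, bin_width_um = 10,
                             include_satellites = FALSE) {
  stop_if_not_scalar(bin_width_um, "bin_width_um", lower = 0,
                     strict_lower = TRUE)
  n_all <- nrow(beads)
  if (!n_all) stop("no beads supplied")
  sat <- beads$satellite_flag
  mal <- beads$malformed_flag
  satellite_fraction <- if (all(is.na(sat))) NA_real_
                        else mean(sat, na.rm = TRUE)
  malformed_fraction <- if (all(is.na(mal))) NA_real_
                        else mean(mal, na.rm = TRUE)
  d <- beads$diameter_um
  if (!include_satellites && !all(is.na(sat)))
    d <- d[!(sat %in% TRUE)]
  if (!length(d)) stop("no beads remain after satellite exclusion")
  degenerate <- length(d) == 1L
  if (degenerate)
    warning("single bead: SD reported as 0")
  lo <- floor(min(d)); hi <- ceiling(max(d))
  breaks <- seq(lo, lo + bin_width_um * ceiling(max(hi - lo, bin_width_um) /
                                                  bin_width_um),
                by = bin_width_um)
  counts <- as.integer(table(cut(d, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(
    n_beads = length(d),
    mean_diameter_um = mean(d),
    sd_diameter_um = if (degenerate) 0 else sd(d),
    median_diameter_um = median(d),
    histogram = data.frame(bin_low_um = breaks[-length(breaks)],
                           bin_high_um = breaks[-1], count = counts),
    satellite_fraction = satellite_fraction,
    malformed_fraction = malformed_fraction,
    sd_degenerate = degenerate
  ), class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("<population_stats> n = %d, diameter %.1f +/- %.1f um (median %.1f)\n",
              x$n_beads, x$mean_diameter_um, x$sd_diameter_um,
              x$median_diameter_um))
  if (!is.na(x$satellite_fraction))
    cat(sprintf("  satellites %.1f%%, malformed %.1f%%\n",
                100 * x$satellite_fraction, 100 * x$malformed_fraction))
  invisible(x)
}

#' Count encapsulated cell spheroids inside a bead
#'
#' Restricts the image to the bead's interior disk (the detected radius
#' shrunk by the rim width plus a safety margin), thresholds dark objects
#' with Otsu's method computed on the interior pixels only, splits touching
#' objects with one round of watershed on the distance transform, and counts
#' connected components whose equivalent diameter falls within the spheroid
#' size gate.
#'
#' @param scene A brightfield \code{"bead_scene"}.
#' @param bead One row of a \code{"detected_beads"} data.frame.
#' @param spheroid_min_um,spheroid_max_um Equivalent-diameter gate
#'   (defaults 80--220 um, bracketing the 100--200 um spheroids produced by
#'   aggregation with margin).
#' @param interior_margin_um Shrinkage of the counting disk below the
#'   detected radius (rim width plus slack), default 30 um.
#' @param watershed_tolerance Tolerance of the watershed split, in distance
#'   map units (pixels).
#' @return Non-negative integer spheroid count.
#' @export
count_spheroids <- function(scene, bead, spheroid_min_um = 80,
                            spheroid_max_um = 220, interior_margin_um = 30,
                            watershed_tolerance = 2) {
  if (scene$modality != "brightfield")
    stop("spheroid counting requires a brightfield scene")
  img <- scene$image
  px <- scene$pixel_size_um
  h <- nrow(img); w <- ncol(img)
  cx <- bead$center_x_px; cy <- bead$center_y_px
  r <- bead$radius_px
  if (cx - r < 0 || cx + r > w - 1 || cy - r < 0 || cy + r > h - 1)
    stop("bead lies partially outside the image")
  r_int <- r - interior_margin_um / px
  if (r_int <= 0) return(0L)

  rows <- max(1, floor(cy - r_int)):min(h, ceiling(cy + r_int) + 1)
  cols <- max(1, floor(cx - r_int)):min(w, ceiling(cx + r_int) + 1)
  DY <- matrix(rows - 1 - cy, length(rows), length(cols))
  DX <- matrix(cols - 1 - cx, length(rows), length(cols), byrow = TRUE)
  disk <- DX^2 + DY^2 <= r_int^2
  sub <- img[rows, cols, drop = FALSE]
  vals <- sub[disk]
  if (!length(vals)) stop("interior ROI is empty")

  thr <- otsu_threshold(vals)
  mask <- disk & sub < thr
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  labs <- as.integer(ws)
  areas <- tabulate(labs[labs > 0])
  eq_diam_um <- 2 * sqrt(areas / pi) * px
  sum(eq_diam_um >= spheroid_min_um & eq_diam_um <= spheroid_max_um)
}

# Otsu threshold on a vector of intensities in [0, 1] (wraps EBImage::otsu
# on a single-column image so the computation is restricted to ROI pixels).
otsu_threshold <- function(vals) {
  vals <- pmin(pmax(vals, 0), 1)
  EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)), range = c(0, 1))
}

#' Spheroid seeding arithmetic
#'
#' Cell density implied by a spheroid (cluster) suspension: clusters per mL
#' times cells per spheroid.  With the encapsulation protocol's
#' 6.25e4 clusters/mL of 800-cell spheroids this is 5e7 cells/mL.
#'
#' @param clusters_per_ml Spheroid concentration of the suspension.
#' @param cells_per_spheroid Cells per spheroid.
#' @return Cells per mL.
#' @export
seeding_cell_density <- function(clusters_per_ml, cells_per_spheroid) {
  stop_if_not_scalar(clusters_per_ml, "clusters_per_ml", lower = 0)
  stop_if_not_scalar(cells_per_spheroid, "cells_per_spheroid", lower = 0)
  clusters_per_ml * cells_per_spheroid
}
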