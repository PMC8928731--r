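#' Mean intensity of a bead's central region
#'
#' The "central point" readout of the permeability assay, taken as a disk
#' ROI of radius \code{roi_fraction * bead radius} rather than a single
#' pixel (a one-pixel readout would be noise-dominated).
#'
#' @param scene A fluorescence \code{"bead_scene"}.
#' @param bead One row of a \code{"detected_beads"} data.frame (or any list
#'   with \code{center_x_px}, \code{center_y_px}, \code{radius_px}).
#' @param roi_fraction Fraction of the bead radius used for the ROI, in
#'   (0, 0.5].
#' @return Mean intensity over the ROI disk.
#' @export
center_intensity <- function(scene, bead, roi_fraction = 0.2) {
  stop_if_not_scalar(roi_fraction, "roi_fraction", lower = 0, upper = 0.5,
                     strict_lower = TRUE)
  img <- scene$image
  h <- nrow(img); w <- ncol(img)
  cx <- bead$center_x_px; cy <- bead$center_y_px
  rr <- roi_fraction * bead$radius_px
  rows <- max(1, floor(cy - rr)):min(h, ceiling(cy + rr) + 1)
  cols <- max(1, floor(cx - rr)):min(w, ceiling(cx + rr) + 1)
  DY <- matrix(rows - 1 - cy, length(rows), length(cols))
  DX <- matrix(cols - 1 - cx, length(rows), length(cols), byrow = TRUE)
  sel <- DX^2 + DY^2 <= rr^2
  if (!any(sel)) stop("central ROI contains no pixels")
  mean(img[rows, cols, drop = FALSE][sel])
}

#' Mean intensity of the bead-free background
#'
#' Mean over all pixels farther than \code{exclusion_factor} times the bead
#' radius from every bead centre.
#'
#' @param scene A \code{"bead_scene"}.
#' @param beads A \code{"detected_beads"} data.frame (may be empty).
#' @param exclusion_factor Multiple of each bead radius excluded around its
#'   centre, default 1.5.
#' @return Mean background intensity.  An error is raised when fewer than
#'   5\% of the pixels remain.
#' @export
background_intensity <- function(scene, beads, exclusion_factor = 1.5) {
  background_stats(scene, beads, exclusion_factor)$mean
}

# Mean and SD of the bead-free background (shared by the permeability and
# PFO modules).
background_stats <- function(scene, beads, exclusion_factor = 1.5) {
  img <- scene$image
  h <- nrow(img); w <- ncol(img)
  free <- matrix(TRUE, h, w)
  if (!is.null(beads) && nrow(beads)) {
    X <- matrix(0:(w - 1), h, w, byrow = TRUE)
    Y <- matrix(0:(h - 1), h, w)
    for (i in seq_len(nrow(beads))) {
      rex <- exclusion_factor * beads$radius_px[i]
      free <- free & ((X - beads$center_x_px[i])^2 +
                        (Y - beads$center_y_px[i])^2 > rex^2)
    }
  }
  if (mean(free) < 0.05)
    stop("insufficient bead-free background area (< 5% of pixels)")
  vals <- img[free]
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0)
}

#' Two-anchor normalization of permeation ratios
#'
#' Maps per-probe mean centre/background intensity ratios onto a 0--100
#' permeation scale anchored at a freely permeating reference (100
#' percent) and an excluded reference (0 percent), i.e.
#' \code{100 * (r - r0) / (r100 - r0)}, clamped to [0, 100].  With the
#' FITC-dextran ladder the anchors are 4 kDa (100) and 2 MDa (0); the
#' anchors themselves map exactly to 100 and 0.
#'
#' @param raw_ratios_by_probe Named numeric vector of mean raw ratios, one
#'   per probe label.
#' @param anchor_100 Label of the probe pinned to 100 percent permeation
#'   (default \code{"4 kDa"}).
#' @param anchor_0 Label of the probe pinned to 0 percent permeation
#'   (default \code{"2 MDa"}).
#' @return Named numeric vector of normalized permeation percentages.
#' @export
normalize_permeation <- function(raw_ratios_by_probe, anchor_100 = "4 kDa",
                                 anchor_0 = "2 MDa") {
  r <- raw_ratios_by_probe
  if (!all(c(anchor_100, anchor_0) %in% names(r)))
    stop("both anchor probes must be present in the ratio table")
  r100 <- r[[anchor_100]]; r0 <- r[[anchor_0]]
  if (r0 >= r100)
    stop("anchor ratios are equal or inverted: the 0% anchor must have the ",
         "smaller ratio")
  pmin(pmax(100 * (r - r0) / (r100 - r0), 0), 100)
}

#' Per-bead permeability records for one probe condition
#'
#' Computes each bead's centre and background mean intensities and their
#' ratio on one fluorescence scene.
#'
#' @inheritParams center_intensity
#' @param beads A \code{"detected_beads"} data.frame.
#' @param probe_label Probe identity (e.g. \code{"70 kDa"}).
#' @param timepoint_h Incubation time in hours (metadata only).
#' @param exclusion_factor Passed to [background_intensity()].
#' @return Data.frame with one row per bead: \code{bead_id},
#'   \code{probe_label}, \code{timepoint_h}, \code{center_mean_intensity},
#'   \code{background_mean_intensity}, \code{raw_ratio}.
#' @export
permeability_records <- function(scene, beads, probe_label,
                                 timepoint_h = NA_real_, roi_fraction = 0.2,
                                 exclusion_factor = 1.5) {
  if (!nrow(beads)) stop("no beads supplied")
  bg <- background_intensity(scene, beads, exclusion_factor)
  if (bg <= 0) stop("background mean intensity must be positive")
  ctr <- vapply(seq_len(nrow(beads)), function(i)
    center_intensity(scene, beads[i, ], roi_fraction), numeric(1))
  data.frame(bead_id = beads$bead_id, probe_label = probe_label,
             timepoint_h = timepoint_h, center_mean_intensity = ctr,
             background_mean_intensity = bg, raw_ratio = ctr / bg)
}

#' Welch comparison of two permeability groups
#'
#' Compares normalized permeation percentages of two bead groups with
#' Welch's t-test (no multiplicity adjustment; the assay's repeated
#' per-probe tests are reported unadjusted by default).
#'
#' @param groupA,groupB Numeric vectors of normalized permeation
#'   percentages, each of length >= 2.
#' @return A \code{"welch_result"} (see [welch_from_samples()]).
#' @export
compare_groups_permeability <- function(groupA, groupB) {
  welch_from_samples(groupA, groupB)
}
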