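#' Detect circular microbeads with a circular Hough transform
#'
#' Votes edge pixels into a three-parameter accumulator over centre and
#' radius (radius discretized at \code{radius_step_px}), using the local
#' gradient direction so each edge pixel casts two votes per radius.
#' Accumulator peaks are suppressed so that no two returned centres are
#' closer than \code{min_center_separation_um}; surviving candidates are
#' refined to sub-pixel accuracy by an algebraic circle fit on the
#' outward-gradient edge pixels of the outermost supported ring.  Each
#' detection carries an \code{accumulator_score}: the fraction of the
#' perimeter (72 angular bins) supported by edge pixels within the rim
#' annulus of the fitted circle.
#'
#' @param edges An [edge_map()] result (binary matrix with gradient
#'   attributes).
#' @param config A [detection_config()].
#' @param pixel_size_um Physical calibration of the image.
#' @return A data.frame of class \code{"detected_beads"}, sorted by
#'   descending score, with columns \code{bead_id}, \code{center_x_px},
#'   \code{center_y_px}, \code{radius_px}, \code{diameter_um},
#'   \code{accumulator_score}, \code{malformed_flag}, \code{satellite_flag}.
#'   An empty edge map yields an empty data.frame.
#' @export
hough_detect <- function(edges, config = detection_config(), pixel_size_um) {
  stop_if_not_scalar(pixel_size_um, "pixel_size_um", lower = 0,
                     strict_lower = TRUE)
  px <- pixel_size_um
  radii <- seq(config$radius_min_um / px, config$radius_max_um / px,
               by = config$radius_step_px)
  if (length(radii) < 2)
    stop("radius search band must span at least 2 radius steps")
  h <- nrow(edges); w <- ncol(edges)
  idx <- which(edges == 1L)
  if (!length(idx)) return(empty_detections())

  iy <- (idx - 1L) %% h + 1L
  jx <- (idx - 1L) %/% h + 1L
  ey <- iy - 1; ex <- jx - 1
  gx <- attr(edges, "grad_x")[idx]; gy <- attr(edges, "grad_y")[idx]
  gmag <- pmax(sqrt(gx^2 + gy^2), 1e-12)
  ux <- gx / gmag; uy <- gy / gmag

  cand <- list()
  for (r in radii) {
    cx <- c(ex - r * ux, ex + r * ux)
    cy <- c(ey - r * uy, ey + r * uy)
    ci <- round(cy) + 1; cj <- round(cx) + 1
    ok <- ci >= 1 & ci <= h & cj >= 1 & cj <= w
    if (!any(ok)) next
    lin <- (cj[ok] - 1) * h + ci[ok]
    acc <- matrix(tabulate(lin, nbins = h * w), h, w)
    accs <- boxsum3(acc)
    thr <- config$vote_fraction * 2 * pi * r
    cells <- which(accs >= thr)
    if (!length(cells)) next
    # keep only 5x5 local maxima among the thresholded cells
    ci0 <- (cells - 1L) %% h + 1L
    cj0 <- (cells - 1L) %/% h + 1L
    v0 <- accs[cells]
    ismax <- rep(TRUE, length(cells))
    for (dy in -2:2) for (dx in -2:2) {
      if (dy == 0 && dx == 0) next
      ri <- ci0 + dy; rj <- cj0 + dx
      inb <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
      nb <- rep(0, length(cells))
      nb[inb] <- accs[(rj[inb] - 1) * h + ri[inb]]
      ismax <- ismax & v0 >= nb
    }
    if (any(ismax))
      cand[[length(cand) + 1L]] <- data.frame(
        cx = cj0[ismax] - 1, cy = ci0[ismax] - 1, r = r,
        votes = v0[ismax], norm = v0[ismax] / (2 * pi * r))
  }
  if (!length(cand)) return(empty_detections())
  cand <- do.call(rbind, cand)

  # greedy suppression: strongest first, ties broken by larger radius then
  # row-major centre order
  ord <- order(-cand$norm, -cand$r, cand$cy, cand$cx)
  cand <- cand[ord, , drop = FALSE]
  min_sep <- config$min_center_separation_um / px
  keep_x <- keep_y <- numeric(0)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep_x) ||
        all(sqrt((keep_x - cand$cx[i])^2 + (keep_y - cand$cy[i])^2) >=
              min_sep)) {
      keep_rows <- c(keep_rows, i)
      keep_x <- c(keep_x, cand$cx[i]); keep_y <- c(keep_y, cand$cy[i])
    }
  }
  cand <- cand[keep_rows, , drop = FALSE]

  ep <- list(x = ex, y = ey, ux = ux, uy = uy)
  fits <- lapply(seq_len(nrow(cand)), function(i)
    refine_circle(ep, cand$cx[i], cand$cy[i], cand$r[i], config, px))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) return(empty_detections())
  det <- do.call(rbind, lapply(fits, as.data.frame))

  det <- det[det$score >= config$peak_threshold, , drop = FALSE]
  if (!nrow(det)) return(empty_detections())

  # de-duplicate refined circles that converged onto the same bead
  ord <- order(-det$score, -det$r, det$cy, det$cx)
  det <- det[ord, , drop = FALSE]
  keep_rows <- integer(0); keep_x <- keep_y <- numeric(0)
  for (i in seq_len(nrow(det))) {
    if (!length(keep_x) ||
        all(sqrt((keep_x - det$cx[i])^2 + (keep_y - det$cy[i])^2) >=
              min_sep)) {
      keep_rows <- c(keep_rows, i)
      keep_x <- c(keep_x, det$cx[i]); keep_y <- c(keep_y, det$cy[i])
    }
  }
  det <- det[keep_rows, , drop = FALSE]

  out <- data.frame(
    bead_id = seq_len(nrow(det)),
    center_x_px = det$cx, center_y_px = det$cy, radius_px = det$r,
    diameter_um = 2 * det$r * px,
    accumulator_score = pmin(det$score, 1),
    malformed_flag = NA, satellite_flag = NA)
  class(out) <- c("detected_beads", class(out))
  out
}

empty_detections <- function() {
  out <- data.frame(bead_id = integer(0), center_x_px = numeric(0),
                    center_y_px = numeric(0), radius_px = numeric(0),
                    diameter_um = numeric(0), accumulator_score = numeric(0),
                    malformed_flag = logical(0), satellite_flag = logical(0))
  class(out) <- c("detected_beads", class(out))
  out
}

# Fraction of 72 angular bins covered by the given edge-pixel subset.
angular_support <- function(angles, sel) {
  if (!any(sel)) return(0)
  length(unique(floor((angles[sel] %% (2 * pi)) / (2 * pi) * 72))) / 72
}

# Sub-pixel refinement of one Hough candidate.  Prefers the outermost ring
# supported by outward-gradient edges (the bead's outer boundary); when the
# boundary is too degraded (heavy fibrotic overgrowth) it falls back to the
# clean inner rim ring offset by the configured rim width.
refine_circle <- function(ep, cx, cy, r, config, px) {
  W <- config$refine_window_px
  rimw <- config$rim_width_um / px
  d <- sqrt((ep$x - cx)^2 + (ep$y - cy)^2)
  sel <- abs(d - r) <= (W + rimw)
  if (sum(sel) < 10) return(NULL)
  sx <- ep$x[sel]; sy <- ep$y[sel]; sd_ <- d[sel]
  sux <- ep$ux[sel]; suy <- ep$uy[sel]
  rux <- (sx - cx) / pmax(sd_, 1e-9); ruy <- (sy - cy) / pmax(sd_, 1e-9)
  dot <- sux * rux + suy * ruy
  outward <- if (config$polarity == "dark") dot > 0.5 else dot < -0.5
  angles <- atan2(sy - cy, sx - cx)

  grid <- seq(max(1, r - W), r + W, by = 0.5)
  pick <- NA_real_
  use_outward <- FALSE
  if (any(outward)) {
    sup <- vapply(grid, function(rr)
      angular_support(angles, outward & abs(sd_ - rr) <= 1.5), numeric(1))
    m <- max(sup)
    if (m >= 0.35) {
      pick <- max(grid[sup >= max(0.35, 0.8 * m)])
      use_outward <- TRUE
    }
  }
  if (!use_outward) {
    # fall back to the innermost strongly supported ring (the rim's inner
    # boundary stays clean under overgrowth) plus the configured rim width
    sup <- vapply(grid, function(rr)
      angular_support(angles, abs(sd_ - rr) <= 1.5), numeric(1))
    m <- max(sup)
    if (m < 0.2) return(NULL)
    pick <- min(grid[sup >= 0.9 * m]) + rimw
  }

  fit_sel <- if (use_outward) outward & abs(sd_ - pick) <= 2
             else abs(sd_ - (pick - rimw)) <= 2
  if (sum(fit_sel) >= 6) {
    fx <- sx[fit_sel]; fy <- sy[fit_sel]
    A <- cbind(2 * fx, 2 * fy, 1)
    b <- fx^2 + fy^2
    sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(sol)) {
      fcx <- sol[1]; fcy <- sol[2]
      fr <- sqrt(sol[3] + fcx^2 + fcy^2)
      if (!use_outward) fr <- fr + rimw
      if (is.finite(fr) && fr > 1 && abs(fr - pick) < 5) {
        cx <- fcx; cy <- fcy; pick <- fr
      }
    }
  }

  # perimeter support over the rim annulus of the fitted circle
  d2 <- sqrt((ep$x - cx)^2 + (ep$y - cy)^2)
  in_annulus <- d2 >= pick - rimw - 1 & d2 <= pick + 2
  score <- angular_support(atan2(ep$y - cy, ep$x - cx), in_annulus)
  list(cx = cx, cy = cy, r = pick, score = score)
}

#' Flag satellite beads by a diameter threshold
#'
#' Satellite beads are small residual alginate beads formed by droplet
#' fission during electrostatic encapsulation.  The flag is purely a
#' diameter gate; the default threshold (200 um) is configurable.
#'
#' @param beads A \code{"detected_beads"} data.frame.
#' @param satellite_max_diameter_um Beads strictly below this diameter are
#'   flagged.
#' @return The same data.frame, order preserved, with
#'   \code{satellite_flag} set.
#' @export
flag_satellites <- function(beads, satellite_max_diameter_um = 200) {
  beads$satellite_flag <- beads$diameter_um < satellite_max_diameter_um
  beads
}

#' Flag malformed beads by low perimeter edge support
#'
#' A bead whose fitted circle is supported by less than
#' \code{min_edge_support} of its perimeter (e.g. a bead with a broken or
#' missing rim segment) is flagged as malformed.
#'
#' @param scene The scene the beads were detected in (reserved; the score is
#'   already stored on the detections).
#' @param beads A \code{"detected_beads"} data.frame.
#' @param min_edge_support Threshold in (0, 1).
#' @return The same data.frame with \code{malformed_flag} set.
#' @export
flag_malformed <- function(scene, beads, min_edge_support = 0.8) {
  stop_if_not_scalar(min_edge_support, "min_edge_support", lower = 0,
                     upper = 1, strict_lower = TRUE)
  beads$malformed_flag <- beads$accumulator_score < min_edge_support
  beads
}

#' One-call bead detection on a scene
#'
#' Convenience wrapper: [edge_map()], [hough_detect()], then
#' [flag_satellites()] and [flag_malformed()].
#'
#' @param scene A \code{"bead_scene"}.
#' @param config A [detection_config()].
#' @param satellite_max_diameter_um,min_edge_support Flag thresholds.
#' @return A \code{"detected_beads"} data.frame.
#' @export
detect_beads <- function(scene, config = detection_config(),
                         satellite_max_diameter_um = 200,
                         min_edge_support = 0.8) {
  em <- edge_map(scene, config)
  det <- hough_detect(em, config, scene$pixel_size_um)
  det <- flag_satellites(det, satellite_max_diameter_um)
  flag_malformed(scene, det, min_edge_support)
}
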