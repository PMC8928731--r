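#' Render a synthetic brightfield microbead scene
#'
#' Draws alginate microbeads as slightly darkened disks with a darker rim
#' annulus on a bright background, encapsulated cell spheroids as darker
#' disks inside the bead, and pericapsular fibrotic overgrowth as speckled
#' dark annular segments just outside the rim.  Gaussian pixel noise is added
#' last.  Rendering is fully determined by \code{spec$seed}: identical
#' arguments give bit-identical images.
#'
#' @param spec A [scene_spec()] with \code{modality = "brightfield"}.
#' @param beads List of [bead_spec()] objects.  Beads must fit within the
#'   image bounds and must not overlap.
#' @param speckle_density Per-pixel Bernoulli probability of a dark speckle
#'   inside an overgrowth arc.  The texture prevents a trivially uniform
#'   overgrowth band.
#'
#' @return A list with elements \code{scene} (a \code{"bead_scene"}) and
#'   \code{truth} (a \code{"bead_truth"} ground-truth record, one row per
#'   bead).
#' @export
render_brightfield_scene <- function(spec, beads, speckle_density = 0.85) {
  if (!inherits(spec, "scene_spec")) stop("'spec' must be a scene_spec")
  if (spec$modality != "brightfield")
    stop("scene_spec modality must be 'brightfield'")
  beads <- as_bead_list(beads)
  check_bead_layout(spec, beads)
  img <- matrix(spec$background_level, spec$image_height_px,
                spec$image_width_px)
  withr::with_seed(spec$seed, {
    for (k in seq_along(beads))
      img <- draw_bead_brightfield(img, beads[[k]], spec, speckle_density)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
  })
  list(scene = new_scene(img, spec), truth = make_truth(spec, beads))
}

#' Render a synthetic fluorescence (FITC-dextran) microbead scene
#'
#' Emulates a permeability-assay field: the bead-free probe solution is
#' bright at \code{spec$background_level} and each bead interior carries the
#' intensity \code{dark_floor + permeation_fraction * (background_level -
#' dark_floor)}.  A fully permeable bead (fraction 1) matches the
#' background; an impermeable bead (fraction 0) sits at the dark floor.
#'
#' @inheritParams render_brightfield_scene
#' @param spec A [scene_spec()] with \code{modality = "fluorescence"}.  Every
#'   bead must carry a \code{permeation_fraction}.
#' @param dark_floor Residual intensity of a fully impermeable bead
#'   (emulates autofluorescence), default 0.02.
#' @return As [render_brightfield_scene()].
#' @export
render_fluorescence_scene <- function(spec, beads, dark_floor = 0.02) {
  if (!inherits(spec, "scene_spec")) stop("'spec' must be a scene_spec")
  if (spec$modality != "fluorescence")
    stop("scene_spec modality must be 'fluorescence'")
  beads <- as_bead_list(beads)
  pf <- vapply(beads, function(b) b$permeation_fraction, numeric(1))
  if (anyNA(pf))
    stop("every bead in a fluorescence scene needs a permeation_fraction")
  check_bead_layout(spec, beads)
  img <- matrix(spec$background_level, spec$image_height_px,
                spec$image_width_px)
  px <- spec$pixel_size_um
  for (b in beads) {
    val <- dark_floor + b$permeation_fraction *
      (spec$background_level - dark_floor)
    img <- paint_disk(img, b$center_x_px, b$center_y_px,
                      b$diameter_um / 2 / px, val)
  }
  withr::with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nrow(img))
  })
  list(scene = new_scene(img, spec), truth = make_truth(spec, beads))
}

as_bead_list <- function(beads) {
  if (inherits(beads, "bead_spec")) return(list(beads))
  if (!is.list(beads) ||
      !all(vapply(beads, inherits, logical(1), "bead_spec")))
    stop("'beads' must be a list of bead_spec objects")
  beads
}

check_bead_layout <- function(spec, beads) {
  px <- spec$pixel_size_um
  w <- spec$image_width_px; h <- spec$image_height_px
  for (k in seq_along(beads)) {
    b <- beads[[k]]
    band <- 0
    if (!is.null(b$overgrowth_arcs) && nrow(b$overgrowth_arcs))
      band <- max(b$overgrowth_arcs$band_width_um)
    r <- (b$diameter_um / 2 + band) / px
    if (b$center_x_px - r < 0 || b$center_x_px + r > w - 1 ||
        b$center_y_px - r < 0 || b$center_y_px + r > h - 1)
      stop(sprintf("bead %d extends outside the image bounds", k))
  }
  if (length(beads) > 1) {
    for (i in seq_len(length(beads) - 1)) for (j in (i + 1):length(beads)) {
      bi <- beads[[i]]; bj <- beads[[j]]
      d <- sqrt((bi$center_x_px - bj$center_x_px)^2 +
                (bi$center_y_px - bj$center_y_px)^2)
      if (d * px < (bi$diameter_um + bj$diameter_um) / 2)
        stop(sprintf("beads %d and %d overlap", i, j))
    }
  }
  invisible(TRUE)
}

make_truth <- function(spec, beads) {
  df <- data.frame(
    bead_id = seq_along(beads),
    center_x_px = vapply(beads, `[[`, numeric(1), "center_x_px"),
    center_y_px = vapply(beads, `[[`, numeric(1), "center_y_px"),
    diameter_um = vapply(beads, `[[`, numeric(1), "diameter_um"),
    spheroid_count = vapply(beads, function(b)
      if (is.null(b$spheroids)) 0L else nrow(b$spheroids), integer(1)),
    permeation_fraction = vapply(beads, `[[`, numeric(1),
                                 "permeation_fraction"),
    coverage_fraction = vapply(beads, bead_coverage_fraction, numeric(1))
  )
  structure(list(beads = df, seed = spec$seed, spec = unclass(spec)),
            class = "bead_truth")
}

#' @export
print.bead_truth <- function(x, ...) {
  cat(sprintf("<bead_truth> %d bead(s), seed %d\n", nrow(x$beads), x$seed))
  invisible(x)
}

# Paint a flat disk (pixel-centre-in-disk test); used for fluorescence beads.
paint_disk <- function(img, cx, cy, r_px, value) {
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, floor(cy - r_px)):min(h, ceiling(cy + r_px) + 2)
  cols <- max(1, floor(cx - r_px)):min(w, ceiling(cx + r_px) + 2)
  DY <- matrix(rows - 1 - cy, length(rows), length(cols))
  DX <- matrix(cols - 1 - cx, length(rows), length(cols), byrow = TRUE)
  sub <- img[rows, cols, drop = FALSE]
  sub[DX^2 + DY^2 <= r_px^2] <- value
  img[rows, cols] <- sub
  img
}

draw_bead_brightfield <- function(img, bead, spec, speckle_density) {
  px <- spec$pixel_size_um
  bg <- spec$background_level
  R <- bead$diameter_um / 2 / px
  rimw <- bead$rim_width_um / px
  band <- 0
  if (!is.null(bead$overgrowth_arcs) && nrow(bead$overgrowth_arcs))
    band <- max(bead$overgrowth_arcs$band_width_um) / px
  ext <- ceiling(R + band) + 2
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, floor(bead$center_y_px - ext)):
    min(h, ceiling(bead$center_y_px + ext))
  cols <- max(1, floor(bead$center_x_px - ext)):
    min(w, ceiling(bead$center_x_px + ext))
  DY <- matrix(rows - 1 - bead$center_y_px, length(rows), length(cols))
  DX <- matrix(cols - 1 - bead$center_x_px, length(rows), length(cols),
               byrow = TRUE)
  D <- sqrt(DX^2 + DY^2)
  sub <- img[rows, cols, drop = FALSE]

  interior_val <- bg - bead$interior_contrast
  rim_val <- bg - bead$rim_contrast
  sub[D <= R] <- interior_val
  rim_sel <- D <= R & D > R - rimw
  sub[rim_sel] <- rim_val

  if (!is.null(bead$rim_gap_arcs) && nrow(bead$rim_gap_arcs)) {
    ang <- (atan2(DY, DX) * 180 / pi) %% 360
    for (g in seq_len(nrow(bead$rim_gap_arcs))) {
      gap <- rim_sel & in_arc(ang, bead$rim_gap_arcs$start_deg[g],
                              bead$rim_gap_arcs$end_deg[g])
      sub[gap] <- interior_val
    }
  }

  if (!is.null(bead$spheroids) && nrow(bead$spheroids)) {
    for (s in seq_len(nrow(bead$spheroids))) {
      sx <- bead$spheroids$offset_x_um[s] / px
      sy <- bead$spheroids$offset_y_um[s] / px
      sr <- bead$spheroids$diameter_um[s] / 2 / px
      sel <- (DX - sx)^2 + (DY - sy)^2 <= sr^2
      sub[sel] <- interior_val - bead$spheroids$contrast[s]
    }
  }

  if (!is.null(bead$overgrowth_arcs) && nrow(bead$overgrowth_arcs)) {
    ang <- (atan2(DY, DX) * 180 / pi) %% 360
    for (a in seq_len(nrow(bead$overgrowth_arcs))) {
      bw <- bead$overgrowth_arcs$band_width_um[a] / px
      sel <- D > R & D <= R + bw &
        in_arc(ang, bead$overgrowth_arcs$start_deg[a],
               bead$overgrowth_arcs$end_deg[a])
      n <- sum(sel)
      if (n) {
        vals <- sub[sel]
        spk <- runif(n) < speckle_density
        vals[spk] <- bg - bead$overgrowth_arcs$contrast[a]
        sub[sel] <- vals
      }
    }
  }

  img[rows, cols] <- sub
  img
}
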