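#' Perimeter coverage of pericapsular fibrotic overgrowth
#'
#' Samples the annulus just outside the bead edge along \code{n_rays}
#' equally spaced angles.  A ray counts as covered when the mean intensity
#' of its annular segment falls below the background mean minus
#' \code{dark_threshold_k} background standard deviations.  The coverage
#' fraction is covered rays / \code{n_rays}.
#'
#' @param scene A brightfield \code{"bead_scene"}.
#' @param bead One row of a \code{"detected_beads"} data.frame.
#' @param band_width_fraction Outer extent of the scored annulus as a
#'   fraction of the bead radius, default 0.15.
#' @param n_rays Number of rays, default 360 (one-degree resolution).
#' @param dark_threshold_k Darkness criterion in background SDs, default 3.
#' @param background Optional list with \code{mean} and \code{sd} of the
#'   bead-free background; computed from the scene (excluding this bead at
#'   1.3 radii) when omitted.
#' @param sd_floor Lower bound on the background SD used in the darkness
#'   threshold, so the criterion stays meaningful on noiseless images.
#' @return Coverage fraction in [0, 1].
#' @export
perimeter_coverage <- function(scene, bead, band_width_fraction = 0.15,
                               n_rays = 360, dark_threshold_k = 3,
                               background = NULL, sd_floor = 0.004) {
  if (scene$modality != "brightfield")
    stop("PFO scoring requires a brightfield scene")
  img <- scene$image
  h <- nrow(img); w <- ncol(img)
  cx <- bead$center_x_px; cy <- bead$center_y_px
  r <- bead$radius_px
  r_out <- r * (1 + band_width_fraction)
  if (cx - r_out < 0 || cx + r_out > w - 1 ||
      cy - r_out < 0 || cy + r_out > h - 1)
    stop("scoring annulus exceeds the image bounds")
  if (is.null(background))
    background <- background_stats(scene, data.frame(
      center_x_px = cx, center_y_px = cy, radius_px = r), 1.3)
  thr <- background$mean -
    dark_threshold_k * max(background$sd, sd_floor) - 1e-9

  # start 2 px outside the fitted radius to clear the rim under small
  # radius-fit errors
  rr <- seq(r + 2, r_out, by = 1)
  if (length(rr) < 2) rr <- c(r + 2, r_out)
  th <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  X <- round(outer(cos(th), rr) + cx) + 1
  Y <- round(outer(sin(th), rr) + cy) + 1
  vals <- matrix(img[(X - 1) * h + Y], n_rays, length(rr))
  ray_means <- rowMeans(vals)
  mean(ray_means < thr)
}

#' Bin a coverage fraction into a PFO grade
#'
#' Coverage categories follow the quartile grading used for encapsulated
#' implants, with an exact-zero class and right-closed bins: 0\%,
#' 1--25\%, 26--50\%, 51--75\%, 76--100\% (a boundary value such as 75
#' assigns downward).
#'
#' @param coverage_fraction Coverage in [0, 1] (vectorized).
#' @return Factor with levels \code{"0%"}, \code{"1-25%"}, \code{"26-50%"},
#'   \code{"51-75%"}, \code{"76-100%"}.
#' @export
bin_coverage <- function(coverage_fraction) {
  if (any(!is.finite(coverage_fraction)) ||
      any(coverage_fraction < 0 | coverage_fraction > 1))
    stop("coverage_fraction must lie in [0, 1]")
  c100 <- 100 * coverage_fraction
  lab <- pfo_categories()
  out <- ifelse(c100 == 0, lab[1],
         ifelse(c100 <= 25, lab[2],
         ifelse(c100 <= 50, lab[3],
         ifelse(c100 <= 75, lab[4], lab[5]))))
  factor(out, levels = lab)
}

#' @rdname bin_coverage
#' @export
pfo_categories <- function() c("0%", "1-25%", "26-50%", "51-75%", "76-100%")

#' Summarize a cohort of PFO records
#'
#' Per-category bead counts converted to percentages of the cohort size,
#' rounded half-up to whole percent (matching whole-percent reporting of
#' graded cohorts).
#'
#' @param records Data.frame with a \code{coverage_category} column (as
#'   produced by [bin_coverage()]), or a vector of categories.
#' @param group_label Cohort label.
#' @return A list of class \code{"cohort_summary"}: \code{group_label},
#'   \code{n_beads}, \code{counts} and \code{pct_per_category} (named
#'   integer vectors over the five categories).
#' @export
summarize_cohort <- function(records, group_label = "cohort") {
  cats <- if (is.data.frame(records)) records$coverage_category else records
  cats <- factor(as.character(cats), levels = pfo_categories())
  if (!length(cats) || anyNA(cats)) stop("no valid PFO records supplied")
  counts <- table(cats)
  n <- length(cats)
  pct <- as.integer(round_half_up(100 * as.integer(counts) / n))
  structure(list(group_label = group_label, n_beads = n,
                 counts = setNames(as.integer(counts), names(counts)),
                 pct_per_category = setNames(pct, names(counts))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s (n = %d beads)\n", x$group_label,
              x$n_beads))
  print(x$pct_per_category)
  invisible(x)
}

#' Score PFO for every bead of a scene
#'
#' Convenience wrapper producing one PFO record per detected bead.
#'
#' @inheritParams perimeter_coverage
#' @param beads A \code{"detected_beads"} data.frame.
#' @return Data.frame with \code{bead_id}, \code{coverage_fraction},
#'   \code{coverage_category}.
#' @export
pfo_records <- function(scene, beads, band_width_fraction = 0.15,
                        n_rays = 360, dark_threshold_k = 3) {
  if (!nrow(beads))
    return(data.frame(bead_id = integer(0), coverage_fraction = numeric(0),
                      coverage_category = factor(character(0),
                                                 levels = pfo_categories())))
  bg <- background_stats(scene, beads, 1.3)
  cov <- vapply(seq_len(nrow(beads)), function(i)
    perimeter_coverage(scene, beads[i, ], band_width_fraction, n_rays,
                       dark_threshold_k, background = bg), numeric(1))
  data.frame(bead_id = beads$bead_id, coverage_fraction = cov,
             coverage_category = bin_coverage(cov))
}
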