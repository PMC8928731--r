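#' Detection configuration
#'
#' Parameters of the edge-detection and circular-Hough pipeline.  Edge
#' thresholds are fractions of the 99th-percentile gradient magnitude, which
#' makes detection invariant to global affine intensity rescaling.
#'
#' @param gaussian_sigma_px Gaussian smoothing sigma before the gradient.
#' @param edge_low,edge_high Hysteresis thresholds as fractions of the
#'   99th-percentile gradient magnitude.
#' @param radius_min_um,radius_max_um Radius search band in micrometres
#'   (defaults cover the 624 and 699 um bead diameters with margin).
#' @param radius_step_px Radius discretization of the Hough accumulator.
#' @param peak_threshold Minimum perimeter edge-support fraction for an
#'   accepted detection, in (0, 1].
#' @param min_center_separation_um No two reported centres may be closer
#'   than this.
#' @param rim_width_um Expected width of the bead rim; sets the annulus used
#'   to score perimeter support and the fallback radius offset for heavily
#'   overgrown beads.
#' @param polarity \code{"dark"} for beads darker than the background
#'   (transmitted light and dye-excluded fluorescence), \code{"bright"} for
#'   the inverted case.
#' @param vote_fraction Internal candidate gate: minimum accumulator votes as
#'   a fraction of the theoretical full-perimeter count.
#' @param refine_window_px Half-width of the radial window used during
#'   sub-pixel refinement.
#' @return An object of class \code{"detection_config"}.
#' @export
detection_config <- function(gaussian_sigma_px = 2, edge_low = 0.1,
                             edge_high = 0.2, radius_min_um = 150,
                             radius_max_um = 400, radius_step_px = 2,
                             peak_threshold = 0.5,
                             min_center_separation_um = 300,
                             rim_width_um = 20,
                             polarity = c("dark", "bright"),
                             vote_fraction = 0.25, refine_window_px = 10) {
  polarity <- match.arg(polarity)
  if (radius_min_um >= radius_max_um)
    stop("radius_min_um must be smaller than radius_max_um")
  stop_if_not_scalar(peak_threshold, "peak_threshold", lower = 0, upper = 1,
                     strict_lower = TRUE)
  structure(list(gaussian_sigma_px = gaussian_sigma_px, edge_low = edge_low,
                 edge_high = edge_high, radius_min_um = radius_min_um,
                 radius_max_um = radius_max_um,
                 radius_step_px = radius_step_px,
                 peak_threshold = peak_threshold,
                 min_center_separation_um = min_center_separation_um,
                 rim_width_um = rim_width_um, polarity = polarity,
                 vote_fraction = vote_fraction,
                 refine_window_px = refine_window_px),
            class = "detection_config")
}

gaussian_kernel <- function(sigma) {
  n <- max(1L, ceiling(3 * sigma))
  x <- -n:n
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

#' Compute a binary edge map of a scene
#'
#' Gaussian smoothing followed by Sobel gradients, non-maximum suppression
#' along the gradient direction, and hysteresis thresholding (weak edges are
#' kept only when connected to a strong edge).  Thresholds are relative to
#' the 99th percentile of the gradient magnitude, so the edge map is
#' invariant to affine intensity rescaling; an exactly uniform image yields
#' an all-zero map.
#'
#' @param scene A \code{"bead_scene"} (or a plain numeric matrix).
#' @param config A [detection_config()].
#' @return A 0/1 integer matrix of the scene's dimensions with attributes
#'   \code{grad_x} and \code{grad_y} (the smoothed gradient fields, used by
#'   [hough_detect()] for direction-informed voting).
#' @export
edge_map <- function(scene, config = detection_config()) {
  img <- if (inherits(scene, "bead_scene")) scene$image else scene
  if (!is.matrix(img) || !is.numeric(img))
    stop("edge_map needs a single-channel 2D image")
  sm <- EBImage::filter2(img, gaussian_kernel(config$gaussian_sigma_px),
                         boundary = "replicate")
  # Sobel derivatives; rows index y, columns index x.  filter2 performs a
  # true convolution (kernel mirrored), so the antisymmetric kernels are
  # pre-negated to obtain correlation-convention gradients.
  kx <- -matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  ky <- t(kx)
  gx <- EBImage::filter2(sm, kx, boundary = "replicate")
  gy <- EBImage::filter2(sm, ky, boundary = "replicate")
  gm <- sqrt(gx^2 + gy^2)

  p99 <- as.numeric(quantile(gm, 0.99))
  hi <- config$edge_high * p99
  lo <- config$edge_low * p99

  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  bin <- (round(ang / (pi / 4))) %% 4  # 0: x, 1: diag(+,+), 2: y, 3: diag(-,+)
  n1 <- matrix(0, nrow(gm), ncol(gm)); n2 <- n1
  sel <- bin == 0
  n1[sel] <- shift_mat(gm, 0, 1)[sel];  n2[sel] <- shift_mat(gm, 0, -1)[sel]
  sel <- bin == 1
  n1[sel] <- shift_mat(gm, 1, 1)[sel];  n2[sel] <- shift_mat(gm, -1, -1)[sel]
  sel <- bin == 2
  n1[sel] <- shift_mat(gm, 1, 0)[sel];  n2[sel] <- shift_mat(gm, -1, 0)[sel]
  sel <- bin == 3
  n1[sel] <- shift_mat(gm, 1, -1)[sel]; n2[sel] <- shift_mat(gm, -1, 1)[sel]
  # strict comparison on one side breaks ties so a symmetric two-pixel
  # gradient plateau yields a one-pixel edge line
  nms <- gm >= n1 & gm > n2 & gm > 1e-12

  strong <- nms & gm >= hi
  weak <- nms & gm >= lo
  edge <- weak
  if (any(weak) && any(strong) && !all(strong[weak])) {
    lab <- EBImage::bwlabel(weak * 1)
    keep <- unique(lab[strong])
    edge <- weak & matrix(lab %in% keep, nrow(lab), ncol(lab))
  } else if (!any(strong)) {
    edge <- matrix(FALSE, nrow(gm), ncol(gm))
  }
  out <- matrix(as.integer(edge), nrow(gm), ncol(gm))
  attr(out, "grad_x") <- gx
  attr(out, "grad_y") <- gy
  class(out) <- c("edge_map", class(out))
  out
}
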