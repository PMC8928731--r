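#' Write a scene to disk as a 16-bit TIFF (or PNG)
#'
#' Intensities are clipped to [0, 1] and quantized to 16 bits (TIFF) or
#' 8 bits (PNG).  The scene's calibration and modality travel in the
#' ground-truth JSON sidecar written by [write_truth()].
#'
#' @param scene A \code{"bead_scene"}.
#' @param path Output file path; the extension selects the format
#'   (\code{.tif}/\code{.tiff} or \code{.png}).
#' @return \code{path}, invisibly.
#' @export
write_scene <- function(scene, path) {
  img <- pmin(pmax(scene$image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a scene image from disk
#'
#' @param path TIFF or PNG file written by [write_scene()] (or any
#'   single-channel grayscale image).
#' @param pixel_size_um Physical calibration in micrometres per pixel.
#' @param modality \code{"brightfield"} or \code{"fluorescence"}.
#' @return A \code{"bead_scene"}.
#' @export
read_scene <- function(path, pixel_size_um,
                       modality = c("brightfield", "fluorescence")) {
  modality <- match.arg(modality)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(list(image = img, pixel_size_um = pixel_size_um,
                 modality = modality, background_level = NA_real_,
                 noise_sd = NA_real_, seed = NA_integer_),
            class = "bead_scene")
}

#' Write / read a ground-truth sidecar
#'
#' The sidecar is a JSON file with the per-bead ground truth (centre,
#' diameter, spheroid count, permeation fraction, perimeter coverage
#' fraction), the scene seed and an echo of the scene specification.
#'
#' @param truth A \code{"bead_truth"}.
#' @param path JSON file path (conventionally the scene basename + .json).
#' @return \code{path} (write) or a \code{"bead_truth"} (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(beads = truth$beads, seed = truth$seed,
                            spec = truth$spec),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beads = as.data.frame(x$beads), seed = x$seed,
                 spec = x$spec), class = "bead_truth")
}
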