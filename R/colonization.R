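#' Class-label mask of a colonized film surface
#'
#' A 2-D integer label image classifying every pixel of an imaged polymer
#' film as intact film (0), hyphal skeleton (1), dense colony (2 --
#' regions so densely colonized that individual hyphae cannot be
#' distinguished), or hole (3 -- fully eroded film). Segmentation producing
#' this mask is upstream; the mask is the input to the quantification.
#'
#' @param labels Integer matrix with values in 0:3.
#' @param pixel_size_um Pixel edge length (micrometres per pixel, > 0).
#' @return An object of class `colonization_mask`.
#' @export
colonization_mask <- function(labels, pixel_size_um) {
  if (!is.matrix(labels) || length(labels) == 0) {
    stop_field("labels", "must be a non-empty matrix")
  }
  if (!all(labels %in% 0:3)) {
    stop_field("labels", "pixel classes must be 0 (intact), 1 (skeleton), 2 (colony), 3 (hole)")
  }
  check_scalar_num(pixel_size_um, "pixel_size_um", lower = 0,
                   allow_zero = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "colonization_mask")
}

#' Read a colonization label mask from a PNG or TIFF file
#'
#' Expects an 8-bit single-channel image with the class-value mapping
#' 0 = intact, 1 = skeleton, 2 = colony, 3 = hole.
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`).
#' @param pixel_size_um Micrometres per pixel.
#' @export
read_colonization_mask <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_field("path", "must be a .png or .tif/.tiff file"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  colonization_mask(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
                    pixel_size_um = pixel_size_um)
}

#' Write a colonization label mask as an 8-bit PNG
#'
#' @param mask A [colonization_mask()].
#' @param path Output path ending in `.png`.
#' @export
write_colonization_mask <- function(mask, path) {
  stopifnot(inherits(mask, "colonization_mask"))
  png::writePNG(mask$labels / 255, target = path)
  invisible(path)
}

#' Total hyphal length per unit film area
#'
#' Sums skeleton step lengths over all 8-connected pairs of skeleton
#' pixels: an orthogonal neighbor pair contributes 1 pixel of length, a
#' diagonal pair `sqrt(2)` pixels, each scaled by the pixel size. The
#' total is divided by the imaged area. This step metric is exact for
#' axis-aligned and 45-degree runs: a straight run of `n` pixels measures
#' `n - 1` (or `(n - 1) sqrt(2)`) pixels.
#'
#' @param mask A [colonization_mask()].
#' @return Hyphal length per area in mm per mm^2, with attributes
#'   `total_length_mm` and `imaged_area_mm2`.
#' @export
hyphal_length <- function(mask) {
  stopifnot(inherits(mask, "colonization_mask"))
  s <- mask$labels == 1L
  nr <- nrow(s); nc <- ncol(s)
  # count neighbor pairs once via half the 8-neighborhood: E, S, SE, SW
  n_orth <- 0L; n_diag <- 0L
  if (nc > 1) n_orth <- n_orth + sum(s[, -nc] & s[, -1])
  if (nr > 1) n_orth <- n_orth + sum(s[-nr, ] & s[-1, ])
  if (nr > 1 && nc > 1) {
    n_diag <- sum(s[-nr, -nc] & s[-1, -1]) + sum(s[-nr, -1] & s[-1, -nc])
  }
  length_mm <- (n_orth + sqrt(2) * n_diag) * mask$pixel_size_um / 1000
  area_mm2 <- nr * nc * (mask$pixel_size_um / 1000)^2
  structure(length_mm / area_mm2,
            total_length_mm = length_mm, imaged_area_mm2 = area_mm2)
}

#' Area fractions of colony, holes and intact film
#'
#' Colony and hole fractions are class pixel counts over total pixels; the
#' intact fraction is the remainder, with skeleton pixels counted as intact
#' area (individual hyphae sit on top of film that is still present), so
#' the three fractions sum to one exactly.
#'
#' @param mask A [colonization_mask()].
#' @return A `colonization_summary` with `hyphal_length_per_area`
#'   (mm/mm^2), `colony_fraction`, `hole_fraction`, `intact_fraction` and
#'   `imaged_area_mm2`.
#' @examples
#' m <- simulate_colonization_mask(dim_px = 128, seed = 7)
#' area_fractions(m)
#' @export
area_fractions <- function(mask) {
  stopifnot(inherits(mask, "colonization_mask"))
  n <- length(mask$labels)
  colony <- sum(mask$labels == 2L) / n
  hole <- sum(mask$labels == 3L) / n
  lpa <- hyphal_length(mask)
  structure(list(
    hyphal_length_per_area = as.numeric(lpa),
    colony_fraction = colony,
    hole_fraction = hole,
    intact_fraction = 1 - colony - hole,
    imaged_area_mm2 = attr(lpa, "imaged_area_mm2")),
    class = "colonization_summary")
}

#' @export
print.colonization_summary <- function(x, ...) {
  cat(sprintf(paste0("<colonization_summary> %.3g mm/mm^2 hyphae; ",
                     "colony %.1f%%, holes %.1f%%, intact %.1f%% ",
                     "(%.3g mm^2 imaged)\n"),
              x$hyphal_length_per_area, 100 * x$colony_fraction,
              100 * x$hole_fraction, 100 * x$intact_fraction,
              x$imaged_area_mm2))
  invisible(x)
}
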