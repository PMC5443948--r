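#' Construct an egg image
#'
#' @param pixels Numeric matrix of grayscale values (rows = y, cols = x).
#' @param mask Logical matrix of the same shape marking the egg region.
#' @return An `egg_image` list.
#' @export
egg_image <- function(pixels, mask) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) abort("pixels must be a numeric matrix")
  if (!is.matrix(mask) || !is.logical(mask) || any(dim(mask) != dim(pixels))) {
    abort("mask must be a logical matrix with the same shape as pixels")
  }
  if (!any(mask)) abort("mask is empty")
  if (any(!is.finite(pixels))) abort("pixel values must be finite")
  structure(list(pixels = pixels, mask = mask), class = "egg_image")
}

#' @export
print.egg_image <- function(x, ...) {
  cat("<egg_image> ", nrow(x$pixels), "x", ncol(x$pixels),
      " px, mask area ", sum(x$mask), " px\n", sep = "")
  invisible(x)
}

elliptical_mask <- function(height_px, width_px, fill = 0.48) {
  cy <- (height_px + 1) / 2; cx <- (width_px + 1) / 2
  ry <- fill * height_px; rx <- fill * width_px
  yy <- matrix(seq_len(height_px), height_px, width_px)
  xx <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Generate a synthetic spotted-egg image
#'
#' A uniform background inside an elliptical egg mask, with darker
#' elliptical spots of roughly `spot_radius_px` placed uniformly at random
#' until the fraction of masked pixels covered by spots reaches
#' `coverage_target` (achieved coverage is within 0.05 of the target).
#' Single-channel grayscale in \[0, 1\]; the granularity pattern metrics are
#' luminance-based, so one channel suffices.
#'
#' @param width_px,height_px Image size in pixels.
#' @param spot_radius_px Nominal spot radius (must be < min(width, height)/2).
#' @param coverage_target Target spot coverage of the egg surface, in
#'   \[0, 0.9\].
#' @param contrast_level Gray-level drop of spots below the background.
#' @param background Background gray level.
#' @param seed Integer seed.
#' @return An [egg_image()].
#' @export
generate_spot_image <- function(width_px, height_px, spot_radius_px,
                                coverage_target, contrast_level = 0.4,
                                background = 0.75, seed = 1L) {
  if (coverage_target < 0 || coverage_target > 0.9) {
    abort("coverage_target must lie in [0, 0.9]")
  }
  if (spot_radius_px >= min(width_px, height_px) / 2) {
    abort("spot_radius_px must be smaller than half the smaller image dimension")
  }
  mask <- elliptical_mask(height_px, width_px)
  px <- matrix(background, height_px, width_px)
  spot_value <- background - contrast_level
  if (coverage_target > 0) {
    px <- with_seed(as.integer(seed), {
      area <- sum(mask)
      yy <- matrix(seq_len(height_px), height_px, width_px)
      xx <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
      mask_idx <- which(mask)
      it <- 0L
      repeat {
        cover <- sum(px[mask] < background - 1e-9) / area
        if (cover >= coverage_target - 0.005 || it > 20000L) break
        ctr <- mask_idx[sample.int(length(mask_idx), 1)]
        cy <- ((ctr - 1) %% height_px) + 1
        cx <- ((ctr - 1) %/% height_px) + 1
        ry <- spot_radius_px * runif(1, 0.75, 1.25)
        rx <- spot_radius_px * runif(1, 0.75, 1.25)
        spot <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
        px[spot & mask] <- spot_value
        it <- it + 1L
      }
      px
    })
    achieved <- sum(px[mask] < background - 1e-9) / sum(mask)
    if (abs(achieved - coverage_target) > 0.05) {
      warn(sprintf("achieved coverage %.3f deviates from target %.3f by more than 0.05",
                   achieved, coverage_target))
    }
  }
  egg_image(px, mask)
}

#' Write / read egg images as PNG
#'
#' The image and its mask are stored as two grayscale PNGs.
#'
#' @param img An [egg_image()].
#' @param pixels_path,mask_path File paths.
#' @return `write_egg_image()` returns the paths invisibly;
#'   `read_egg_image()` returns an [egg_image()].
#' @export
write_egg_image <- function(img, pixels_path, mask_path) {
  stopifnot(inherits(img, "egg_image"))
  png::writePNG(pmin(pmax(img$pixels, 0), 1), pixels_path)
  png::writePNG(img$mask * 1.0, mask_path)
  invisible(c(pixels_path, mask_path))
}

#' @rdname write_egg_image
#' @export
read_egg_image <- function(pixels_path, mask_path) {
  px <- png::readPNG(pixels_path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  mk <- png::readPNG(mask_path)
  if (length(dim(mk)) == 3) mk <- mk[, , 1]
  egg_image(px, mk > 0.5)
}
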