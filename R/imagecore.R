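#' Luminance image with visual-field geometry
#'
#' The universal input container of the package: a 2-D field of luminance
#' values in \[0, 1\] together with the geometry that relates pixels to the
#' visual field — a pixels-per-degree scale and a fixation point.  All
#' downstream machinery (pooling, encoding, synthesis) is defined in degrees
#' of visual angle and reaches the pixel grid through this container.
#'
#' Coordinates are 0-based `(row, col)` with pixel centers at integer
#' coordinates; the fixation may be fractional and may lie outside the
#' image (flagged in the `fixation_inside` attribute).
#'
#' @param pixels numeric matrix of luminance values in \[0, 1\].
#' @param ppd pixels per degree of visual angle (> 0).
#' @param fixation numeric length-2, 0-based `(row, col)` fixation point.
#' @param color_planes optional original 3-plane array kept for per-channel
#'   processing.
#' @param meta named list of provenance entries.
#' @return An object of class `lum_img`.
#' @export
lum_img <- function(pixels, ppd, fixation = (dim(pixels) - 1) / 2,
                    color_planes = NULL, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("luminance values must lie in [0, 1]; convert with to_luminance()",
         call. = FALSE)
  pixels <- pmin(pmax(pixels, 0), 1)
  if (!is.numeric(ppd) || length(ppd) != 1L || !is.finite(ppd) || ppd <= 0)
    stop("`ppd` (pixels per degree) must be a single positive number",
         call. = FALSE)
  if (length(fixation) != 2L || any(!is.finite(fixation)))
    stop("`fixation` must be a finite (row, col) pair", call. = FALSE)
  inside <- fixation[1] >= 0 && fixation[1] <= nrow(pixels) - 1 &&
    fixation[2] >= 0 && fixation[2] <= ncol(pixels) - 1
  structure(list(pixels = pixels, ppd = ppd,
                 fixation = as.numeric(fixation),
                 color_planes = color_planes,
                 fixation_inside = inside, meta = meta),
            class = "lum_img")
}

#' @export
print.lum_img <- function(x, ...) {
  cat(sprintf("<lum_img> %d x %d px, %.3g px/deg (%.2f x %.2f deg)\n",
              nrow(x$pixels), ncol(x$pixels), x$ppd,
              nrow(x$pixels) / x$ppd, ncol(x$pixels) / x$ppd))
  cat(sprintf("  fixation (row, col) = (%.2f, %.2f)%s\n",
              x$fixation[1], x$fixation[2],
              if (x$fixation_inside) "" else " [outside image]"))
  invisible(x)
}

#' Convert a raster to a luminance image
#'
#' Accepts a 1-plane matrix or a 3-plane RGB array.  Three-plane input is
#' collapsed by a weighted sum of the channels (Rec. 709 luma weights by
#' default); one-plane input passes through, rescaled from 8-bit or 16-bit
#' integer ranges to \[0, 1\] when needed.  The conversion weights are
#' recorded in the result's `meta$lum_weights` for provenance.  Applying the
#' function to an existing `lum_img` is a no-op (idempotence).
#'
#' @param raster matrix, 3-plane array, or `lum_img`.
#' @param ppd,fixation visual-field geometry (see [lum_img()]).
#' @param weights length-3 color weight triple, summing to 1.
#' @param keep_color keep the original planes in `color_planes`?
#' @return A [lum_img()].
#' @export
to_luminance <- function(raster, ppd, fixation = NULL,
                         weights = c(0.2126, 0.7152, 0.0722),
                         keep_color = FALSE) {
  if (inherits(raster, "lum_img")) return(raster)
  if (any(!is.finite(raster)))
    stop("raster contains non-finite values", call. = FALSE)
  if (length(weights) != 3L || any(weights < 0))
    stop("`weights` must be a non-negative triple", call. = FALSE)
  rescale <- function(m) {
    mx <- max(m)
    if (mx > 1) m / (if (mx > 255) 65535 else 255) else m
  }
  if (is.matrix(raster)) {
    plane <- rescale(raster)
    planes <- NULL
  } else if (is.array(raster) && length(dim(raster)) == 3L &&
             dim(raster)[3] %in% c(3L, 4L)) {
    a <- rescale(raster[, , 1:3, drop = FALSE])
    plane <- weights[1] * a[, , 1] + weights[2] * a[, , 2] +
      weights[3] * a[, , 3]
    plane <- plane / sum(weights)
    planes <- if (keep_color) a else NULL
  } else {
    stop("unsupported raster: need a matrix or a 3-plane array", call. = FALSE)
  }
  if (is.null(fixation)) fixation <- (dim(plane) - 1) / 2
  lum_img(plane, ppd = ppd, fixation = fixation, color_planes = planes,
          meta = list(lum_weights = weights))
}

#' Eccentricity map in degrees of visual angle
#'
#' Angular distance of every pixel from the fixation point: Euclidean pixel
#' distance divided by the pixels-per-degree scale.  Zero exactly at
#' fixation.
#'
#' @param image a [lum_img()].
#' @return numeric matrix of eccentricities (deg), same shape as the image.
#' @export
eccentricity_map <- function(image) {
  stopifnot(inherits(image, "lum_img"))
  if (is.null(image$ppd)) stop("image has no ppd scale", call. = FALSE)
  r <- (seq_len(nrow(image$pixels)) - 1) - image$fixation[1]
  c <- (seq_len(ncol(image$pixels)) - 1) - image$fixation[2]
  sqrt(outer(r^2, c^2, `+`)) / image$ppd
}

# Polar angle (radians, in (-pi, pi]) of every pixel about fixation.
# Internal companion of eccentricity_map used by the pooling lattice.
polar_angle_map <- function(image) {
  stopifnot(inherits(image, "lum_img"))
  r <- (seq_len(nrow(image$pixels)) - 1) - image$fixation[1]
  c <- (seq_len(ncol(image$pixels)) - 1) - image$fixation[2]
  atan2(outer(r, rep(1, length(c))), outer(rep(1, length(r)), c))
}

#' Read a raster image with its visual-field geometry
#'
#' Reads PNG or TIFF by extension.  Because neither format embeds
#' pixels-per-degree or fixation, the geometry is carried in a sidecar JSON
#' file `<path>.json` (written by [write_image()]); explicit `ppd` /
#' `fixation` arguments override the sidecar.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param ppd,fixation optional geometry overrides.
#' @param ... passed to [to_luminance()].
#' @return A [lum_img()].
#' @export
read_image <- function(path, ppd = NULL, fixation = NULL, ...) {
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    m <- jsonlite::read_json(side, simplifyVector = TRUE)
    ppd <- ppd %||% m$ppd
    fixation <- fixation %||% m$fixation
  }
  if (is.null(ppd))
    stop("no ppd given and no sidecar JSON found for ", path, call. = FALSE)
  to_luminance(raster, ppd = ppd, fixation = fixation, ...)
}

#' Write a luminance image plus sidecar geometry JSON
#'
#' @param image a [lum_img()] (or plain matrix in \[0,1\]).
#' @param path output path (`.png` or `.tif`/`.tiff`).
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "lum_img")) image$pixels else image
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (inherits(image, "lum_img")) {
    jsonlite::write_json(list(ppd = image$ppd, fixation = image$fixation),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
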