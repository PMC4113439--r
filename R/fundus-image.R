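# internal constructor for rasters already known to be valid 8-bit integers
new_fundus_image <- function(pixels, eye_id) {
  structure(
    list(pixels = pixels, width = dim(pixels)[2], height = dim(pixels)[1],
         eye_id = as.character(eye_id)),
    class = "fundus_image")
}

#' Fundus image container
#'
#' An 8-bit RGB fundus photograph held as an integer array together with its
#' dimensions and an opaque eye identifier. Channel values are raw camera
#' output on the 0--255 scale; no gamma or white-balance correction is applied
#' at any point.
#'
#' @param pixels integer array `height x width x 3`, values in 0--255.
#' @param eye_id character scalar identifying the eye.
#' @return An object of class `fundus_image` with elements `pixels`, `width`,
#'   `height`, `eye_id`.
#' @export
fundus_image <- function(pixels, eye_id = "eye") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  if (any(pixels != round(pixels)))
    stop("channel values must be integers (8-bit)", call. = FALSE)
  storage.mode(pixels) <- "integer"
  new_fundus_image(pixels, eye_id)
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %s: %d x %d px, 8-bit RGB\n",
              x$eye_id, x$width, x$height))
  invisible(x)
}

#' Read a fundus photograph from disk
#'
#' Reads an 8-bit PNG, TIFF or JPEG image into a [fundus_image]. Grayscale
#' rasters are replicated across the three channels; an alpha channel is
#' dropped. Higher bit depths (16-bit PNG/TIFF, float TIFF) are rejected so
#' that the caller converts explicitly rather than silently losing the scale.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @param eye_id identifier stored in the result; defaults to the file stem.
#' @return A [fundus_image]; channel values are preserved bit-exactly for
#'   8-bit inputs.
#' @export
load_image <- function(path, eye_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(eye_id)) eye_id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = {
      img <- tryCatch(png::readPNG(path, info = TRUE),
                      error = function(e) stop("cannot read PNG '", path, "': ",
                                               conditionMessage(e), call. = FALSE))
      info <- attr(img, "info")
      if (!is.null(info$bit.depth) && info$bit.depth > 8L)
        stop("unsupported bit depth (", info$bit.depth,
             "-bit); pre-convert to 8-bit", call. = FALSE)
      img
    },
    tif = ,
    tiff = {
      img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                      error = function(e) stop("cannot read TIFF '", path, "': ",
                                               conditionMessage(e), call. = FALSE))
      bits <- attr(img, "bits.per.sample")
      fmt <- attr(img, "sample.format")
      if (!is.null(bits) && bits > 8L)
        stop("unsupported bit depth (", bits, "-bit); pre-convert to 8-bit",
             call. = FALSE)
      if (!is.null(fmt) && !identical(fmt, "uint"))
        stop("unsupported sample format '", fmt, "'; pre-convert to 8-bit uint",
             call. = FALSE)
      img
    },
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop("cannot read JPEG '", path, "': ",
                                             conditionMessage(e), call. = FALSE)),
    stop("unsupported image format '.", ext, "' (need PNG, TIFF or JPEG)",
         call. = FALSE)
  )
  # readers return values on [0,1]; for 8-bit input x/255 round-trips exactly
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))  # grayscale
  if (dim(raw)[3] == 2L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]  # gray+alpha
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  fundus_image(array(round(raw * 255), dim(raw)), eye_id = eye_id)
}

#' Write a fundus image as PNG
#'
#' @param image a [fundus_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(image, path) {
  stopifnot(inherits(image, "fundus_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Fovea and optic-disc landmarks
#'
#' Pixel coordinates of the fovea center and optic-disc center, 0-based, x
#' rightward and y downward. Both must lie inside the image and must differ.
#'
#' @param fovea,disc_center length-2 numeric `(x, y)` in pixels (0-based).
#' @param image optional [fundus_image]; when given, bounds are checked.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(fovea, disc_center, image = NULL) {
  fovea <- as.numeric(fovea); disc_center <- as.numeric(disc_center)
  stopifnot(length(fovea) == 2L, length(disc_center) == 2L)
  if (all(fovea == disc_center))
    stop("fovea and disc center coincide", call. = FALSE)
  if (!is.null(image)) {
    inb <- function(p) p[1] >= 0 && p[1] <= image$width - 1 &&
      p[2] >= 0 && p[2] <= image$height - 1
    if (!inb(fovea) || !inb(disc_center))
      stop("landmark outside image bounds", call. = FALSE)
  }
  structure(list(fovea = fovea, disc_center = disc_center),
            class = "landmarks")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Circular analysis region
#'
#' A disk of given diameter centered on an integer pixel. Pixel membership is
#' tested at pixel centers: pixel `(px, py)` (0-based) belongs to the ROI when
#' the Euclidean distance between its center and the center pixel's center is
#' at most `diameter / 2` (closed boundary). The whole disk must lie inside
#' the image.
#'
#' @param center length-2 integer `(x, y)`, 0-based pixel indices.
#' @param diameter disk diameter in pixels (> 0).
#' @param image a [fundus_image] used for the bounds check.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center, diameter, image) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2L, diameter > 0)
  if (any(center != round(center)))
    stop("ROI center must be an integer pixel", call. = FALSE)
  r <- diameter / 2
  cx <- center[1] + 0.5; cy <- center[2] + 0.5  # continuous center point
  if (cx - r < 0 || cx + r > image$width || cy - r < 0 || cy + r > image$height)
    stop(sprintf(
      "ROI (center %d,%d diameter %g) exceeds the %d x %d image bounds",
      center[1], center[2], diameter, image$width, image$height),
      call. = FALSE)
  structure(list(center = center, diameter = diameter), class = "circular_roi")
}

#' Default ROI between fovea and optic disc
#'
#' Places the analysis circle at the midpoint of the fovea--disc segment
#' (rounded half away from zero to the nearest integer pixel), with a default
#' diameter of 250 pixels. Midpoint placement keeps the region in the
#' fovea--macula area, away from the large retinal vessel arcades and the
#' disc conus.
#'
#' @param image a [fundus_image].
#' @param lm a [landmarks] object.
#' @param diameter disk diameter in pixels; default 250.
#' @return A [circular_roi]; errors if the disk does not fit in the image.
#' @export
default_roi <- function(image, lm, diameter = 250) {
  stopifnot(inherits(image, "fundus_image"), inherits(lm, "landmarks"))
  mid <- (lm$fovea + lm$disc_center) / 2
  circular_roi(round_half_away(mid), diameter, image)
}

#' Extract the pixels of a circular region
#'
#' Returns the RGB triplets of every pixel whose center lies within the ROI
#' disk, in row-major (y, then x) order.
#'
#' @param image a [fundus_image].
#' @param roi a [circular_roi].
#' @return Integer matrix with one row per pixel and columns `r`, `g`, `b`.
#' @export
roi_pixels <- function(image, roi) {
  stopifnot(inherits(image, "fundus_image"), inherits(roi, "circular_roi"))
  r <- roi$diameter / 2
  cx <- roi$center[1]; cy <- roi$center[2]
  # pixel centers are offset from the center pixel's center by integer steps,
  # so membership reduces to dx^2 + dy^2 <= r^2 over integer offsets
  span <- floor(r)
  xs <- (cx - span):(cx + span)
  ys <- (cy - span):(cy + span)
  xs <- xs[xs >= 0 & xs <= image$width - 1]
  ys <- ys[ys >= 0 & ys <= image$height - 1]
  dx2 <- (xs - cx)^2
  inside <- outer((ys - cy)^2, dx2, "+") <= r^2  # rows = y, cols = x
  idx <- which(inside, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # row-major
  idx <- idx[ord, , drop = FALSE]
  rows <- ys[idx[, 1L]] + 1L
  cols <- xs[idx[, 2L]] + 1L
  out <- cbind(r = image$pixels[cbind(rows, cols, 1L)],
               g = image$pixels[cbind(rows, cols, 2L)],
               b = image$pixels[cbind(rows, cols, 3L)])
  out
}

#' Per-channel summary statistics of ROI pixels
#'
#' Computes, for each of the red, green and blue channels, the mean, the
#' population standard deviation (divisor `n`, matching image-histogram
#' summaries), minimum, maximum, median (midpoint of the two central values
#' for even counts) and pixel count.
#'
#' @param pixels integer matrix as returned by [roi_pixels()].
#' @return A data frame of class `channel_stats` with rows `R`, `G`, `B` and
#'   columns `mean`, `sd`, `min`, `max`, `median`, `count`.
#' @export
channel_stats <- function(pixels) {
  if (is.null(dim(pixels)) || nrow(pixels) == 0L)
    stop("empty ROI: no pixels to summarize", call. = FALSE)
  n <- nrow(pixels)
  one <- function(v) {
    m <- mean(v)
    data.frame(mean = m,
               sd = sqrt(sum((v - m)^2) / n),  # population SD
               min = min(v), max = max(v),
               median = stats::median(v), count = n)
  }
  out <- rbind(R = one(pixels[, 1L]), G = one(pixels[, 2L]), B = one(pixels[, 3L]))
  class(out) <- c("channel_stats", "data.frame")
  out
}

#' Read a landmarks table
#'
#' The CSV must have the header
#' `eye_id,fovea_x,fovea_y,disc_x,disc_y` with 0-based integer pixel
#' coordinates.
#'
#' @param path CSV path.
#' @return A data frame with those five columns.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "fovea_x", "fovea_y", "disc_x", "disc_y")
  if (!identical(names(df), need))
    stop("landmarks CSV header must be exactly: ",
         paste(need, collapse = ","), call. = FALSE)
  df$eye_id <- as.character(df$eye_id)
  df
}

#' @rdname read_landmarks_csv
#' @param df landmarks data frame.
#' @export
write_landmarks_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
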