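#' 8-bit RGB image container
#'
#' Wraps an `height x width x 3` array of 8-bit digital numbers (DN, integers
#' in 0..255) as the package's raw-observation type. All segmentation
#' algorithms operate on this representation.
#'
#' @param x A three-dimensional numeric array with third dimension 3 (R, G, B)
#'   and integer values in `[0, 255]`.
#' @return An integer array of class `"rgb_image"`.
#' @examples
#' img <- rgb_image(array(c(50, 150, 50), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("an RGB image must be a height x width x 3 array", call. = FALSE)
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) {
    stop("an RGB image must have at least one pixel", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 255) || any(x != round(x))) {
    stop("channel values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  structure(x, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 8-bit RGB\n", d[1], d[2]))
  invisible(x)
}

#' Binary vegetation mask
#'
#' A logical `height x width` matrix labelling each pixel as vegetation
#' (`TRUE`) or background (`FALSE`). Every segmentation algorithm returns one,
#' and the synthetic generator uses one as ground truth.
#'
#' @param x A logical matrix (or a numeric matrix; any nonzero value is
#'   vegetation).
#' @return A logical matrix of class `"binary_mask"`.
#' @export
binary_mask <- function(x) {
  if (!is.matrix(x)) stop("a binary mask must be a matrix", call. = FALSE)
  if (anyNA(x)) stop("a binary mask may not contain missing values", call. = FALSE)
  m <- if (is.logical(x)) x else x != 0
  structure(m, class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d pixels, %.2f%% vegetation\n",
    nrow(x), ncol(x), 100 * mean(x)
  ))
  invisible(x)
}

# Decode a [0,1]-scaled raster array to 8-bit integers, rejecting anything
# that is not an 8-bit RGB(A) image.
decode_raster <- function(arr, path) {
  if (is.matrix(arr) || length(dim(arr)) == 2L) {
    stop(sprintf("'%s' is a single-channel (greyscale) image; an RGB image is required", path),
         call. = FALSE)
  }
  nc <- dim(arr)[3]
  if (nc == 2L) {
    stop(sprintf("'%s' is a greyscale+alpha image; an RGB image is required", path),
         call. = FALSE)
  }
  if (nc == 4L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] != 3L) {
    stop(sprintf("'%s' has %d channels; an RGB image is required", path, nc), call. = FALSE)
  }
  dn <- arr * 255
  if (max(abs(dn - round(dn))) > 1e-6) {
    stop(sprintf("'%s' is not an 8-bit-per-channel image", path), call. = FALSE)
  }
  rgb_image(round(dn))
}

#' Read an RGB photograph
#'
#' Reads a PNG, JPEG or TIFF raster as an 8-bit RGB image. An alpha channel is
#' silently dropped; greyscale and non-8-bit inputs are rejected rather than
#' guessed at.
#'
#' @param path Path to a PNG, JPEG or TIFF file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    decode_raster(png::readPNG(path), path)
  } else if (ext %in% c("jpg", "jpeg")) {
    decode_raster(jpeg::readJPEG(path), path)
  } else if (ext %in% c("tif", "tiff")) {
    decode_raster(tiff::readTIFF(path), path)
  } else {
    stop(sprintf("unsupported raster format '%s' (PNG, JPEG or TIFF expected)", ext),
         call. = FALSE)
  }
}

#' Write a binary mask as a single-band PNG
#'
#' Vegetation pixels are stored as 255, background as 0. [read_mask()] is the
#' tolerant inverse: any nonzero stored value reads back as vegetation.
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  mask <- binary_mask(unclass(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ok <- tryCatch({
    png::writePNG(m, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write mask to '%s'", path), call. = FALSE)
  invisible(NULL)
}

#' Read a binary mask from a PNG
#'
#' @param path Path to a mask PNG written by [write_mask()] (or any greyscale
#'   PNG; nonzero values are vegetation).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  binary_mask(arr > 0)
}

#' Fractional vegetation coverage of a mask
#'
#' FVC is the share of vegetation pixels in the frame, expressed as a
#' percentage: `FVC = X_i / X_j * 100` with `X_i` the vegetation-pixel count
#' and `X_j` the total pixel count.
#'
#' @param mask A [binary_mask()].
#' @param algorithm_id,image_id Optional identifiers carried into measurement
#'   tables.
#' @return A list of class `"fvc_measurement"` with elements `value` (percent),
#'   `vegetation_pixels`, `total_pixels`, `algorithm_id`, `image_id`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
#' compute_fvc(m)$value  # 25
#' @export
compute_fvc <- function(mask, algorithm_id = NA_character_, image_id = NA_character_) {
  if (!inherits(mask, "binary_mask")) mask <- binary_mask(mask)
  total <- length(mask)
  if (total < 1L) stop("cannot compute FVC of an empty mask", call. = FALSE)
  veg <- sum(mask)
  structure(
    list(
      # 100 * veg first: this order keeps the complement identity
      # fvc(m) + fvc(!m) == 100 exact in floating point
      value = 100 * veg / total,
      vegetation_pixels = as.integer(veg),
      total_pixels = as.integer(total),
      algorithm_id = algorithm_id,
      image_id = image_id
    ),
    class = "fvc_measurement"
  )
}

#' @export
print.fvc_measurement <- function(x, ...) {
  cat(sprintf(
    "FVC %.2f%% (%d / %d vegetation pixels)\n",
    x$value, x$vegetation_pixels, x$total_pixels
  ))
  invisible(x)
}
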