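# Image and mask I/O: PNG and TIFF in, 8-bit PNG masks and 32-bit float
# TIFF bias fields out.

#' Read a grayscale intensity image
#'
#' Reads an 8- or 16-bit PNG or TIFF, converts RGB to luminance with the
#' 0.2989/0.5870/0.1140 weights, drops any alpha channel, and returns
#' intensities rescaled to `[0, 1]` by the bit depth's full range.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Numeric matrix with values in `[0, 1]` and attribute
#'   `"bits_per_sample"` where the format reports it.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("I/O error: '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path, info = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(pages) > 1) {
      stop(sprintf("I/O error: '%s' is multi-page", path), call. = FALSE)
    }
    pages[[1]]
  } else {
    stop(sprintf("I/O error: '%s' is neither PNG nor TIFF", path),
         call. = FALSE)
  }
  info <- attr(img, "info")
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    img <- if (nch >= 3) {
      0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
    } else {
      img[, , 1]  # grey + alpha
    }
  }
  if (!is.matrix(img)) {
    stop(sprintf("I/O error: '%s' did not decode to a 2-D image", path),
         call. = FALSE)
  }
  out <- pmin(pmax(img, 0), 1)
  bits <- if (!is.null(info$bit.depth)) info$bit.depth
          else if (!is.null(info$bits.per.sample)) info$bits.per.sample
          else NA_integer_
  attr(out, "bits_per_sample") <- bits
  out
}

#' Write a binary mask as 8-bit PNG
#'
#' Foreground pixels become byte 255, background 0; the round trip through
#' [read_image()] is lossless.
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path (parent directory must exist).
#' @export
write_mask <- function(mask, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("I/O error: directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  }
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Write a bias field as 32-bit float TIFF
#'
#' 32-bit float TIFF storage is defined on `[0, 1]`, so the field is
#' min-max scaled before writing; the original `(min, max)` is returned
#' (and recorded in run reports) so the field can be restored exactly up
#' to float precision.
#'
#' @param bias Numeric matrix.
#' @param path Output path.
#' @return Invisibly, `c(min, max)` of the original field.
#' @export
write_bias <- function(bias, path) {
  rng <- range(bias)
  scaled <- if (diff(rng) > 0) (bias - rng[1]) / diff(rng)
            else matrix(0, nrow(bias), ncol(bias))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(rng)
}
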