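# Image data model and raster I/O.
#
# A ct_image is a plain numeric matrix (rows = image rows, origin top-left,
# 0-based patch coordinates throughout the package) together with the peak
# representable intensity. All quality metrics assume the [0, peak] domain
# with peak = 255, so 16-bit input is rescaled to 255 on read.

#' Construct a CT image object
#'
#' @param pixels Numeric matrix of intensities, rows = image rows (origin
#'   top-left).
#' @param peak Maximum representable intensity (default 255). PSNR/SSIM in
#'   this package are defined on the `[0, 255]` domain.
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(pixels, peak = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_input("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop_input("image must have height >= 1 and width >= 1")
  }
  if (!is.numeric(peak) || length(peak) != 1 || peak <= 0) {
    stop_input("peak must be a single positive number")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         peak = as.numeric(peak)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image %d x %d, peak %g, range [%.3f, %.3f]>\n",
              x$height, x$width, x$peak, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) c(x$height, x$width)

# Accept either a ct_image or a bare matrix wherever pixels are needed.
as_pixels <- function(img) {
  if (inherits(img, "ct_image")) img$pixels
  else if (is.matrix(img)) img
  else stop_input("expected a ct_image or a numeric matrix")
}

img_peak <- function(img) if (inherits(img, "ct_image")) img$peak else 255

#' Coerce a matrix to a ct_image
#' @param x Numeric matrix or ct_image.
#' @param peak Peak intensity for a bare matrix.
#' @return A `ct_image`.
#' @export
as_ct_image <- function(x, peak = 255) {
  if (inherits(x, "ct_image")) x else ct_image(x, peak = peak)
}

#' Read a grayscale PNG or TIFF raster as a CT image
#'
#' Multi-channel rasters are collapsed by luminance averaging of the first
#' three channels. 16-bit data are rescaled so that the maximum representable
#' code maps to 255; 8-bit data are read losslessly.
#'
#' @param path Path to a PNG or TIFF file.
#' @param bit_depth_hint Optional; unused for PNG/TIFF (depth is taken from
#'   the file), kept for interface stability.
#' @return A `ct_image` with `peak = 255`.
#' @export
read_ct_image <- function(path, bit_depth_hint = NULL) {
  if (!file.exists(path)) stop_input("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_input("unsupported raster format: .", ext, " (PNG/TIFF supported)")
  )
  if (length(dim(arr)) == 3) {
    nc <- min(dim(arr)[3], 3)                     # drop alpha, average RGB
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  if (length(arr) == 0) stop_input("zero-sized image: ", path)
  px <- arr * 255
  near <- abs(px - round(px)) < 1e-6              # snap 8-bit codes exactly
  px[near] <- round(px[near])
  ct_image(px, peak = 255)
}

#' Write a CT image as a PNG or TIFF raster
#'
#' Values are clipped to `[0, peak]` and quantized by round-half-up to the
#' requested bit depth.
#'
#' @param img A `ct_image` (or matrix).
#' @param path Output path ending in .png, .tif or .tiff.
#' @param bits Bits per sample, 8 (default) or 16.
#' @return Invisibly, the path.
#' @export
write_ct_image <- function(img, path, bits = 8) {
  if (!bits %in% c(8L, 16L)) stop_input("bits must be 8 or 16")
  px <- as_pixels(img)
  peak <- img_peak(img)
  maxcode <- 2^bits - 1
  q <- round_half_up(clip_range(px, 0, peak) / peak * maxcode) / maxcode
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(q, target = path),
      tif = ,
      tiff = tiff::writeTIFF(q, where = path, bits.per.sample = bits),
      stop_input("unsupported raster format: .", ext)
    )
    TRUE
  }, error = function(e) stop_input("cannot write image to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Affinely rescale intensities to the [0, peak] domain
#'
#' Maps `[lo, hi]` onto `[0, peak]`; values outside are clipped. Applying the
#' map twice with `(lo, hi) = (0, peak)` is the identity.
#'
#' @param img A `ct_image` or matrix.
#' @param lo,hi Source intensity window, `hi > lo`.
#' @return A `ct_image`.
#' @export
normalize_intensity <- function(img, lo = 0, hi = NULL) {
  peak <- img_peak(img)
  if (is.null(hi)) hi <- peak
  if (!(hi > lo)) stop_input("normalize_intensity: hi must be greater than lo")
  px <- (as_pixels(img) - lo) / (hi - lo) * peak
  ct_image(clip_range(px, 0, peak), peak = peak)
}

#' Display a CT image with ggplot2
#'
#' @param object A `ct_image`.
#' @param ... Unused.
#' @return A ggplot object (grayscale raster, origin top-left).
#' @exportS3Method ggplot2::autoplot
autoplot.ct_image <- function(object, ...) {
  px <- as_pixels(object)
  df <- data.frame(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    value = as.vector(px)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, img_peak(object))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "HU-like")
}
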