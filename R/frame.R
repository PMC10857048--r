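#' Construct a thermal frame
#'
#' A thermal frame is the atomic reading of an 8x8 infrared array sensor:
#' a grid of 64 pixel temperatures plus the device's scalar ambient
#' (thermistor) temperature and a timestamp.
#'
#' @param pixels numeric 8x8 matrix of pixel temperatures in degrees
#'   Celsius, or a length-64 vector which is reshaped row-major (the
#'   sensor's native scan order).
#' @param thermistor ambient temperature in degrees Celsius reported by
#'   the on-board thermistor, distinct from the pixel array.
#' @param timestamp acquisition time in seconds (any epoch); defaults to 0.
#'
#' @details Pixel and thermistor temperatures must lie within the sensor's
#'   operating range of \[-20, 80\] degrees Celsius.
#'
#' @return An object of class `thermal_frame`: a list with elements
#'   `pixels` (8x8 matrix), `thermistor` and `timestamp`.
#' @examples
#' fr <- thermal_frame(matrix(20, 8, 8), thermistor = 18)
#' mean(fr$pixels)
#' @export
thermal_frame <- function(pixels, thermistor, timestamp = 0) {
  if (is.vector(pixels) && length(pixels) == 64L) {
    pixels <- matrix(as.numeric(pixels), nrow = 8L, ncol = 8L, byrow = TRUE)
  }
  if (!is.matrix(pixels) || !identical(dim(pixels), c(8L, 8L))) {
    stop("'pixels' must be an 8x8 matrix or a length-64 vector", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(pixels < -20 | pixels > 80)) {
    stop("pixel temperatures must be finite and within [-20, 80] degrees C",
         call. = FALSE)
  }
  thermistor <- as.numeric(thermistor)
  if (length(thermistor) != 1L || is.na(thermistor) ||
      thermistor < -20 || thermistor > 80) {
    stop("'thermistor' must be a single temperature within [-20, 80] degrees C",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, thermistor = thermistor,
         timestamp = as.numeric(timestamp)),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat("<thermal_frame> 8x8 pixels, thermistor ",
      format(x$thermistor), " degC, t = ", format(x$timestamp), " s\n",
      sep = "")
  cat("  pixel range [", format(min(x$pixels)), ", ",
      format(max(x$pixels)), "] degC, mean ",
      format(mean(x$pixels)), " degC\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.thermal_frame <- function(x, ...) x$pixels

# Row-major flattening matching the sensor scan order and the CSV
# column layout p00..p63.
frame_to_row <- function(frame) as.vector(t(frame$pixels))
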