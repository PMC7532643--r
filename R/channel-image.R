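#' Two-dimensional fluorescence channel with micron calibration
#'
#' A `channel_image` couples a grid of nonnegative intensities with the
#' physical pixel size, so that every downstream distance (dilation radii,
#' distance bands, extravasation ranges) can be stated in micrometres.
#'
#' @param values Numeric matrix of nonnegative intensities. Rows index the
#'   vertical (y) direction, columns the horizontal (x) direction, origin at
#'   the top-left pixel.
#' @param pixel_size_um Positive scalar, physical size of one pixel in
#'   micrometres (pixels are assumed square and isotropic).
#'
#' @return An object of class `channel_image`: a list with elements `values`
#'   and `pixel_size_um`.
#' @examples
#' img <- channel_image(matrix(runif(64), 8, 8), pixel_size_um = 0.75)
#' img
#' @export
channel_image <- function(values, pixel_size_um) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (any(values < 0)) stop("`values` must be nonnegative", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  v <- x$values
  cat(sprintf("<channel_image> %d x %d px, %.4g um/px, intensity [%.4g, %.4g]\n",
              nrow(v), ncol(v), x$pixel_size_um, min(v), max(v)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$values)

# Accept either a channel_image or a bare matrix wherever intensities are needed.
.chan_values <- function(x, what = "image") {
  if (inherits(x, "channel_image")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("`%s` must be a channel_image or a numeric matrix", what),
       call. = FALSE)
}

.chan_pixel_size <- function(x, default = NULL) {
  if (inherits(x, "channel_image")) return(x$pixel_size_um)
  if (!is.null(default)) return(default)
  stop("pixel size unavailable: supply a channel_image or pixel_size_um",
       call. = FALSE)
}

.as_binary_matrix <- function(mask, what = "mask") {
  if (is.matrix(mask) && is.logical(mask)) return(mask)
  if (is.matrix(mask) && is.numeric(mask) && all(mask %in% c(0, 1))) {
    return(mask != 0)
  }
  stop(sprintf("`%s` must be a logical (binary) matrix", what), call. = FALSE)
}
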