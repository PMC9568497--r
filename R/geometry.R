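#' Screen geometry for pixel/degree conversion
#'
#' Describes the stimulus display: its extent in visual angle, the viewing
#' distance, and its pixel raster. Degrees are measured from the screen
#' center with +x rightward and +y upward; pixels use the image convention
#' (origin top-left, +y downward). The conversion between the two is a
#' linear (small-angle) mapping, appropriate for displays of this angular
#' size where stimulus extents are themselves specified as flat visual
#' angles.
#'
#' The default angular extent (18.4 x 13.8 deg at 75 cm) matches a typical
#' gaze-cueing video display; the default raster (1280 x 960) is an
#' arbitrary but isotropic choice (equal pixels per degree horizontally and
#' vertically) used by the synthetic-data generator.
#'
#' @param width_deg,height_deg Display extent in degrees of visual angle.
#' @param viewing_distance_cm Eye-to-screen distance in centimeters.
#' @param width_px,height_px Pixel raster of the display.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_per_degree(geom)
#' @export
screen_geometry <- function(width_deg = 18.4, height_deg = 13.8,
                            viewing_distance_cm = 75,
                            width_px = 1280, height_px = 960) {
  fields <- c(width_deg = width_deg, height_deg = height_deg,
              viewing_distance_cm = viewing_distance_cm,
              width_px = width_px, height_px = height_px)
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    stop("screen_geometry: all fields must be finite and > 0 (",
         paste(names(fields)[!is.finite(fields) | fields <= 0],
               collapse = ", "), ")",
         call. = FALSE)
  }
  structure(as.list(fields), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %.1f x %.1f deg, %d x %d px, %.0f cm\n",
              x$width_deg, x$height_deg, x$width_px, x$height_px,
              x$viewing_distance_cm))
  invisible(x)
}

#' Pixels per degree of a display
#'
#' @param geometry A [screen_geometry()].
#' @return Named vector with horizontal (`x`) and vertical (`y`) pixels per
#'   degree.
#' @export
pixels_per_degree <- function(geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  c(x = geometry$width_px / geometry$width_deg,
    y = geometry$height_px / geometry$height_deg)
}

#' Convert screen points between pixel and degree coordinates
#'
#' Pixel coordinates use the image convention (origin at the top-left
#' corner, +y downward); degree coordinates are centered on the screen with
#' +x rightward and +y upward. The mapping is linear and bijective, so
#' composing both directions returns the input.
#'
#' @param p A point, either a length-2 numeric `c(x, y)` or a two-column
#'   matrix / data.frame with columns x, y.
#' @param geometry A [screen_geometry()].
#' @param direction `"px_to_deg"` or `"deg_to_px"`.
#' @return Converted point(s), same shape as the input.
#' @examples
#' geom <- screen_geometry()
#' convert_point(c(640, 480), geom, "px_to_deg")  # screen center -> (0, 0)
#' @export
convert_point <- function(p, geometry, direction = c("px_to_deg", "deg_to_px")) {
  stopifnot(inherits(geometry, "screen_geometry"))
  direction <- match.arg(direction)
  vec_in <- is.null(dim(p))
  m <- if (vec_in) matrix(as.numeric(p), ncol = 2) else as.matrix(p)
  if (ncol(m) != 2) stop("convert_point: p must have two columns (x, y)", call. = FALSE)
  ppd <- pixels_per_degree(geometry)
  out <- m
  if (direction == "px_to_deg") {
    out[, 1] <- (m[, 1] - geometry$width_px / 2) / ppd["x"]
    out[, 2] <- (geometry$height_px / 2 - m[, 2]) / ppd["y"]
  } else {
    out[, 1] <- m[, 1] * ppd["x"] + geometry$width_px / 2
    out[, 2] <- geometry$height_px / 2 - m[, 2] * ppd["y"]
  }
  if (vec_in) c(x = out[1, 1], y = out[1, 2]) else out
}

#' Viewing distance implied by the angular size of a head
#'
#' Inverts the perspective relation between an object's physical size and
#' the visual angle it subtends: `distance = size / (2 * tan(angle / 2))`.
#' Used to translate the vertical angular size of a person's head in a
#' scene into the real-world distance at which a head of average adult
#' vertical length (0.24 m, chin to crown) would subtend that angle.
#'
#' @param head_vertical_angle_deg Subtended vertical visual angle, degrees.
#' @param head_length_m Physical vertical head length in meters.
#' @return Distance in meters.
#' @examples
#' head_angle_to_distance(0.4583)  # a distant pedestrian, ~30 m
#' @export
head_angle_to_distance <- function(head_vertical_angle_deg, head_length_m = 0.24) {
  if (any(head_vertical_angle_deg <= 0)) {
    stop("head_angle_to_distance: angle must be > 0", call. = FALSE)
  }
  if (any(head_vertical_angle_deg >= 180)) {
    stop("head_angle_to_distance: angle must be < 180 degrees", call. = FALSE)
  }
  head_length_m / (2 * tan(head_vertical_angle_deg * pi / 360))
}
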