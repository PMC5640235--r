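# Visual-angle geometry for a flat (tangent) screen.
#
# Conventions, applied everywhere: field coordinates are degrees of visual
# angle relative to the fixation point, x positive rightward, y positive
# superior; screen pixel origin is top-left with y increasing downward.
# Conversion between the two happens only in grid_pixel_positions().

#' Describe the physical screen and viewing geometry
#'
#' @param width_mm,height_mm physical screen size in mm.
#' @param resolution_x,resolution_y screen resolution in pixels.
#' @param distance_mm eye-to-screen distance in mm (cornea to screen centre).
#' @return object of class `screen_setup`.
#' @examples
#' screen_setup(535, 300, 1920, 1080, 370)
#' @export
screen_setup <- function(width_mm, height_mm, resolution_x, resolution_y,
                         distance_mm) {
  vals <- c(width_mm, height_mm, resolution_x, resolution_y, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_setup dimensions must be strictly positive")
  }
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         resolution_x = resolution_x, resolution_y = resolution_y,
         distance_mm = distance_mm),
    class = "screen_setup"
  )
}

#' @export
print.screen_setup <- function(x, ...) {
  cat(sprintf("<screen_setup> %g x %g mm, %d x %d px, viewed at %g mm\n",
              x$width_mm, x$height_mm, x$resolution_x, x$resolution_y,
              x$distance_mm))
  ext <- field_extent(x)
  cat(sprintf("  field: %.2f deg x %.2f deg (%.2f / %.2f px per deg)\n",
              ext$horizontal_deg, ext$vertical_deg,
              ext$px_per_deg_x, ext$px_per_deg_y))
  invisible(x)
}

#' Visual-field extension subtended by one screen dimension
#'
#' The angular extent of the patient's visual field occupied by a screen
#' side of length y viewed at distance x is `2 * atan(y / (2x))`, returned
#' in degrees.
#'
#' @param screen_side_mm screen width or height in mm.
#' @param distance_mm viewing distance in mm.
#' @return extension in degrees of arc (0, 180).
#' @examples
#' field_extension(535, 370) # 71.73 deg
#' @export
field_extension <- function(screen_side_mm, distance_mm) {
  if (any(screen_side_mm <= 0) || any(distance_mm <= 0)) {
    stop("screen side and distance must be strictly positive")
  }
  2 * atan(screen_side_mm / (2 * distance_mm)) * 180 / pi
}

#' Pixels per degree of visual angle
#'
#' @param resolution_px resolution along the axis, px.
#' @param extent_deg field extension along the axis, degrees.
#' @export
pixels_per_degree <- function(resolution_px, extent_deg) {
  if (any(resolution_px <= 0) || any(extent_deg <= 0)) {
    stop("resolution and extent must be strictly positive")
  }
  resolution_px / extent_deg
}

#' Full field extent of a screen setup
#'
#' @param screen a [screen_setup()].
#' @return object of class `field_extent` with `horizontal_deg`,
#'   `vertical_deg`, `px_per_deg_x`, `px_per_deg_y`.
#' @export
field_extent <- function(screen) {
  stopifnot(inherits(screen, "screen_setup"))
  h <- field_extension(screen$width_mm, screen$distance_mm)
  v <- field_extension(screen$height_mm, screen$distance_mm)
  structure(
    list(horizontal_deg = h, vertical_deg = v,
         px_per_deg_x = pixels_per_degree(screen$resolution_x, h),
         px_per_deg_y = pixels_per_degree(screen$resolution_y, v)),
    class = "field_extent"
  )
}

#' Sphericity-corrected on-screen offset of an eccentric location
#'
#' On a hemispherical perimeter bowl every stimulus is equidistant from the
#' eye; on a flat screen, equal steps of visual angle map to increasingly
#' large physical offsets. The physical distance from the fixation point of
#' a location at eccentricity beta (degrees) viewed from distance x mm is
#' `D = x * tan(beta)`, applied per axis.
#'
#' @param distance_mm viewing distance x, mm.
#' @param eccentricity_deg angular distance beta from fixation, degrees,
#'   `0 <= beta < 90`.
#' @return offset in mm from the fixation point.
#' @export
sphericity_correct <- function(distance_mm, eccentricity_deg) {
  if (any(distance_mm <= 0)) stop("distance must be strictly positive")
  if (any(eccentricity_deg < 0) || any(eccentricity_deg >= 90)) {
    stop("eccentricity must lie in [0, 90) degrees")
  }
  distance_mm * tan(eccentricity_deg * pi / 180)
}

#' Convert a physical offset on the screen to pixels
#'
#' `P = D * R / y` where D is the offset in mm, R the resolution and y the
#' physical screen side along the same axis.
#'
#' @param d_mm offset in mm.
#' @param resolution_px screen resolution along the axis.
#' @param screen_side_mm physical screen side along the axis, mm.
#' @export
mm_to_pixels <- function(d_mm, resolution_px, screen_side_mm) {
  if (any(resolution_px <= 0) || any(screen_side_mm <= 0)) {
    stop("resolution and screen side must be strictly positive")
  }
  d_mm * resolution_px / screen_side_mm
}

#' Generate the matrix-like stimulus grid
#'
#' Locations are spread uniformly in degrees of visual angle, arranged as an
#' `n_x` by `n_y` matrix centred on the fixation point, with
#' `n_axis = round(extent_axis / spacing_axis)`. On-screen pixel positions
#' (when a screen is supplied) are computed either linearly in degrees or
#' through the per-axis sphericity correction.
#'
#' @param extent a `field_extent`, or a numeric length-2 vector
#'   `c(horizontal_deg, vertical_deg)`.
#' @param spacing_x_deg,spacing_y_deg distance between neighbouring stimuli
#'   in degrees; must be positive and smaller than the extent.
#' @param fixation fixation-point field location `c(x_deg, y_deg)` relative
#'   to the screen centre; the grid is centred on it.
#' @param sphericity logical; use the tangent correction for pixel
#'   placement.
#' @param screen optional [screen_setup()]; when given, pixel coordinates
#'   `x_px`, `y_px` are attached to each location.
#' @return object of class `stimulus_grid`: a list with `locations` (data
#'   frame `index`, `x_deg`, `y_deg` and optionally `x_px`, `y_px`),
#'   `n_x`, `n_y`, the spacings and the `sphericity` flag.
#' @examples
#' g <- generate_grid(c(71.73, 44.41), 5.98, 5.52)
#' nrow(g$locations) # 96
#' @export
generate_grid <- function(extent, spacing_x_deg, spacing_y_deg,
                          fixation = c(0, 0), sphericity = FALSE,
                          screen = NULL) {
  if (inherits(extent, "field_extent")) {
    ext <- c(extent$horizontal_deg, extent$vertical_deg)
  } else {
    ext <- as.numeric(extent)
  }
  if (length(ext) != 2L || any(ext <= 0) || any(ext >= 180)) {
    stop("extent must give horizontal and vertical extensions in (0, 180)")
  }
  if (spacing_x_deg <= 0 || spacing_y_deg <= 0 ||
      spacing_x_deg > ext[1] || spacing_y_deg > ext[2]) {
    stop("spacings must be positive and no larger than the field extent")
  }
  n_x <- round(ext[1] / spacing_x_deg)
  n_y <- round(ext[2] / spacing_y_deg)
  if (n_x < 1 || n_y < 1) stop("grid would be empty")

  off_x <- (seq_len(n_x) - (n_x + 1) / 2) * spacing_x_deg
  off_y <- (seq_len(n_y) - (n_y + 1) / 2) * spacing_y_deg
  locs <- expand.grid(x_deg = fixation[1] + off_x,
                      y_deg = fixation[2] + off_y,
                      KEEP.OUT.ATTRS = FALSE)
  locs <- data.frame(index = seq_len(nrow(locs)), locs)

  grid <- structure(
    list(locations = locs, n_x = n_x, n_y = n_y,
         spacing_x_deg = spacing_x_deg, spacing_y_deg = spacing_y_deg,
         fixation = c(x_deg = fixation[1], y_deg = fixation[2]),
         sphericity = isTRUE(sphericity)),
    class = "stimulus_grid"
  )
  if (!is.null(screen)) {
    px <- grid_pixel_positions(grid, screen)
    grid$locations$x_px <- px$x_px
    grid$locations$y_px <- px$y_px
  }
  grid
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf(
    "<stimulus_grid> %d x %d = %d locations, spacing %.2f x %.2f deg%s\n",
    x$n_x, x$n_y, nrow(x$locations), x$spacing_x_deg, x$spacing_y_deg,
    if (x$sphericity) ", sphericity-corrected" else ""))
  invisible(x)
}

#' On-screen pixel positions of grid locations
#'
#' Degrees are measured from the fixation point; the fixation point itself
#' sits at the screen centre shifted by its own field offset (converted with
#' the same rule). With sphericity on, the per-axis offset in mm is
#' `distance * tan(deg)` converted via [mm_to_pixels()]; otherwise offsets
#' are linear in degrees at the screen's pixels-per-degree. Screen y grows
#' downward while field y grows upward, hence the sign flip.
#'
#' @param grid a `stimulus_grid`.
#' @param screen a [screen_setup()].
#' @return data frame `x_px`, `y_px` parallel to `grid$locations`.
#' @export
grid_pixel_positions <- function(grid, screen) {
  stopifnot(inherits(grid, "stimulus_grid"), inherits(screen, "screen_setup"))
  ext <- field_extent(screen)
  deg_to_px <- function(deg, res, side, ppd) {
    if (grid$sphericity) {
      sign(deg) * mm_to_pixels(
        sphericity_correct(screen$distance_mm, abs(deg)), res, side)
    } else {
      deg * ppd
    }
  }
  cx <- screen$resolution_x / 2
  cy <- screen$resolution_y / 2
  data.frame(
    x_px = cx + deg_to_px(grid$locations$x_deg, screen$resolution_x,
                          screen$width_mm, ext$px_per_deg_x),
    y_px = cy - deg_to_px(grid$locations$y_deg, screen$resolution_y,
                          screen$height_mm, ext$px_per_deg_y)
  )
}

#' Default assumed blind-spot location
#'
#' The physiological blind spot (optic disc) lies about 15 degrees temporal
#' and 3 degrees inferior to the fixation point: temporal means leftward for
#' the left eye and rightward for the right eye.
#'
#' @param eye `"left"` or `"right"`.
#' @return named numeric `c(x_deg, y_deg)`.
#' @export
default_blindspot <- function(eye = c("left", "right")) {
  eye <- match.arg(eye)
  c(x_deg = if (eye == "left") -15 else 15, y_deg = -3)
}

#' Export a grid as CSV
#'
#' Columns `index,x_deg,y_deg,x_px,y_px` (pixel columns NA when the grid was
#' built without a screen).
#' @param grid a `stimulus_grid`.
#' @param path output CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "stimulus_grid"))
  d <- grid$locations
  if (is.null(d$x_px)) d$x_px <- NA_real_
  if (is.null(d$y_px)) d$y_px <- NA_real_
  utils::write.csv(d[, c("index", "x_deg", "y_deg", "x_px", "y_px")],
                   path, row.names = FALSE)
  invisible(path)
}
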