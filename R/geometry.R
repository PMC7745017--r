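#' Scene geometry
#'
#' Reference frame for all pixel coordinates of a scene image. Coordinates are
#' 0-based with the origin at the top-left pixel, x increasing rightward and y
#' increasing downward. The scene centre is the midpoint of the inclusive
#' pixel range, `((width - 1) / 2, (height - 1) / 2)`.
#'
#' @param scene_id identifier of the scene (coerced to character).
#' @param width_px,height_px image dimensions in pixels (positive integers).
#' @param px_per_degree pixels per degree of visual angle; the default
#'   corresponds to an 800 px wide image subtending 25.78 degrees.
#'
#' @return An object of class `scene_geometry`: a list with elements
#'   `scene_id`, `width_px`, `height_px`, `centre` (length-2 numeric) and
#'   `px_per_degree`.
#' @export
#' @examples
#' g <- scene_geometry("scene_001", 800, 600)
#' g$centre # c(399.5, 299.5)
scene_geometry <- function(scene_id, width_px, height_px,
                           px_per_degree = DEFAULT_PX_PER_DEGREE) {
  stopifnot(length(width_px) == 1L, length(height_px) == 1L)
  if (width_px <= 0 || height_px <= 0)
    stop("image dimensions must be strictly positive")
  if (px_per_degree <= 0) stop("px_per_degree must be strictly positive")
  structure(
    list(scene_id = as.character(scene_id),
         width_px = as.integer(width_px),
         height_px = as.integer(height_px),
         centre = c((width_px - 1) / 2, (height_px - 1) / 2),
         px_per_degree = px_per_degree),
    class = "scene_geometry")
}

#' @exportS3Method base::print
print.scene_geometry <- function(x, ...) {
  cat(sprintf("<scene_geometry> %s: %d x %d px, centre (%.1f, %.1f), %.2f px/deg\n",
              x$scene_id, x$width_px, x$height_px,
              x$centre[1], x$centre[2], x$px_per_degree))
  invisible(x)
}

#' Anisotropic central-bias distance
#'
#' Distance of a region centre from the scene centre with the vertical
#' component down-weighted: `sqrt(dx^2 + (vertical_scale * dy)^2)`. The
#' default scaling of 0.45 reflects the wider horizontal spread of fixations
#' in scene viewing.
#'
#' @param region_centre numeric vector `c(x, y)` or a two-column matrix of
#'   region centres in pixels.
#' @param scene_centre numeric vector `c(x, y)`, the scene centre in pixels.
#' @param vertical_scale positive scaling factor applied to vertical
#'   distances before combining.
#'
#' @return Numeric vector of distances in pixels.
#' @export
#' @examples
#' central_bias(c(399.5, 199.5), c(399.5, 299.5)) # 45: dy = 100 scaled by 0.45
central_bias <- function(region_centre, scene_centre,
                         vertical_scale = DEFAULT_VERTICAL_SCALE) {
  if (vertical_scale <= 0) stop("vertical_scale must be strictly positive")
  if (is.matrix(region_centre)) {
    dx <- region_centre[, 1] - scene_centre[1]
    dy <- region_centre[, 2] - scene_centre[2]
  } else {
    dx <- region_centre[1] - scene_centre[1]
    dy <- region_centre[2] - scene_centre[2]
  }
  sqrt(dx^2 + (vertical_scale * dy)^2)
}

#' Logit and inverse logit
#'
#' Exact log-odds transforms used when converting fitted coefficients to
#' probabilities (e.g. a fitted intercept of -0.2278 corresponds to an
#' overall fixation probability of 0.44).
#'
#' @param p probability strictly inside (0, 1).
#' @param x value on the log-odds scale.
#' @return `logit` returns log-odds; `inverse_logit` returns probabilities.
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("logit is defined for probabilities in (0, 1)")
  qlogis(p)
}

#' @rdname logit
#' @export
inverse_logit <- function(x) plogis(x)
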